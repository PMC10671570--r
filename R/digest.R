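#' In-silico tryptic/LysC digestion
#'
#' Cleaves a protein sequence after every Lys (K) or Arg (R) — the combined
#' trypsin + LysC rule — and enumerates all peptides carrying up to
#' `max_missed` internal missed-cleavage sites.
#'
#' @param sequence A single uppercase amino-acid string.
#' @param max_missed Maximum number of internal uncleaved K/R sites per
#'   peptide (the open search behind this workflow allows up to 5).
#' @return A tibble with columns `peptide`, `start` (1-based position of the
#'   first residue in the protein), `missed_cleavages`.
#' @export
#' @examples
#' digest("AAKBBRCC", max_missed = 1)
digest <- function(sequence, max_missed = 5L) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop("sequence must be non-empty")
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  # fragment boundaries: after each K/R, plus the sequence end
  cut_after <- which(chars %in% c("K", "R"))
  ends <- unique(c(cut_after, n))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- starts <= n
  starts <- starts[keep]; ends <- ends[keep]
  n_frag <- length(starts)
  out <- vector("list", n_frag)
  for (i in seq_len(n_frag)) {
    j_max <- min(n_frag, i + max_missed)
    j <- i:j_max
    out[[i]] <- tibble::tibble(
      peptide = substring(sequence, starts[i], ends[j]),
      start = starts[i],
      missed_cleavages = j - i
    )
  }
  dplyr::bind_rows(out)
}
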