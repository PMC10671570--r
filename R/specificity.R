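#' Residue specificity profile of a delta-mass peak
#'
#' For the PSMs of one peak, computes the raw residue-type frequency of the
#' modified position (as a percentage of the peak's PSMs) and a
#' background-corrected score: the raw frequency minus the average
#' frequency of the same residue type at the three positions before and
#' the three after the modified position (offsets outside the peptide are
#' dropped from the average, not padded).
#'
#' @param peak_psms PSM tibble restricted to one peak; rows without a
#'   modified position are excluded (and counted in the `"n_excluded"`
#'   attribute).
#' @return Tibble: `residue`, `raw` (\%), `background` (\%), `corrected`
#'   (percentage points), covering the 20 standard residues. `raw` sums to
#'   100.
#' @export
residue_profile <- function(peak_psms) {
  aa <- strsplit(AA_ALPHABET, "")[[1]]
  excl <- sum(is.na(peak_psms$mod_pos))
  p <- peak_psms[!is.na(peak_psms$mod_pos), ]
  n <- nrow(p)
  if (n == 0) stop("no PSMs with a modified position")
  raw <- 100 * as.vector(table(factor(p$mod_residue, levels = aa))) / n
  # per-PSM flank indicator frequency, averaged over in-peptide offsets
  bg_mat <- matrix(0, n, 20, dimnames = list(NULL, aa))
  len <- nchar(p$peptide)
  for (i in seq_len(n)) {
    off <- p$mod_pos[i] + c(-3:-1, 1:3)
    off <- off[off >= 1 & off <= len[i]]
    if (length(off) == 0) next
    fl <- substring(p$peptide[i], off, off)
    bg_mat[i, ] <- as.vector(table(factor(fl, levels = aa))) / length(off)
  }
  bg <- 100 * colMeans(bg_mat)
  out <- tibble::tibble(residue = aa, raw = raw, background = unname(bg),
                        corrected = raw - unname(bg))
  attr(out, "n_excluded") <- excl
  attr(out, "n_psm") <- n
  out
}

#' Sequence-quintile profile of a delta-mass peak
#'
#' Splits each peptide into five equal-length sequence quintiles and
#' reports what percentage of the peak's PSMs place the modification in
#' each quintile. The quintile of position `pos` in a peptide of length
#' `L` is `floor(5 * (pos - 1) / L) + 1`, clamped to 5.
#'
#' @inheritParams residue_profile
#' @return Tibble: `quintile` (1..5), `freq` (\%, sums to 100).
#' @export
quintile_profile <- function(peak_psms) {
  p <- peak_psms[!is.na(peak_psms$mod_pos), ]
  if (nrow(p) == 0) stop("no PSMs with a modified position")
  q <- position_quintile(p$mod_pos, nchar(p$peptide))
  tibble::tibble(
    quintile = 1:5,
    freq = 100 * as.vector(table(factor(q, levels = 1:5))) / nrow(p))
}

#' Sequence quintile of a peptide position
#'
#' @param pos 1-based position(s) within the peptide.
#' @param len Peptide length(s).
#' @return Integer quintile(s) in 1..5.
#' @export
position_quintile <- function(pos, len) {
  pmin(5L, as.integer(floor(5 * (pos - 1) / len)) + 1L)
}

#' Classify a delta-mass peak as artefactual or biological
#'
#' Modifications introduced during sample preparation or fragmentation
#' concentrate on the newly generated peptide N-terminus: when more than
#' `q1_threshold` percent of a peak's PSMs fall in the first sequence
#' quintile, the peak is called artefactual. The test is computed over
#' PSMs whose peptide does not start at protein position 1, because a
#' first-quintile concentration on protein-N-terminal peptides (e.g.
#' N-terminal Met loss with acetylation) reflects protein biology, not an
#' artefact. Peaks with fewer than `min_psm` usable PSMs are `"unknown"`.
#'
#' @param peak_psms PSM tibble restricted to one peak, with `peptide_start`.
#' @param q1_threshold First-quintile percentage above which a peak is
#'   artefactual (default 70).
#' @param min_psm Minimum PSMs for a call.
#' @return One of `"artefactual"`, `"biological"`, `"unknown"`.
#' @export
classify_origin <- function(peak_psms, q1_threshold = 70, min_psm = 10L) {
  p <- peak_psms[!is.na(peak_psms$mod_pos), ]
  if (nrow(p) < min_psm) return("unknown")
  internal <- p[p$peptide_start > 1, ]
  # too few internal peptides to assess N-terminal concentration: the peak
  # lives on protein-N-terminal peptides, so the signal is biological
  if (nrow(internal) < min_psm) return("biological")
  q1 <- mean(position_quintile(internal$mod_pos,
                               nchar(internal$peptide)) == 1L) * 100
  if (q1 > q1_threshold) "artefactual" else "biological"
}

#' Specificity profiles for all peaks
#'
#' Convenience wrapper running [residue_profile()], [quintile_profile()]
#' and [classify_origin()] over every peak of an assigned PSM table.
#'
#' @param psms PSM tibble with a `peak_id` column.
#' @param peaks Peak tibble.
#' @param min_psm Minimum modified PSMs for residue/quintile profiles and
#'   origin calls.
#' @return A list of class `ptm_specificity`: `residues` (long tibble
#'   peak x residue), `quintiles` (long tibble peak x quintile), `origin`
#'   (tibble `peak_id`, `apex`, `n_psm`, `origin`).
#' @export
specificity_profiles <- function(psms, peaks, min_psm = 10L) {
  modded <- psms[!is.na(psms$mod_pos) & !is.na(psms$peak_id) &
                   !psms$is_decoy, ]
  by_peak <- split(modded, modded$peak_id)
  res <- list(); qn <- list(); org <- list()
  for (pid in names(by_peak)) {
    p <- by_peak[[pid]]
    call <- classify_origin(p, min_psm = min_psm)
    org[[pid]] <- tibble::tibble(
      peak_id = pid, apex = peaks$apex[match(pid, peaks$peak_id)],
      n_psm = nrow(p), origin = call)
    if (nrow(p) >= min_psm) {
      rp <- residue_profile(p); rp$peak_id <- pid
      qp <- quintile_profile(p); qp$peak_id <- pid
      res[[pid]] <- rp; qn[[pid]] <- qp
    }
  }
  structure(list(residues = dplyr::bind_rows(res),
                 quintiles = dplyr::bind_rows(qn),
                 origin = dplyr::bind_rows(org)),
            class = "ptm_specificity")
}
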