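#' Read an open-search PSM table
#'
#' Reads a tab-delimited peptide-spectrum-match table (one row per PSM) as
#' produced by an open-search engine and validates every row. Rows that
#' violate the PSM invariants (modified position outside the peptide,
#' residue mismatch, non-finite delta mass) are rejected, and the reasons
#' are attached to the result.
#'
#' @param path Path to a tab-separated file with a header.
#' @param dialect Named character vector mapping the canonical column names
#'   (`sample_id`, `scan_id`, `peptide`, `protein`, `peptide_start`,
#'   `delta_mass`, `mod_pos`, `mod_residue`, `score`, `is_decoy`,
#'   `missed_cleavages`) to the column names used in the file. Defaults to
#'   the identity mapping.
#' @param proteins Optional protein database tibble (see
#'   [read_protein_db()]); when given, each peptide is checked against the
#'   protein sequence at `peptide_start`.
#' @return A tibble of validated PSMs, one row per accepted PSM, with a
#'   `"rejected"` attribute holding a tibble of rejected row numbers and
#'   reasons.
#' @export
read_psm_table <- function(path, dialect = NULL, proteins = NULL) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  canonical <- c("sample_id", "scan_id", "peptide", "protein",
                 "peptide_start", "delta_mass", "mod_pos", "mod_residue",
                 "score", "is_decoy", "missed_cleavages")
  dialect <- if (is.null(dialect)) stats::setNames(canonical, canonical)
             else utils::modifyList(as.list(stats::setNames(canonical, canonical)),
                                    as.list(dialect)) |> unlist()
  missing <- setdiff(unname(dialect[canonical]), names(raw))
  if (length(missing) > 0)
    stop("PSM table is missing required column(s): ",
         paste(missing, collapse = ", "))
  psms <- tibble::tibble(
    sample_id = raw[[dialect[["sample_id"]]]],
    scan_id = raw[[dialect[["scan_id"]]]],
    peptide = toupper(raw[[dialect[["peptide"]]]]),
    protein = raw[[dialect[["protein"]]]],
    peptide_start = as.integer(raw[[dialect[["peptide_start"]]]]),
    delta_mass = as.numeric(raw[[dialect[["delta_mass"]]]]),
    mod_pos = suppressWarnings(as.integer(raw[[dialect[["mod_pos"]]]])),
    mod_residue = raw[[dialect[["mod_residue"]]]],
    score = as.numeric(raw[[dialect[["score"]]]]),
    is_decoy = as.logical(raw[[dialect[["is_decoy"]]]]),
    missed_cleavages = as.integer(raw[[dialect[["missed_cleavages"]]]])
  )
  # mod_pos 0 / NA and empty residue mean an unmodified PSM
  unmod <- is.na(psms$mod_pos) | psms$mod_pos == 0L
  psms$mod_pos[unmod] <- NA_integer_
  psms$mod_residue[unmod | is.na(psms$mod_residue) | psms$mod_residue == ""] <-
    NA_character_
  validate_psms(psms, proteins = proteins)
}

#' Validate PSM records
#'
#' Applies the PSM invariants and splits a PSM tibble into accepted rows
#' (returned) and rejected rows (attached as the `"rejected"` attribute,
#' with one reason per row).
#'
#' @param psms A PSM tibble.
#' @inheritParams read_psm_table
#' @return The accepted rows, with attribute `"rejected"`.
#' @export
validate_psms <- function(psms, proteins = NULL) {
  reason <- rep(NA_character_, nrow(psms))
  len <- nchar(psms$peptide)
  modded <- !is.na(psms$mod_pos)
  bad_pos <- modded & (psms$mod_pos < 1L | psms$mod_pos > len)
  reason[bad_pos] <- "mod_pos outside peptide"
  at <- ifelse(modded & !bad_pos,
               substr(psms$peptide, psms$mod_pos, psms$mod_pos), NA)
  bad_res <- modded & !bad_pos & !is.na(psms$mod_residue) &
    psms$mod_residue != at
  reason[bad_res] <- "mod_residue does not match peptide"
  bad_dm <- !is.finite(psms$delta_mass)
  reason[is.na(reason) & bad_dm] <- "delta_mass not finite"
  if (!is.null(proteins)) {
    seqs <- stats::setNames(proteins$sequence, proteins$accession)
    sub <- substr(seqs[psms$protein], psms$peptide_start,
                  psms$peptide_start + len - 1L)
    mism <- !is.na(sub) & sub != psms$peptide
    reason[is.na(reason) & mism] <- "peptide does not match protein sequence"
  }
  rejected <- tibble::tibble(row = which(!is.na(reason)),
                             reason = reason[!is.na(reason)])
  if (nrow(rejected) > 0)
    rlang::inform(paste0("rejected ", nrow(rejected), " PSM row(s): ",
                         paste(unique(rejected$reason), collapse = "; ")))
  out <- psms[is.na(reason), , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Write a PSM table
#'
#' @param psms A PSM tibble.
#' @param path Output path (tab-separated, header).
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  readr::write_tsv(psms, path, progress = FALSE)
  invisible(path)
}

#' Read a protein database from FASTA
#'
#' @param path Path to a FASTA file of protein sequences.
#' @param decoy_prefix Accession prefix marking decoy entries
#'   (default `"rev_"`).
#' @return A tibble with columns `accession`, `sequence`, `is_decoy`.
#' @export
read_protein_db <- function(path, decoy_prefix = "rev_") {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("read_protein_db() requires the Biostrings package")
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) stop("FASTA file is empty: ", path)
  acc <- sub("\\s.*$", "", names(aas))
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  tibble::tibble(
    accession = acc,
    sequence = toupper(as.character(aas)),
    is_decoy = startsWith(acc, decoy_prefix)
  )
}

#' Write a protein database to FASTA
#'
#' @param proteins A tibble with `accession` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_db <- function(proteins, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("write_protein_db() requires the Biostrings package")
  aas <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                 proteins$accession))
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}
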