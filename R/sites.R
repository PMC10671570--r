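#' Map modified PSMs to protein sites (qdna elements)
#'
#' Converts each modified, FDR-passing target PSM into its modified
#' protein site: protein `q`, delta-mass peak `d`, residue type `a`,
#' protein position `n = peptide_start + mod_pos - 1`. Different
#' peptidoforms (e.g. partial digestions) covering the same (q, d, a, n)
#' integrate into the same site; the same protein position carrying
#' different delta-mass peaks yields distinct sites. PSMs whose residue
#' does not match the protein sequence at `n` are rejected and logged;
#' decoy-protein PSMs are excluded.
#'
#' @param psms PSM tibble with `peak_id` (and `fdr_pass` if FDR has been
#'   run; rows failing it are dropped).
#' @param proteins Protein tibble from [read_protein_db()] or the
#'   simulator.
#' @return A tibble with one row per contributing PSM: `site_id` (
#'   `q:a n:d`), `protein`, `peak_id`, `residue`, `position`, `sample_id`,
#'   `scan_id`, `peptide`, `mod_at_cterm` (modified residue is the
#'   peptide's C-terminal residue). Attribute `"rejected"` counts
#'   residue-mismatch rejections.
#' @export
map_to_sites <- function(psms, proteins) {
  p <- psms[!is.na(psms$mod_pos) & !is.na(psms$peak_id) & !psms$is_decoy, ]
  if ("fdr_pass" %in% names(p)) p <- p[p$fdr_pass, ]
  decoy_acc <- proteins$accession[proteins$is_decoy]
  p <- p[!p$protein %in% decoy_acc, ]
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  pos <- p$peptide_start + p$mod_pos - 1L
  at <- substr(seqs[p$protein], pos, pos)
  ok <- !is.na(at) & at == p$mod_residue
  n_rej <- sum(!ok)
  if (n_rej > 0)
    rlang::inform(paste0("rejected ", n_rej,
                         " PSM(s): residue mismatch with protein sequence"))
  p <- p[ok, ]; pos <- pos[ok]
  out <- tibble::tibble(
    site_id = paste0(p$protein, ":", p$mod_residue, pos, ":", p$peak_id),
    protein = p$protein,
    peak_id = p$peak_id,
    residue = p$mod_residue,
    position = pos,
    sample_id = p$sample_id,
    scan_id = p$scan_id,
    peptide = p$peptide,
    mod_at_cterm = p$mod_pos == nchar(p$peptide))
  attr(out, "rejected") <- n_rej
  out
}

#' Partial-digestion filter for cleavage-blocking Lys modifications
#'
#' Bulky charge-switching Lys modifications (e.g. glycerophosphoryl-Lys)
#' block tryptic cleavage at the modified residue, so every genuine PSM of
#' such a site must be a partial digestion with the modified Lys internal.
#' PSMs whose modified residue sits at the peptide C-terminus are removed
#' for the designated peaks; sites losing all their PSMs disappear.
#'
#' @param site_psms Site-level PSM tibble from [map_to_sites()].
#' @param target_peaks Character vector of `peak_id`s subject to the
#'   filter (typically the pgK peak).
#' @return The filtered site-level PSM tibble.
#' @export
partial_digestion_filter <- function(site_psms, target_peaks) {
  drop <- site_psms$peak_id %in% target_peaks & site_psms$mod_at_cterm
  site_psms[!drop, , drop = FALSE]
}

#' Per-site per-sample PSM counts
#'
#' Aggregates site-level PSMs into the qdna count table behind
#' quantitation.
#'
#' @param site_psms Site-level PSM tibble from [map_to_sites()].
#' @param samples Optional character vector of all sample ids (so samples
#'   with zero counts appear as explicit zeros).
#' @return Long tibble: `site_id`, `protein`, `peak_id`, `residue`,
#'   `position`, `sample_id`, `n_psm`.
#' @export
site_counts <- function(site_psms, samples = NULL) {
  meta <- dplyr::distinct(site_psms, site_id, protein, peak_id, residue,
                          position)
  counts <- dplyr::count(site_psms, site_id, sample_id, name = "n_psm")
  if (is.null(samples)) samples <- sort(unique(site_psms$sample_id))
  full <- tidyr::expand_grid(site_id = meta$site_id, sample_id = samples) |>
    dplyr::left_join(counts, by = c("site_id", "sample_id")) |>
    dplyr::mutate(n_psm = dplyr::coalesce(n_psm, 0L))
  dplyr::left_join(meta, full, by = "site_id")
}

#' Per-protein per-sample PSM counts
#'
#' Protein-level spectral counts over all target PSMs (modified and
#' unmodified) passing FDR, the denominator level for protein-normalized
#' site quantitation.
#'
#' @param psms PSM tibble (with `fdr_pass` if FDR has been run).
#' @param proteins Protein tibble (decoy accessions are excluded).
#' @param samples Optional character vector of all sample ids.
#' @return Long tibble: `protein`, `sample_id`, `n_psm`.
#' @export
protein_counts <- function(psms, proteins, samples = NULL) {
  p <- psms[!psms$is_decoy, ]
  if ("fdr_pass" %in% names(p)) p <- p[p$fdr_pass, ]
  p <- p[!p$protein %in% proteins$accession[proteins$is_decoy], ]
  if (is.null(samples)) samples <- sort(unique(psms$sample_id))
  counts <- dplyr::count(p, protein, sample_id, name = "n_psm")
  tidyr::expand_grid(protein = unique(counts$protein),
                     sample_id = samples) |>
    dplyr::left_join(counts, by = c("protein", "sample_id")) |>
    dplyr::mutate(n_psm = dplyr::coalesce(n_psm, 0L))
}
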