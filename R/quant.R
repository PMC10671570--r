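#' Standardized spectral-count quantitation
#'
#' Builds the layered quantitation table used at both the protein (Zq) and
#' modified-site (Zqdna) levels: raw per-sample PSM counts are scaled by
#' the sample's total PSMs, log2-transformed against the per-element
#' median across all samples, and standardized per sample (z-score across
#' elements).
#'
#' @param counts Long tibble with columns `element` (or whatever
#'   `element_col` names), `sample_id`, `n_psm`.
#' @param element_col Name of the element identifier column (default
#'   `"element"`; `site_counts()` output uses `"site_id"`,
#'   `protein_counts()` uses `"protein"`).
#' @param sample_totals Optional named numeric of total PSMs per sample
#'   (the scaling denominator). Defaults to the per-sample sum of
#'   `counts`, but when quantifying a filtered subset pass the totals of
#'   the full table.
#' @param pseudocount Added to raw counts before scaling so zeros survive
#'   the log (default 0.5 PSM).
#' @return Tibble of class `ptm_quant`, one row per element x sample:
#'   `element`, `sample_id`, `n_psm`, `scaled`, `log2_ratio`, `z`. For
#'   every sample, `z` has mean 0 and SD 1 across elements.
#' @export
quantify <- function(counts, element_col = "element", sample_totals = NULL,
                     pseudocount = 0.5) {
  stopifnot(element_col %in% names(counts),
            all(c("sample_id", "n_psm") %in% names(counts)))
  x <- counts
  names(x)[names(x) == element_col] <- "element"
  x <- x[, c("element", "sample_id", "n_psm")]
  if (anyDuplicated(x[, c("element", "sample_id")]))
    stop("duplicate element x sample rows in counts")
  if (is.null(sample_totals)) {
    tt <- tapply(x$n_psm, x$sample_id, sum)
    sample_totals <- stats::setNames(as.numeric(tt), names(tt))
  }
  if (any(sample_totals <= 0)) stop("sample total PSM count is zero")
  x$scaled <- unname((x$n_psm + pseudocount) / sample_totals[x$sample_id])
  x <- x |>
    dplyr::group_by(element) |>
    dplyr::mutate(log2_ratio = log2(scaled / stats::median(scaled))) |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(z = {
      s <- stats::sd(log2_ratio)
      if (!is.finite(s) || s == 0)
        stop("zero variance across elements in sample ", sample_id[1])
      (log2_ratio - mean(log2_ratio)) / s
    }) |>
    dplyr::ungroup()
  class(x) <- c("ptm_quant", class(x))
  attr(x, "sample_totals") <- sample_totals
  x
}

#' Filter quantifiable elements
#'
#' Keeps elements whose PSM sum across all samples is strictly greater
#' than `min_total` (default 15, below which elements carry mostly 1-2
#' PSMs per sample) and, optionally, that are observed (count >= 1) in
#' every sample.
#'
#' @param counts Long count tibble (as for [quantify()]).
#' @inheritParams quantify
#' @param min_total Keep elements with total PSMs strictly above this.
#' @param require_all_samples Require a nonzero count in every sample.
#' @return The filtered count tibble (same columns).
#' @export
filter_quantifiable <- function(counts, element_col = "element",
                                min_total = 15, require_all_samples = TRUE) {
  el <- counts[[element_col]]
  keep_tot <- tapply(counts$n_psm, el, sum) > min_total
  keep <- keep_tot[el]
  if (require_all_samples) {
    all_obs <- tapply(counts$n_psm, el, function(v) all(v >= 1))
    keep <- keep & all_obs[el]
  }
  counts[keep, , drop = FALSE]
}

#' Protein-normalized site quantitation (Zqdna)
#'
#' Subtracts each site's protein-level standardized quantity from the
#' site-level one, so that site changes are detected independently of
#' changes in the parent protein's abundance, then re-standardizes per
#' sample. Sites whose protein is absent from the protein matrix (e.g.
#' failed the quantifiability filter) are dropped and logged.
#'
#' @param site_quant `ptm_quant` tibble at site level (elements are
#'   `site_id`s).
#' @param protein_quant `ptm_quant` tibble at protein level (elements are
#'   protein accessions).
#' @param site_proteins Tibble mapping `element` (site_id) to `protein`;
#'   defaults to parsing the protein from the site_id prefix
#'   (`"protein:residue+position:peak"`).
#' @return The site `ptm_quant` tibble with added columns `z_protein` and
#'   `z_qdna` (protein-normalized, per-sample re-standardized).
#' @export
protein_normalize <- function(site_quant, protein_quant,
                              site_proteins = NULL) {
  if (is.null(site_proteins))
    site_proteins <- tibble::tibble(
      element = unique(site_quant$element),
      protein = sub(":.*$", "", unique(site_quant$element)))
  x <- dplyr::left_join(site_quant, site_proteins, by = "element")
  pz <- protein_quant[, c("element", "sample_id", "z")]
  names(pz) <- c("protein", "sample_id", "z_protein")
  x <- dplyr::left_join(x, pz, by = c("protein", "sample_id"))
  lost <- unique(x$element[is.na(x$z_protein)])
  if (length(lost) > 0)
    rlang::inform(paste0("dropped ", length(lost),
                         " site(s) without a quantified protein"))
  x <- x[!x$element %in% lost, ]
  x |>
    dplyr::mutate(z_qdna = z - z_protein) |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(z_qdna = (z_qdna - mean(z_qdna)) / stats::sd(z_qdna)) |>
    dplyr::ungroup()
}

#' Per-group averages and contrasts of a quantitation layer
#'
#' Arithmetic mean of a quantitation column over the replicates of each
#' group, plus the contrast of every group against the reference
#' (first) group.
#'
#' @param quant A `ptm_quant` tibble (or any tibble with `element`,
#'   `sample_id` and the value column).
#' @param design Tibble mapping `sample_id` to `group`.
#' @param value Name of the value column to average (default `"z_qdna"`
#'   falling back to `"z"`).
#' @param reference Reference group; defaults to the first level in
#'   `design`.
#' @return Tibble: `element`, `group`, `mean_value`, `contrast`
#'   (`mean_value` minus the element's reference-group mean).
#' @export
group_average <- function(quant, design, value = NULL, reference = NULL) {
  stopifnot(all(c("sample_id", "group") %in% names(design)))
  if (is.null(value))
    value <- if ("z_qdna" %in% names(quant)) "z_qdna" else "z"
  if (is.null(reference)) reference <- design$group[1]
  x <- dplyr::inner_join(quant, design, by = "sample_id")
  if (!all(unique(design$group) %in% x$group))
    stop("group without any quantified sample")
  out <- x |>
    dplyr::group_by(element, group) |>
    dplyr::summarise(mean_value = mean(.data[[value]]), .groups = "drop")
  ref <- out[out$group == reference, c("element", "mean_value")]
  names(ref)[2] <- "ref_value"
  dplyr::left_join(out, ref, by = "element") |>
    dplyr::mutate(contrast = mean_value - ref_value) |>
    dplyr::select(element, group, mean_value, contrast)
}
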