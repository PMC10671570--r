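#' Annotate delta-mass peaks against a modification catalog
#'
#' For each peak, lists every catalog entry whose monoisotopic mass lies
#' within `tol` of the peak apex, ranked by absolute mass error. Peaks with
#' no candidate are unknown — in open-search phosphoproteome data most of
#' the abundant delta masses are.
#'
#' @param peaks Peak tibble from [detect_peaks()] (or any tibble with
#'   `peak_id` and `apex`).
#' @param catalog Catalog tibble (see [default_catalog()]).
#' @param tol Matching tolerance (Da); the source data report delta masses
#'   to two decimals, so the default is 0.01.
#' @return A tibble with one row per (peak, candidate): `peak_id`, `apex`,
#'   `name`, `mono_mass`, `error`, `specificity`, `origin`. Unannotated
#'   peaks appear once with `name = NA`.
#' @export
annotate_peaks <- function(peaks, catalog = default_catalog(), tol = 0.01) {
  if (tol <= 0) stop("tol must be positive")
  validate_catalog(catalog)
  hits <- tidyr::expand_grid(
    peaks[, c("peak_id", "apex")],
    catalog[, c("name", "mono_mass", "specificity", "origin")]) |>
    dplyr::mutate(error = apex - mono_mass) |>
    dplyr::filter(abs(error) <= tol) |>
    dplyr::arrange(peak_id, abs(error), name)
  missed <- peaks[!peaks$peak_id %in% hits$peak_id, c("peak_id", "apex")]
  if (nrow(missed) > 0) {
    missed$name <- NA_character_
    missed$mono_mass <- NA_real_
    missed$specificity <- NA_character_
    missed$origin <- NA_character_
    missed$error <- NA_real_
    hits <- dplyr::bind_rows(hits, missed)
  }
  dplyr::arrange(hits, peak_id)
}

#' Decompose a delta mass into a composite of catalog modifications
#'
#' Exhaustively enumerates every multiset of at most `max_terms` catalog
#' entries plus up to `max_isotopes` C13 isotope spacings whose summed mass
#' lies within `tol` of the target, e.g. 79.97 + 0.98 = 80.95 Da
#' (phosphorylation plus deamidation). Results are ranked by absolute
#' error, then by fewer components, then by name.
#'
#' @param target Target delta mass (Da); losses are negative.
#' @param catalog Catalog tibble. The C13 spacing entry (if present) is
#'   removed from the combinatorial terms and handled by the isotope
#'   counter instead.
#' @param max_terms Maximum number of catalog entries per composite.
#' @param tol Mass tolerance (Da).
#' @param max_isotopes Maximum number of added C13 spacings.
#' @param isotope_spacing Mass of one C13 spacing (Da).
#' @param max_combinations Guard against combinatorial blow-up.
#' @return Tibble: `components` (terms joined by `+`), `n_terms`,
#'   `n_isotopes`, `mass` (composite sum), `error` (target - mass), ranked
#'   best first. Zero rows when nothing matches.
#' @export
decompose_composite <- function(target, catalog = default_catalog(),
                                max_terms = 2L, tol = 0.005,
                                max_isotopes = 1L,
                                isotope_spacing = 1.003355,
                                max_combinations = 2e6) {
  if (max_terms < 1) stop("max_terms must be >= 1")
  validate_catalog(catalog)
  cat2 <- catalog[abs(catalog$mono_mass - isotope_spacing) > 1e-6, ]
  if (nrow(cat2) == 0) stop("catalog has no non-isotope entries")
  n <- nrow(cat2)
  n_comb <- sum(choose(n + seq_len(max_terms) - 1, seq_len(max_terms))) *
    (max_isotopes + 1)
  if (n_comb > max_combinations)
    stop("combinatorial bound exceeded (", format(n_comb, big.mark = ","),
         " candidates); reduce max_terms or the catalog")
  combos <- multisets_upto(n, max_terms)
  masses <- vapply(combos, function(ix) sum(cat2$mono_mass[ix]), 0)
  res <- list()
  for (k in 0:max_isotopes) {
    err <- target - (masses + k * isotope_spacing)
    hit <- which(abs(err) <= tol)
    if (length(hit) == 0) next
    res[[length(res) + 1L]] <- tibble::tibble(
      components = vapply(combos[hit], function(ix)
        paste(sort(cat2$name[ix]), collapse = " + "), ""),
      n_terms = lengths(combos[hit]),
      n_isotopes = k,
      mass = masses[hit] + k * isotope_spacing,
      error = err[hit])
  }
  if (length(res) == 0)
    return(tibble::tibble(components = character(), n_terms = integer(),
                          n_isotopes = integer(), mass = numeric(),
                          error = numeric()))
  dplyr::bind_rows(res) |>
    dplyr::arrange(abs(error), n_terms + n_isotopes, components)
}

# All multisets of 1..k indices from 1..n (non-decreasing index tuples).
multisets_upto <- function(n, k) {
  grow <- function(prefix, lo, depth) {
    out <- list()
    for (i in lo:n) {
      tup <- c(prefix, i)
      out <- c(out, list(tup))
      if (depth < k) out <- c(out, grow(tup, i, depth + 1L))
    }
    out
  }
  grow(integer(0), 1L, 1L)
}

#' Map C13 isotope satellite peaks to their parent peaks
#'
#' A peak B is a satellite of peak A when its apex sits k isotope spacings
#' above A's apex (k = 1..3) within `tol`, and A has the larger PSM count.
#' The isotopic envelope of a peptide population thus collapses onto its
#' monoisotopic peak (e.g. 1.003/2.006/3.009 Da onto 0, or 80.97/81.97 onto
#' the 79.97 phosphorylation peak).
#'
#' @param peaks Peak tibble.
#' @param spacing C13 spacing (Da).
#' @param tol Matching tolerance (Da).
#' @param max_k Maximum number of spacings.
#' @return Tibble: `satellite` (peak_id), `parent` (peak_id), `k`. When a
#'   satellite matches several parents the closest (smallest apex
#'   mismatch) wins.
#' @export
collapse_isotopes <- function(peaks, spacing = 1.003355, tol = 0.005,
                              max_k = 3L) {
  if (nrow(peaks) < 2)
    return(tibble::tibble(satellite = character(), parent = character(),
                          k = integer()))
  cand <- tidyr::expand_grid(
    sat = seq_len(nrow(peaks)), par = seq_len(nrow(peaks)),
    k = seq_len(max_k)) |>
    dplyr::filter(sat != par) |>
    dplyr::mutate(
      mismatch = abs(peaks$apex[sat] - peaks$apex[par] - k * spacing)) |>
    dplyr::filter(mismatch <= tol,
                  peaks$psm_count[par] > peaks$psm_count[sat]) |>
    dplyr::arrange(sat, mismatch) |>
    dplyr::distinct(sat, .keep_all = TRUE)
  tibble::tibble(satellite = peaks$peak_id[cand$sat],
                 parent = peaks$peak_id[cand$par],
                 k = as.integer(cand$k))
}
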