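#' Recalibrate delta-mass values per sample
#'
#' Open-search delta masses carry small per-sample systematic offsets. The
#' unmodified PSM population (|delta mass| below `anchor_window`) is used as
#' an internal anchor: its per-sample median is subtracted from every delta
#' mass of that sample. Samples with fewer than `min_anchor` anchor PSMs
#' are left uncorrected with a warning.
#'
#' @param psms PSM tibble (see [read_psm_table()]).
#' @param anchor_window Half-width (Da) of the window around zero defining
#'   the unmodified anchor population.
#' @param min_anchor Minimum anchor PSMs per sample required to correct.
#' @return The PSM tibble with corrected `delta_mass` and a `"correction"`
#'   attribute (tibble: `sample_id`, `n_anchor`, `offset`).
#' @export
recalibrate <- function(psms, anchor_window = 0.05, min_anchor = 50L) {
  corr <- psms |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(
      n_anchor = sum(abs(delta_mass) < anchor_window),
      offset = if (sum(abs(delta_mass) < anchor_window) >= min_anchor)
        stats::median(delta_mass[abs(delta_mass) < anchor_window]) else 0,
      .groups = "drop")
  if (any(corr$n_anchor < min_anchor))
    warning("too few anchor PSMs in sample(s) ",
            paste(corr$sample_id[corr$n_anchor < min_anchor],
                  collapse = ", "), "; no correction applied there")
  out <- psms |>
    dplyr::left_join(corr[, c("sample_id", "offset")], by = "sample_id") |>
    dplyr::mutate(delta_mass = delta_mass - offset) |>
    dplyr::select(-offset)
  attr(out, "correction") <- corr
  out
}

#' Detect peaks in the delta-mass distribution
#'
#' Smooths the delta-mass values with a Gaussian kernel density, takes
#' local maxima as peak apexes and the flanking local minima as peak
#' boundaries, and keeps peaks supported by at least `min_psm` PSMs. The
#' reported apex is the mean delta mass of the member PSMs. Peaks are
#' non-overlapping by construction (boundaries are shared minima).
#'
#' @param psms Recalibrated PSM tibble.
#' @param bandwidth Gaussian kernel bandwidth (Da).
#' @param min_psm Minimum supporting PSMs per peak.
#' @param grid_n Number of density grid points (power of two; the grid must
#'   be finer than `bandwidth` across the delta-mass range).
#' @return Tibble of class `ptm_peaks`: `peak_id`, `apex`, `left`, `right`,
#'   `psm_count`.
#' @export
detect_peaks <- function(psms, bandwidth = 0.005, min_psm = 5L,
                         grid_n = 2^20) {
  x <- psms$delta_mass
  if (length(x) == 0)
    return(empty_peaks())
  rng <- range(x)
  d <- stats::density(x, bw = bandwidth, n = grid_n,
                      from = rng[1] - 4 * bandwidth,
                      to = rng[2] + 4 * bandwidth)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  is_min <- c(TRUE, y[2:(n - 1)] < y[1:(n - 2)] &
                y[2:(n - 1)] <= y[3:n], TRUE)
  max_idx <- which(is_max)
  min_idx <- which(is_min)
  if (length(max_idx) == 0) return(empty_peaks())
  # interval between consecutive minima containing each maximum / PSM
  xmins <- d$x[min_idx]
  iv_max <- findInterval(d$x[max_idx], xmins)
  if (anyDuplicated(iv_max)) {  # plateau: keep the highest maximum per interval
    o <- order(iv_max, -y[max_idx])
    keep1 <- !duplicated(iv_max[o])
    max_idx <- max_idx[o][keep1]
    iv_max <- iv_max[o][keep1]
  }
  left <- xmins[iv_max]
  right <- xmins[iv_max + 1L]
  iv_psm <- findInterval(x, xmins)
  counts <- tabulate(iv_psm, nbins = length(xmins))[iv_max]
  keep <- counts >= min_psm
  sums <- vapply(split(x, factor(iv_psm, levels = iv_max)), sum, 0)
  apex <- unname(sums) / pmax(counts, 1L)
  out <- tibble::tibble(
    peak_id = sprintf("pk_%04d", seq_len(sum(keep))),
    apex = apex[keep], left = left[keep], right = right[keep],
    psm_count = as.integer(counts[keep]))
  class(out) <- c("ptm_peaks", class(out))
  out
}

empty_peaks <- function() {
  out <- tibble::tibble(peak_id = character(), apex = numeric(),
                        left = numeric(), right = numeric(),
                        psm_count = integer())
  class(out) <- c("ptm_peaks", class(out))
  out
}

#' Assign PSMs to delta-mass peaks
#'
#' Each PSM whose delta mass falls inside a peak's `[left, right]` window
#' receives that peak's id; delta masses outside every window are left
#' unassigned (`NA`).
#'
#' @param psms PSM tibble.
#' @param peaks Peak tibble from [detect_peaks()].
#' @return The PSM tibble with an added `peak_id` column.
#' @export
assign_to_peaks <- function(psms, peaks) {
  if (nrow(peaks) > 1) {
    o <- order(peaks$left)
    if (any(peaks$left[o][-1] < peaks$right[o][-nrow(peaks)]))
      stop("internal error: overlapping peaks")
  }
  psms$peak_id <- NA_character_
  if (nrow(peaks) > 0) {
    o <- order(peaks$left)
    idx <- findInterval(psms$delta_mass, peaks$left[o])
    ok <- idx >= 1 & idx <= nrow(peaks)
    inside <- ok & psms$delta_mass <= peaks$right[o][pmax(idx, 1L)]
    psms$peak_id[inside] <- peaks$peak_id[o][idx[inside]]
  }
  psms
}

#' Target-decoy FDR filtering at global, local and peak levels
#'
#' Computes a q-value for every PSM in three strata — globally, within
#' 1-Da delta-mass bins, and within the assigned delta-mass peak — by
#' target-decoy estimation `FDR(s) = #decoys(score >= s) / #targets(score
#' >= s)`, monotonized into q-values by a cumulative minimum from the
#' score-sorted tail. Ties in score rank decoys above targets
#' (conservative). A PSM passes when all three q-values are at or below
#' `threshold`. PSMs without a peak assignment form their own peak-level
#' stratum.
#'
#' @param psms PSM tibble with a `peak_id` column (see
#'   [assign_to_peaks()]).
#' @param threshold q-value threshold (default 0.01, i.e. 1\% FDR).
#' @return The PSM tibble with columns `q_global`, `q_local`, `q_peak`,
#'   `fdr_pass` (targets only; decoys get their q-values but `fdr_pass =
#'   FALSE`), plus a `"strata"` attribute with per-stratum target/decoy
#'   counts.
#' @export
fdr_filter <- function(psms, threshold = 0.01) {
  if (!"peak_id" %in% names(psms))
    stop("psms must carry a peak_id column; run assign_to_peaks() first")
  if (sum(psms$is_decoy) == 0)
    warning("no decoy PSMs: all q-values are 0")
  bin <- round(psms$delta_mass)
  peak_stratum <- dplyr::coalesce(psms$peak_id, "unassigned")
  psms$q_global <- qvalues_stratified(psms$score, psms$is_decoy,
                                      rep("all", nrow(psms)))
  psms$q_local <- qvalues_stratified(psms$score, psms$is_decoy, bin)
  psms$q_peak <- qvalues_stratified(psms$score, psms$is_decoy, peak_stratum)
  psms$fdr_pass <- !psms$is_decoy &
    psms$q_global <= threshold & psms$q_local <= threshold &
    psms$q_peak <= threshold
  attr(psms, "strata") <- tibble::tibble(stratum = peak_stratum,
                                         is_decoy = psms$is_decoy) |>
    dplyr::count(stratum, is_decoy) |>
    tidyr::pivot_wider(names_from = is_decoy, values_from = n,
                       values_fill = 0L,
                       names_prefix = "decoy_")
  psms
}

# q-values per stratum: FDR(s) = #decoys(>= s)/#targets(>= s), ties decoy
# first, monotonized by cumulative minimum from the tail.
qvalues_stratified <- function(score, is_decoy, stratum) {
  q <- numeric(length(score))
  for (st in split(seq_along(score), stratum)) {
    o <- st[order(-score[st], !is_decoy[st])]
    dec_cum <- cumsum(is_decoy[o])
    tgt_cum <- cumsum(!is_decoy[o])
    fdr <- dec_cum / pmax(tgt_cum, 1L)
    q[o] <- rev(cummin(rev(pmin(fdr, 1))))
  }
  q
}
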