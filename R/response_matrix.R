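#' Simulate a site-response quantitation matrix
#'
#' Generates standardized site profiles over a grouped sample design with
#' two planted anti-correlated response modules riding on a flat
#' background: module sites follow the treatment pattern (scaled by a
#' per-animal severity factor) with opposite signs, background sites are
#' pure noise. This is the matrix-level counterpart of the full PSM
#' simulation, used to study the correlation-network clustering stage in
#' isolation.
#'
#' @param n_up,n_down,n_background Sites per class (default 20/20/10, a
#'   50-site matrix).
#' @param effect Response magnitude in log2 units (default 1).
#' @param noise_sd Per-observation Gaussian noise SD in log2 units
#'   (default 0.2, the counting precision of a well-quantified site).
#' @param effect_sample_sd SD of the per-animal severity factor.
#' @param groups,replicates Sample design; the first group is the
#'   untreated reference (pattern 0), all others respond.
#' @param seed Integer seed.
#' @return Long tibble `element`, `sample_id`, `z` of class `ptm_quant`
#'   shape, with attributes `"modules"` (named list of up/down member ids)
#'   and `"design"` (sample/group tibble).
#' @export
simulate_response_matrix <- function(n_up = 20L, n_down = 20L,
                                     n_background = 10L, effect = 1,
                                     noise_sd = 0.2,
                                     effect_sample_sd = 0.25,
                                     groups = c("control", "HFD3", "HFD12"),
                                     replicates = 3L, seed = 1L) {
  set.seed(seed)
  design <- tidyr::expand_grid(group = groups,
                               rep = seq_len(replicates)) |>
    dplyr::mutate(sample_id = paste(group, rep, sep = "_")) |>
    dplyr::select(sample_id, group)
  n_s <- nrow(design)
  severity <- ifelse(design$group == groups[1], 0,
                     stats::rnorm(n_s, 1, effect_sample_sd))
  beta <- c(rep(effect, n_up), rep(-effect, n_down), rep(0, n_background))
  ids <- c(sprintf("up_%02d", seq_len(n_up)),
           sprintf("down_%02d", seq_len(n_down)),
           sprintf("bg_%02d", seq_len(n_background)))
  prof <- outer(beta, severity) +
    matrix(stats::rnorm(length(beta) * n_s, 0, noise_sd),
           nrow = length(beta))
  dimnames(prof) <- list(ids, design$sample_id)
  out <- tibble::as_tibble(prof, rownames = "element") |>
    tidyr::pivot_longer(-element, names_to = "sample_id",
                        values_to = "z")
  attr(out, "modules") <- list(up = ids[seq_len(n_up)],
                               down = ids[n_up + seq_len(n_down)])
  attr(out, "design") <- design
  out
}
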