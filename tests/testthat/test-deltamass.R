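make_shifted_psms <- function(n, delta, offset, sample = "s1", seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sample,
    scan_id = paste0(sample, "_", seq_len(n)),
    peptide = "ACDEFGHIK",
    protein = "P1",
    peptide_start = 1L,
    delta_mass = delta + offset,
    mod_pos = NA_integer_, mod_residue = NA_character_,
    score = stats::rnorm(n, 5), is_decoy = FALSE, missed_cleavages = 0L)
}

test_that("recalibration removes a constant per-sample offset exactly", {
  psms <- make_shifted_psms(200, rnorm(200, 0, 0.003), offset = 0.010)
  rc <- recalibrate(psms)
  anchors <- rc$delta_mass[abs(rc$delta_mass) < 0.05]
  expect_equal(median(anchors), 0, tolerance = 1e-9)
  expect_lt(abs(attr(rc, "correction")$offset - 0.010), 2e-3)
})

test_that("samples are recalibrated independently", {
  a <- make_shifted_psms(300, rnorm(300, 0, 0.003), 0.01, "a", seed = 2)
  b <- make_shifted_psms(300, rnorm(300, 0, 0.003), -0.02, "b", seed = 3)
  rc <- recalibrate(dplyr::bind_rows(a, b))
  corr <- attr(rc, "correction")
  expect_lt(abs(corr$offset[corr$sample_id == "a"] - 0.01), 2e-3)
  expect_lt(abs(corr$offset[corr$sample_id == "b"] + 0.02), 2e-3)
  # already-centred data: correction below noise_sd / sqrt(n)
  c0 <- make_shifted_psms(400, rnorm(400, 0, 0.003), 0, "c", seed = 4)
  corr0 <- attr(recalibrate(c0), "correction")
  expect_lt(abs(corr0$offset), 0.003 / sqrt(400) * 4)
})

test_that("too few anchors leave the sample uncorrected with a warning", {
  psms <- make_shifted_psms(20, rnorm(20, 0, 0.003), 0.01)
  expect_warning(rc <- recalibrate(psms), "too few anchor")
  expect_equal(rc$delta_mass, psms$delta_mass)
})

test_that("peak detection resolves known clusters", {
  set.seed(7)
  x <- c(rnorm(500, 0, 0.003), rnorm(500, 79.966, 0.003))
  psms <- make_shifted_psms(1000, x, 0)
  pk <- detect_peaks(psms)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$apex), c(0, 79.966), tolerance = 0.002 / 79)
  expect_true(all(pk$left < pk$apex & pk$apex < pk$right))
  # single cluster
  pk1 <- detect_peaks(make_shifted_psms(300, rnorm(300, 15.995, 0.003), 0))
  expect_equal(nrow(pk1), 1)
  # below min_psm no peak; empty input empty output
  pk0 <- detect_peaks(make_shifted_psms(3, rnorm(3, 0, 0.001), 0),
                      min_psm = 5)
  expect_equal(nrow(pk0), 0)
  expect_equal(nrow(detect_peaks(make_shifted_psms(0, numeric(0), 0))), 0)
})

test_that("peak assignment equals the brute-force oracle and partitions PSMs", {
  pl <- default_pipeline()
  psms <- pl$rc[sample.int(nrow(pl$rc), 1000), ]
  got <- assign_to_peaks(psms, pl$pk)$peak_id
  oracle <- vapply(psms$delta_mass, function(dm) {
    hit <- which(pl$pk$left <= dm & dm <= pl$pk$right)
    if (length(hit) == 0) NA_character_ else pl$pk$peak_id[hit[1]]
  }, "")
  expect_identical(got, oracle)
  # apex membership and window partition over the full set
  full <- assign_to_peaks(pl$rc, pl$pk)
  tab <- table(full$peak_id, useNA = "ifany")
  counted <- tab[pl$pk$peak_id]
  expect_equal(sum(counted) + sum(is.na(full$peak_id)), nrow(full))
  expect_equal(unname(counted), pl$pk$psm_count, ignore_attr = TRUE)
})

test_that("q-values match an independent threshold-sweep oracle", {
  set.seed(11)
  n <- 400
  psms <- tibble::tibble(
    sample_id = "s1", scan_id = paste0("x", 1:n), peptide = "ACDEFGHIK",
    protein = "P1", peptide_start = 1L,
    delta_mass = runif(n, -20, 20),
    mod_pos = NA_integer_, mod_residue = NA_character_,
    score = c(rnorm(n * 0.8, 6), rnorm(n * 0.2, 3)),
    is_decoy = c(rep(FALSE, n * 0.8), rep(TRUE, n * 0.2)),
    missed_cleavages = 0L)
  psms$peak_id <- NA_character_
  fd <- suppressWarnings(fdr_filter(psms))
  # oracle: FDR(s) = #decoys >= s over #targets >= s at every observed
  # score; q = minimum FDR over thresholds at or below the PSM's score
  fdr_at <- vapply(psms$score, function(s)
    sum(psms$is_decoy & psms$score >= s) /
      max(sum(!psms$is_decoy & psms$score >= s), 1), 0)
  q_oracle <- vapply(psms$score, function(s)
    min(pmin(fdr_at[psms$score <= s], 1)), 0)
  expect_equal(fd$q_global, q_oracle, tolerance = 1e-12)
  # q-values are monotone non-increasing in score
  o <- order(-fd$score)
  expect_true(all(diff(fd$q_global[o]) >= -1e-12))
})

test_that("score ties rank decoys above targets", {
  psms <- tibble::tibble(
    sample_id = "s1", scan_id = c("a", "b", "c"), peptide = "ACDEFGHIK",
    protein = "P1", peptide_start = 1L, delta_mass = 0,
    mod_pos = NA_integer_, mod_residue = NA_character_,
    score = c(5, 5, 4), is_decoy = c(FALSE, TRUE, FALSE),
    missed_cleavages = 0L, peak_id = NA_character_)
  fd <- fdr_filter(psms)
  # decoy at 5 precedes the tied target: FDR ranks are 1/1, 1/1, 1/2
  expect_equal(fd$q_global, c(0.5, 0.5, 0.5))
})

test_that("small worked example and the no-decoy edge case behave", {
  base <- tibble::tibble(
    sample_id = "s1", peptide = "ACDEFGHIK", protein = "P1",
    peptide_start = 1L, delta_mass = 0, mod_pos = NA_integer_,
    mod_residue = NA_character_, missed_cleavages = 0L,
    peak_id = NA_character_)
  psms <- dplyr::bind_rows(
    dplyr::mutate(base[rep(1, 4), ], scan_id = paste0("t", 1:4),
                  score = c(10, 9, 8, 7), is_decoy = FALSE),
    dplyr::mutate(base[rep(1, 2), ], scan_id = paste0("d", 1:2),
                  score = c(6, 5), is_decoy = TRUE))
  fd <- fdr_filter(psms)
  expect_equal(fd$q_global[!fd$is_decoy], rep(0, 4))
  expect_true(all(fd$fdr_pass[!fd$is_decoy]))
  # no decoys at all: every target passes, with a warning
  expect_warning(fd0 <- fdr_filter(psms[!psms$is_decoy, ]), "no decoy")
  expect_true(all(fd0$fdr_pass))
  expect_true(all(fd0$q_global == 0))
})
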