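toy_counts <- function(counts_matrix) {
  tibble::as_tibble(counts_matrix, rownames = "element") |>
    tidyr::pivot_longer(-element, names_to = "sample_id",
                        values_to = "n_psm")
}

test_that("median-referenced log2 ratios vanish for constant elements", {
  m <- rbind(e1 = c(10, 10, 10), e2 = c(5, 8, 20), e3 = c(30, 2, 7))
  colnames(m) <- c("a", "b", "c")
  q <- quantify(toy_counts(m),
                sample_totals = c(a = 100, b = 100, c = 100))
  expect_equal(q$log2_ratio[q$element == "e1"], rep(0, 3))
  # depth rescaling cancels: 10/1000 and 20/2000 give identical F, R = 0
  m2 <- rbind(e1 = c(10, 20), e2 = c(100, 250), e3 = c(50, 60))
  colnames(m2) <- c("a", "b")
  q2 <- quantify(toy_counts(m2), sample_totals = c(a = 1000, b = 2000),
                 pseudocount = 0)
  expect_equal(q2$scaled[q2$element == "e1"], c(0.01, 0.01))
  expect_equal(q2$log2_ratio[q2$element == "e1"], c(0, 0))
})

test_that("the standardized layer has zero mean and unit SD per sample", {
  pl <- default_pipeline()
  for (q in list(pl$qs, pl$qp)) {
    stats_by_sample <- q |>
      dplyr::group_by(sample_id) |>
      dplyr::summarise(m = mean(z), s = sd(z))
    expect_true(all(abs(stats_by_sample$m) < 1e-6))
    expect_true(all(abs(stats_by_sample$s - 1) < 1e-6))
  }
  # protein-normalized layer is re-standardized the same way
  zq <- pl$qn |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(m = mean(z_qdna), s = sd(z_qdna))
  expect_true(all(abs(zq$m) < 1e-6 & abs(zq$s - 1) < 1e-6))
})

test_that("degenerate inputs raise errors", {
  m <- rbind(e1 = c(10, 10), e2 = c(10, 10))
  colnames(m) <- c("a", "b")
  expect_error(quantify(toy_counts(m), sample_totals = c(a = 0, b = 10)),
               "zero")
  expect_error(quantify(toy_counts(m),
                        sample_totals = c(a = 100, b = 100)),
               "variance")
})

test_that("the quantifiability filter keeps sums strictly above 15", {
  m <- rbind(kept = rep(2, 9),       # sum 18
             border = c(rep(2, 6), 1, 1, 1),  # sum 15 exactly
             gap = c(0, rep(3, 8)))  # sum 24 but one missing sample
  colnames(m) <- paste0("s", 1:9)
  f <- filter_quantifiable(toy_counts(m))
  expect_setequal(unique(f$element), "kept")
  f2 <- filter_quantifiable(toy_counts(m), require_all_samples = FALSE)
  expect_setequal(unique(f2$element), c("kept", "gap"))
})

test_that("protein normalization cancels protein-level trends", {
  set.seed(51)
  # site counts exactly 10% of their protein's counts in every sample:
  # after normalization the site carries no signal of its own
  prot <- matrix(rpois(5 * 6, 200), nrow = 5,
                 dimnames = list(paste0("P", 1:5), paste0("s", 1:6)))
  site <- round(prot * 0.1)
  rownames(site) <- paste0("P", 1:5, ":S10:pk1")
  tot <- stats::setNames(rep(5000, 6), paste0("s", 1:6))
  qp <- quantify(toy_counts(prot), sample_totals = tot, pseudocount = 0)
  qs <- quantify(toy_counts(site), sample_totals = tot, pseudocount = 0)
  qn <- protein_normalize(qs, qp)
  raw_diff <- qn$z - qn$z_protein
  expect_lt(stats::sd(raw_diff), 0.25)  # rounding noise only
  # planted site-specific effects survive normalization with their sign
  pl <- default_pipeline()
  ps <- planted_elements(pl)
  ga <- group_average(pl$qn, pl$sim$design)
  hit <- dplyr::inner_join(ga[ga$group == "HFD12", ], ps,
                           by = "element")
  expect_gte(mean(sign(hit$contrast) ==
                    ifelse(hit$module == "up", 1, -1)), 0.9)
})

test_that("protein-level-only effects leave site Zqdna flat", {
  set.seed(52)
  samples <- paste0("s", 1:6)
  groupB <- samples[4:6]
  # protein doubles in group B; its site tracks it exactly; other elements flat
  prot <- rbind(
    P1 = c(rpois(3, 100), rpois(3, 200)),
    P2 = rpois(6, 150), P3 = rpois(6, 80), P4 = rpois(6, 120))
  colnames(prot) <- samples
  site <- round(prot * 0.2) + matrix(rpois(24, 2), 4)
  rownames(site) <- paste0(rownames(prot), ":S5:pk1")
  tot <- stats::setNames(rep(3000, 6), samples)
  qn <- protein_normalize(
    quantify(toy_counts(site), sample_totals = tot),
    quantify(toy_counts(prot), sample_totals = tot))
  x <- qn$z_qdna[qn$element == "P1:S5:pk1"]
  ks <- ks_two_sample(x[1:3], x[4:6])
  expect_gt(ks$p_value, 0.05)
})

test_that("group averages match an independent tally", {
  pl <- default_pipeline()
  ga <- group_average(pl$qn, pl$sim$design)
  # oracle for a handful of elements
  some <- unique(pl$qn$element)[1:5]
  x <- dplyr::inner_join(pl$qn, pl$sim$design, by = "sample_id")
  for (e in some) {
    for (g in unique(pl$sim$design$group)) {
      want <- mean(x$z_qdna[x$element == e & x$group == g])
      expect_equal(ga$mean_value[ga$element == e & ga$group == g], want)
    }
    expect_equal(ga$contrast[ga$element == e & ga$group == "control"], 0)
  }
  # identical replicates average to the replicate value
  d <- tibble::tibble(element = "e", sample_id = paste0("s", 1:4),
                      z = c(2, 2, 5, 5))
  des <- tibble::tibble(sample_id = paste0("s", 1:4),
                        group = c("g1", "g1", "g2", "g2"))
  out <- group_average(d, des, value = "z")
  expect_equal(out$mean_value, c(2, 5))
  expect_error(group_average(d[1:2, ], des, value = "z"), "group")
})
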