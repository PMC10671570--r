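test_that("correlation edges follow the r > 0.5 rule", {
  d <- tibble::tibble(
    element = rep(c("a", "b", "c"), each = 4),
    sample_id = rep(paste0("s", 1:4), 3),
    z = c(1, 2, 3, 4,   2, 4, 6, 8,   1, -1, 1, -1))
  net <- correlation_network(d, value = "z")
  expect_equal(nrow(net), 1)
  expect_equal(net$from, "a"); expect_equal(net$to, "b")
  expect_equal(net$weight, 1)
  # zero-variance sites are dropped with a message
  d2 <- dplyr::bind_rows(d, tibble::tibble(
    element = "flat", sample_id = paste0("s", 1:4), z = 1))
  expect_message(net2 <- correlation_network(d2, value = "z"), "zero-variance")
  expect_false("flat" %in% attr(net2, "nodes"))
})

test_that("the edge set equals a brute-force all-pairs recomputation", {
  rm0 <- simulate_response_matrix(seed = 6)
  net <- correlation_network(rm0, value = "z")
  wide <- tidyr::pivot_wider(rm0, names_from = sample_id, values_from = z)
  m <- as.matrix(wide[, -1]); rownames(m) <- wide$element
  want <- list()
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    r <- cor(m[i, ], m[j, ])
    if (r > 0.5) {
      a <- sort(c(rownames(m)[i], rownames(m)[j]))
      want[[length(want) + 1L]] <- tibble::tibble(
        from = a[1], to = a[2], weight = r)
    }
  }
  want <- dplyr::arrange(dplyr::bind_rows(want), from, to)
  expect_equal(net$from, want$from)
  expect_equal(net$to, want$to)
  expect_equal(net$weight, want$weight)
})

test_that("cohesiveness evaluates the ClusterONE objective", {
  clique5 <- make_clique_edges("v", 5)
  # W_in = 10, no boundary, penalty 2: f = 10 / (10 + 0 + 10) = 0.5
  expect_identical(cohesiveness(clique5, paste0("v", 1:5), penalty = 2), 0.5)
  # boundary edges count in the denominator
  edges <- dplyr::bind_rows(clique5, tibble::tibble(
    from = "v1", to = "w1", weight = 1))
  expect_equal(cohesiveness(edges, paste0("v", 1:5), penalty = 2),
               10 / (10 + 1 + 10))
})

test_that("two disjoint cliques are recovered exactly", {
  edges <- dplyr::bind_rows(make_clique_edges("a", 6),
                            make_clique_edges("b", 6))
  cl <- cluster_cohesive(edges)
  expect_equal(length(cl$clusters), 2)
  expect_setequal(cl$clusters[[1]], paste0(c("a"), 1:6))
  expect_setequal(cl$clusters[[2]], paste0(c("b"), 1:6))
  expect_true(all(glance(cl)$p_value < 0.05))
  expect_true(all(glance(cl)$size >= 5))
  # empty graph
  empty <- tibble::tibble(from = character(), to = character(),
                          weight = numeric())
  expect_equal(length(cluster_cohesive(empty)$clusters), 0)
})

test_that("planted anti-correlated response modules are recovered", {
  rm0 <- simulate_response_matrix(seed = 8)
  mods <- attr(rm0, "modules")
  design <- attr(rm0, "design")
  cl <- cluster_cohesive(correlation_network(rm0, value = "z"))
  j_up <- max(vapply(cl$clusters, jaccard, 0, b = mods$up), 0)
  j_dn <- max(vapply(cl$clusters, jaccard, 0, b = mods$down), 0)
  expect_gte(j_up, 0.7)
  expect_gte(j_dn, 0.7)
  # response signs match the planted directions
  ga <- group_average(rm0, design, value = "z")
  for (mem in cl$clusters) {
    s <- mean(ga$contrast[ga$group == "HFD12" & ga$element %in% mem])
    planted_dir <- if (jaccard(mem, mods$up) > jaccard(mem, mods$down))
      1 else -1
    expect_equal(sign(s), planted_dir)
  }
  # determinism
  cl2 <- cluster_cohesive(correlation_network(rm0, value = "z"))
  expect_identical(cl$clusters, cl2$clusters)
})

test_that("the KS test matches exact enumeration and edge cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(x, x)$p_value, 1)
  # disjoint supports at n = m = 5: D = 1, exact p = 2 / choose(10, 5)
  ks <- ks_two_sample(x, x + 100)
  expect_equal(ks$statistic, 1)
  expect_equal(ks$p_value, 2 / choose(10, 5))
  # oracle: enumerate all assignments of 10 ranks to two groups of 5 and
  # count those with D >= observed
  ranks <- 1:10
  combos <- utils::combn(10, 5)
  d_of <- function(ix) {
    a <- ranks[ix]; b <- ranks[-ix]
    grid <- sort(ranks)
    max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  }
  d_all <- apply(combos, 2, function(ix) d_of(ix))
  expect_equal(mean(d_all >= 1), ks$p_value)
  expect_error(ks_two_sample(1, x), "at least 2")
})

test_that("cluster tidiers expose membership and summaries", {
  edges <- dplyr::bind_rows(make_clique_edges("a", 6),
                            make_clique_edges("b", 5))
  cl <- cluster_cohesive(edges)
  td <- tidy(cl)
  expect_setequal(names(td), c("cluster", "element", "cohesiveness",
                               "p_value"))
  expect_equal(nrow(td), 11)
  gl <- glance(cl)
  expect_equal(gl$size, c(6L, 5L))
  expect_equal(gl$cohesiveness[2], 0.5)  # isolated 5-clique, penalty 2
})
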