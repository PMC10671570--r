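#' Correlation network over site quantitation profiles
#'
#' Computes Pearson correlations between the quantitative profiles
#' (across samples) of all site pairs and keeps edges with r strictly
#' above `r_min` (default 0.5; negative correlations never create edges).
#' Sites with zero variance across samples are excluded and logged.
#'
#' @param quant Long quantitation tibble with `element`, `sample_id` and
#'   the profile column.
#' @param value Profile column name (default `"z_qdna"` falling back to
#'   `"z"`).
#' @param r_min Correlation threshold (edges require `r > r_min`).
#' @return Edge tibble of class `ptm_network`: `from`, `to`, `weight`
#'   (from < to lexicographically), with attribute `"nodes"` holding all
#'   included site ids.
#' @export
correlation_network <- function(quant, value = NULL, r_min = 0.5) {
  if (is.null(value))
    value <- if ("z_qdna" %in% names(quant)) "z_qdna" else "z"
  wide <- quant |>
    dplyr::select(element, sample_id, dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = sample_id,
                       values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$element
  v <- apply(m, 1, stats::var)
  if (any(v == 0 | is.na(v))) {
    rlang::inform(paste0("excluded ", sum(v == 0 | is.na(v)),
                         " zero-variance site(s)"))
    m <- m[v > 0 & !is.na(v), , drop = FALSE]
  }
  r <- stats::cor(t(m))
  r[lower.tri(r, diag = TRUE)] <- NA
  hit <- which(r > r_min, arr.ind = TRUE)
  out <- tibble::tibble(
    from = pmin(rownames(r)[hit[, 1]], colnames(r)[hit[, 2]]),
    to = pmax(rownames(r)[hit[, 1]], colnames(r)[hit[, 2]]),
    weight = r[hit]) |>
    dplyr::arrange(from, to)
  class(out) <- c("ptm_network", class(out))
  attr(out, "nodes") <- rownames(m)
  out
}

#' Cohesiveness of a node set
#'
#' The clustering objective: internal edge weight over internal plus
#' boundary edge weight plus a per-node penalty,
#' `f(V) = W_in / (W_in + W_bound + penalty * |V|)`. An isolated 5-clique
#' of unit weights with penalty 2 scores 10 / (10 + 0 + 10) = 0.5.
#'
#' @param edges Edge tibble (`from`, `to`, `weight`).
#' @param members Character vector of node ids.
#' @param penalty Per-node penalty.
#' @return The cohesiveness value in `[0, 1]`.
#' @export
cohesiveness <- function(edges, members, penalty = 2) {
  a <- edges$from %in% members
  b <- edges$to %in% members
  w_in <- sum(edges$weight[a & b])
  w_bound <- sum(edges$weight[xor(a, b)])
  if (w_in == 0) return(0)
  w_in / (w_in + w_bound + penalty * length(members))
}

#' Cohesiveness-based graph clustering
#'
#' Greedy growth of clusters in the style of ClusterONE: starting from
#' each not-yet-covered seed node (processed by descending weighted
#' degree, ties by label), repeatedly applies the single addition or
#' removal that most increases the cohesiveness
#' `f(V) = W_in / (W_in + W_bound + penalty * |V|)` until no move
#' improves it. Candidate clusters are merged in a single pass whenever
#' their overlap score `|A ∩ B|^2 / (|A| * |B|)` reaches `overlap`;
#' clusters smaller than `min_size`, with weighted density below
#' `min_density`, or with a one-sided Mann-Whitney p-value (per-vertex
#' in-cluster vs boundary weight) above `p_max` are discarded.
#'
#' @param edges Edge tibble from [correlation_network()].
#' @param min_size Minimum cluster size (default 5).
#' @param penalty Per-node cohesiveness penalty (default 2).
#' @param overlap Overlap-score threshold for the merging pass
#'   (default 0.8).
#' @param min_density Minimum mean internal edge weight per node pair
#'   (default 0.3).
#' @param p_max Significance cutoff for reported clusters (default 0.05).
#' @return An object of class `ptm_clusters`: a list with `clusters` (list
#'   of member vectors), `summary` tibble (`cluster`, `size`,
#'   `cohesiveness`, `density`, `p_value`) and the call parameters. Use
#'   [generics::tidy()] / [generics::glance()] to extract tibbles.
#' @export
cluster_cohesive <- function(edges, min_size = 5L, penalty = 2,
                             overlap = 0.8, min_density = 0.3,
                             p_max = 0.05) {
  nodes <- attr(edges, "nodes")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  if (n == 0 || nrow(edges) == 0)
    return(new_ptm_clusters(list(), edges, penalty, min_size))
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ii <- match(edges$from, nodes); jj <- match(edges$to, nodes)
  adj[cbind(ii, jj)] <- edges$weight
  adj[cbind(jj, ii)] <- edges$weight
  wdeg <- rowSums(adj)
  seeds <- nodes[order(-wdeg, nodes)]
  candidates <- list()
  f_of <- function(members) {
    w_in <- sum(adj[members, members, drop = FALSE]) / 2
    w_bound <- sum(adj[members, setdiff(nodes, members), drop = FALSE])
    if (w_in == 0) return(0)
    w_in / (w_in + w_bound + penalty * length(members))
  }
  for (seed in seeds) {
    if (wdeg[seed] == 0) next
    in_set <- stats::setNames(rep(FALSE, n), nodes)
    in_set[seed] <- TRUE
    w2m <- adj[, seed]            # weight from each node to the cluster
    w_in <- 0; w_bound <- wdeg[seed]
    f_cur <- 0
    for (iter in seq_len(200L)) {
      k <- sum(in_set)
      # cohesiveness after adding each external neighbour
      f_add <- (w_in + w2m) /
        (w_in + w_bound + wdeg - w2m + penalty * (k + 1))
      f_add[in_set | w2m <= 0] <- -Inf
      # cohesiveness after removing each non-seed member
      f_rem <- (w_in - w2m) /
        (w_in - w2m + w_bound + 2 * w2m - wdeg + penalty * (k - 1))
      f_rem[!in_set | nodes == seed | (w_in - w2m) <= 0] <- -Inf
      gains <- pmax(f_add, f_rem) - f_cur
      best <- which(gains > 1e-12)
      if (length(best) == 0) break
      v <- nodes[best[order(-gains[best], nodes[best])][1]]
      if (!in_set[v]) {
        in_set[v] <- TRUE
        w_in <- w_in + w2m[v]
        w_bound <- w_bound - w2m[v] + (wdeg[v] - w2m[v])
        w2m <- w2m + adj[, v]
      } else {
        in_set[v] <- FALSE
        w2m <- w2m - adj[, v]
        w_in <- w_in - w2m[v]
        w_bound <- w_bound + 2 * w2m[v] - wdeg[v]
      }
      f_cur <- if (w_in == 0) 0 else
        w_in / (w_in + w_bound + penalty * sum(in_set))
    }
    members <- sort(nodes[in_set])
    if (!any(vapply(candidates, identical, TRUE, y = members)))
      candidates[[length(candidates) + 1L]] <- members
  }
  # single-pass merging of overlapping candidates
  if (length(candidates) > 1) {
    merged <- list(); used <- rep(FALSE, length(candidates))
    for (i in seq_along(candidates)) {
      if (used[i]) next
      acc <- candidates[[i]]
      for (j in seq_along(candidates)) {
        if (j == i || used[j]) next
        b <- candidates[[j]]
        om <- length(intersect(acc, b))^2 / (length(acc) * length(b))
        if (om >= overlap) { acc <- sort(union(acc, b)); used[j] <- TRUE }
      }
      used[i] <- TRUE
      merged[[length(merged) + 1L]] <- acc
    }
    candidates <- merged
  }
  candidates <- candidates[lengths(candidates) >= min_size]
  # density + significance screening
  keep <- list()
  for (members in candidates) {
    k <- length(members)
    sub <- adj[members, members, drop = FALSE]
    dens <- sum(sub) / 2 / (k * (k - 1) / 2)
    # per-vertex in-cluster vs boundary weight, one-sided Mann-Whitney
    in_w <- rowSums(sub)
    bound_w <- rowSums(adj[members, setdiff(nodes, members), drop = FALSE])
    p <- suppressWarnings(stats::wilcox.test(in_w, bound_w,
                                             alternative = "greater")$p.value)
    if (dens >= min_density && p <= p_max)
      keep[[length(keep) + 1L]] <- list(members = members,
                                        cohesiveness = f_of(members),
                                        density = dens, p_value = p)
  }
  new_ptm_clusters(keep, edges, penalty, min_size)
}

new_ptm_clusters <- function(keep, edges, penalty, min_size) {
  summary <- if (length(keep) == 0) {
    tibble::tibble(cluster = integer(), size = integer(),
                   cohesiveness = numeric(), density = numeric(),
                   p_value = numeric())
  } else {
    tibble::tibble(
      cluster = seq_along(keep),
      size = vapply(keep, function(k) length(k$members), 0L),
      cohesiveness = vapply(keep, `[[`, 0, "cohesiveness"),
      density = vapply(keep, `[[`, 0, "density"),
      p_value = vapply(keep, `[[`, 0, "p_value"))
  }
  structure(list(clusters = lapply(keep, `[[`, "members"),
                 summary = summary, penalty = penalty,
                 min_size = min_size, edges = edges),
            class = "ptm_clusters")
}

#' @export
print.ptm_clusters <- function(x, ...) {
  cat("cohesiveness clustering:", length(x$clusters), "cluster(s)\n")
  print(x$summary)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' is exact (enumeration over label permutations) when `n * m <= 10^4`
#' and asymptotic otherwise.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return Tibble: `statistic` (D), `p_value`, `n_x`, `n_y`, `method`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("both samples must have at least 2 values")
  exact <- length(x) * length(y) <= 1e4
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = res$p.value,
                 n_x = length(x), n_y = length(y),
                 method = if (exact) "exact" else "asymptotic")
}
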