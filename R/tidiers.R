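#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohesiveness clustering result
#'
#' @param x A `ptm_clusters` object from [cluster_cohesive()].
#' @param ... Unused.
#' @return Tibble with one row per member: `cluster`, `element`, plus the
#'   cluster's `cohesiveness` and `p_value`.
#' @export
tidy.ptm_clusters <- function(x, ...) {
  if (length(x$clusters) == 0)
    return(tibble::tibble(cluster = integer(), element = character(),
                          cohesiveness = numeric(), p_value = numeric()))
  purrr::map_dfr(seq_along(x$clusters), function(i)
    tibble::tibble(cluster = i, element = x$clusters[[i]],
                   cohesiveness = x$summary$cohesiveness[i],
                   p_value = x$summary$p_value[i]))
}

#' Cluster-level summary of a cohesiveness clustering result
#'
#' @inheritParams tidy.ptm_clusters
#' @return The per-cluster summary tibble (`cluster`, `size`,
#'   `cohesiveness`, `density`, `p_value`).
#' @export
glance.ptm_clusters <- function(x, ...) x$summary

#' Tidy a specificity profile set
#'
#' @param x A `ptm_specificity` object from [specificity_profiles()].
#' @param ... Unused.
#' @return The per-peak origin tibble joined with first-quintile frequency.
#' @export
tidy.ptm_specificity <- function(x, ...) {
  q1 <- x$quintiles[x$quintiles$quintile == 1, c("peak_id", "freq")]
  names(q1)[2] <- "quintile1_freq"
  dplyr::left_join(x$origin, q1, by = "peak_id")
}
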