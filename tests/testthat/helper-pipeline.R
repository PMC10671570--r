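# Shared end-to-end pipeline fixture: simulated once per test run under a
# fixed seed and reused by the simulator, quantitation and acceptance
# tests.
.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  cfg <- sim_config(seed = seed)
  sim <- simulate_psm_dataset(cfg)
  rc <- suppressWarnings(recalibrate(sim$psms))
  pk <- detect_peaks(rc)
  fd <- suppressMessages(fdr_filter(assign_to_peaks(rc, pk)))
  sp <- suppressMessages(map_to_sites(fd, sim$proteins))
  sc <- site_counts(sp, samples = sim$design$sample_id)
  pcnt <- protein_counts(fd, sim$proteins, samples = sim$design$sample_id)
  tot <- attr(quantify(pcnt, "protein"), "sample_totals")
  qs <- quantify(filter_quantifiable(sc, "site_id"), "site_id",
                 sample_totals = tot)
  qp <- quantify(filter_quantifiable(pcnt, "protein"), "protein",
                 sample_totals = tot)
  qn <- suppressMessages(protein_normalize(qs, qp))
  out <- list(cfg = cfg, sim = sim, rc = rc, pk = pk, fd = fd, sp = sp,
              sc = sc, pcnt = pcnt, tot = tot, qs = qs, qp = qp, qn = qn)
  .pipeline_cache[[key]] <- out
  out
}

# Peak id whose apex is closest to a catalog mass (NA if > tol away).
peak_near <- function(peaks, mass, tol = 0.01) {
  i <- which.min(abs(peaks$apex - mass))
  if (length(i) == 0 || abs(peaks$apex[i] - mass) > tol) return(NA_character_)
  peaks$peak_id[i]
}

# Planted-site element ids in the site quantitation table.
planted_elements <- function(pl) {
  pkphos <- peak_near(pl$pk, 79.966331)
  ps <- dplyr::distinct(
    pl$sim$truth$sites[pl$sim$truth$sites$module != "background", ],
    protein, residue, position, module)
  ps$element <- paste0(ps$protein, ":", ps$residue, ps$position, ":", pkphos)
  ps
}

# Mean per-site log2-ratio contrast (treated minus control) for a set of
# elements, computed by an independent tally on the quant table.
site_delta_r <- function(quant, design, elements) {
  x <- dplyr::inner_join(quant, design, by = "sample_id")
  x <- x[x$element %in% elements, ]
  tr <- tapply(x$log2_ratio[x$group != "control"],
               x$element[x$group != "control"], mean)
  ct <- tapply(x$log2_ratio[x$group == "control"],
               x$element[x$group == "control"], mean)
  tr[names(ct)] - ct
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

make_clique_edges <- function(prefix, n, weight = 1) {
  v <- paste0(prefix, seq_len(n))
  g <- expand.grid(from = v, to = v, stringsAsFactors = FALSE)
  g <- g[g$from < g$to, ]
  tibble::tibble(from = g$from, to = g$to, weight = weight)
}
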