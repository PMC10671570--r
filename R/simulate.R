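#' Simulation configuration
#'
#' Builds the configuration for the synthetic open-search PSM generator.
#' The defaults emulate the statistical structure of a label-free
#' phosphoproteome open search over a 3-group x 3-replicate rodent
#' high-fat-diet design: an in-silico proteome digested with the combined
#' trypsin/LysC rule, modified PSMs whose delta masses scatter around
#' catalog masses, sample-preparation artefacts confined to the first fifth
#' of the peptide sequence, decoy PSMs with a score distribution
#' overlapping the targets, and planted per-site group effects arranged in
#' two anti-correlated response modules.
#'
#' @param n_proteins Number of target proteins in the in-silico proteome.
#' @param protein_length_mean,protein_length_sd Protein length distribution
#'   (residues; normal, clipped to `[120, 800]`).
#' @param kr_density Combined K+R residue density of the proteome.
#' @param max_missed_cleavages Maximum missed cleavages in the digest.
#' @param groups Ordered group labels; first group is the reference.
#' @param replicates Replicates per group.
#' @param catalog Modification catalog tibble (see [default_catalog()]).
#' @param prevalence Named numeric: relative PSM mass of each biological
#'   catalog entry among background modified sites.
#' @param artefact_entries Catalog entries emitted as peptide-N-terminal
#'   (first-quintile) artefact events rather than fixed protein sites.
#' @param artefact_weight Named numeric: expected raw PSM weight per sample
#'   for each artefact entry (plus the `c13` precursor-isotope channel).
#' @param n_background_sites Number of background (no group effect)
#'   modified protein sites.
#' @param planted_effects Tibble with columns `site`, `group`, `lfc` giving
#'   planted log2 fold changes versus the reference group; see
#'   [sim_planted_effects()].
#' @param planted_base_lambda Expected raw PSMs per planted site per sample
#'   in the reference group.
#' @param planted_protein_unmod Expected raw unmodified PSMs per sample for
#'   each protein carrying a planted site (keeps those proteins flat at the
#'   protein level so site effects survive protein normalization).
#' @param background_unmod_total Total raw unmodified PSM weight per sample
#'   spread over the remaining proteins (log-normal protein abundances).
#' @param psm_depth Expected total PSMs per sample (all classes).
#' @param decoy_fraction Expected fraction of emitted PSMs that are decoys;
#'   an equal fraction of incorrect (ground-truth-false) target PSMs is
#'   drawn so that target-decoy FDR estimation is calibrated.
#' @param noise_sd_da Gaussian measurement noise of delta mass (Da).
#' @param calibration_offset_sd Per-sample systematic delta-mass offset SD
#'   (Da), removed by [recalibrate()].
#' @param score_target_mean,score_decoy_mean,score_sd Parameters of the two
#'   Gaussian score distributions (correct targets vs decoys/false
#'   targets).
#' @param effect_sample_sd SD of the per-animal response scale: every
#'   sample draws a severity factor ~ N(1, effect_sample_sd) that
#'   multiplies all planted log2 fold changes in that sample, emulating
#'   animal-to-animal variation in disease progression (and giving
#'   co-responding sites their shared within-group co-variation).
#' @param dispersion Negative-binomial size parameter for per-site counts;
#'   `Inf` (default) gives the Poisson limit.
#' @param seed Integer seed; every draw is reproducible under it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 120,
                       protein_length_mean = 380,
                       protein_length_sd = 90,
                       kr_density = 0.12,
                       max_missed_cleavages = 5L,
                       groups = c("control", "HFD3", "HFD12"),
                       replicates = 3L,
                       catalog = default_catalog(),
                       prevalence = c(phospho = 0.42, oxidation = 0.14,
                                      deamidation = 0.09,
                                      carbamidomethyl = 0.06,
                                      phosphoglyceryl = 0.10,
                                      glyceryl_pe = 0.07, fmn = 0.05,
                                      acetyl_protein_nterm = 0.07),
                       artefact_entries = c("ammonia_loss", "carbamylation"),
                       artefact_weight = c(ammonia_loss = 140,
                                           carbamylation = 80, c13 = 70),
                       n_background_sites = 160L,
                       planted_effects = sim_planted_effects(),
                       planted_base_lambda = 80,
                       planted_protein_unmod = 200,
                       background_unmod_total = 1600,
                       psm_depth = 18000,
                       decoy_fraction = 0.075,
                       noise_sd_da = 0.003,
                       calibration_offset_sd = 0.002,
                       score_target_mean = 6,
                       score_decoy_mean = 3,
                       score_sd = 1,
                       effect_sample_sd = 0.25,
                       dispersion = Inf,
                       seed = 1L) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  if (psm_depth <= 0) stop("psm_depth must be positive")
  if (decoy_fraction < 0 || decoy_fraction >= 0.5)
    stop("decoy_fraction must be in [0, 0.5)")
  if (kr_density <= 0 || kr_density >= 1)
    stop("kr_density must be in (0, 1)")
  validate_catalog(catalog)
  stopifnot(all(names(prevalence) %in% catalog$name),
            all(artefact_entries %in% catalog$name))
  structure(as.list(environment()), class = "sim_config")
}

#' Default planted group effects
#'
#' Two anti-correlated response modules: `n_up` sites gaining and `n_down`
#' sites losing `lfc` log2 units in every treatment group relative to the
#' reference.
#'
#' @param n_up,n_down Sites per module.
#' @param lfc Planted |log2 fold change|.
#' @param groups Treatment groups the effect applies to.
#' @return Tibble with columns `site`, `module`, `group`, `lfc`.
#' @export
sim_planted_effects <- function(n_up = 20L, n_down = 20L, lfc = 1,
                                groups = c("HFD3", "HFD12")) {
  up <- tidyr::expand_grid(site = sprintf("planted_up_%02d", seq_len(n_up)),
                           group = groups) |>
    dplyr::mutate(module = "up", lfc = lfc)
  dn <- tidyr::expand_grid(site = sprintf("planted_down_%02d", seq_len(n_down)),
                           group = groups) |>
    dplyr::mutate(module = "down", lfc = -lfc)
  dplyr::bind_rows(up, dn)[, c("site", "module", "group", "lfc")]
}

#' Generate an in-silico proteome
#'
#' Random protein sequences over the 20-letter alphabet with a configurable
#' combined K+R density (K and R equally likely), deterministic under the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `accession`, `sequence`, `is_decoy`.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  aa <- strsplit(AA_ALPHABET, "")[[1]]
  p <- rep((1 - config$kr_density) / 18, 20)
  p[aa %in% c("K", "R")] <- config$kr_density / 2
  lens <- pmin(800L, pmax(120L, round(stats::rnorm(
    config$n_proteins, config$protein_length_mean,
    config$protein_length_sd))))
  seqs <- vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE, prob = p), collapse = ""), "")
  tibble::tibble(
    accession = sprintf("P%04d", seq_len(config$n_proteins)),
    sequence = seqs,
    is_decoy = FALSE
  )
}

# Digest every protein, keep emission-sized peptides.
build_peptide_pool <- function(proteins, max_missed, len_range = c(7L, 30L)) {
  pool <- purrr::map2_dfr(proteins$accession, proteins$sequence,
                          function(acc, sq) {
    d <- digest(sq, max_missed)
    d$protein <- acc
    d
  })
  pool$len <- nchar(pool$peptide)
  pool <- pool[pool$len >= len_range[1] & pool$len <= len_range[2], ]
  pool$form_id <- seq_len(nrow(pool))
  pool
}

#' Simulate an open-search PSM dataset with ground truth
#'
#' Draws a full PSM table under a [sim_config()]: unmodified PSMs,
#' background and planted modified-site PSMs (counts Poisson or
#' negative-binomial per site per sample), first-quintile artefact events,
#' C13 precursor-isotope events, ground-truth-false target PSMs and decoy
#' PSMs. Delta masses are catalog masses plus Gaussian noise plus a
#' per-sample calibration offset; scores come from two overlapping
#' Gaussians (correct targets above decoys/false matches).
#'
#' @param config A [sim_config()].
#' @return A list with elements `psms` (PSM tibble), `proteins` (target +
#'   reversed-decoy protein tibble), `design` (sample/group tibble) and
#'   `truth` (list: per-PSM classes, planted/background site table, planted
#'   effects, per-sample calibration offsets).
#' @export
simulate_psm_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  proteins <- generate_proteome(config)  # seeds the RNG stream
  pool <- build_peptide_pool(proteins, config$max_missed_cleavages)
  catalog <- config$catalog
  cat_mass <- stats::setNames(catalog$mono_mass, catalog$name)

  design <- tidyr::expand_grid(group = config$groups,
                               rep = seq_len(config$replicates)) |>
    dplyr::mutate(sample_id = paste(group, rep, sep = "_")) |>
    dplyr::select(sample_id, group)
  n_samples <- nrow(design)

  ## ---- choose modified sites -------------------------------------------
  planted <- unique(config$planted_effects[, c("site", "module")])
  n_planted <- nrow(planted)
  if (n_planted > config$n_proteins)
    stop("more planted sites than proteins")
  planted_prot <- proteins$accession[seq_len(n_planted)]
  seq_of <- stats::setNames(proteins$sequence, proteins$accession)

  pool_by_prot <- split(seq_len(nrow(pool)), pool$protein)

  # positions of the protein covered by at least one emitted peptidoform
  covered_mask <- function(acc) {
    rows <- pool_by_prot[[acc]]
    mask <- rep(FALSE, nchar(seq_of[[acc]]))
    for (r in rows) mask[pool$start[r]:(pool$start[r] + pool$len[r] - 1L)] <-
      TRUE
    mask
  }
  pick_position <- function(acc, residues, protein_nterm = FALSE) {
    sq <- seq_of[[acc]]
    if (protein_nterm) return(1L)
    cand <- which(strsplit(sq, "")[[1]] %in% residues)
    cand <- cand[cand > 1 & cand < nchar(sq) & covered_mask(acc)[cand]]
    if (length(cand) == 0) return(NA_integer_)
    sample(cand, 1L)
  }

  site_rows <- list()
  for (i in seq_len(n_planted)) {
    pos <- pick_position(planted_prot[i], "S")
    if (is.na(pos)) stop("planted protein without an internal Ser: ",
                         planted_prot[i])
    site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
      site = planted$site[i], module = planted$module[i],
      protein = planted_prot[i], position = pos, residue = "S",
      mod_name = "phospho", base_lambda = config$planted_base_lambda)
  }

  bio_prev <- config$prevalence / sum(config$prevalence)
  n_per_entry <- pmax(1, round(config$n_background_sites * bio_prev))
  names(n_per_entry) <- names(bio_prev)
  bg_prot <- proteins$accession[-seq_len(n_planted)]
  k <- 0L
  for (e in names(n_per_entry)) {
    spec <- catalog$specificity[catalog$name == e]
    is_nterm <- grepl("protein-Nterm", spec)
    residues <- specificity_residues(spec)
    internal_only <- e == "phosphoglyceryl"  # pgK blocks cleavage
    for (j in seq_len(n_per_entry[[e]])) {
      acc <- bg_prot[(k %% length(bg_prot)) + 1L]; k <- k + 1L
      pos <- pick_position(acc, residues, protein_nterm = is_nterm)
      if (is.na(pos)) next
      site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
        site = sprintf("bg_%s_%03d", e, j), module = "background",
        protein = acc, position = pos,
        residue = substr(seq_of[[acc]], pos, pos),
        mod_name = e,
        base_lambda = stats::rlnorm(1, meanlog = log(12), sdlog = 0.6))
    }
  }
  sites <- dplyr::bind_rows(site_rows)
  # residue consistency of planted/background sites with the catalog
  bad <- purrr::map_lgl(seq_len(nrow(sites)), function(i) {
    spec <- catalog$specificity[catalog$name == sites$mod_name[i]]
    res <- specificity_residues(spec)
    length(res) > 0 && !sites$residue[i] %in% res
  })
  if (any(bad)) stop("site residue inconsistent with catalog specificity")

  # covering peptidoforms per site (pgK: modified K must be internal)
  sites$forms <- purrr::map(seq_len(nrow(sites)), function(i) {
    rows <- pool_by_prot[[sites$protein[i]]]
    n <- sites$position[i]
    ok <- pool$start[rows] <= n & pool$start[rows] + pool$len[rows] - 1L >= n
    if (sites$mod_name[i] == "phosphoglyceryl")
      ok <- ok & (n - pool$start[rows] + 1L) < pool$len[rows]
    if (sites$mod_name[i] %in% c("acetyl_protein_nterm", "met_loss"))
      ok <- ok & pool$start[rows] == 1L
    rows[ok]
  })
  sites <- sites[lengths(sites$forms) > 0, ]

  ## ---- per-sample expected counts --------------------------------------
  effects <- config$planted_effects
  lfc_of <- function(site, group) {
    hit <- effects$site == site & effects$group == group
    if (any(hit)) effects$lfc[hit][1] else 0
  }
  severity <- stats::rnorm(n_samples, 1, config$effect_sample_sd)
  lambda_site <- matrix(0, nrow(sites), n_samples,
                        dimnames = list(sites$site, design$sample_id))
  for (i in seq_len(nrow(sites)))
    for (s in seq_len(n_samples))
      lambda_site[i, s] <- sites$base_lambda[i] *
        2^(lfc_of(sites$site[i], design$group[s]) * severity[s])

  unmod_w <- stats::rlnorm(config$n_proteins, log(1), 0.7)
  unmod_w <- unmod_w / sum(unmod_w) * config$background_unmod_total
  unmod_w[seq_len(n_planted)] <- config$planted_protein_unmod
  names(unmod_w) <- proteins$accession

  art_w <- config$artefact_weight
  target_mass <- sum(unmod_w) + mean(colSums(lambda_site)) + sum(art_w)
  f <- config$decoy_fraction
  decoy_mass <- target_mass * f / (1 - 2 * f)
  scale_c <- config$psm_depth / (target_mass + 2 * decoy_mass)

  offsets <- stats::rnorm(n_samples, 0, config$calibration_offset_sd)
  names(offsets) <- design$sample_id

  rdraw <- function(n, mu) {
    if (is.infinite(config$dispersion)) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = config$dispersion)
  }
  draw_forms <- function(rows, k) rows[sample.int(length(rows), k,
                                                  replace = TRUE)]

  ## ---- emit PSMs --------------------------------------------------------
  out <- list()
  emit <- function(df) out[[length(out) + 1L]] <<- df
  q1max <- function(len) pmax(1L, ceiling(len / 5 - 1e-9))

  for (s in seq_len(n_samples)) {
    sid <- design$sample_id[s]
    # unmodified
    for (pi in seq_len(config$n_proteins)) {
      rows <- pool_by_prot[[proteins$accession[pi]]]
      if (is.null(rows)) next
      k <- rdraw(1, scale_c * unmod_w[pi])
      if (k == 0) next
      fr <- draw_forms(rows, k)
      emit(tibble::tibble(sample_id = sid, form = fr, mod_pos = NA_integer_,
                          mod_name = NA_character_, truth = "true_target",
                          site_id = NA_character_, dm0 = 0))
    }
    # modified sites
    ks <- rdraw(nrow(sites), scale_c * lambda_site[, s])
    for (i in which(ks > 0)) {
      fr <- draw_forms(sites$forms[[i]], ks[i])
      emit(tibble::tibble(
        sample_id = sid, form = fr,
        mod_pos = sites$position[i] - pool$start[fr] + 1L,
        mod_name = sites$mod_name[i], truth = "true_target",
        site_id = sites$site[i], dm0 = cat_mass[[sites$mod_name[i]]]))
    }
    # artefact events (first sequence quintile) and C13 events
    for (e in names(art_w)) {
      k <- rdraw(1, scale_c * art_w[[e]])
      if (k == 0) next
      fr <- sample.int(nrow(pool), k, replace = TRUE)
      len <- pool$len[fr]
      pos <- if (e == "c13") {
        1L + floor(stats::runif(k) * len)
      } else {
        1L + floor(stats::runif(k) * q1max(len))
      }
      emit(tibble::tibble(sample_id = sid, form = fr, mod_pos = as.integer(pos),
                          mod_name = e, truth = "true_target",
                          site_id = NA_character_, dm0 = cat_mass[[e]]))
    }
    # ground-truth-false targets and decoys
    for (cls in c("false_target", "decoy")) {
      k <- rdraw(1, scale_c * decoy_mass)
      if (k == 0) next
      fr <- sample.int(nrow(pool), k, replace = TRUE)
      pos <- 1L + floor(stats::runif(k) * pool$len[fr])
      emit(tibble::tibble(sample_id = sid, form = fr, mod_pos = as.integer(pos),
                          mod_name = NA_character_, truth = cls,
                          site_id = NA_character_,
                          dm0 = stats::runif(k, -140, 470)))
    }
  }
  raw <- dplyr::bind_rows(out)

  psms <- tibble::tibble(
    sample_id = raw$sample_id,
    peptide = pool$peptide[raw$form],
    protein = pool$protein[raw$form],
    peptide_start = pool$start[raw$form],
    delta_mass = unname(raw$dm0 +
      pmax(pmin(stats::rnorm(nrow(raw), 0, config$noise_sd_da),
                4 * config$noise_sd_da), -4 * config$noise_sd_da) +
      offsets[raw$sample_id]),
    mod_pos = raw$mod_pos,
    score = ifelse(raw$truth == "true_target",
                   stats::rnorm(nrow(raw), config$score_target_mean,
                                config$score_sd),
                   stats::rnorm(nrow(raw), config$score_decoy_mean,
                                config$score_sd)),
    is_decoy = raw$truth == "decoy",
    missed_cleavages = pool$missed_cleavages[raw$form]
  )
  # decoys: reversed peptide on the reversed (rev_) protein
  dec <- psms$is_decoy
  rev_str <- function(x) vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), "")
  plen <- nchar(psms$peptide[dec])
  prot_len <- nchar(seq_of[psms$protein[dec]])
  psms$peptide_start[dec] <- prot_len - (psms$peptide_start[dec] + plen - 1L) + 1L
  psms$peptide[dec] <- rev_str(psms$peptide[dec])
  psms$mod_pos[dec] <- plen - psms$mod_pos[dec] + 1L
  psms$protein[dec] <- paste0("rev_", psms$protein[dec])
  psms$mod_residue <- ifelse(is.na(psms$mod_pos), NA_character_,
                             substr(psms$peptide, psms$mod_pos, psms$mod_pos))
  # unmodified PSMs carry no placement
  psms <- psms |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(scan_id = paste0(sample_id, "_",
                                   sprintf("%06d", dplyr::row_number()))) |>
    dplyr::ungroup() |>
    dplyr::select(sample_id, scan_id, peptide, protein, peptide_start,
                  delta_mass, mod_pos, mod_residue, score, is_decoy,
                  missed_cleavages)

  decoy_prot <- tibble::tibble(
    accession = paste0("rev_", proteins$accession),
    sequence = rev_str(proteins$sequence),
    is_decoy = TRUE
  )
  truth <- list(
    psm = tibble::tibble(scan_id = psms$scan_id, truth = raw$truth,
                         mod_name = raw$mod_name, site_id = raw$site_id),
    sites = sites[, c("site", "module", "protein", "position", "residue",
                      "mod_name", "base_lambda")],
    effects = config$planted_effects,
    offsets = tibble::tibble(sample_id = design$sample_id, offset = offsets),
    config = config
  )
  list(psms = psms, proteins = dplyr::bind_rows(proteins, decoy_prot),
       design = design, truth = truth)
}
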