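#' Configuration for the paired-assay simulator
#'
#' The generator emulates a factorial greenhouse drought study: two
#' crop-conditioned soil pools, planted/unplanted, drought/watered over a
#' run of sampling days plus a watered pre-drought baseline at day 0, with
#' replicated destructive sampling. Each taxon carries a latent activity
#' multiplier `a_t`: the cDNA (rRNA) composition of a sample is its DNA
#' composition reweighted by `a_t` and renormalized, so the ground truth of
#' "active" is well defined. Counts are multinomial draws at a per-sample
#' negative-binomial depth. A configurable set of phantom taxa has DNA
#' relative abundance below `1/depth_mean` but high activity, so they
#' surface in cDNA libraries only; reagent contaminants are extra taxa
#' enriched in negative controls.
#'
#' Defaults: 500 taxa with log-normal(0, 1.5) base abundances and log-normal
#' per-sample composition noise (sd 0.3); half the taxa active with
#' multipliers log-uniform on \[1, `active_max`\], the rest log-uniform on
#' \[`inactive_min`, 1\]; mean depth 25,000 so a 15,000-read rarefaction
#' retains most samples while exercising the dropping path; 2-fold abundance
#' effects on 25 responder taxa per factor.
#'
#' @param n_taxa number of non-contaminant taxa.
#' @param crops soil pools (distinct base compositions).
#' @param days post-drought sampling days.
#' @param n_replicates replicates per factor cell.
#' @param depth_mean,depth_dispersion negative-binomial library-size model
#'   (mu and size).
#' @param abund_meanlog,abund_sdlog log-normal base-abundance parameters.
#' @param sample_noise_sdlog per-sample composition noise (log scale).
#' @param fraction_active fraction of taxa with `a_t >= 1`.
#' @param active_max,inactive_min bounds of the log-uniform multiplier draws.
#' @param phantom_fraction fraction of taxa made phantom (rare DNA, high
#'   activity).
#' @param phantom_activity activity multiplier of phantom taxa.
#' @param n_contaminants,contam_prev_controls,contam_prev_samples,contam_level
#'   reagent-contaminant settings: count, per-sample inclusion probability in
#'   negative controls and in biological samples, and relative-abundance
#'   level when included.
#' @param n_controls number of negative-control samples.
#' @param n_responder_taxa responder taxa per factor (planted, drought,
#'   planted:drought).
#' @param effect_log2 log2 fold change applied to responder abundances.
#' @param rng_seed integer; fully determines the output.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 500,
                              crops = c("bean", "switchgrass"),
                              days = 2:6,
                              n_replicates = 5,
                              depth_mean = 25000,
                              depth_dispersion = 30,
                              abund_meanlog = 0,
                              abund_sdlog = 1.5,
                              sample_noise_sdlog = 0.3,
                              fraction_active = 0.5,
                              active_max = 4,
                              inactive_min = 0.1,
                              phantom_fraction = 0.02,
                              phantom_activity = 25,
                              n_contaminants = 5,
                              contam_prev_controls = 1.0,
                              contam_prev_samples = 0.05,
                              contam_level = 0.005,
                              n_controls = 6,
                              n_responder_taxa = 25,
                              effect_log2 = 1,
                              rng_seed = 1) {
  cfg <- as.list(environment())
  fr <- c(fraction_active = fraction_active,
          phantom_fraction = phantom_fraction,
          contam_prev_controls = contam_prev_controls,
          contam_prev_samples = contam_prev_samples)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (n_taxa < 1) stop("n_taxa must be positive")
  if (3 * n_responder_taxa + ceiling(phantom_fraction * n_taxa) > n_taxa)
    stop("n_responder_taxa too large for n_taxa")
  if (inactive_min <= 0 || active_max < 1)
    stop("need inactive_min > 0 and active_max >= 1")
  structure(cfg, class = "simulation_config")
}

#' Simulate a paired DNA/cDNA assay with known ground truth
#'
#' @param config a [simulation_config()].
#' @return list with `assay` (a [pair_assays()] object), `metadata`
#'   (validated sample metadata including negative controls), and `truth`:
#'   per-taxon activity multipliers, phantom and contaminant flags,
#'   responder assignments, and the expected per-sample DNA composition.
#' @export
simulate_paired_assay <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("`config` must come from simulation_config()")
  with_seed(config$rng_seed, simulate_paired_assay_impl(config))
}

simulate_paired_assay_impl <- function(cfg) {
  n <- cfg$n_taxa
  taxa <- sprintf("taxon_%04d", seq_len(n))
  contam <- if (cfg$n_contaminants > 0)
    sprintf("contam_%02d", seq_len(cfg$n_contaminants)) else character()
  all_taxa <- c(taxa, contam)

  # latent activity multipliers
  a <- numeric(n)
  n_act <- round(cfg$fraction_active * n)
  act_idx <- sample.int(n, n_act)
  a[act_idx] <- exp(runif(n_act, 0, log(cfg$active_max)))
  a[-act_idx] <- exp(runif(n - n_act, log(cfg$inactive_min), 0))

  n_ph <- round(cfg$phantom_fraction * n)
  phantom_idx <- sample.int(n, n_ph)
  a[phantom_idx] <- cfg$phantom_activity

  pool <- setdiff(seq_len(n), phantom_idx)
  resp_planted <- sample(pool, cfg$n_responder_taxa)
  pool <- setdiff(pool, resp_planted)
  resp_drought <- sample(pool, cfg$n_responder_taxa)
  pool <- setdiff(pool, resp_drought)
  resp_inter <- sample(pool, cfg$n_responder_taxa)

  base <- sapply(cfg$crops, function(cr)
    rlnorm(n, cfg$abund_meanlog, cfg$abund_sdlog))
  # phantom taxa: DNA relative abundance pinned below 1/depth_mean
  for (j in seq_along(cfg$crops))
    base[phantom_idx, j] <- 0.3 / cfg$depth_mean * sum(base[-phantom_idx, j])

  md <- expand.grid(crop = cfg$crops, planted = c("planted", "unplanted"),
                    drought = c("drought", "watered"), day = cfg$days,
                    replicate = seq_len(cfg$n_replicates),
                    stringsAsFactors = FALSE)
  base_md <- expand.grid(crop = cfg$crops,
                         planted = c("planted", "unplanted"),
                         drought = "pre-drought", day = 0,
                         replicate = seq_len(cfg$n_replicates),
                         stringsAsFactors = FALSE)
  md <- rbind(base_md, md)
  md$sample_id <- sprintf("%s_%s_%s_d%d_r%d", md$crop, substr(md$planted, 1, 2),
                          sub("-", "", md$drought), md$day, md$replicate)
  md$is_negative_control <- FALSE

  draw_depth <- function(k) pmax(1L, rnbinom(k, mu = cfg$depth_mean,
                                             size = cfg$depth_dispersion))
  ns <- nrow(md)
  dna <- matrix(0L, ns, length(all_taxa),
                dimnames = list(md$sample_id, all_taxa))
  cdna <- dna
  expected <- matrix(0, ns, length(all_taxa),
                     dimnames = list(md$sample_id, all_taxa))
  dna_depth <- draw_depth(ns)
  cdna_depth <- draw_depth(ns)
  fold <- 2^cfg$effect_log2

  for (i in seq_len(ns)) {
    comp <- base[, md$crop[i]] * rlnorm(n, 0, cfg$sample_noise_sdlog)
    if (md$planted[i] == "planted") comp[resp_planted] <- comp[resp_planted] * fold
    if (md$drought[i] == "drought") comp[resp_drought] <- comp[resp_drought] * fold
    if (md$planted[i] == "planted" && md$drought[i] == "drought")
      comp[resp_inter] <- comp[resp_inter] * fold
    z <- numeric(cfg$n_contaminants)
    if (cfg$n_contaminants > 0) {
      on <- runif(cfg$n_contaminants) < cfg$contam_prev_samples
      z[on] <- cfg$contam_level * sum(comp)
    }
    p <- c(comp, z); p <- p / sum(p)
    expected[i, ] <- p
    q <- p * c(a, rep(1, cfg$n_contaminants)); q <- q / sum(q)
    dna[i, ] <- as.integer(rmultinom(1, dna_depth[i], p))
    cdna[i, ] <- as.integer(rmultinom(1, cdna_depth[i], q))
  }

  if (cfg$n_controls > 0) {
    ctl_ids <- sprintf("control_%02d", seq_len(cfg$n_controls))
    ctl_dna <- matrix(0L, cfg$n_controls, length(all_taxa),
                      dimnames = list(ctl_ids, all_taxa))
    ctl_cdna <- ctl_dna
    ctl_depth_d <- pmax(1L, rnbinom(cfg$n_controls,
                                    mu = cfg$depth_mean / 10, size = 5))
    ctl_depth_c <- pmax(1L, rnbinom(cfg$n_controls,
                                    mu = cfg$depth_mean / 10, size = 5))
    for (i in seq_len(cfg$n_controls)) {
      w <- numeric(length(all_taxa))
      if (cfg$n_contaminants > 0) {
        on <- runif(cfg$n_contaminants) < cfg$contam_prev_controls
        w[n + which(on)] <- 1
      }
      # faint cross-talk background so controls are not degenerate
      bg <- sample.int(n, min(20L, n))
      w[bg] <- w[bg] + 0.001
      w <- w / sum(w)
      ctl_dna[i, ] <- as.integer(rmultinom(1, ctl_depth_d[i], w))
      ctl_cdna[i, ] <- as.integer(rmultinom(1, ctl_depth_c[i], w))
    }
    dna <- rbind(dna, ctl_dna)
    cdna <- rbind(cdna, ctl_cdna)
    md <- rbind(md, data.frame(crop = NA, planted = NA, drought = NA,
                               day = NA, replicate = NA, sample_id = ctl_ids,
                               is_negative_control = TRUE))
  }
  md$dna_concentration <- ifelse(md$is_negative_control, 0.05,
                                 rlnorm(nrow(md), log(20), 0.4))
  md <- md[, c("sample_id", "crop", "planted", "drought", "day", "replicate",
               "is_negative_control", "dna_concentration")]
  md <- validate_sample_metadata(md)

  truth <- list(
    activity = setNames(c(a, rep(1, cfg$n_contaminants)), all_taxa),
    phantom = setNames(seq_along(all_taxa) %in% phantom_idx, all_taxa),
    contaminant = setNames(seq_along(all_taxa) > n, all_taxa),
    responders = list(planted = taxa[resp_planted],
                      drought = taxa[resp_drought],
                      interaction = taxa[resp_inter]),
    expected_composition = expected)

  list(assay = pair_assays(dna, cdna), metadata = md, truth = truth)
}

#' Simulate a two-group metabolite feature matrix
#'
#' Feature intensities are log-normal; `n_discriminating` features are
#' shifted between the two groups by `shift_sd_units` standard deviations on
#' the log scale. Feature names follow the `RT_mz` convention of untargeted
#' LC-MS feature tables.
#'
#' @param n_features,n_per_group,n_discriminating sizes.
#' @param shift_sd_units between-group shift in units of the log-scale SD.
#' @param groups the two group labels.
#' @param seed integer RNG seed.
#' @return list with `intensities` (samples x features), `groups` (factor of
#'   length `2 * n_per_group`), and `discriminating` (character vector of
#'   ground-truth feature ids).
#' @export
simulate_metabolome <- function(n_features = 200, n_per_group = 7,
                                n_discriminating = 10, shift_sd_units = 2,
                                groups = c("drought", "watered"), seed = 1) {
  if (n_features < 1 || n_per_group < 2)
    stop("n_features and n_per_group must be positive (n_per_group >= 2)")
  if (n_discriminating > n_features)
    stop("n_discriminating cannot exceed n_features")
  with_seed(seed, {
    feat <- sprintf("%0.2f_%0.4fm/z", runif(n_features, 0.5, 15),
                    runif(n_features, 100, 1500))
    feat <- make.unique(feat)
    n <- 2 * n_per_group
    g <- factor(rep(groups, each = n_per_group), levels = groups)
    mu <- runif(n_features, 3, 6)       # log10 baseline intensity
    sdl <- 0.3                          # log10 within-group SD
    logx <- matrix(rnorm(n * n_features, rep(mu, each = n), sdl), n,
                   n_features, dimnames = list(sprintf("samp_%02d", 1:n), feat))
    disc <- sample.int(n_features, n_discriminating)
    logx[g == groups[2], disc] <- logx[g == groups[2], disc] +
      shift_sd_units * sdl
    list(intensities = 10^logx, groups = g, discriminating = feat[disc])
  })
}
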