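#' Simulate a phylogeny of OTUs
#'
#' Birth-death tree with positive branch lengths and unique tip labels,
#' reproducible by seed. Non-ultrametric trees are produced by jittering
#' branch lengths with a log-normal rate factor.
#'
#' @param n_otus number of tips (>= 3).
#' @param seed integer seed.
#' @param birth,death birth-death rates.
#' @param ultrametric keep the tree ultrametric?
#' @return a `phylo` object with tips `OTU0001`, ...
#' @export
simulate_tree <- function(n_otus, seed = NULL, birth = 1, death = 0.9,
                          ultrametric = TRUE) {
  if (n_otus < 3)
    abort("need at least 3 OTUs", class = "pelagos_domain_error")
  tree <- with_seed_(seed, {
    tr <- ape::rphylo(n_otus, birth = birth, death = death)
    if (!ultrametric)
      tr$edge.length <- tr$edge.length * exp(rnorm(length(tr$edge.length),
                                                   0, 0.3))
    tr
  })
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  tree$tip.label <- sprintf("OTU%04d", seq_len(n_otus))
  tree
}

#' Evolve a niche optimum along the tree
#'
#' Brownian motion with rate `bm_rate` (variance per unit branch length), so
#' trait covariance between OTUs is proportional to shared path length from
#' the root: phylogenetically conserved niches, the assumption behind reading
#' phylogenetic turnover as selection. By default the rate declines
#' exponentially with time from the root (an early-burst model, `eb_decay`
#' rate-halvings per unit of relative tree height): most niche divergence
#' happens between deep clades and little at the tips, which is what "niche
#' conservatism" means phylogenetically. `eb_decay = 0` recovers plain
#' Brownian motion.
#'
#' @param tree `phylo` object.
#' @param bm_rate Brownian rate at the root (variance per unit branch
#'   length); zero returns the root value for every tip.
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @param eb_decay exponential rate-decay constant per unit tree height.
#' @return named numeric vector of niche optima per OTU.
#' @export
evolve_niche <- function(tree, bm_rate = 1, root_value = 0, seed = NULL,
                         eb_decay = 2) {
  if (bm_rate < 0)
    abort("bm_rate must be non-negative", class = "pelagos_domain_error")
  if (bm_rate == 0)
    return(setNames(rep(root_value, length(tree$tip.label)), tree$tip.label))
  tr_sim <- tree
  if (eb_decay > 0) {
    # rescale branch lengths so BM on the new tree has rate bm_rate *
    # exp(-eb_decay * t/H) at height t on the original tree
    nh <- ape::node.depth.edgelength(tree)
    r <- eb_decay / max(nh)
    t0 <- nh[tree$edge[, 1]]
    t1 <- nh[tree$edge[, 2]]
    tr_sim$edge.length <- (exp(-r * t0) - exp(-r * t1)) / r
  }
  tr <- with_seed_(seed,
    ape::rTraitCont(tr_sim, model = "BM", sigma = sqrt(bm_rate),
                    root.value = root_value))
  tr[tree$tip.label]
}

#' Default depth layers of the sampling design
#'
#' Eight layers from surface water to the bottom, in metres, following a
#' typical deep-sea station profile (surface, deep chlorophyll maximum,
#' mesopelagic horizons, and bottom water).
#'
#' @return named numeric vector of depths.
#' @export
default_layers <- function() {
  c(surface = 5, DCM = 75, "200m" = 200, "300m" = 300,
    "500m" = 500, "1000m" = 1000, "2000m" = 2000, bottom = 3500)
}

#' Assembly-regime parameter presets
#'
#' Each of the five processes is realized by one corner of the generator's
#' parameter space:
#' * `variable_selection`: strong niche filter, environment varying with
#'   depth across samples.
#' * `homogeneous_selection`: strong niche filter, identical environment
#'   everywhere (with colonisation-lottery turnover, so samples share the
#'   selected clades but not their exact members).
#' * `homogeneous_dispersal`: no filter; vertical mixing below
#'   `mixing_depth` makes all deeper samples replicates of one shared
#'   realized community — they share far more taxa than the
#'   occupancy-weighted null expects.
#' * `dispersal_limitation`: no filter, no dispersal, site-restricted
#'   colonisation (each site samples its own random subset of the pool), so
#'   cross-site pairs share fewer taxa than the null expects.
#' * `drift`: no filter, independent per-sample abundance noise and a small
#'   read depth — communities assembled essentially the way the null model
#'   assembles them.
#'
#' @param regime one of the five process names.
#' @return named list of generator parameters.
#' @export
regime_defaults <- function(regime = c("variable_selection",
                                       "homogeneous_selection",
                                       "homogeneous_dispersal",
                                       "dispersal_limitation", "drift")) {
  regime <- match.arg(regime)
  switch(regime,
    variable_selection = list(selection_strength = 2, env_mode = "gradient",
                              dispersal_rate = 0, drift_sd = 0.3,
                              lottery = 0.5, drift_depth = 5000,
                              site_pool_frac = 1, mixing_depth = NA),
    homogeneous_selection = list(selection_strength = 2, env_mode = "constant",
                                 dispersal_rate = 0, drift_sd = 0.2,
                                 lottery = 0.5, drift_depth = 5000,
                                 site_pool_frac = 1, mixing_depth = NA),
    homogeneous_dispersal = list(selection_strength = 0, env_mode = "gradient",
                                 dispersal_rate = 0, drift_sd = 1.5,
                                 lottery = 0.8, drift_depth = 2000,
                                 site_pool_frac = 1, mixing_depth = 100),
    dispersal_limitation = list(selection_strength = 0, env_mode = "gradient",
                                dispersal_rate = 0, drift_sd = 1,
                                lottery = 1, drift_depth = 5000,
                                site_pool_frac = 0.25, mixing_depth = NA),
    drift = list(selection_strength = 0, env_mode = "gradient",
                 dispersal_rate = 0, drift_sd = 1.5, lottery = 0.7,
                 drift_depth = 500, site_pool_frac = 1, mixing_depth = NA))
}

#' Build a simulation configuration
#'
#' The stated world of the generator: a five-site, eight-layer water-column
#' design (40 samples), 300 OTUs, 5,000 reads per sample, matching the shape
#' of a typical seamount survey. Regime-specific parameters default to
#' [regime_defaults()] and can be overridden individually.
#'
#' @param regime generating assembly regime.
#' @param n_otus number of OTUs.
#' @param n_sites number of sampling sites.
#' @param layers named depth vector (strictly increasing).
#' @param niche_conservatism Brownian rate for [evolve_niche()].
#' @param env_noise_sd per-sample noise on the environmental axis.
#' @param meta_sd log-normal spread of metacommunity relative abundances.
#' @param seed integer seed.
#' @param ... overrides for the regime parameters
#'   (`selection_strength`, `dispersal_rate`, `drift_sd`, `lottery`,
#'   `drift_depth`, `env_mode`, `site_pool_frac`, `mixing_depth`).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(regime = "variable_selection", n_otus = 300,
                              n_sites = 5, layers = default_layers(),
                              niche_conservatism = 1, env_noise_sd = 0.1,
                              meta_sd = 0.3, seed = NULL, ...) {
  base <- regime_defaults(regime)
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0)
    abort(paste0("unknown parameters: ", paste(unknown, collapse = ", ")),
          class = "pelagos_domain_error")
  base[names(over)] <- over
  if (base$selection_strength < 0)
    abort("selection_strength must be >= 0", class = "pelagos_domain_error")
  if (base$dispersal_rate < 0 || base$dispersal_rate > 1)
    abort("dispersal_rate must be in [0, 1]", class = "pelagos_domain_error")
  if (is.unsorted(layers, strictly = TRUE))
    abort("layers must be strictly increasing in depth",
          class = "pelagos_domain_error")
  if (base$lottery <= 0 || base$lottery > 1)
    abort("lottery must be in (0, 1]", class = "pelagos_domain_error")
  structure(c(list(regime = regime, n_otus = n_otus, n_sites = n_sites,
                   layers = layers, niche_conservatism = niche_conservatism,
                   env_noise_sd = env_noise_sd, meta_sd = meta_sd,
                   seed = seed), base),
            class = "simulation_config")
}

# depth-correlated environmental factor table (units approximate field
# values; every factor is a monotone or peaked function of depth plus noise)
env_factor_table <- function(depths) {
  n <- length(depths)
  noise <- function(sd) rnorm(n, 0, sd)
  tibble(
    depth = depths,
    temperature = pmax(0.5, 1.5 + 26.5 * exp(-depths / 300) + noise(0.3)),
    salinity = 34.4 + 0.4 * exp(-depths / 150) + noise(0.02),
    NO3_N = pmax(0, 38 * depths / (depths + 400) + noise(0.8)),
    NO2_N = pmax(0, 0.25 * exp(-((depths - 75) / 60)^2) + noise(0.02)),
    NH4_N = pmax(0, 0.3 * exp(-depths / 200) + noise(0.03)),
    SiO3_Si = pmax(0, 150 * depths / (depths + 1500) + noise(2)),
    PO4_P = pmax(0, 2.8 * depths / (depths + 500) + noise(0.06)),
    dissolved_oxygen = 7 - 3.5 * exp(-((log(depths) - log(800)) / 0.9)^2) +
      noise(0.1),
    chlorophyll_a = pmax(0.001, 0.45 * exp(-((depths - 75) / 45)^2) +
                           noise(0.01)),
    POC = pmax(0.5, 6 * exp(-depths / 400) + 1 + noise(0.2))
  )
}

#' Assemble synthetic communities under a known regime
#'
#' For each sample the expected relative abundance is the metacommunity
#' profile filtered by a Gaussian niche kernel
#' \eqn{\exp(-\omega (niche - env)^2)} on the sample's position along a
#' depth-driven environmental axis, mixed with the unfiltered metacommunity
#' at the dispersal rate, perturbed by independent log-normal drift noise,
#' and finally drawn as a multinomial of `drift_depth` reads. Under the
#' dispersal-limitation regime each site additionally restricts colonisation
#' to its own random subset of the OTU pool.
#'
#' @param tree phylogeny from [simulate_tree()].
#' @param niches niche optima from [evolve_niche()].
#' @param config a [simulation_config()].
#' @return list of class `community_simulation`: `counts` (samples x OTUs),
#'   `samples` (tibble with site, layer, depth and environmental factors),
#'   `truth` (regime, niches, per-sample environmental axis value,
#'   metacommunity profile).
#' @export
assemble_communities <- function(tree, niches, config) {
  stopifnot(inherits(config, "simulation_config"))
  n_otus <- length(niches)
  sites <- paste0("S", seq_len(config$n_sites))
  design <- tidyr::expand_grid(site = sites,
                               layer = names(config$layers))
  design$depth <- unname(config$layers[design$layer])
  design$sample_id <- paste0(design$site, "_", design$layer)
  n_samp <- nrow(design)

  with_seed_(config$seed, {
    meta <- exp(rnorm(n_otus, 0, config$meta_sd))  # log-normal metacommunity
    meta <- meta / sum(meta)
    names(meta) <- names(niches)

    # environmental axis: log-depth mapped onto the occupied span of the
    # niche trait (inner 90% of tip optima; the tails are taxa-sparse)
    ld <- log10(design$depth)
    axis01 <- (ld - min(ld)) / (max(ld) - min(ld))
    rng <- unname(quantile(niches, c(0.05, 0.95)))
    env_axis <- switch(config$env_mode,
      gradient = rng[1] + axis01 * diff(rng),
      constant = rep(unname(median(niches)), n_samp),
      abort("unknown env_mode", class = "pelagos_domain_error"))
    env_axis <- env_axis + rnorm(n_samp, 0, config$env_noise_sd)

    site_pools <- lapply(sites, function(s) {
      if (config$site_pool_frac >= 1) rep(TRUE, n_otus)
      else seq_len(n_otus) %in% sample.int(n_otus,
                                           ceiling(config$site_pool_frac * n_otus))
    })
    names(site_pools) <- sites

    counts <- matrix(0L, n_samp, n_otus,
                     dimnames = list(design$sample_id, names(niches)))
    # vertical mixing: samples below mixing_depth are replicates of one
    # shared realized community (homogenising dispersal), instead of
    # drawing independent drift/lottery realizations
    mixed <- !is.na(config$mixing_depth) & design$depth > config$mixing_depth
    shared_keep <- if (config$lottery < 1)
      stats::rbinom(n_otus, 1, config$lottery) else rep(1, n_otus)
    shared_noise <- exp(rnorm(n_otus, 0, config$drift_sd))

    for (s in seq_len(n_samp)) {
      filt <- exp(-config$selection_strength * (niches - env_axis[s])^2)
      if (mixed[s]) {
        keep <- shared_keep
        noise <- shared_noise
      } else {
        # colonisation lottery: independent per-sample membership turnover
        keep <- if (config$lottery < 1)
          stats::rbinom(n_otus, 1, config$lottery) else 1
        noise <- exp(rnorm(n_otus, 0, config$drift_sd))
      }
      local <- meta * filt * site_pools[[design$site[s]]] * keep * noise
      if (sum(local) == 0) local <- meta
      local <- local / sum(local)
      p <- config$dispersal_rate * meta + (1 - config$dispersal_rate) * local
      counts[s, ] <- rmultinom(1, config$drift_depth, p)
    }
    # a sample could in principle end up empty only if drift_depth were 0
    env <- env_factor_table(design$depth)
    samples <- dplyr::bind_cols(
      tibble(sample_id = design$sample_id, site = design$site,
             layer = design$layer),
      env)

    structure(list(
      counts = counts,
      samples = samples,
      truth = list(regime = config$regime, niches = niches,
                   env_axis = setNames(env_axis, design$sample_id),
                   metacommunity = meta, config = config)
    ), class = "community_simulation")
  })
}

#' Simulate a full synthetic survey in one call
#'
#' Tree, niches, and communities under one regime and one seed.
#'
#' @param config a [simulation_config()] (its `seed` drives everything).
#' @return a `community_simulation` with `tree` attached.
#' @export
simulate_survey <- function(config = simulation_config()) {
  seed <- config$seed
  tree <- simulate_tree(config$n_otus,
                        seed = if (is.null(seed)) NULL else seed)
  niches <- evolve_niche(tree, bm_rate = config$niche_conservatism,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  config2 <- config
  config2$seed <- if (is.null(seed)) NULL else seed + 2L
  sim <- assemble_communities(tree, niches, config2)
  sim$tree <- tree
  sim$truth$config <- config
  sim
}

#' @export
print.community_simulation <- function(x, ...) {
  cat("Synthetic community survey:", nrow(x$counts), "samples x",
      ncol(x$counts), "OTUs, regime =", x$truth$regime, "\n")
  invisible(x)
}
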