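#' Subset every input to a common sample arrangement
#'
#' Consistent filtering of an OTU table, metadata, distance/phi matrices, or
#' a whole simulation to a sample list — used for matched-arrangement
#' re-analyses where one group's sample set constrains the others. Results
#' computed on the subset equal results computed from pre-filtered inputs.
#'
#' @param x count matrix, labelled square matrix, `dist`, tibble with
#'   `sample_id`, or `community_simulation`.
#' @param samples character vector of sample ids to keep.
#' @return `x` filtered to `samples`, same type.
#' @export
subset_samples <- function(x, samples) {
  UseMethod("subset_samples")
}

#' @export
subset_samples.matrix <- function(x, samples) {
  unknown <- setdiff(samples, rownames(x))
  if (length(unknown) > 0)
    abort(paste0("unknown sample ids: ", paste(unknown, collapse = ", ")),
          class = "pelagos_id_error")
  square <- !is.null(colnames(x)) && identical(rownames(x), colnames(x))
  if (square) x[samples, samples, drop = FALSE]
  else x[samples, , drop = FALSE]
}

#' @export
subset_samples.dist <- function(x, samples) {
  as.dist(subset_samples(as.matrix(x), samples))
}

#' @export
subset_samples.data.frame <- function(x, samples) {
  unknown <- setdiff(samples, x$sample_id)
  if (length(unknown) > 0)
    abort(paste0("unknown sample ids: ", paste(unknown, collapse = ", ")),
          class = "pelagos_id_error")
  x[match(samples, x$sample_id), , drop = FALSE]
}

#' @export
subset_samples.community_simulation <- function(x, samples) {
  x$counts <- subset_samples(x$counts, samples)
  x$samples <- subset_samples(x$samples, samples)
  x$truth$env_axis <- x$truth$env_axis[samples]
  x
}

# deterministic per-stage seeds fanned out from the global seed; each stage
# gets its own stream so changing one stage's replicate count cannot perturb
# another stage's results
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(simulate = 11L, diversity = 23L, compositional = 37L,
               network = 53L, assembly = 71L, rda = 97L)
  (as.integer(seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order — input (read or
#' simulate), diversity, compositional, then network / assembly / rda — with
#' consistent seeding, and writes all artifacts plus a checksummed manifest
#' via [write_results()]. Two runs with the same config and seed are
#' bit-identical on every TSV/JSON output.
#'
#' The config is a named list (or path to a JSON file) with elements:
#' `simulate` (arguments for [simulation_config()]) *or* `inputs` (paths
#' `otu_table`, `tree`, `samples`), `stages` (subset of `"diversity"`,
#' `"compositional"`, `"network"`, `"assembly"`, `"rda"`), `seed`, and
#' optional per-stage parameter lists `diversity`, `compositional`,
#' `network`, `assembly`, `rda` mirroring the function arguments.
#'
#' @param config named list or JSON path.
#' @param out_dir output directory; nothing is written when `NULL`.
#' @return a [result_bundle()] with the manifest attached (when written).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stages <- config$stages %||% c("diversity", "compositional", "network",
                                 "assembly", "rda")
  seed <- config$seed
  results <- list()
  meta <- list(seed = seed, stages = stages,
               package_version = as.character(utils::packageVersion("pelagos")))

  # --- inputs -------------------------------------------------------------
  tree <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% stage_seed(seed, "simulate")
    cfg <- do.call(simulation_config, sim_args)
    sim <- simulate_survey(cfg)
    counts <- sim$counts
    samples <- sim$samples
    tree <- sim$tree
    meta$simulate <- sim_args[setdiff(names(sim_args), "layers")]
  } else if (!is.null(config$inputs)) {
    counts <- read_otu_table(config$inputs$otu_table)
    samples <- as_tibble(read.delim(config$inputs$samples))
    if (!is.null(config$inputs$tree)) tree <- read_phylo_tree(config$inputs$tree)
  } else {
    abort("config needs either a `simulate` block or `inputs` paths",
          class = "pelagos_config_error")
  }
  if ("assembly" %in% stages && is.null(tree))
    abort("assembly stage requested but no tree is available",
          class = "pelagos_config_error")
  if (!is.null(config$subset))
    { counts <- subset_samples(counts, config$subset)
      samples <- subset_samples(samples, config$subset) }

  results$otu_table <- counts
  results$sample_table <- samples

  # --- diversity ----------------------------------------------------------
  if ("diversity" %in% stages) {
    pars <- config$diversity %||% list()
    norm <- normalize_to_min_depth(counts,
                                   seed = stage_seed(seed, "diversity"))
    rt <- richness_by_group(norm, samples, group_col = "layer",
                            alpha = pars$alpha %||% 0.05)
    results$normalized_table <- norm
    results$richness <- tidy(rt)
    results$richness_test <- as.list(glance(rt))
    meta$diversity <- list(normalized_depth = attr(norm, "normalized_depth"),
                           seed = stage_seed(seed, "diversity"))
  } else {
    norm <- counts
  }

  # --- compositional ------------------------------------------------------
  clr <- NULL
  if (any(c("compositional", "network", "rda") %in% stages)) {
    pars <- config$compositional %||% list()
    delta <- pars$delta %||% 0.65
    clr <- clr_transform(replace_zeros(counts, delta))
    if ("compositional" %in% stages) {
      n_perm <- pars$n_perm %||% 999
      cl <- cluster_samples(counts, n_perm = n_perm,
                            alpha = pars$alpha %||% 0.05,
                            seed = stage_seed(seed, "compositional"),
                            delta = delta)
      results$aitchison_dist <- as.matrix(cl$distance)
      results$cluster_groups <- tidy(cl)
      meta$compositional <- list(n_perm = n_perm, delta = delta,
                                 linkage = cl$linkage,
                                 seed = stage_seed(seed, "compositional"))
    }
  }

  # --- network ------------------------------------------------------------
  if ("network" %in% stages) {
    pars <- config$network %||% list()
    threshold <- pars$threshold %||% 0.15
    phi <- phi_matrix(clr)
    g <- build_network(phi, threshold = threshold, metadata = samples)
    results$phi <- phi
    results$network <- g
    results$connectivity <- connectivity_report(g, seed = stage_seed(seed, "network"))
    results$shared_otu_horizontal <- shared_otu_horizontal(counts, samples)
    results$shared_otu_vertical <- shared_otu_vertical(counts, samples)
    meta$network <- list(threshold = threshold,
                         seed = stage_seed(seed, "network"))
  }

  # --- assembly -----------------------------------------------------------
  if ("assembly" %in% stages) {
    pars <- config$assembly %||% list()
    n_null_bnti <- pars$n_null_bnti %||% 999
    n_null_rc <- pars$n_null_rc %||% 9999
    # assembly runs on the depth-normalized table (relative abundances are
    # taken inside beta_mntd); falls back to the raw counts when the
    # diversity stage was not requested
    al <- align_tree_table(norm, tree, action = pars$coverage %||% "error")
    part <- quantify_assembly(al$table, al$tree,
                              n_null_bnti = n_null_bnti,
                              n_null_rc = n_null_rc,
                              seed = stage_seed(seed, "assembly"))
    results$bnti <- part$bnti_result$bnti
    results$process_pairs <- tidy(part)
    results$process_summary <- list(
      fractions = setNames(as.list(part$summary$fraction),
                           part$summary$process),
      n_pairs = sum(part$summary$n_pairs), n_excluded = part$n_excluded)
    meta$assembly <- list(n_null_bnti = n_null_bnti, n_null_rc = n_null_rc,
                          seed = stage_seed(seed, "assembly"))
  }

  # --- rda ----------------------------------------------------------------
  if ("rda" %in% stages) {
    pars <- config$rda %||% list()
    fs <- forward_select(clr, samples,
                         factors = pars$factors,
                         alpha = pars$alpha %||% 0.01,
                         n_perm = pars$n_perm %||% 999,
                         seed = stage_seed(seed, "rda"))
    results$rda_selection <- tidy(fs)
    results$rda_summary <- as.list(glance(fs))
    meta$rda <- list(alpha = pars$alpha %||% 0.01,
                     n_perm = pars$n_perm %||% 999,
                     seed = stage_seed(seed, "rda"))
  }

  bundle <- result_bundle(results, metadata = meta)
  if (!is.null(out_dir)) {
    manifest <- write_results(bundle, out_dir)
    attr(bundle, "manifest") <- manifest
  }
  bundle
}
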