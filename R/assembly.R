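#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree `phylo` object with branch lengths.
#' @return symmetric matrix labelled by tip.
#' @export
patristic_matrix <- function(tree) {
  stats::cophenetic(tree)
}

# rows of x as relative abundances, aligned to the distance matrix
rel_abund_aligned <- function(x, d) {
  missing <- setdiff(colnames(x), rownames(d))
  if (length(missing) > 0)
    abort(paste0("OTUs absent from the distance matrix: ",
                 paste(head(missing, 10), collapse = ", ")),
          class = "pelagos_coverage_error")
  d <- d[colnames(x), colnames(x)]
  if (any(rowSums(x) == 0))
    abort("every sample needs at least one OTU present",
          class = "pelagos_validation_error")
  list(freq = x / rowSums(x), d = d)
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For samples A and B with within-sample relative abundances \eqn{f},
#' \deqn{\beta MNTD = 0.5 [ \sum_{i \in A} f_{iA} \min_{j \in B} d_{ij}
#'                        + \sum_{j \in B} f_{jB} \min_{i \in A} d_{ij} ]}
#' where the minimum runs over OTUs present in the other sample, so a taxon
#' present in both contributes zero for that direction.
#'
#' @param x samples x OTUs count (or relative abundance) matrix.
#' @param d patristic distance matrix covering every OTU in `x` (or a
#'   `phylo` tree, converted via [patristic_matrix()]).
#' @return symmetric samples x samples matrix of beta MNTD values.
#' @export
beta_mntd <- function(x, d) {
  if (inherits(d, "phylo")) d <- patristic_matrix(d)
  al <- rel_abund_aligned(as.matrix(x), d)
  out <- cpp_bmntd(al$freq, al$d)
  dimnames(out) <- list(rownames(x), rownames(x))
  out
}

#' Beta nearest taxon index (phylogenetic turnover z-score)
#'
#' Standardizes observed beta MNTD against a taxa-shuffle null in which OTU
#' labels are permuted on the patristic distance matrix:
#' \deqn{\beta NTI = (\beta MNTD_{obs} - mean(\beta MNTD_{null})) /
#'        sd(\beta MNTD_{null}).}
#' One shuffle per null replicate is shared across all sample pairs, so the
#' replicates are mutually consistent. `|betaNTI| > 2` is conventionally read
#' as selection: above +2 heterogeneous (variable) selection, below -2
#' homogeneous selection. Pairs whose null spread is zero (e.g. a star tree
#' with equal branch lengths) are flagged undefined (`NA`).
#'
#' @param x samples x OTUs count matrix.
#' @param tree `phylo` tree (or a precomputed patristic matrix).
#' @param n_null number of label shuffles (999 by default).
#' @param seed integer seed.
#' @return object of class `bnti_result` with matrices `bnti`, `bmntd_obs`,
#'   `null_mean`, `null_sd`.
#' @export
bnti <- function(x, tree, n_null = 999, seed = NULL) {
  d <- if (inherits(tree, "phylo")) patristic_matrix(tree) else tree
  al <- rel_abund_aligned(as.matrix(x), d)
  n_otu <- ncol(al$freq)
  perms <- with_seed_(seed, {
    t(vapply(seq_len(n_null), function(i) sample.int(n_otu) - 1L,
             integer(n_otu)))
  })
  res <- cpp_bnti_null(al$freq, al$d, perms)
  z <- (res$obs - res$null_mean) / res$null_sd
  undef <- res$null_sd < 1e-12
  z[undef] <- NA_real_
  diag(z) <- 0
  lab <- list(rownames(x), rownames(x))
  dimnames(z) <- lab
  dimnames(res$obs) <- lab
  dimnames(res$null_mean) <- lab
  dimnames(res$null_sd) <- lab
  structure(list(bnti = z, bmntd_obs = res$obs, null_mean = res$null_mean,
                 null_sd = res$null_sd, n_null = n_null, seed = seed),
            class = "bnti_result")
}

#' Raup-Crick beta diversity on occurrence data
#'
#' For a pair with observed richnesses \eqn{n_A, n_B}, each null replicate
#' draws \eqn{n_A} and \eqn{n_B} OTUs from the pool without replacement with
#' probability proportional to a weight (occupancy frequency across all
#' samples by default) and counts shared OTUs. With
#' \eqn{p = [\#(SS_{null} > SS_{obs}) + 0.5\,\#(SS_{null} = SS_{obs})] /
#' n_{null}}, \eqn{\beta_{RC} = 2(p - 0.5) \in [-1, 1]}; positive values mean
#' the pair shares fewer taxa than the null expects (dispersal limitation at
#' the +0.95 extreme), negative values more (homogeneous dispersal at -0.95).
#'
#' @param x samples x OTUs count matrix; occurrence is `count > 0`.
#' @param n_null null replicates (9,999 by default).
#' @param seed integer seed.
#' @param weighting `"occupancy"` (default), `"equal"`, or `"abundance"`
#'   draw weights.
#' @return symmetric samples x samples matrix of beta_RC values.
#' @export
raup_crick <- function(x, n_null = 9999, seed = NULL,
                       weighting = c("occupancy", "equal", "abundance")) {
  weighting <- match.arg(weighting)
  x <- as.matrix(x)
  if (nrow(x) < 2)
    abort("need at least 2 samples", class = "pelagos_validation_error")
  P <- x > 0
  w <- switch(weighting,
    occupancy = colSums(P),
    equal = as.numeric(colSums(P) > 0),
    abundance = colSums(x))
  if (any(rowSums(P) > sum(w > 0)))
    abort("sample richness exceeds the null pool size",
          class = "pelagos_validation_error")
  res <- with_seed_(seed, cpp_raup_crick(P, as.numeric(w), as.integer(n_null)))
  brc <- res$brc
  dimnames(brc) <- list(rownames(x), rownames(x))
  attr(brc, "ss_obs") <- res$ss_obs
  attr(brc, "n_null") <- n_null
  attr(brc, "weighting") <- weighting
  brc
}

#' Classify sample pairs into assembly processes
#'
#' The two-stage null-model rule: \eqn{\beta NTI > 2} is variable
#' (heterogeneous) selection and \eqn{\beta NTI < -2} homogeneous selection;
#' for the remaining pairs \eqn{\beta_{RC} > 0.95} is dispersal limitation,
#' \eqn{\beta_{RC} < -0.95} homogeneous dispersal, and \eqn{|\beta_{RC}| \le
#' 0.95} drift. Pairs with an undefined \eqn{\beta NTI} are excluded and
#' counted.
#'
#' @param bnti_mat symmetric beta NTI matrix (or a `bnti_result`).
#' @param brc_mat symmetric beta_RC matrix aligned on the same samples; only
#'   consulted for pairs with `|betaNTI| <= 2`.
#' @return object of class `process_partition`: per-pair tibble and a
#'   fraction-per-process summary.
#' @export
partition_processes <- function(bnti_mat, brc_mat) {
  if (inherits(bnti_mat, "bnti_result")) bnti_mat <- bnti_mat$bnti
  if (!identical(rownames(bnti_mat), rownames(brc_mat)))
    abort("beta NTI and beta_RC matrices must cover the same samples",
          class = "pelagos_validation_error")
  ids <- rownames(bnti_mat)
  pr <- which(upper.tri(bnti_mat), arr.ind = TRUE)
  b <- bnti_mat[pr]
  r <- brc_mat[pr]
  process <- dplyr::case_when(
    is.na(b) ~ NA_character_,
    b > 2 ~ "variable_selection",
    b < -2 ~ "homogeneous_selection",
    is.na(r) ~ NA_character_,
    r > 0.95 ~ "dispersal_limitation",
    r < -0.95 ~ "homogeneous_dispersal",
    TRUE ~ "drift"
  )
  pairs <- tibble(
    sample_a = ids[pr[, 1]], sample_b = ids[pr[, 2]],
    bnti = b,
    brc = ifelse(!is.na(b) & abs(b) <= 2, r, NA_real_),
    process = process
  )
  lev <- c("variable_selection", "homogeneous_selection",
           "dispersal_limitation", "homogeneous_dispersal", "drift")
  ok <- !is.na(pairs$process)
  counts <- table(factor(pairs$process[ok], levels = lev))
  summary <- tibble(process = lev,
                    n_pairs = as.integer(counts),
                    fraction = if (sum(ok)) as.numeric(counts) / sum(ok)
                               else rep(NA_real_, 5))
  structure(list(pairs = pairs, summary = summary,
                 n_excluded = sum(!ok)),
            class = "process_partition")
}

#' Quantify assembly processes end to end
#'
#' Runs [bnti()] and [raup_crick()] and combines them with
#' [partition_processes()]. By default beta_RC is the second stage and only
#' evaluated for pairs not already assigned to selection; `rc_full = TRUE`
#' also keeps the full matrix.
#'
#' @inheritParams bnti
#' @inheritParams raup_crick
#' @param n_null_bnti null replicates for beta NTI.
#' @param n_null_rc null replicates for beta_RC.
#' @param rc_full keep the ungated beta_RC matrix in the result?
#' @return a `process_partition` with `bnti_result` and `brc` attached.
#' @export
quantify_assembly <- function(x, tree, n_null_bnti = 999, n_null_rc = 9999,
                              seed = NULL, weighting = "occupancy",
                              rc_full = FALSE) {
  seed_b <- if (is.null(seed)) NULL else as.integer(seed)
  seed_r <- if (is.null(seed)) NULL else as.integer(seed) + 1L
  bn <- bnti(x, tree, n_null = n_null_bnti, seed = seed_b)
  rc <- raup_crick(x, n_null = n_null_rc, seed = seed_r, weighting = weighting)
  part <- partition_processes(bn, rc)
  part$bnti_result <- bn
  if (rc_full) part$brc_full <- rc
  part$params <- list(n_null_bnti = n_null_bnti, n_null_rc = n_null_rc,
                      seed = seed, weighting = weighting)
  part
}

#' @describeIn partition_processes per-pair classification.
#' @param x a `process_partition`.
#' @param ... unused.
#' @export
tidy.process_partition <- function(x, ...) x$pairs

#' @describeIn partition_processes one-row fraction summary.
#' @export
glance.process_partition <- function(x, ...) {
  wide <- setNames(as.list(x$summary$fraction), x$summary$process)
  dplyr::bind_cols(tibble(n_pairs = sum(x$summary$n_pairs),
                          n_excluded = x$n_excluded),
                   as_tibble(wide))
}

#' @export
print.process_partition <- function(x, ...) {
  cat("Assembly process partition over", sum(x$summary$n_pairs), "pairs")
  if (x$n_excluded > 0) cat(" (", x$n_excluded, " excluded)", sep = "")
  cat("\n")
  print(x$summary)
  invisible(x)
}
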