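#' Normalize all samples to the minimum sequencing depth
#'
#' Each sample is subsampled once, without replacement, to the smallest row
#' total (or an explicit depth), so per-sample richness is comparable across
#' samples. One random subsample is drawn per sample rather than an average
#' over many, and the seed is recorded as an attribute.
#'
#' @param x samples x OTUs count matrix.
#' @param depth target depth; defaults to the minimum row total.
#' @param seed integer seed for the subsampling.
#' @return count matrix with every row summing to `depth`.
#' @export
normalize_to_min_depth <- function(x, depth = NULL, seed = NULL) {
  validate_otu_table(x)
  totals <- rowSums(x)
  depth <- depth %||% min(totals)
  if (any(totals < depth))
    abort("all samples must have at least `depth` reads",
          class = "pelagos_validation_error")
  # rrarefy's "observed counts" warning is a heuristic; inputs are validated
  out <- with_seed_(seed, suppressWarnings(vegan::rrarefy(x, depth)))
  dimnames(out) <- dimnames(x)
  storage.mode(out) <- "integer"
  attr(out, "normalized_depth") <- as.integer(depth)
  attr(out, "seed") <- seed
  out
}

#' Expected rarefaction curve
#'
#' Analytic expected richness at each subsampling depth under hypergeometric
#' subsampling without replacement:
#' \eqn{E[S_n] = \sum_i (1 - C(N - N_i, n) / C(N, n))}.
#'
#' @param x count matrix (samples x OTUs) or a single sample's count vector.
#' @param depths integer vector of subsample sizes; defaults to an even grid
#'   up to each sample's total.
#' @param n_grid grid size when `depths` is NULL.
#' @return tibble with `sample_id`, `depth`, `expected_richness`.
#' @export
rarefaction_curve <- function(x, depths = NULL, n_grid = 25) {
  if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1, dimnames = list("sample", paste0("otu", seq_along(x))))
  }
  purrr::map_dfr(rownames(x), function(s) {
    counts <- x[s, ]
    total <- sum(counts)
    dd <- depths %||% unique(round(seq(1, total, length.out = n_grid)))
    if (any(dd > total))
      abort(paste0("depth exceeds total reads of sample ", s),
            class = "pelagos_domain_error")
    tibble(
      sample_id = s,
      depth = as.integer(dd),
      # rarefy warns when the smallest count exceeds 1 (a heuristic about
      # whether the data are counts); our inputs are validated counts
      expected_richness = as.numeric(suppressWarnings(
        vegan::rarefy(counts, sample = dd)))
    )
  })
}

#' OTU richness per sample with between-group testing
#'
#' Observed richness (OTUs with at least one read) per sample, compared
#' between groups (typically depth layers). The test branch follows the usual
#' gate: Shapiro-Wilk normality within every group and Bartlett homogeneity
#' across groups at `gate_alpha`; if both pass, one-way ANOVA, followed (when
#' the ANOVA is significant at `alpha`) by Fisher's LSD with compact letter
#' display; otherwise the Kruskal-Wallis rank sum test. The report records
#' which branch ran.
#'
#' Fisher's LSD is the unadjusted pairwise t test with the pooled within-group
#' mean square; no multiplicity correction is applied, which is the
#' definition of the procedure.
#'
#' @param x samples x OTUs count matrix (normalize first for comparability).
#' @param groups factor/character vector named by sample, or a data frame
#'   with `sample_id` and a grouping column.
#' @param group_col grouping column name when `groups` is a data frame.
#' @param alpha significance level for the omnibus test and LSD letters.
#' @param gate_alpha level for the normality/homoscedasticity gate.
#' @return object of class `richness_test`; see [tidy.richness_test()].
#' @export
richness_by_group <- function(x, groups, group_col = "layer",
                              alpha = 0.05, gate_alpha = 0.05) {
  validate_otu_table(x)
  if (is.data.frame(groups)) {
    g <- setNames(as.character(groups[[group_col]]), groups$sample_id)
  } else {
    g <- setNames(as.character(groups), names(groups) %||% rownames(x))
  }
  g <- g[rownames(x)]
  if (anyNA(g))
    abort("every sample needs a group", class = "pelagos_grouping_error")
  richness <- rowSums(x > 0)
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2))
    abort("need >= 2 groups with >= 2 samples each",
          class = "pelagos_grouping_error")

  df <- tibble(sample_id = rownames(x), group = g,
               observed_richness = as.integer(richness))
  grp <- factor(df$group)

  degenerate <- all(richness == richness[1])
  if (degenerate) {
    out <- list(richness = df, method = "degenerate",
                p.value = NA_real_, statistic = NA_real_,
                letters = NULL, gate = NULL, alpha = alpha)
    class(out) <- "richness_test"
    return(out)
  }

  shapiro_p <- vapply(split(df$observed_richness, grp), function(v) {
    if (length(unique(v)) == 1) return(0)  # constant within group: not normal
    if (length(v) < 3) return(0)           # too small to assess: fail the gate
    shapiro.test(v)$p.value
  }, numeric(1))
  bartlett_p <- tryCatch(
    bartlett.test(df$observed_richness, grp)$p.value,
    error = function(e) 0)
  gate <- list(shapiro_p = shapiro_p, bartlett_p = bartlett_p,
               passed = all(shapiro_p > gate_alpha) && bartlett_p > gate_alpha)

  if (gate$passed) {
    fit <- aov(observed_richness ~ group, data = df)
    an <- summary(fit)[[1]]
    p <- an[["Pr(>F)"]][1]
    statistic <- an[["F value"]][1]
    method <- "anova"
    letters <- if (p < alpha)
      lsd_letters(df$observed_richness, grp, alpha = alpha) else NULL
  } else {
    kw <- kruskal.test(df$observed_richness, grp)
    p <- kw$p.value
    statistic <- unname(kw$statistic)
    method <- "kruskal-wallis"
    letters <- NULL
  }

  out <- list(richness = df, method = method, p.value = p,
              statistic = statistic, letters = letters, gate = gate,
              alpha = alpha)
  class(out) <- "richness_test"
  out
}

# Fisher's LSD pairwise t tests with pooled MSE, summarised as a compact
# letter display. Groups share a letter iff every pair inside the letter's
# clique is non-significant; letters are ordered by decreasing group mean.
lsd_letters <- function(values, grp, alpha = 0.05) {
  grp <- factor(grp)
  k <- nlevels(grp)
  ns <- tapply(values, grp, length)
  means <- tapply(values, grp, mean)
  n_tot <- length(values)
  mse <- sum(tapply(values, grp, function(v) sum((v - mean(v))^2))) / (n_tot - k)
  dfree <- n_tot - k

  pmat <- matrix(1, k, k, dimnames = list(levels(grp), levels(grp)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tt <- if (se == 0) Inf else abs(means[i] - means[j]) / se
    p <- 2 * pt(tt, dfree, lower.tail = FALSE)
    pmat[i, j] <- p
    pmat[j, i] <- p
  }

  # non-significant pairs form a graph; maximal cliques become letters
  adj <- pmat >= alpha
  diag(adj) <- FALSE
  gph <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(gph)
  if (length(cliques) == 0) cliques <- lapply(seq_len(k), identity)
  # singletons not inside any clique still get a letter
  covered <- unique(unlist(lapply(cliques, as.integer)))
  lone <- setdiff(seq_len(k), covered)
  cliques <- c(cliques, lapply(lone, identity))
  cl_means <- vapply(cliques, function(cl) max(means[as.integer(cl)]), numeric(1))
  cliques <- cliques[order(-cl_means)]
  lab <- rep("", k)
  for (ci in seq_along(cliques)) {
    members <- as.integer(cliques[[ci]])
    lab[members] <- paste0(lab[members], letters[ci])
  }
  tibble(group = levels(grp), mean = as.numeric(means), n = as.integer(ns),
         letters = lab)
}

#' @describeIn richness_by_group per-sample richness with group letters.
#' @param x a `richness_test` object.
#' @param ... unused.
#' @export
tidy.richness_test <- function(x, ...) {
  df <- x$richness
  if (!is.null(x$letters))
    df <- dplyr::left_join(df, dplyr::select(x$letters, "group", "letters"),
                           by = "group")
  df
}

#' @describeIn richness_by_group one-row test summary.
#' @export
glance.richness_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p.value = x$p.value,
         gate_passed = if (is.null(x$gate)) NA else x$gate$passed,
         n_groups = length(unique(x$richness$group)),
         n_samples = nrow(x$richness))
}

#' @export
print.richness_test <- function(x, ...) {
  cat("Richness test (", x$method, "): p = ", format(x$p.value), "\n", sep = "")
  if (!is.null(x$letters)) print(x$letters)
  invisible(x)
}
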