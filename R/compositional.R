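#' Count-zero-multiplicative zero replacement
#'
#' Replaces zero counts with a small pseudo-proportion scaled by the sample's
#' sequencing depth and multiplicatively shrinks the non-zero entries so each
#' row remains a composition (sums to 1). The replacement for a zero in a
#' sample of total \eqn{t} is \eqn{\delta / t} with \eqn{\delta = 0.65} by
#' default, the common count-zero-multiplicative choice.
#'
#' @param x samples x OTUs count matrix.
#' @param delta zero-replacement multiplier.
#' @return strictly positive matrix of row compositions (rows sum to 1).
#' @export
replace_zeros <- function(x, delta = 0.65) {
  validate_otu_table(x)
  totals <- rowSums(x)
  out <- x / totals
  for (i in seq_len(nrow(x))) {
    z <- x[i, ] == 0
    if (!any(z)) next
    repl <- delta / totals[i]
    # very sparse, shallow rows could push the total replaced mass past the
    # whole composition; cap it at half so the row stays a valid composition
    if (sum(z) * repl >= 0.5) repl <- 0.5 / sum(z)
    mass <- sum(z) * repl
    out[i, z] <- repl
    out[i, !z] <- out[i, !z] * (1 - mass)
  }
  out
}

#' Centred log-ratio transform
#'
#' \eqn{clr(x)_j = \ln(x_j / g(x))} with \eqn{g} the row geometric mean; rows
#' of the result sum to zero and the transform is invariant to row scaling.
#'
#' @param x strictly positive matrix (use [replace_zeros()] first on counts).
#' @return CLR matrix, same shape and dimnames.
#' @export
clr_transform <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x) || any(x <= 0))
    abort("CLR needs strictly positive entries; replace zeros first",
          class = "pelagos_domain_error")
  lx <- log(x)
  sweep(lx, 1, rowMeans(lx))
}

#' Aitchison distance between samples
#'
#' Euclidean distance between CLR-transformed rows. Counts are zero-replaced
#' and CLR-transformed first when `from = "counts"`.
#'
#' @param x CLR matrix or count matrix.
#' @param from what `x` holds.
#' @param delta passed to [replace_zeros()] when starting from counts.
#' @return a `dist` object labelled by sample.
#' @export
aitchison_dist <- function(x, from = c("clr", "counts"), delta = 0.65) {
  from <- match.arg(from)
  if (from == "counts") x <- clr_transform(replace_zeros(x, delta))
  dist(x)
}

#' Hierarchical clustering of samples with SIMPROF-gated groups
#'
#' Agglomerative clustering on the Aitchison distance matrix (Ward linkage by
#' default; Aitchison distances are Euclidean, so Ward is valid). Flat groups
#' are obtained top-down: the similarity-profile permutation test
#' ([simprof_test()]) is run on the full sample set, and each split is
#' followed only while the test keeps rejecting homogeneity; a subtree where
#' SIMPROF stops rejecting (p >= `alpha`) becomes one group.
#'
#' @param x samples x OTUs count matrix.
#' @param linkage linkage method for [stats::hclust()].
#' @param simprof gate the flat groups with SIMPROF?
#' @param n_perm permutations per SIMPROF test.
#' @param alpha SIMPROF significance level.
#' @param seed integer seed for the permutations.
#' @param delta zero-replacement multiplier.
#' @return object of class `sample_clustering`: `hclust` tree, `groups`
#'   tibble, and the SIMPROF `tests` run along the way.
#' @export
cluster_samples <- function(x, linkage = "ward.D2", simprof = TRUE,
                            n_perm = 999, alpha = 0.05, seed = NULL,
                            delta = 0.65) {
  validate_otu_table(x)
  if (nrow(x) < 2)
    abort("need at least 2 samples", class = "pelagos_grouping_error")
  d <- aitchison_dist(x, from = "counts", delta = delta)
  hc <- hclust(d, method = linkage)

  groups <- rep(1L, nrow(x))
  names(groups) <- rownames(x)
  tests <- list()

  if (simprof && nrow(x) >= 3) {
    members <- leaf_sets(hc)          # leaves under each merge row
    next_id <- 0L
    assign_group <- function(samples) {
      next_id <<- next_id + 1L
      groups[samples] <<- next_id
    }
    recurse <- function(node_samples, node_row) {
      if (length(node_samples) < 3) {
        assign_group(node_samples)
        return(invisible())
      }
      res <- simprof_test(x[node_samples, , drop = FALSE], n_perm = n_perm,
                          alpha = alpha, seed = seed, delta = delta)
      tests[[length(tests) + 1L]] <<-
        tibble(n_samples = length(node_samples), pi = res$pi,
               p.value = res$p.value, significant = res$significant)
      if (!res$significant) {
        assign_group(node_samples)
        return(invisible())
      }
      for (child in hc$merge[node_row, ]) {
        child_samples <- if (child < 0) hc$labels[-child] else
          hc$labels[members[[child]]]
        child_row <- if (child < 0) NA_integer_ else child
        if (length(child_samples) <= 2 || is.na(child_row)) {
          assign_group(child_samples)
        } else {
          recurse(child_samples, child_row)
        }
      }
      invisible()
    }
    recurse(rownames(x), nrow(hc$merge))
    # renumber groups in dendrogram leaf order
    ord <- unique(groups[hc$labels[hc$order]])
    groups <- match(groups, ord)
    names(groups) <- rownames(x)
  }

  structure(list(
    hclust = hc, distance = d, linkage = linkage,
    groups = tibble(sample_id = names(groups), group = as.integer(groups)),
    tests = if (length(tests)) dplyr::bind_rows(tests) else NULL,
    alpha = alpha, n_perm = n_perm, seed = seed
  ), class = "sample_clustering")
}

# leaf index sets under each row of an hclust merge matrix
leaf_sets <- function(hc) {
  n <- nrow(hc$merge)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    kids <- hc$merge[i, ]
    out[[i]] <- unlist(lapply(kids, function(k)
      if (k < 0) -k else out[[k]]))
  }
  out
}

#' Similarity-profile (SIMPROF) permutation test
#'
#' Tests whether a group of samples has internal multivariate structure. The
#' observed profile is the sorted vector of pairwise distances; null profiles
#' are obtained by permuting each OTU column independently across samples and
#' recomputing the distances; the statistic is
#' \eqn{\pi = \sum |observed - mean\ null|} and the p-value is the fraction
#' of permuted \eqn{\pi} at least as large as the observed one.
#'
#' @param x count matrix of the samples in the group (rows).
#' @param n_perm number of permutations (values below 100 draw a warning).
#' @param alpha significance level.
#' @param seed integer seed.
#' @param distance `"aitchison"` (zero-replace + CLR + Euclidean) or plain
#'   `"euclidean"` on `x` as given.
#' @param delta zero-replacement multiplier for the Aitchison route.
#' @return list with `pi`, `p.value`, `significant`, `n_perm`.
#' @export
simprof_test <- function(x, n_perm = 999, alpha = 0.05, seed = NULL,
                         distance = c("aitchison", "euclidean"),
                         delta = 0.65) {
  distance <- match.arg(distance)
  x <- as.matrix(x)
  if (nrow(x) < 3) {
    if (nrow(x) < 2)
      abort("need at least 2 samples", class = "pelagos_grouping_error")
    return(list(pi = NA_real_, p.value = NA_real_, significant = FALSE,
                n_perm = 0L))
  }
  if (n_perm < 100)
    warn("fewer than 100 permutations; SIMPROF p-values will be coarse")

  profile_of <- function(m) {
    d <- if (distance == "aitchison")
      aitchison_dist(m, from = "counts", delta = delta)
    else dist(m)
    sort(as.vector(d))
  }
  guard <- function(m) {
    # column permutation can zero out a whole sample row; re-draw those rows
    if (distance == "aitchison") {
      bad <- rowSums(m) == 0
      if (any(bad)) m[bad, 1] <- 1
    }
    m
  }

  obs <- profile_of(x)
  nulls <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(b) {
      xp <- apply(x, 2, sample)
      rownames(xp) <- rownames(x)
      profile_of(guard(xp))
    }, numeric(length(obs)))
  })
  mean_null <- rowMeans(nulls)
  pi_obs <- sum(abs(obs - mean_null))
  pi_null <- colSums(abs(nulls - mean_null))
  p <- mean(pi_null >= pi_obs)
  list(pi = pi_obs, p.value = p, significant = is.finite(p) && p < alpha,
       n_perm = as.integer(n_perm))
}

#' @describeIn cluster_samples group membership per sample.
#' @param x a `sample_clustering` object.
#' @param ... unused.
#' @export
tidy.sample_clustering <- function(x, ...) x$groups

#' @describeIn cluster_samples one-row clustering summary.
#' @export
glance.sample_clustering <- function(x, ...) {
  tibble(n_samples = nrow(x$groups),
         n_groups = length(unique(x$groups$group)),
         linkage = x$linkage, n_perm = x$n_perm, alpha = x$alpha)
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("Sample clustering (", x$linkage, " on Aitchison distances): ",
      length(unique(x$groups$group)), " SIMPROF-supported groups over ",
      nrow(x$groups), " samples\n", sep = "")
  invisible(x)
}
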