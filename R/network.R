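#' Proportionality (phi) statistic between samples
#'
#' Symmetric proportionality of CLR rows:
#' \eqn{\phi_s(x, y) = var(x - y) / var(x + y)}, variances taken across OTUs.
#' Zero means perfectly proportional log-ratio profiles. Pairs with a
#' degenerate denominator (\eqn{x + y} constant) are returned as `NA` and
#' never become edges. The asymmetric Lovell variant
#' \eqn{\phi(x, y) = var(x - y) / var(x)} is available for inspection but an
#' undirected network needs the symmetric form.
#'
#' @param clr CLR matrix, samples x OTUs (>= 3 OTUs).
#' @param variant `"symmetric"` (default) or `"lovell"`.
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
phi_matrix <- function(clr, variant = c("symmetric", "lovell")) {
  variant <- match.arg(variant)
  clr <- as.matrix(clr)
  if (nrow(clr) < 2 || ncol(clr) < 3)
    abort("need >= 2 samples and >= 3 OTUs", class = "pelagos_validation_error")
  C <- stats::cov(t(clr))            # covariance of sample rows across OTUs
  v <- diag(C)
  va <- outer(v, v, "+")
  num <- va - 2 * C                  # var(x - y)
  den <- va + 2 * C                  # var(x + y)
  if (variant == "lovell") {
    phi <- num / matrix(v, nrow(clr), nrow(clr))
  } else {
    phi <- num / den
    phi[abs(den) < 1e-12] <- NA_real_
  }
  diag(phi) <- 0
  dimnames(phi) <- list(rownames(clr), rownames(clr))
  phi
}

#' Build the sample proportionality network
#'
#' Edges connect sample pairs with \eqn{\phi} strictly below the threshold
#' (0.15 by default), weighted by \eqn{1 - \phi} so stronger proportionality
#' means heavier edges. Isolated samples are retained as nodes.
#'
#' @param phi symmetric phi matrix from [phi_matrix()].
#' @param threshold edge rule: keep pairs with `phi < threshold`.
#' @param metadata optional tibble with `sample_id` and node attributes
#'   (site, layer, depth) to attach.
#' @return an `igraph` graph with `phi` and `weight` edge attributes.
#' @export
build_network <- function(phi, threshold = 0.15, metadata = NULL) {
  if (!is.numeric(threshold) || threshold <= 0)
    abort("threshold must be positive", class = "pelagos_domain_error")
  adj <- ifelse(!is.na(phi) & phi < threshold, 1 - phi, 0)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  ij <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(ij) > 0)
    igraph::E(g)$phi <- phi[cbind(ij[, 1], ij[, 2])]
  if (!is.null(metadata)) {
    idx <- match(igraph::V(g)$name, metadata$sample_id)
    for (col in setdiff(names(metadata), "sample_id"))
      g <- igraph::set_vertex_attr(g, col, value = metadata[[col]][idx])
  }
  g
}

#' Edge list of a sample network
#' @param g igraph network from [build_network()].
#' @return tibble with `from`, `to`, `phi`, `weight`.
#' @export
network_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  tibble(from = el[, 1], to = el[, 2],
         phi = if (igraph::ecount(g)) igraph::E(g)$phi else numeric(0),
         weight = if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0))
}

#' Weighted modularity of the best Louvain partition
#'
#' Louvain community detection (resolution 1) on the 1-phi edge weights,
#' seeded for reproducibility, and the Newman modularity Q of the partition
#' found. An edgeless network has no defined modularity.
#'
#' @param g igraph network.
#' @param seed integer seed.
#' @return list with `modularity`, `membership` (named), `n_communities`.
#' @export
network_modularity <- function(g, seed = NULL) {
  if (igraph::ecount(g) == 0)
    return(list(modularity = NA_real_, membership = NULL,
                n_communities = NA_integer_))
  cl <- with_seed_(seed %||% 1L,
                   igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  memb <- igraph::membership(cl)
  q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  list(modularity = q, membership = setNames(as.integer(memb), names(memb)),
       n_communities = length(unique(memb)))
}

#' Mean clustering coefficient
#'
#' Unweighted local clustering coefficient (triangles over possible triangles
#' among neighbours) averaged over all nodes, with nodes of degree < 2
#' contributing zero. The convention is recorded as an attribute.
#'
#' @param g igraph network.
#' @return mean clustering coefficient in [0, 1].
#' @export
mean_clustering_coefficient <- function(g) {
  if (igraph::vcount(g) == 0) return(NA_real_)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  out <- mean(cc)
  attr(out, "convention") <- "unweighted; degree<2 counted as 0; averaged over all nodes"
  out
}

#' One-row connectivity summary of a sample network
#'
#' @param g igraph network.
#' @param seed seed for the Louvain partition.
#' @return tibble with node/edge counts, modularity, and mean clustering
#'   coefficient.
#' @export
connectivity_report <- function(g, seed = NULL) {
  mod <- network_modularity(g, seed = seed)
  tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    modularity = mod$modularity,
    n_communities = mod$n_communities,
    mean_clustering_coefficient = as.numeric(mean_clustering_coefficient(g))
  )
}

# shared percentage of one presence submatrix under one mode
shared_pct <- function(P, mode) {
  occ <- colSums(P)
  n_any <- sum(occ >= 1)
  if (n_any == 0) return(NA_real_)
  switch(mode,
    at_least_2 = 100 * sum(occ >= 2) / n_any,
    all = 100 * sum(occ == nrow(P)) / n_any,
    mean_pairwise_jaccard = {
      pairs <- combn(nrow(P), 2)
      jac <- apply(pairs, 2, function(ij) {
        a <- P[ij[1], ]; b <- P[ij[2], ]
        u <- sum(a | b)
        if (u == 0) NA_real_ else sum(a & b) / u
      })
      100 * mean(jac, na.rm = TRUE)
    },
    abort(paste0("unknown mode ", mode), class = "pelagos_domain_error"))
}

#' Proportion of OTUs shared among samples within each water layer
#'
#' For each layer, the percentage of the layer's OTU pool (OTUs present in at
#' least one sample) that is shared. Because "shared among samples" admits
#' several readings, all three are reported side by side: `at_least_2`
#' (present in two or more of the layer's samples; default reading), `all`
#' (strict intersection over union), and `mean_pairwise_jaccard`.
#'
#' @param x samples x OTUs count matrix.
#' @param groups layer per sample: named vector or tibble with `sample_id`
#'   and `layer`.
#' @param modes sharing modes to report.
#' @return tibble with `group`, `n_samples`, `mode`, `shared_pct`.
#' @export
shared_otu_horizontal <- function(x, groups,
                                  modes = c("at_least_2", "all",
                                            "mean_pairwise_jaccard")) {
  validate_otu_table(x)
  if (is.data.frame(groups))
    groups <- setNames(as.character(groups$layer), groups$sample_id)
  g <- groups[rownames(x)]
  P <- x > 0
  purrr::map_dfr(unique(g[!is.na(g)]), function(layer) {
    rows <- which(!is.na(g) & g == layer)
    if (length(rows) < 2) {
      warn(paste0("layer ", layer, " has fewer than 2 samples; skipped"))
      return(NULL)
    }
    tibble(group = layer, n_samples = length(rows), mode = modes,
           shared_pct = vapply(modes, function(m)
             shared_pct(P[rows, , drop = FALSE], m), numeric(1)))
  })
}

#' Proportion of OTUs shared along the vertical profile of each site
#'
#' Same sharing modes as [shared_otu_horizontal()], applied to the samples of
#' one site inside a depth window (bounds inclusive), e.g. `c(0, 1000)` for
#' "at and above 1,000 m" or `c(2000, Inf)` for "at and below 2,000 m".
#'
#' @param x samples x OTUs count matrix.
#' @param samples tibble with `sample_id`, `site`, `depth`.
#' @param depth_window numeric length-2 inclusive depth bounds, or NULL for
#'   the whole column.
#' @inheritParams shared_otu_horizontal
#' @return tibble with `group` (site), `n_samples`, `mode`, `shared_pct`.
#' @export
shared_otu_vertical <- function(x, samples, depth_window = NULL,
                                modes = c("at_least_2", "all",
                                          "mean_pairwise_jaccard")) {
  validate_otu_table(x)
  keep <- samples
  if (!is.null(depth_window))
    keep <- dplyr::filter(keep, .data$depth >= depth_window[1],
                          .data$depth <= depth_window[2])
  keep <- dplyr::filter(keep, .data$sample_id %in% rownames(x))
  P <- x > 0
  purrr::map_dfr(unique(keep$site), function(st) {
    ids <- keep$sample_id[keep$site == st]
    if (length(ids) < 2) {
      warn(paste0("site ", st, " has fewer than 2 samples in the window; skipped"))
      return(NULL)
    }
    tibble(group = st, n_samples = length(ids), mode = modes,
           shared_pct = vapply(modes, function(m)
             shared_pct(P[ids, , drop = FALSE], m), numeric(1)))
  })
}
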