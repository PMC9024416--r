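test_that("phi matches a naive per-pair variance computation", {
  clr <- clr_transform(replace_zeros(random_counts(4, 12, lambda = 6, seed = 3)))
  phi <- phi_matrix(clr)
  for (a in 1:4) for (b in 1:4) {
    if (a == b) { expect_equal(phi[a, b], 0); next }
    expect_equal(phi[a, b],
                 var(clr[a, ] - clr[b, ]) / var(clr[a, ] + clr[b, ]),
                 tolerance = 1e-12)
  }
  expect_equal(phi, t(phi), tolerance = 1e-12)

  # identical rows: phi = 0; anti-proportional rows: undefined
  clr2 <- rbind(a = clr[1, ], b = clr[1, ], c = -clr[1, ])
  phi2 <- phi_matrix(clr2)
  expect_equal(phi2["a", "b"], 0, tolerance = 1e-12)
  expect_true(is.na(phi2["a", "c"]))
})

test_that("edge rule is a strict threshold and is monotone", {
  ids <- paste0("s", 1:3)
  phi <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(phi) <- 0
  phi["s1", "s2"] <- phi["s2", "s1"] <- 0.10
  phi["s1", "s3"] <- phi["s3", "s1"] <- 0.14
  phi["s2", "s3"] <- phi["s3", "s2"] <- 0.16
  g <- build_network(phi, threshold = 0.15)
  expect_equal(igraph::ecount(g), 2)           # 0.16 excluded, strict <
  expect_equal(igraph::vcount(g), 3)
  expect_equal(sort(igraph::E(g)$weight), sort(1 - c(0.10, 0.14)))

  # lowering the threshold never adds edges
  for (thr in c(0.15, 0.12, 0.05)) {
    gs <- build_network(phi, threshold = thr)
    expect_lte(igraph::ecount(gs), igraph::ecount(g))
    g <- gs
  }
  expect_error(build_network(phi, threshold = 0), class = "pelagos_domain_error")

  # all phi = 0.5: edgeless; all phi = 0: complete with unit weights
  none <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(none) <- 0
  expect_equal(igraph::ecount(build_network(none)), 0)
  all0 <- matrix(0, 3, 3, dimnames = list(ids, ids))
  gc <- build_network(all0)
  expect_equal(igraph::ecount(gc), 3)
  expect_equal(igraph::E(gc)$weight, rep(1, 3))
})

test_that("Louvain modularity agrees with exhaustive search on two triangles", {
  ids <- paste0("v", 1:6)
  adj <- matrix(0, 6, 6, dimnames = list(ids, ids))
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    adj[e[1], e[2]] <- 1; adj[e[2], e[1]] <- 1
  }
  # exhaustive maximum over all 203 partitions of 6 nodes
  best <- max(vapply(all_partitions(6), function(p) modularity_of(adj, p),
                     numeric(1)), na.rm = TRUE)
  expect_equal(best, 0.5, tolerance = 1e-12)

  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  mod <- network_modularity(g, seed = 1)
  expect_equal(mod$modularity, 0.5, tolerance = 1e-12)
  expect_equal(mod$n_communities, 2)
  expect_identical(mod$membership[1:3], setNames(rep(mod$membership[[1]], 3),
                                                 ids[1:3]))

  # single edge: both partitions enumerate to Q = 0
  adj1 <- matrix(0, 2, 2, dimnames = list(ids[1:2], ids[1:2]))
  adj1[1, 2] <- adj1[2, 1] <- 1
  expect_equal(max(vapply(all_partitions(2), function(p)
    modularity_of(adj1, p), numeric(1))), 0)
  g1 <- igraph::graph_from_adjacency_matrix(adj1, mode = "undirected",
                                            weighted = TRUE)
  expect_equal(network_modularity(g1, seed = 1)$modularity, 0)

  # complete uniform graph: no structure, best found stays near 0
  gk <- igraph::make_full_graph(6)
  igraph::V(gk)$name <- ids
  igraph::E(gk)$weight <- 1
  expect_lte(network_modularity(gk, seed = 1)$modularity, 0.05)

  # edgeless: undefined
  ge <- igraph::make_empty_graph(3, directed = FALSE)
  expect_true(is.na(network_modularity(ge)$modularity))
})

test_that("clustering coefficient anchors: triangle, path, K5", {
  tri <- igraph::make_full_graph(3)
  expect_equal(as.numeric(mean_clustering_coefficient(tri)), 1)
  path <- igraph::make_graph(~ a - b, b - c)
  expect_equal(as.numeric(mean_clustering_coefficient(path)), 0)
  k5 <- igraph::make_full_graph(5)
  expect_equal(as.numeric(mean_clustering_coefficient(k5)), 1)
})

test_that("shared-OTU percentages match hand enumeration in all modes", {
  # sets {A,B}, {B,C}, {C,D}
  x <- matrix(0L, 3, 4, dimnames = list(paste0("s", 1:3), LETTERS[1:4]))
  x["s1", c("A", "B")] <- 1L
  x["s2", c("B", "C")] <- 1L
  x["s3", c("C", "D")] <- 1L
  g <- setNames(rep("L1", 3), rownames(x))
  out <- shared_otu_horizontal(x, g)
  pct <- setNames(out$shared_pct, out$mode)
  expect_equal(pct[["at_least_2"]], 50)
  expect_equal(pct[["all"]], 0)
  expect_equal(pct[["mean_pairwise_jaccard"]], 100 * (1 / 3 + 1 / 3 + 0) / 3,
               tolerance = 1e-9)

  # identical presence sets: 100% everywhere; disjoint sets: 0%
  xi <- rbind(s1 = c(1L, 1L, 0L), s2 = c(2L, 3L, 0L))
  colnames(xi) <- paste0("o", 1:3)
  oi <- shared_otu_horizontal(xi, setNames(rep("L", 2), rownames(xi)))
  expect_true(all(oi$shared_pct == 100))
  xd <- rbind(s1 = c(1L, 0L), s2 = c(0L, 1L))
  colnames(xd) <- paste0("o", 1:2)
  od <- shared_otu_horizontal(xd, setNames(rep("L", 2), rownames(xd)))
  expect_true(all(od$shared_pct == 0))

  # "all" is never above "at_least_2"
  xr <- random_counts(6, 25, lambda = 1, seed = 9)
  gr <- setNames(rep(c("a", "b"), each = 3), rownames(xr))
  or <- shared_otu_horizontal(xr, gr) |>
    tidyr::pivot_wider(names_from = "mode", values_from = "shared_pct")
  expect_true(all(or$all <= or$at_least_2 + 1e-9))
})

test_that("vertical sharing applies the inclusive depth window", {
  x <- random_counts(3, 10, lambda = 5, seed = 4)
  meta <- tibble::tibble(sample_id = rownames(x), site = "A",
                         depth = c(5, 500, 2000))
  out <- shared_otu_vertical(x, meta, depth_window = c(0, 1000))
  expect_equal(unique(out$n_samples), 2)      # 2000 m excluded, bound inclusive
  out2 <- shared_otu_vertical(x, meta, depth_window = c(0, 2000))
  expect_equal(unique(out2$n_samples), 3)

  # identical samples at one site: 100%
  xi <- rbind(a = c(3L, 1L, 0L), b = c(1L, 2L, 0L))
  colnames(xi) <- paste0("o", 1:3)
  mi <- tibble::tibble(sample_id = c("a", "b"), site = "S", depth = c(10, 100))
  oi <- shared_otu_vertical(xi, mi)
  expect_true(all(oi$shared_pct == 100))
})

test_that("matched-arrangement subsetting commutes with the analysis", {
  x <- random_counts(8, 30, lambda = 3, seed = 12)
  keep <- rownames(x)[c(1, 3, 5, 7)]
  g <- setNames(rep(c("a", "b"), 4), rownames(x))
  direct <- shared_otu_horizontal(subset_samples(x, keep), g[keep])
  pre <- shared_otu_horizontal(x[keep, ], g[keep])
  expect_equal(direct, pre)

  clr <- clr_transform(replace_zeros(x))
  phi_sub <- phi_matrix(clr[keep, ])
  phi_full_cut <- subset_samples(phi_matrix(clr), keep)
  # phi is computed per pair, so subsetting commutes exactly
  expect_equal(phi_sub, phi_full_cut, tolerance = 1e-12)
})
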