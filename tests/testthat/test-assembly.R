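# brute-force beta MNTD oracle: nested loops over present taxa
bmntd_oracle <- function(fa, fb, d) {
  fa <- fa / sum(fa); fb <- fb / sum(fb)
  ia <- which(fa > 0); ib <- which(fb > 0)
  acc_a <- sum(vapply(ia, function(i) fa[i] * min(d[i, ib]), numeric(1)))
  acc_b <- sum(vapply(ib, function(j) fb[j] * min(d[j, ia]), numeric(1)))
  0.5 * (acc_a + acc_b)
}

test_that("beta MNTD matches hand computation and the brute-force oracle", {
  tree <- toy_tree()
  d <- patristic_matrix(tree)
  x <- matrix(0, 2, 4, dimnames = list(c("p", "q"), c("A", "B", "C", "D")))
  x["p", "A"] <- 1; x["q", "C"] <- 1
  expect_equal(beta_mntd(x, tree)["p", "q"], 4)   # 0.5 * (4 + 4)

  # identical communities: zero
  xi <- rbind(p = c(2, 1, 0, 3), q = c(2, 1, 0, 3))
  colnames(xi) <- c("A", "B", "C", "D")
  expect_equal(beta_mntd(xi, tree)["p", "q"], 0)

  # 20 random 6-taxon fixtures against the nested-loop oracle
  withr::with_seed(31, {
    for (rep in 1:20) {
      tr <- ape::rtree(6)
      tr$tip.label <- paste0("t", 1:6)
      dd <- patristic_matrix(tr)
      xx <- matrix(rpois(12, 2), 2, 6,
                   dimnames = list(c("a", "b"), paste0("t", 1:6)))
      xx[1, ][xx[1, ] == 0][1] <- 1  # guarantee occupancy
      if (sum(xx[1, ]) == 0) xx[1, 1] <- 1
      if (sum(xx[2, ]) == 0) xx[2, 1] <- 1
      got <- beta_mntd(xx, dd[paste0("t", 1:6), paste0("t", 1:6)])["a", "b"]
      want <- bmntd_oracle(xx[1, ], xx[2, ], dd[colnames(xx), colnames(xx)])
      expect_equal(got, want, tolerance = 1e-12)
    }
  })

  expect_error(beta_mntd(xi[, 1:3] + 1,
                         patristic_matrix(ape::read.tree(text = "(A:1,B:1);"))),
               class = "pelagos_coverage_error")
})

test_that("beta NTI is flagged undefined on a star tree and is relabelling-invariant", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  x <- matrix(c(3, 1, 0, 0,
                0, 0, 2, 2), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), c("A", "B", "C", "D")))
  res <- bnti(x, star, n_null = 99, seed = 1)
  expect_true(is.na(res$bnti["a", "b"]))      # every shuffle leaves d unchanged

  # joint relabelling of table and tree leaves beta NTI unchanged
  tree <- toy_tree()
  res1 <- bnti(x, tree, n_null = 199, seed = 9)
  perm <- c(A = "C", B = "D", C = "A", D = "B")
  tree2 <- tree; tree2$tip.label <- unname(perm[tree$tip.label])
  x2 <- x; colnames(x2) <- unname(perm[colnames(x)])
  x2 <- x2[, colnames(x)]
  res2 <- bnti(x2, tree2, n_null = 199, seed = 9)
  expect_equal(res1$bmntd_obs, res2$bmntd_obs, tolerance = 1e-12)
})

test_that("Raup-Crick honours ties, symmetry, and bounds", {
  # both samples contain the whole pool: every null replicate ties
  x <- matrix(1L, 2, 5, dimnames = list(c("a", "b"), paste0("o", 1:5)))
  rc <- raup_crick(x, n_null = 199, seed = 1)
  expect_equal(rc["a", "b"], 0)

  x2 <- random_counts(5, 12, lambda = 1, seed = 14)
  rc2 <- raup_crick(x2, n_null = 499, seed = 3)
  expect_equal(rc2, t(rc2))
  expect_true(all(abs(rc2[upper.tri(rc2)]) <= 1))
})

test_that("null-true communities stay inside the null bands", {
  # communities drawn by the Raup-Crick null itself: ~95% inside +/-0.95
  withr::with_seed(17, {
    pool <- 40; occ <- rep(1, pool)
    x <- t(sapply(1:12, function(i) {
      p <- integer(pool); p[sample.int(pool, 15)] <- 1L; p
    }))
    dimnames(x) <- list(paste0("s", 1:12), paste0("o", 1:pool))
    rc <- raup_crick(x, n_null = 999, seed = 5, weighting = "equal")
    inside <- mean(abs(rc[upper.tri(rc)]) < 0.95)
    expect_gte(inside, 0.85)
  })

  # communities assembled at random wrt the phylogeny: |betaNTI| <= 2 for
  # about 95% of pairs
  withr::with_seed(19, {
    tree <- simulate_tree(60, seed = 2)
    x <- t(sapply(1:10, function(i) rmultinom(1, 80, rep(1 / 60, 60))[, 1]))
    dimnames(x) <- list(paste0("s", 1:10), tree$tip.label)
    storage.mode(x) <- "integer"
    res <- bnti(x, tree, n_null = 299, seed = 4)
    z <- res$bnti[upper.tri(res$bnti)]
    expect_gte(mean(abs(z) <= 2, na.rm = TRUE), 0.85)
  })
})

test_that("the five threshold cases map to the five processes", {
  ids <- paste0("s", 1:5)
  bnti_m <- matrix(0, 5, 5, dimnames = list(ids, ids))
  brc_m <- matrix(0, 5, 5, dimnames = list(ids, ids))
  set_pair <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  bnti_m <- set_pair(bnti_m, 1, 2, 3)     # variable selection
  bnti_m <- set_pair(bnti_m, 1, 3, -3)    # homogeneous selection
  brc_m <- set_pair(brc_m, 1, 4, 0.99)    # dispersal limitation
  brc_m <- set_pair(brc_m, 1, 5, -0.99)   # homogeneous dispersal
  brc_m <- set_pair(brc_m, 2, 3, 0.2)     # drift
  part <- partition_processes(bnti_m, brc_m)
  look <- function(a, b)
    part$pairs$process[part$pairs$sample_a == a & part$pairs$sample_b == b]
  expect_identical(look("s1", "s2"), "variable_selection")
  expect_identical(look("s1", "s3"), "homogeneous_selection")
  expect_identical(look("s1", "s4"), "dispersal_limitation")
  expect_identical(look("s1", "s5"), "homogeneous_dispersal")
  expect_identical(look("s2", "s3"), "drift")
  expect_equal(sum(part$summary$fraction), 1, tolerance = 1e-9)
})

test_that("undefined beta NTI pairs are excluded and counted", {
  ids <- paste0("s", 1:3)
  b <- matrix(0, 3, 3, dimnames = list(ids, ids))
  b[1, 2] <- b[2, 1] <- NA
  r <- matrix(0, 3, 3, dimnames = list(ids, ids))
  part <- partition_processes(b, r)
  expect_equal(part$n_excluded, 1)
  expect_equal(sum(part$summary$n_pairs), 2)
  expect_equal(sum(part$summary$fraction), 1, tolerance = 1e-9)
})

test_that("beta MNTD is non-negative and zero only with zero nearest distances", {
  withr::with_seed(53, {
    tr <- ape::rtree(8)
    x <- matrix(rpois(3 * 8, 3), 3, 8,
                dimnames = list(paste0("s", 1:3), tr$tip.label))
    for (i in 1:3) if (sum(x[i, ]) == 0) x[i, 1] <- 1
    bm <- beta_mntd(x, tr)
    expect_true(all(bm >= 0))
  })
})
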