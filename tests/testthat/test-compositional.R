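test_that("zero replacement matches the count-zero-multiplicative formula", {
  x <- random_counts(5, 12, lambda = 2, seed = 7)
  x[1, 1:4] <- 0L
  x[2, ] <- x[2, ] + 1L                    # a row with no zeros at all
  out <- replace_zeros(x, delta = 0.65)
  expect_true(all(out > 0))
  expect_equal(unname(rowSums(out)), rep(1, 5), tolerance = 1e-12)

  # independent re-implementation of the formula for one row
  row <- x[1, ]; total <- sum(row)
  z <- row == 0
  repl <- 0.65 / total
  oracle <- ifelse(z, repl, (row / total) * (1 - sum(z) * repl))
  expect_equal(unname(out[1, ]), unname(oracle), tolerance = 1e-12)

  # a row with no zeros comes back proportional to the input
  expect_equal(unname(out[2, ]), unname(x[2, ] / sum(x[2, ])),
               tolerance = 1e-12)

  # ordering of entries preserved
  expect_identical(order(out[1, !z]), order(row[!z]))
})

test_that("CLR transform matches its closed forms and invariances", {
  expect_equal(unname(clr_transform(matrix(c(1, 1, 1, 1), 1))[1, ]),
               rep(0, 4))
  v <- clr_transform(matrix(c(1, 3, 9, 27), 1))[1, ]
  expect_equal(unname(v), log(3) * c(-1.5, -0.5, 0.5, 1.5), tolerance = 1e-12)
  # scale invariance
  m <- matrix(runif(12) + 0.1, 3, 4)
  expect_equal(clr_transform(7 * m), clr_transform(m), tolerance = 1e-12)
  # rows sum to zero
  expect_equal(rowSums(clr_transform(m)), rep(0, 3), tolerance = 1e-9)
  expect_error(clr_transform(matrix(c(0, 1), 1)), class = "pelagos_domain_error")
})

test_that("Aitchison distance is Euclidean on CLR rows and scale-free", {
  m <- rbind(u = c(1, 1, 1, 1), g = c(1, 3, 9, 27))
  d <- aitchison_dist(clr_transform(m))
  expect_equal(as.numeric(d), log(3) * sqrt(5), tolerance = 1e-12)

  # brute-force double loop oracle on a 5 x 8 fixture
  clr <- clr_transform(matrix(runif(40) + 0.05, 5, 8,
                              dimnames = list(paste0("s", 1:5), NULL)))
  d2 <- as.matrix(aitchison_dist(clr))
  for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (k in 1:8) acc <- acc + (clr[i, k] - clr[j, k])^2
    expect_equal(unname(d2[i, j]), unname(sqrt(acc)), tolerance = 1e-12)
  }

  # invariance to per-sample rescaling of the raw positive data
  x <- random_counts(4, 10, lambda = 8, seed = 2)
  pos <- replace_zeros(x)
  scaled <- pos * c(1, 10, 100, 7)
  expect_equal(as.numeric(aitchison_dist(clr_transform(scaled))),
               as.numeric(aitchison_dist(clr_transform(pos))),
               tolerance = 1e-9)
})

test_that("Aitchison distances behave like a metric on random fixtures", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      x <- matrix(rpois(6 * 15, 8) + 0L, 6, 15,
                  dimnames = list(paste0("s", 1:6), paste0("o", 1:15)))
      x[rowSums(x) == 0, 1] <- 1L
      D <- as.matrix(aitchison_dist(x, from = "counts"))
      expect_equal(D, t(D), tolerance = 1e-9)
      expect_equal(unname(diag(D)), rep(0, 6))
      for (i in 1:6) for (j in 1:6) for (k in 1:6)
        expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
    }
  })
})

test_that("clustering recovers well-separated clusters and SIMPROF gates them", {
  x <- two_cluster_counts(n_per = 4, shift = 6)
  cl <- cluster_samples(x, n_perm = 199, seed = 42)
  g <- cl$groups$group
  # the first split separates the two known clouds
  expect_equal(length(unique(g[1:4])), 1)
  expect_equal(length(unique(g[5:8])), 1)
  expect_false(g[1] == g[5])

  # 2 samples: a single merge at their Aitchison distance
  x2 <- x[1:2, ]
  cl2 <- cluster_samples(x2, simprof = FALSE)
  expect_equal(cl2$hclust$height,
               as.numeric(aitchison_dist(x2, from = "counts")))
  expect_error(cluster_samples(x[1, , drop = FALSE]),
               class = "pelagos_grouping_error")
})

test_that("SIMPROF: no structure on identical samples, power on separated ones", {
  x <- matrix(rep(c(5L, 3L, 2L, 8L), each = 4), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("o", 1:4)))
  res <- simprof_test(x, n_perm = 199, seed = 1)
  expect_equal(res$pi, 0, tolerance = 1e-9)
  expect_equal(res$p.value, 1)

  # two tight, distant clusters: rejected in nearly every seeded run
  hits <- sapply(1:20, function(s)
    simprof_test(two_cluster_counts(seed = s), n_perm = 199,
                 seed = s)$p.value < 0.05)
  expect_gte(mean(hits), 0.95)

  # group of two is non-significant by convention
  expect_false(simprof_test(x[1:2, ], n_perm = 199)$significant)
  expect_warning(simprof_test(x, n_perm = 50), "100 permutations")
})

test_that("cluster recovery on a 3-cluster fixture is nearly perfect", {
  withr::with_seed(8, {
    n_otus <- 30
    centers <- lapply(1:3, function(i) exp(rnorm(n_otus, 0, 2)))
    x <- do.call(rbind, lapply(1:3, function(cl)
      t(sapply(1:4, function(i)
        rmultinom(1, 3000, centers[[cl]] * exp(rnorm(n_otus, 0, 0.15)))[, 1]))))
    dimnames(x) <- list(paste0("s", 1:12), paste0("o", 1:n_otus))
    storage.mode(x) <- "integer"
    truth <- rep(1:3, each = 4)
    cl <- cluster_samples(x, simprof = FALSE)
    got <- cutree(cl$hclust, k = 3)
    # adjusted agreement via pair-counting (Rand-style, exact match expected)
    agree <- outer(got, got, "==") == outer(truth, truth, "==")
    expect_gte(mean(agree[upper.tri(agree)]), 0.9)
  })
})
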