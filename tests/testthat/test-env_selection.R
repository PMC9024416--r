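mk_env <- function(X) {
  tibble::tibble(sample_id = rownames(X), as.data.frame(X))
}

test_that("RDA closed forms: perfect fit, Ezekiel adjustment, vegan cross-check", {
  withr::with_seed(5, {
    n <- 12
    f1 <- rnorm(n)
    Y <- outer(f1, c(2, -1, 0.5, 3))          # exactly linear in one factor
    rownames(Y) <- paste0("s", 1:n)
    env <- tibble::tibble(sample_id = rownames(Y), f1 = exp(f1))
    fit <- rda_fit(Y, env, n_perm = 99, seed = 1)
    expect_equal(fit$r2, 1, tolerance = 1e-9)

    # Ezekiel formula anchor: R2 = 0.5, n = 11, p = 1
    expect_equal(pelagos:::ezekiel_adj(0.5, 11, 1), 1 - 0.5 * 10 / 9,
                 tolerance = 1e-12)

    # against vegan on a noisy fixture (independent implementation)
    Y2 <- Y + matrix(rnorm(n * 4), n)
    env2 <- tibble::tibble(sample_id = rownames(Y), a = exp(rnorm(n)),
                           b = exp(rnorm(n)))
    fit2 <- rda_fit(Y2, env2, n_perm = 99, seed = 2)
    X <- scale(log(cbind(env2$a, env2$b)))
    vfit <- vegan::rda(Y2 ~ X)
    expect_equal(fit2$r2, summary(vfit)$constr.chi / summary(vfit)$tot.chi,
                 tolerance = 1e-9)
    expect_equal(fit2$r2_adjusted, vegan::RsquareAdj(vfit)$adj.r.squared,
                 tolerance = 1e-9)
  })
})

test_that("dbRDA on Aitchison distances equals RDA on the CLR matrix", {
  x <- random_counts(10, 20, lambda = 5, seed = 6)
  clr <- clr_transform(replace_zeros(x))
  env <- withr::with_seed(7, tibble::tibble(
    sample_id = rownames(x), t1 = exp(rnorm(10)), t2 = exp(rnorm(10))))
  f1 <- rda_fit(clr, env, n_perm = 49, seed = 3)
  f2 <- dbrda_fit(aitchison_dist(clr), env, n_perm = 49, seed = 3)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-9)
  expect_equal(f1$r2_adjusted, f2$r2_adjusted, tolerance = 1e-9)
})

test_that("adding a factor never lowers raw R2", {
  withr::with_seed(11, {
    Y <- matrix(rnorm(15 * 6), 15)
    rownames(Y) <- paste0("s", 1:15)
    env <- tibble::tibble(sample_id = rownames(Y), a = runif(15) + 1,
                          b = runif(15) + 1, c = runif(15) + 1)
    r2s <- sapply(1:3, function(k)
      rda_fit(Y, env, factors = c("a", "b", "c")[1:k], n_perm = 9)$r2)
    expect_true(all(diff(r2s) >= -1e-12))
  })
})

test_that("permutation p is uniform and adjusted R2 centred under the null", {
  n_rep <- 500
  out <- withr::with_seed(23, {
    t(replicate(n_rep, {
      Y <- matrix(rnorm(14 * 6), 14)
      rownames(Y) <- paste0("s", 1:14)
      env <- tibble::tibble(sample_id = rownames(Y), f = exp(rnorm(14)))
      fit <- rda_fit(Y, env, n_perm = 99)
      c(p = fit$model_p, adj = fit$r2_adjusted)
    }))
  })
  rej <- mean(out[, "p"] <= 0.05)
  band <- qbinom(c(0.005, 0.995), n_rep, 0.05) / n_rep
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
  se <- sd(out[, "adj"]) / sqrt(n_rep)
  expect_lt(abs(mean(out[, "adj"])), 4 * se + 0.01)
})

test_that("forward selection finds the true factor and guards duplicates", {
  hits <- sapply(1:20, function(s) {
    withr::with_seed(s, {
      n <- 20
      driver <- rnorm(n)
      Y <- outer(driver, rnorm(8)) + matrix(rnorm(n * 8, 0, 0.5), n)
      rownames(Y) <- paste0("s", 1:n)
      env <- tibble::tibble(sample_id = rownames(Y),
                            true = exp(driver),
                            n1 = exp(rnorm(n)), n2 = exp(rnorm(n)),
                            n3 = exp(rnorm(n)), n4 = exp(rnorm(n)),
                            n5 = exp(rnorm(n)))
      fs <- forward_select(Y, env, alpha = 0.01, n_perm = 199, seed = s)
      length(fs$selected_factors) > 0 && fs$selected_factors[1] == "true"
    })
  })
  expect_gte(mean(hits), 0.95)

  # duplicated factor: only one admitted
  withr::with_seed(2, {
    n <- 20
    driver <- rnorm(n)
    Y <- outer(driver, rnorm(8)) + matrix(rnorm(n * 8, 0, 0.5), n)
    rownames(Y) <- paste0("s", 1:n)
    env <- tibble::tibble(sample_id = rownames(Y), f = exp(driver),
                          f_copy = exp(driver))
    fs <- forward_select(Y, env, alpha = 0.05, n_perm = 199, seed = 9)
    expect_equal(length(fs$selected_factors), 1)
  })

  # pure noise at alpha = 0.01: selections are rare
  sel <- sapply(1:50, function(s) {
    withr::with_seed(100 + s, {
      Y <- matrix(rnorm(15 * 5), 15)
      rownames(Y) <- paste0("s", 1:15)
      env <- tibble::tibble(sample_id = rownames(Y), a = exp(rnorm(15)),
                            b = exp(rnorm(15)), c = exp(rnorm(15)))
      length(forward_select(Y, env, alpha = 0.01, n_perm = 99,
                            seed = s)$selected_factors) > 0
    })
  })
  expect_lte(mean(sel), 0.15)
})

test_that("samples with missing environmental data are dropped only here", {
  x <- random_counts(8, 15, lambda = 4, seed = 31)
  clr <- clr_transform(replace_zeros(x))
  env <- withr::with_seed(33, tibble::tibble(
    sample_id = rownames(x), t1 = exp(rnorm(8)), t2 = exp(rnorm(8))))
  env$t1[3] <- NA
  fit <- rda_fit(clr, env, n_perm = 49, seed = 1)
  expect_equal(fit$n, 7)
  expect_equal(fit$n_dropped, 1)
  expect_identical(fit$dropped_samples, env$sample_id[3])
})
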