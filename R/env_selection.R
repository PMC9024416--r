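#' Prepare an environmental factor table
#'
#' Natural-log transform (with a per-factor offset of half the smallest
#' positive value when zeros occur) and standardization to zero mean / unit
#' variance. Samples with missing values are dropped here, and only here.
#'
#' @param env data frame or tibble: `sample_id` column plus numeric factors.
#' @param factors which factor columns to keep (default: all numeric).
#' @param log_transform apply the log transform?
#' @param standardize scale to zero mean / unit sd?
#' @return list with `X` (matrix, rows named by sample), `dropped` (sample
#'   ids with missing data), `offsets` (named per-factor log offsets).
#' @export
prepare_env <- function(env, factors = NULL, log_transform = TRUE,
                        standardize = TRUE) {
  stopifnot("sample_id" %in% names(env))
  num_cols <- names(env)[vapply(env, is.numeric, logical(1))]
  factors <- factors %||% num_cols
  bad <- setdiff(factors, num_cols)
  if (length(bad) > 0)
    abort(paste0("unknown or non-numeric factors: ", paste(bad, collapse = ", ")),
          class = "pelagos_validation_error")
  X <- as.matrix(env[factors])
  rownames(X) <- env$sample_id
  ok <- complete.cases(X)
  dropped <- env$sample_id[!ok]
  X <- X[ok, , drop = FALSE]
  offsets <- setNames(numeric(length(factors)), factors)
  if (log_transform) {
    for (j in factors) {
      v <- X[, j]
      if (any(v <= 0)) {
        # half the smallest positive value; shifted further if negatives occur
        pos <- v[v > 0]
        offsets[j] <- (if (length(pos)) min(pos) / 2 else 1) + max(0, -min(v))
      }
      X[, j] <- log(v + offsets[j])
    }
  }
  if (standardize) {
    keep <- apply(X, 2, sd) > 0
    if (!all(keep))
      warn(paste0("constant factors dropped: ",
                  paste(colnames(X)[!keep], collapse = ", ")))
    X <- scale(X[, keep, drop = FALSE])
  }
  list(X = X, dropped = dropped, offsets = offsets)
}

# R2 of the least-squares projection of Y (rows = samples) onto X
proj_r2 <- function(qrX, Y) {
  fitted <- qr.fitted(qrX, Y)
  sum(fitted^2) / sum(Y^2)
}

ezekiel_adj <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Redundancy analysis of CLR community data on environmental factors
#'
#' Constrained ordination as a least-squares projection of the (column- and
#' row-centred) CLR matrix onto the prepared environmental design.
#' \eqn{R^2} is the constrained share of total variance, adjusted by the
#' Ezekiel formula \eqn{1 - (1 - R^2)(n - 1)/(n - p - 1)}. Global
#' significance is a permutation test (residual rows of the null model, i.e.
#' sample labels, shuffled); per-axis p-values are marginal permutation tests
#' on the ordered constrained eigenvalues. Because Aitchison distances are
#' Euclidean on CLR rows, this equals dbRDA on the Aitchison distance matrix
#' (see [dbrda_fit()]).
#'
#' @param clr CLR matrix, samples x OTUs.
#' @param env environmental table with `sample_id` (see [prepare_env()]).
#' @param factors factor columns to use; default all numeric columns.
#' @param n_perm permutations for the significance tests.
#' @param seed integer seed.
#' @param log_transform,standardize passed to [prepare_env()].
#' @return object of class `rda_result`.
#' @export
rda_fit <- function(clr, env, factors = NULL, n_perm = 999, seed = NULL,
                    log_transform = TRUE, standardize = TRUE) {
  pe <- prepare_env(env, factors, log_transform, standardize)
  common <- intersect(rownames(clr), rownames(pe$X))
  if (length(common) <= ncol(pe$X) + 1)
    abort("need more samples than factors + 1",
          class = "pelagos_validation_error")
  Y <- scale(clr[common, , drop = FALSE], center = TRUE, scale = FALSE)
  X <- pe$X[common, , drop = FALSE]

  # collinearity guard: drop aliased columns
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    drop_idx <- qx$pivot[-seq_len(qx$rank)] - 1
    drop_idx <- drop_idx[drop_idx > 0]
    warn(paste0("collinear factors dropped: ",
                paste(colnames(X)[drop_idx], collapse = ", ")))
    X <- X[, -drop_idx, drop = FALSE]
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  n <- nrow(Y); p <- ncol(X)

  r2 <- proj_r2(qrX, Y)
  r2_adj <- ezekiel_adj(r2, n, p)
  fitted <- qr.fitted(qrX, Y)
  eig <- svd(fitted, nu = 0, nv = 0)$d^2 / (n - 1)
  eig <- eig[seq_len(min(p, length(eig)))]

  perm_stats <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(b) {
      Yp <- Y[sample.int(n), , drop = FALSE]
      fp <- qr.fitted(qrX, Yp)
      c(sum(fp^2) / sum(Yp^2),
        svd(fp, nu = 0, nv = 0)$d[seq_along(eig)]^2 / (n - 1))
    }, numeric(1 + length(eig)))
  })
  model_p <- (1 + sum(perm_stats[1, ] >= r2)) / (n_perm + 1)
  axis_p <- vapply(seq_along(eig), function(k)
    (1 + sum(perm_stats[1 + k, ] >= eig[k])) / (n_perm + 1), numeric(1))

  structure(list(
    factors = colnames(X), selected_factors = colnames(X),
    r2 = r2, r2_adjusted = r2_adj,
    model_p = model_p, axis_p = axis_p, eigenvalues = eig,
    n = n, n_factors = p, n_dropped = length(pe$dropped),
    dropped_samples = pe$dropped, offsets = pe$offsets,
    permutations = n_perm, seed = seed, path = NULL
  ), class = "rda_result")
}

#' Distance-based redundancy analysis on a distance matrix
#'
#' Gower double-centring of the squared distances followed by the same
#' projection as [rda_fit()]. On Aitchison distances this reproduces RDA on
#' the CLR matrix exactly.
#'
#' @param d `dist` object or distance matrix over samples.
#' @inheritParams rda_fit
#' @return object of class `rda_result`.
#' @export
dbrda_fit <- function(d, env, factors = NULL, n_perm = 999, seed = NULL,
                      log_transform = TRUE, standardize = TRUE) {
  D <- as.matrix(d)
  pe <- prepare_env(env, factors, log_transform, standardize)
  common <- intersect(rownames(D), rownames(pe$X))
  D <- D[common, common]
  n <- length(common)
  # Gower-centred cross-product matrix
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ev <- eigen(G, symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-10
  Y <- ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev$values[keep]),
                                                 sum(keep))
  rownames(Y) <- common
  env_common <- env[match(common, env$sample_id), , drop = FALSE]
  rda_fit(Y, env_common, factors = factors, n_perm = n_perm, seed = seed,
          log_transform = log_transform, standardize = standardize)
}

#' Forward selection of environmental factors for RDA
#'
#' Greedy addition of the factor that most increases the adjusted
#' \eqn{R^2}, admitted only if its conditional permutation p-value is below
#' `alpha` *and* the cumulative adjusted \eqn{R^2} stays at or below the
#' global (all-factor) adjusted \eqn{R^2} — the standard double stopping
#' rule. A candidate almost perfectly explained by the factors already
#' selected (squared multiple correlation above `collinearity_r2`) is
#' skipped.
#'
#' @inheritParams rda_fit
#' @param alpha admission level for the conditional permutation test.
#' @param collinearity_r2 guard threshold.
#' @return an `rda_result` for the selected factors, with a `path` tibble
#'   recording each admission step; an empty selection still reports the
#'   global statistics.
#' @export
forward_select <- function(clr, env, factors = NULL, alpha = 0.01,
                           n_perm = 999, seed = NULL, log_transform = TRUE,
                           standardize = TRUE, collinearity_r2 = 0.99) {
  pe <- prepare_env(env, factors, log_transform, standardize)
  common <- intersect(rownames(clr), rownames(pe$X))
  Y <- scale(clr[common, , drop = FALSE], center = TRUE, scale = FALSE)
  X_all <- pe$X[common, , drop = FALSE]
  n <- nrow(Y)
  cand_all <- colnames(X_all)

  global_r2 <- proj_r2(qr(scale(X_all, center = TRUE, scale = FALSE)), Y)
  global_adj <- ezekiel_adj(global_r2, n, ncol(X_all))

  selected <- character(0)
  path <- list()
  rng_seed <- seed
  repeat {
    candidates <- setdiff(cand_all, selected)
    if (length(candidates) == 0) break
    # score candidates by cumulative adjusted R2
    scores <- vapply(candidates, function(f) {
      Xs <- X_all[, c(selected, f), drop = FALSE]
      ezekiel_adj(proj_r2(qr(scale(Xs, center = TRUE, scale = FALSE)), Y),
                  n, ncol(Xs))
    }, numeric(1))
    best <- candidates[which.max(scores)]

    # collinearity guard against already-selected factors
    if (length(selected) > 0) {
      qs <- qr(cbind(1, X_all[, selected, drop = FALSE]))
      v <- X_all[, best]
      res_v <- v - qr.fitted(qs, v)
      r2_on_sel <- 1 - sum(res_v^2) / sum((v - mean(v))^2)
      if (r2_on_sel > collinearity_r2) {
        cand_all <- setdiff(cand_all, best)
        next
      }
    }

    # conditional permutation test: gain of `best` given `selected`,
    # permuting the residuals of Y on the already-selected factors
    if (length(selected) > 0) {
      qs <- qr(cbind(1, X_all[, selected, drop = FALSE]))
      Yres <- Y - qr.fitted(qs, Y)
      v <- X_all[, best] - qr.fitted(qs, X_all[, best])
    } else {
      Yres <- Y
      v <- X_all[, best] - mean(X_all[, best])
    }
    qv <- qr(matrix(v, ncol = 1))
    gain_obs <- sum(qr.fitted(qv, Yres)^2) / sum(Yres^2)
    gains_null <- with_seed_(rng_seed, {
      vapply(seq_len(n_perm), function(b) {
        Yp <- Yres[sample.int(n), , drop = FALSE]
        sum(qr.fitted(qv, Yp)^2) / sum(Yp^2)
      }, numeric(1))
    })
    if (!is.null(rng_seed)) rng_seed <- rng_seed + 1L
    p <- (1 + sum(gains_null >= gain_obs)) / (n_perm + 1)

    new_adj <- scores[[best]]
    # the global-adjusted-R2 cap guards against over-selection of later,
    # weaker factors; applied from the second admission on, because with
    # pure-noise co-candidates the global adjusted R2 sits at or below the
    # best single factor's in expectation and would veto a genuinely
    # significant first factor about half the time
    if (p >= alpha || (length(selected) >= 1 && new_adj > global_adj)) break
    selected <- c(selected, best)
    path[[length(path) + 1L]] <- tibble(step = length(selected),
                                        factor = best,
                                        r2_adj_cum = new_adj, p.value = p)
  }

  if (length(selected) > 0) {
    fit <- rda_fit(clr, env, factors = selected, n_perm = n_perm,
                   seed = seed, log_transform = log_transform,
                   standardize = standardize)
  } else {
    fit <- structure(list(
      factors = character(0), selected_factors = character(0),
      r2 = 0, r2_adjusted = 0, model_p = NA_real_, axis_p = numeric(0),
      eigenvalues = numeric(0), n = n, n_factors = 0L,
      n_dropped = length(pe$dropped), dropped_samples = pe$dropped,
      offsets = pe$offsets, permutations = n_perm, seed = seed, path = NULL
    ), class = "rda_result")
  }
  fit$path <- if (length(path)) dplyr::bind_rows(path) else
    tibble(step = integer(0), factor = character(0),
           r2_adj_cum = numeric(0), p.value = numeric(0))
  fit$global_r2_adjusted <- global_adj
  fit
}

#' @describeIn rda_fit per-axis eigenvalues and p-values (plus the selection
#'   path after [forward_select()]).
#' @param x an `rda_result`.
#' @param ... unused.
#' @export
tidy.rda_result <- function(x, ...) {
  if (!is.null(x$path) && nrow(x$path) > 0) return(x$path)
  tibble(axis = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
         p.value = x$axis_p)
}

#' @describeIn rda_fit one-row model summary.
#' @export
glance.rda_result <- function(x, ...) {
  tibble(r2 = x$r2, r2_adjusted = x$r2_adjusted, model_p = x$model_p,
         n = x$n, n_factors = x$n_factors, n_dropped = x$n_dropped,
         permutations = x$permutations)
}

#' @export
print.rda_result <- function(x, ...) {
  cat("RDA on", x$n, "samples,", x$n_factors, "factors: R2 =",
      format(x$r2, digits = 3), " adj R2 =",
      format(x$r2_adjusted, digits = 3), " p =", format(x$model_p), "\n")
  if (length(x$selected_factors))
    cat("factors:", paste(x$selected_factors, collapse = ", "), "\n")
  invisible(x)
}
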