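.numeric_matrix <- function(data) {
  num <- data[vapply(data, is.numeric, TRUE)]
  X <- as.matrix(num)
  keep <- complete.cases(X)
  if (sum(!keep) > 0) {
    warning(sprintf("dropping %d incomplete row(s)", sum(!keep)))
    X <- X[keep, , drop = FALSE]
  }
  const <- apply(X, 2, sd) == 0
  if (any(const)) {
    warning(sprintf("excluding constant column(s): %s",
                    paste(colnames(X)[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  X
}

#' PCA over tract-section latent change scores
#'
#' Unrotated principal component analysis on the correlation matrix of the
#' subjects-by-sections change-score matrix, probing whether distributed
#' white-matter plasticity forms a shared dimension. Loadings are reported
#' as component-variable correlations (`eigenvector * sqrt(eigenvalue)`);
#' each component's sign is fixed so its mean loading is positive.
#'
#' @param data Data frame of numeric change-score columns (rows = subjects);
#'   incomplete rows and constant columns are dropped with a warning.
#' @param scores `"standardized"` (unit-variance subject scores, default) or
#'   `"raw"` (variance = eigenvalue).
#' @return A `change_pca`: `loadings`, `explained_variance`, `scores`,
#'   `eigenvalues`, `n`.
#' @export
pca_change_scores <- function(data, scores = c("standardized", "raw")) {
  scores <- match.arg(scores)
  X <- .numeric_matrix(data)
  abort_if(nrow(X) < 3, "need >= 3 complete rows")
  abort_if(ncol(X) < 2, "need >= 2 columns")
  R <- cor(X)
  ev <- eigen(R, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  vec <- ev$vectors
  for (j in seq_len(ncol(vec))) {
    if (mean(vec[, j]) < 0) vec[, j] <- -vec[, j]
  }
  load <- sweep(vec, 2, sqrt(lam), "*")
  dimnames(load) <- list(colnames(X), paste0("PC", seq_along(lam)))
  Z <- scale(X)
  sc <- Z %*% vec
  if (scores == "standardized") {
    sds <- apply(sc, 2, sd)
    pos <- sds > 1e-12
    sc[, pos] <- sweep(sc[, pos, drop = FALSE], 2, sds[pos], "/")
  }
  colnames(sc) <- paste0("PC", seq_along(lam))
  structure(list(loadings = load, explained_variance = lam / sum(lam),
                 eigenvalues = lam, scores = sc, n = nrow(X)),
            class = "change_pca")
}

#' @export
print.change_pca <- function(x, ...) {
  cat(sprintf("<change_pca> %d subjects x %d variables; PC1 explains %.1f%%\n",
              x$n, nrow(x$loadings), 100 * x$explained_variance[1]))
  cat("  PC1 loadings:\n")
  print(round(x$loadings[, 1], 2))
  invisible(x)
}

#' Horn's parallel analysis
#'
#' Retains components whose observed correlation-matrix eigenvalues exceed
#' the reference eigenvalue (mean or 95th percentile) of `n_sim` simulated
#' uncorrelated normal datasets of the same shape. Correlation-based, hence
#' invariant to column rescaling.
#'
#' @param data Numeric data frame (rows = subjects).
#' @param n_sim Simulated datasets.
#' @param criterion `"mean"` (Horn's original) or `"p95"`.
#' @param seed RNG seed.
#' @return List with `n_factors` and a tibble `eigen` (`rank`, `observed`,
#'   `threshold`, `retained`).
#' @export
parallel_analysis <- function(data, n_sim = 1000, criterion = c("mean", "p95"),
                              seed = NULL) {
  criterion <- match.arg(criterion)
  if (!is.null(seed)) set.seed(seed)
  X <- .numeric_matrix(data)
  n <- nrow(X); p <- ncol(X)
  obs <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  sims <- vapply(seq_len(n_sim), function(i) {
    eigen(cor(matrix(rnorm(n * p), n, p)), symmetric = TRUE,
          only.values = TRUE)$values
  }, numeric(p))
  thr <- if (criterion == "mean") rowMeans(sims)
         else apply(sims, 1, quantile, probs = 0.95)
  above <- obs > thr
  n_factors <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  list(n_factors = as.integer(n_factors),
       eigen = tibble::tibble(rank = seq_len(p), observed = obs,
                              threshold = thr,
                              retained = seq_len(p) <= n_factors))
}

#' Factorability diagnostics for a change-score matrix
#'
#' Kaiser-Meyer-Olkin sampling adequacy (overall and per variable) from
#' anti-image partial correlations, Bartlett's test of sphericity
#' (`chi2 = -(n - 1 - (2p + 5)/6) log det(R)`, `df = p(p-1)/2`), and the
#' determinant of the correlation matrix checked against 1e-5 as a
#' multicollinearity screen.
#'
#' @param data Numeric data frame (rows = subjects).
#' @return A `factorability` object (list): `kmo_overall`, `kmo_per_var`,
#'   `bartlett_chi2`, `bartlett_df`, `bartlett_p`, `determinant`, `det_ok`,
#'   `n`, `p`.
#' @export
factorability <- function(data) {
  X <- .numeric_matrix(data)
  n <- nrow(X); p <- ncol(X)
  abort_if(p < 2, "need >= 2 variables")
  if (n <= p) warning("n <= p: diagnostics unstable")
  R <- cor(X)
  detR <- det(R)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) {
    warning("singular correlation matrix: KMO undefined")
    kmo <- NA_real_; kmo_i <- rep(NA_real_, p)
  } else {
    dS <- 1 / sqrt(diag(inv))
    Q <- -inv * tcrossprod(dS)          # anti-image partial correlations
    diag(Q) <- 0
    R0 <- R; diag(R0) <- 0
    kmo <- sum(R0^2) / (sum(R0^2) + sum(Q^2))
    kmo_i <- colSums(R0^2) / (colSums(R0^2) + colSums(Q^2))
    names(kmo_i) <- colnames(X)
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(max(detR, .Machine$double.xmin))
  df <- p * (p - 1) / 2
  structure(list(kmo_overall = kmo, kmo_per_var = kmo_i,
                 bartlett_chi2 = chi2, bartlett_df = df,
                 bartlett_p = pchisq(chi2, df, lower.tail = FALSE),
                 determinant = detR, det_ok = detR > 1e-5,
                 n = n, p = p),
            class = "factorability")
}

#' @export
print.factorability <- function(x, ...) {
  cat(sprintf("<factorability> n = %d, p = %d\n", x$n, x$p))
  cat(sprintf("  KMO overall %.2f (per-variable %.2f-%.2f)\n",
              x$kmo_overall, min(x$kmo_per_var), max(x$kmo_per_var)))
  cat(sprintf("  Bartlett chi2(%d) = %.2f, p = %.2g; det(R) = %.3g (> 1e-5: %s)\n",
              x$bartlett_df, x$bartlett_chi2, x$bartlett_p, x$determinant,
              x$det_ok))
  invisible(x)
}

# Tukey bisquare rho, 95% Gaussian efficiency tuning
.bisquare_rho <- function(u, c = 4.685) {
  out <- rep(c^2 / 6, length(u))
  inside <- abs(u) <= c
  out[inside] <- (c^2 / 6) * (1 - (1 - (u[inside] / c)^2)^3)
  out
}

.robust_deviance <- function(res, s, c = 4.685) sum(.bisquare_rho(res / s, c))

#' Robust MM regression with bootstrap BCa intervals
#'
#' MM estimation (S-estimator start, bisquare M-step at 95% Gaussian
#' efficiency, tuning c = 4.685) of a linear model, with case-resampling
#' bootstrap BCa intervals for the coefficients, a deviance-based robust
#' R-squared, and a pseudo-F test against the intercept-only model.
#' The robust deviance of a fit is `D = sum rho_c(r_i / s)` at the full
#' model's MM scale `s`; the pseudo-F is `((D0 - D1)/q) / (D1/(n - q - 1))`
#' with `q` slopes, referred to an F(q, n - q - 1) distribution, and the
#' robust R-squared is `1 - D1/D0`. A condition number of the predictor
#' matrix is always reported as a collinearity diagnostic.
#'
#' @param data Data frame holding response and predictors.
#' @param formula Model formula, e.g. `odi_change ~ pc1`.
#' @param B_boot Bootstrap replicates for coefficient intervals.
#' @param seed RNG seed.
#' @param level Interval level.
#' @return A `robust_fit`: `coef` tibble (`term`, `estimate`, `conf_low`,
#'   `conf_high`), `r2`, `pseudo_f`, `df1`, `df2`, `p_value`, `scale`,
#'   `weights`, `condition_number`, `n`, and the underlying `rlm` fit.
#' @export
robust_fit <- function(data, formula, B_boot = 2000, seed = NULL,
                       level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  mf <- stats::model.frame(formula, data)
  n <- nrow(mf)
  q <- ncol(model.matrix(formula, mf)) - 1
  abort_if(n < q + 3, "need n >= p + 3 complete cases")
  # exact linear data break the S-estimation subsampling; short-circuit
  ols0 <- lm(formula, data = mf)
  if (max(abs(resid(ols0))) < 1e-10 * max(1, sd(stats::model.response(mf)))) {
    warning("perfect fit: pseudo-F infinite")
    est <- coef(ols0)
    Xmat <- model.matrix(formula, mf)
    kappa_x <- if (q >= 1) kappa(scale(Xmat[, -1, drop = FALSE]), exact = TRUE)
               else NA_real_
    return(structure(list(
      fit = ols0,
      coef = tibble::tibble(term = names(est), estimate = unname(est),
                            conf_low = unname(est), conf_high = unname(est)),
      r2 = 1, pseudo_f = Inf, df1 = q, df2 = n - q - 1, p_value = 0,
      scale = 0, weights = rep(1, n), condition_number = kappa_x,
      n = n, B_boot = B_boot, level = level, n_boot_failed = 0L,
      formula = formula), class = "robust_fit"))
  }
  fit <- MASS::rlm(formula, data = mf, method = "MM", maxit = 200)
  abort_if(!fit$converged, "MM estimation did not converge")
  y <- stats::model.response(mf)
  fit0 <- MASS::rlm(y ~ 1, method = "MM", maxit = 200)
  s <- fit$s
  D1 <- .robust_deviance(resid(fit), s)
  D0 <- .robust_deviance(y - coef(fit0)[1], s)
  if (D1 < 1e-12) {
    warning("perfect fit: pseudo-F infinite")
    r2 <- 1; Fstat <- Inf; pval <- 0
  } else {
    r2 <- 1 - D1 / D0
    Fstat <- ((D0 - D1) / q) / (D1 / (n - q - 1))
    pval <- pf(Fstat, q, n - q - 1, lower.tail = FALSE)
  }

  est <- coef(fit)
  boot_fn <- function(d) {
    f <- tryCatch(suppressWarnings(MASS::rlm(formula, data = d, method = "MM",
                                             maxit = 200)),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) return(rep(NA_real_, length(est)))
    coef(f)
  }
  boot_mat <- t(vapply(seq_len(B_boot), function(b) {
    boot_fn(mf[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, numeric(length(est))))
  jack_mat <- t(vapply(seq_len(n), function(i) {
    boot_fn(mf[-i, , drop = FALSE])
  }, numeric(length(est))))
  ci <- t(vapply(seq_along(est), function(j) {
    tb <- boot_mat[, j]; tj <- jack_mat[, j]
    bca_ci(est[j], tb[is.finite(tb)], tj[is.finite(tj)], level = level)
  }, numeric(2)))

  Xmat <- model.matrix(formula, mf)
  kappa_x <- if (q >= 1) kappa(scale(Xmat[, -1, drop = FALSE]), exact = TRUE)
             else NA_real_
  structure(list(
    fit = fit,
    coef = tibble::tibble(term = names(est), estimate = unname(est),
                          conf_low = ci[, 1], conf_high = ci[, 2]),
    r2 = r2, pseudo_f = Fstat, df1 = q, df2 = n - q - 1, p_value = pval,
    scale = s, weights = fit$w, condition_number = kappa_x,
    n = n, B_boot = B_boot, level = level,
    n_boot_failed = sum(!complete.cases(boot_mat)),
    formula = formula),
    class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> %s (MM, bisquare c = 4.685), n = %d\n",
              deparse(x$formula), x$n))
  print(x$coef)
  cat(sprintf("  robust R2 = %.3f; pseudo-F(%d, %d) = %.2f, p = %.3g; condition number %.1f\n",
              x$r2, x$df1, x$df2, x$pseudo_f, x$p_value, x$condition_number))
  invisible(x)
}

#' Leave-one-out cross-validation of a regression model
#'
#' Refits the model `n` times leaving each subject out, predicts the held-out
#' response, and summarizes prediction error as MSE, RMSE, and
#' `1 - SSE_model / SSE_null`, where the null model predicts each held-out
#' observation by its training fold's mean (positive ratios indicate
#' predictive power; negative ratios indicate overfitting).
#'
#' @param data Data frame holding response and predictors.
#' @param formula Model formula.
#' @param fitter `"robust"` (MM) or `"ols"`.
#' @return One-row tibble: `mse`, `rmse`, `sse_ratio`, `n`, `n_failed`.
#' @export
loocv <- function(data, formula, fitter = c("robust", "ols")) {
  fitter <- match.arg(fitter)
  mf <- stats::model.frame(formula, data)
  n <- nrow(mf)
  abort_if(n < 4, "need n >= 4")
  y <- stats::model.response(mf)
  pred <- rep(NA_real_, n)
  pred_null <- rep(NA_real_, n)
  failed <- 0L
  for (i in seq_len(n)) {
    train <- mf[-i, , drop = FALSE]
    f <- tryCatch({
      if (fitter == "robust")
        suppressWarnings(MASS::rlm(formula, data = train, method = "MM",
                                   maxit = 200))
      else lm(formula, data = train)
    }, error = function(e) NULL)
    if (is.null(f) || (fitter == "robust" && !f$converged)) {
      failed <- failed + 1L
      next
    }
    pred[i] <- predict(f, newdata = mf[i, , drop = FALSE])
    pred_null[i] <- mean(stats::model.response(train))
  }
  if (failed > 0) warning(sprintf("%d fold(s) failed to converge", failed))
  ok <- is.finite(pred)
  err2 <- (y[ok] - pred[ok])^2
  sse_m <- sum(err2)
  sse_0 <- sum((y[ok] - pred_null[ok])^2)
  tibble::tibble(mse = mean(err2), rmse = sqrt(mean(err2)),
                 sse_ratio = 1 - sse_m / sse_0, n = sum(ok),
                 n_failed = failed)
}
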