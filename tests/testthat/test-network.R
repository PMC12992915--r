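one_factor_data <- function(n = 24, p = 5, loading = 0.8, seed = 1) {
  set.seed(seed)
  f <- rnorm(n)
  X <- sapply(seq_len(p), function(j) loading * f +
                sqrt(1 - loading^2) * rnorm(n))
  colnames(X) <- paste0("V", seq_len(p))
  tibble::as_tibble(X)
}

test_that("PCA of identical columns puts all variance on an equal-loading PC1", {
  d <- tibble::as_tibble(matrix(rep(rnorm(24), 5), 24, 5,
                                dimnames = list(NULL, paste0("V", 1:5))))
  pc <- pca_change_scores(d)
  expect_equal(pc$explained_variance[1], 1)
  expect_equal(unname(pc$loadings[, 1]), rep(1, 5), tolerance = 1e-12)
})

test_that("two independent correlated blocks give two dominant components", {
  set.seed(11)
  f1 <- rnorm(200); f2 <- rnorm(200)
  d <- tibble::tibble(a1 = f1 + 0.3 * rnorm(200), a2 = f1 + 0.3 * rnorm(200),
                      b1 = f2 + 0.3 * rnorm(200), b2 = f2 + 0.3 * rnorm(200))
  pc <- pca_change_scores(d)
  expect_gt(sum(pc$explained_variance[1:2]), 0.85)
  # each of the two leading components aligns with one block
  l <- abs(pc$loadings[, 1:2])
  block <- c(1, 1, 2, 2)
  top <- apply(l, 2, function(v) block[order(v, decreasing = TRUE)[1:2]])
  expect_setequal(c(top[, 1], top[, 2]), c(1, 1, 2, 2))
})

test_that("spiked one-factor data match the expected PC1 variance share", {
  # population: explained share = l^2 + (1 - l^2)/p
  shares <- vapply(1:40, function(i) {
    pca_change_scores(one_factor_data(n = 100, seed = 100 + i))$explained_variance[1]
  }, 1)
  expect_lt(abs(mean(shares) - (0.64 + 0.36 / 5)), 0.03)
})

test_that("standardized subject scores have unit variance and track the factor", {
  d <- one_factor_data(n = 50, seed = 3)
  pc <- pca_change_scores(d)
  expect_equal(sd(pc$scores[, 1]), 1, tolerance = 1e-12)
  # raw scores carry the component variance (eigenvalue) exactly
  raw <- pca_change_scores(d, scores = "raw")
  expect_equal(stats::var(raw$scores[, 1]), raw$eigenvalues[1],
               tolerance = 1e-10)
})

test_that("parallel analysis retains the right number of factors", {
  hits <- vapply(1:25, function(i) {
    parallel_analysis(one_factor_data(seed = 200 + i), n_sim = 150,
                      seed = i)$n_factors
  }, 1L)
  expect_gte(mean(hits == 1), 0.95)
  # pure noise: the mean criterion retains few factors, the stricter 95th
  # percentile criterion almost never retains more than one
  noise_mean <- vapply(1:25, function(i) {
    d <- tibble::as_tibble(matrix(rnorm(24 * 5), 24, 5,
                                  dimnames = list(NULL, paste0("V", 1:5))))
    parallel_analysis(d, n_sim = 150, seed = 400 + i)$n_factors
  }, 1L)
  expect_lt(mean(noise_mean), 1.2)
  noise_p95 <- vapply(1:25, function(i) {
    d <- tibble::as_tibble(matrix(rnorm(24 * 5), 24, 5,
                                  dimnames = list(NULL, paste0("V", 1:5))))
    parallel_analysis(d, n_sim = 150, criterion = "p95",
                      seed = 600 + i)$n_factors
  }, 1L)
  expect_gte(mean(noise_p95 <= 1), 0.95)
  # two strong orthogonal factors
  set.seed(5)
  f1 <- rnorm(100); f2 <- rnorm(100)
  d2 <- tibble::tibble(a = f1 + 0.3 * rnorm(100), b = f1 + 0.3 * rnorm(100),
                       c = f2 + 0.3 * rnorm(100), d = f2 + 0.3 * rnorm(100))
  expect_equal(parallel_analysis(d2, n_sim = 200, seed = 6)$n_factors, 2L)
  # invariance to column rescaling
  d3 <- dplyr::mutate(d2, a = a * 100, c = c / 50)
  expect_equal(parallel_analysis(d3, n_sim = 200, seed = 6)$n_factors, 2L)
})

test_that("factorability diagnostics match their closed forms", {
  # exactly uncorrelated columns (QR of centered data): R = identity,
  # Bartlett chi2 = 0, det = 1
  set.seed(12)
  X <- qr.Q(qr(scale(matrix(rnorm(30 * 3), 30, 3), scale = FALSE)))
  d <- tibble::as_tibble(`colnames<-`(X, c("a", "b", "c")))
  f <- factorability(d)
  expect_equal(f$bartlett_chi2, 0, tolerance = 1e-8)
  expect_equal(f$determinant, 1, tolerance = 1e-10)
  # p = 5 gives df = 10
  f5 <- factorability(one_factor_data(seed = 7))
  expect_equal(f5$bartlett_df, 10)
  expect_gte(f5$bartlett_chi2, 0)
  expect_gt(f5$kmo_overall, 0.5)
  expect_length(f5$kmo_per_var, 5)
  # any two-variable dataset has overall KMO exactly 0.5
  d2 <- one_factor_data(p = 2, seed = 8)
  expect_equal(factorability(d2)$kmo_overall, 0.5, tolerance = 1e-12)
})

test_that("robust MM regression recovers a noiseless line exactly", {
  d <- tibble::tibble(x = seq(-2, 2, length.out = 24), y = -1.82 * x)
  expect_warning(f <- robust_fit(d, y ~ x, B_boot = 50, seed = 1),
                 "perfect fit")
  expect_equal(f$coef$estimate[2], -1.82, tolerance = 1e-6)
  expect_equal(f$r2, 1)
  expect_true(is.infinite(f$pseudo_f))
})

test_that("MM estimation resists gross contamination where OLS does not", {
  set.seed(13)
  sl_mm <- sl_ols <- numeric(400)
  for (i in seq_len(400)) {
    x <- rnorm(24)
    y <- 2 * x + rnorm(24)
    out <- sample.int(24, 2)
    y[out] <- y[out] + 10
    d <- tibble::tibble(x = x, y = y)
    f <- tryCatch(suppressWarnings(MASS::rlm(y ~ x, data = d, method = "MM")),
                  error = function(e) NULL)
    sl_mm[i] <- if (is.null(f)) NA else coef(f)[2]
    sl_ols[i] <- coef(lm(y ~ x, data = d))[2]
  }
  expect_lt(abs(median(sl_mm, na.rm = TRUE) - 2), 0.15)
  # OLS intercept is pulled up by the shifted outliers; its slope noise grows
  expect_gt(sd(sl_ols), sd(sl_mm, na.rm = TRUE))
})

test_that("the pseudo-F test holds its nominal size under the null", {
  set.seed(14)
  pvals <- replicate(600, {
    d <- tibble::tibble(x = rnorm(24), y = rnorm(24))
    f <- tryCatch(robust_fit(d, y ~ x, B_boot = 0), error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$p_value
  })
  rej <- mean(pvals < 0.05, na.rm = TRUE)
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("bootstrap BCa coefficient intervals bracket a strong true slope", {
  set.seed(15)
  d <- tibble::tibble(x = rnorm(24))
  d$y <- -1.82 * d$x + rnorm(24, 0, 0.5)
  f <- robust_fit(d, y ~ x, B_boot = 400, seed = 2)
  sl <- f$coef[f$coef$term == "x", ]
  expect_true(sl$conf_low <= -1.82 + 0.5 && -1.82 - 0.5 <= sl$conf_high)
  expect_lt(sl$conf_low, sl$conf_high)
})

test_that("LOOCV is exact on linear data and penalizes null models", {
  d <- tibble::tibble(x = seq_len(24), y = 3 * seq_len(24) + 1)
  cv <- loocv(d, y ~ x, fitter = "ols")
  expect_equal(cv$mse, 0, tolerance = 1e-16)
  expect_equal(cv$sse_ratio, 1)
  expect_equal(cv$rmse^2, cv$mse)
  # independent response: expected ratio is negative (overfitting signature)
  set.seed(16)
  ratios <- replicate(300, {
    d0 <- tibble::tibble(x = rnorm(20), y = rnorm(20))
    loocv(d0, y ~ x, fitter = "ols")$sse_ratio
  })
  expect_lte(mean(ratios), 0)
})

test_that("MM estimates converge to OLS without contamination at larger n", {
  set.seed(17)
  d <- tibble::tibble(x = rnorm(200))
  d$y <- 1.5 * d$x + rnorm(200)
  f_mm <- suppressWarnings(MASS::rlm(y ~ x, data = d, method = "MM"))
  f_ols <- lm(y ~ x, data = d)
  expect_lt(abs(coef(f_mm)[2] - coef(f_ols)[2]), 0.05)
})

test_that("the network stage links latent white-matter change to cortical change", {
  # five sections driven by one latent; cortical response from the same latent
  set.seed(18)
  n <- 24
  m <- rnorm(n, 0, 0.5)
  sections <- tibble::as_tibble(
    sapply(1:5, function(j) m + rnorm(n, 0, 0.25),
           simplify = "matrix") |> `colnames<-`(paste0("sec", 1:5)))
  pc <- pca_change_scores(sections)
  expect_gt(abs(cor(pc$scores[, 1], m, method = "spearman")), 0.8)
  cortical <- tibble::tibble(odi_change = -1.82 * m + rnorm(n, 0, 0.4),
                             pc1 = pc$scores[, 1])
  f <- robust_fit(cortical, odi_change ~ pc1, B_boot = 200, seed = 3)
  expect_lt(f$p_value, 0.01)
  expect_lt(f$coef$estimate[2], 0)
  cv <- loocv(cortical, odi_change ~ pc1)
  expect_gt(cv$sse_ratio, 0)
})
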