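std_obs <- function(beta2 = 0.1, beta3 = 0.4, n = 6, u_sd = 0, seed = 1) {
  set.seed(seed)
  u <- rnorm(n, 0, u_sd)
  d <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:n),
                          session = c("MRI1", "MRI2", "MRI3"))
  d$metric <- "MT"
  d$outcome <- u[match(d$subject_id, unique(d$subject_id))] +
    c(0, beta2, beta3)[match(d$session, c("MRI1", "MRI2", "MRI3"))]
  attr(d, "session_levels") <- c("MRI1", "MRI2", "MRI3")
  d
}

test_that("standardization gives per-metric mean 0 / SD 1 and inverts exactly", {
  cfg <- tiny_config(n_subjects = 8, seed = 21)
  p <- generate_tract_profiles(cfg)
  obs <- standardize_panel(p, "ATR_R", 2)
  stats <- obs |>
    dplyr::group_by(metric) |>
    dplyr::summarise(m = mean(outcome), s = sd(outcome))
  expect_equal(stats$m, rep(0, 4), tolerance = 1e-12)
  expect_equal(stats$s, rep(1, 4), tolerance = 1e-12)
  # de-standardization round trip
  sc <- attr(obs, "scale")
  back <- obs |>
    dplyr::left_join(sc, by = "metric") |>
    dplyr::mutate(v = outcome * sd + mean)
  orig <- dplyr::filter(p, tract == "ATR_R", segment == 2)
  key <- function(d) paste(d$subject_id, d$session, d$metric)
  expect_equal(back$v[order(key(back))], orig$value[order(key(orig))],
               tolerance = 1e-12)
})

test_that("zero-variance metrics are excluded with a warning", {
  cfg <- tiny_config(n_subjects = 4, seed = 2)
  p <- generate_tract_profiles(cfg)
  p$value[p$metric == "ODI"] <- 0.25
  expect_warning(obs <- standardize_panel(p, "ATR_R", 1), "ODI")
  expect_false("ODI" %in% obs$metric)
})

test_that("mixed-model fixed effects equal session-mean differences on balanced data", {
  # deterministic session means (0, 0.1, 0.4) with subject offsets
  d <- std_obs(0.1, 0.4, n = 6, u_sd = 0.8)
  fit <- fit_segment_lmm(d, "MT")
  mns <- tapply(d$outcome, d$session, mean)
  expect_equal(unname(fit$beta["MRI2"]), unname(mns["MRI2"] - mns["MRI1"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$beta["MRI3"]), unname(mns["MRI3"] - mns["MRI1"]),
               tolerance = 1e-8)
  # OLS oracle gives the same estimates on balanced complete data
  ols <- lm(outcome ~ factor(session, levels = c("MRI1", "MRI2", "MRI3")),
            data = d)
  expect_equal(unname(fit$beta), unname(coef(ols)[2:3]), tolerance = 1e-8)
})

test_that("the balanced fast path and the mixed-model path agree exactly", {
  cfg <- tiny_config(n_subjects = 10, seed = 31,
                     effects = list(fiso_mt_effect()))
  p <- generate_tract_profiles(cfg)
  fast <- fit_segment_asca(p, "ATR_R", 2, method = "auto")
  slow <- fit_segment_asca(p, "ATR_R", 2, method = "lmm")
  expect_equal(fast$method, "balanced-exact")
  expect_equal(unname(fast$beta[, fast$metrics]),
               unname(slow$beta[, fast$metrics]), tolerance = 1e-6)
  expect_equal(fast$explained_variance, slow$explained_variance,
               tolerance = 1e-6)
  expect_equal(abs(unname(fast$loadings[, 1])),
               abs(unname(slow$loadings[fast$metrics, 1])), tolerance = 1e-5)
})

test_that("variance components are recovered with small bias", {
  set.seed(41)
  vc <- t(replicate(400, {
    d <- std_obs(0, 0.2, n = 24, u_sd = 0.5, seed = sample.int(1e6, 1))
    d$outcome <- d$outcome + rnorm(nrow(d), 0, 0.2)
    fit_segment_lmm(d, "MT")$varcomp
  }))
  expect_lt(abs(mean(vc[, "subject"]) - 0.25), 0.025)
  expect_lt(abs(mean(vc[, "residual"]) - 0.04), 0.004)
})

test_that("singular fits land at the zero boundary with a flag, not an error", {
  d <- std_obs(0.1, 0.4, n = 8, u_sd = 0)
  d$outcome <- d$outcome + rep(c(-0.01, 0.01), length.out = nrow(d))
  fit <- fit_segment_lmm(d, "MT")
  expect_lt(fit$varcomp["subject"], 1e-6)
  expect_true(fit$singular)
})

test_that("the time-effect matrix has the balanced combinatorial structure", {
  beta <- matrix(c(0.1, 0.4, -0.2, 0.3), nrow = 2,
                 dimnames = list(c("MRI2", "MRI3"), c("MT", "FISO")))
  keys <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:24),
                             session = c("MRI1", "MRI2", "MRI3"))
  em <- build_time_effect_matrix(beta, keys, c("MRI1", "MRI2", "MRI3"))
  expect_equal(dim(em), c(72, 2))
  expect_equal(nrow(unique(em)), 3)
  expect_true(all(em[keys$session == "MRI1", ] == 0))
  # baseline-only observations give an all-zero matrix
  k0 <- keys[keys$session == "MRI1", ]
  expect_true(all(build_time_effect_matrix(beta, k0, c("MRI1", "MRI2", "MRI3")) == 0))
  # a single active metric yields a single nonzero column
  beta1 <- matrix(c(0, 1, 0, 0), nrow = 2,
                  dimnames = list(c("MRI2", "MRI3"), c("MT", "FISO")))
  em1 <- build_time_effect_matrix(beta1, keys, c("MRI1", "MRI2", "MRI3"))
  expect_true(all(em1[, 2] == 0) && any(em1[, 1] != 0))
})

test_that("effect-matrix PCA matches constructed oracles", {
  keys <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:5),
                             session = c("MRI1", "MRI2", "MRI3"))
  sess <- c("MRI1", "MRI2", "MRI3")
  # single nonzero column: PC1 explains all variance, unit loading
  b1 <- matrix(c(0.2, 0.5, 0, 0), 2, dimnames = list(sess[-1], c("MT", "FISO")))
  d1 <- decompose_effects(build_time_effect_matrix(b1, keys, sess) |>
                            `colnames<-`(c("MT", "FISO")),
                          keys = keys, sessions = sess)
  expect_equal(d1$explained_variance[1], 1)
  expect_equal(unname(d1$loadings[, 1]), c(1, 0))
  # identical trajectories in two metrics: loadings 1/sqrt(2), 100% on PC1
  b2 <- matrix(c(0.2, 0.5, 0.2, 0.5), 2, dimnames = list(sess[-1], c("MT", "FISO")))
  d2 <- decompose_effects(build_time_effect_matrix(b2, keys, sess) |>
                            `colnames<-`(c("MT", "FISO")),
                          keys = keys, sessions = sess)
  expect_equal(d2$explained_variance[1], 1)
  expect_equal(unname(d2$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-12)
  # orthogonal equal-norm patterns split 50/50
  b3 <- matrix(c(0.5, 0, 0, 0.5), 2, dimnames = list(sess[-1], c("MT", "FISO")))
  d3 <- decompose_effects(build_time_effect_matrix(b3, keys, sess) |>
                            `colnames<-`(c("MT", "FISO")),
                          keys = keys, sessions = sess)
  expect_equal(d3$explained_variance, c(0.5, 0.5), tolerance = 1e-12)
  # session scores are the unique-row projections; baseline at the origin
  expect_equal(unname(d1$scores["MRI1", 1]), 0)
  expect_equal(unname(d1$scores["MRI3", 1]), 0.5)
})

test_that("PC1 loadings recover an injected single-pattern effect", {
  lam <- c(FISO = 0.9, MT = -sqrt(1 - 0.81))
  cfg <- tiny_config(n_subjects = 24, seed = 51,
                     sigma_resid = 0.4,
                     effects = list(effect_template("ATR_R", 2, lam,
                                                    group_magnitude = -1,
                                                    subject_sd = 0.3)))
  p <- generate_tract_profiles(cfg)
  m <- fit_segment_asca(p, "ATR_R", 2)
  l1 <- m$loadings[names(lam), 1]
  cosine <- abs(sum(l1 * lam) / sqrt(sum(l1^2) * sum(lam^2)))
  expect_gt(cosine, 0.99)
})

test_that("bootstrap CIs shrink to the point estimate as noise vanishes", {
  # every metric must carry the deterministic signal: standardization
  # rescales pure-noise metrics to unit variance however small the noise
  cfg <- tiny_config(n_subjects = 12, seed = 61, sigma_subject = 0.01,
                     sigma_resid = 0.01, metrics = c("FISO", "MT"),
                     effects = list(fiso_mt_effect(subject_sd = 0.01)))
  p <- generate_tract_profiles(cfg)
  bt <- bootstrap_asca(p, "ATR_R", 2, B = 200, seed = 5)
  sc <- dplyr::filter(bt$ci, kind == "score")
  # widths are tiny relative to the |score| ~ 3 signal
  expect_true(all(sc$conf_high - sc$conf_low < 0.1))
  expect_true(all(sc$conf_low - 1e-9 <= sc$estimate &
                    sc$estimate <= sc$conf_high + 1e-9))
})

test_that("bootstrap is deterministic given a seed", {
  cfg <- tiny_config(n_subjects = 10, seed = 71,
                     effects = list(fiso_mt_effect()))
  p <- generate_tract_profiles(cfg)
  b1 <- bootstrap_asca(p, "ATR_R", 2, B = 100, seed = 9)
  b2 <- bootstrap_asca(p, "ATR_R", 2, B = 100, seed = 9)
  expect_identical(b1$ci, b2$ci)
})

test_that("interval-overlap classification reproduces reported decisions", {
  # right ATR: stable control, post-training interval below both
  atr <- tibble::tibble(conf_low = c(-0.07, -0.08, -0.81),
                        conf_high = c(0.56, 0.52, -0.17))
  expect_true(classify_segment(atr)$plastic)
  # inferior left CST: control intervals overlap on [-0.38, -0.12],
  # post-training interval above both
  cst <- tibble::tibble(conf_low = c(-0.38, -0.68, 0.26),
                        conf_high = c(0.24, -0.12, 0.79))
  fl <- classify_segment(cst)
  expect_true(fl$stable_control)
  expect_true(fl$plastic)
  # identical intervals at all sessions: no change
  same <- tibble::tibble(conf_low = rep(-0.2, 3), conf_high = rep(0.4, 3))
  expect_false(classify_segment(same)$plastic)
})

test_that("subject score prediction is a projection of standardized data", {
  cfg <- tiny_config(n_subjects = 10, seed = 81,
                     effects = list(fiso_mt_effect()))
  p <- generate_tract_profiles(cfg)
  m <- fit_segment_asca(p, "ATR_R", 2)
  sc <- predict_subject_scores(m, p)
  expect_equal(nrow(sc), 30)
  # manual projection for one subject-session
  obs <- standardize_panel(p, "ATR_R", 2)
  one <- dplyr::filter(obs, subject_id == "S03", session == "MRI3")
  manual <- sum(one$outcome * m$loadings[one$metric, 1])
  expect_equal(sc$score[sc$subject_id == "S03" & sc$session == "MRI3"],
               manual, tolerance = 1e-12)
  # group means of predicted scores reproduce the model's session-score
  # differences exactly (prediction is grand-mean anchored, the model's
  # trajectory is baseline-anchored; offsets cancel in differences)
  grp <- tapply(sc$score, sc$session, mean)
  expect_equal(as.numeric(grp[m$sessions] - grp[m$sessions[1]]),
               as.numeric(m$scores[, 1] - m$scores[1, 1]),
               tolerance = 1e-8)
})

test_that("predicted interval changes rank-recover the injected magnitudes", {
  # SNR 2: subject effect SD 0.5 vs interval score noise 0.18 * sqrt(2)
  cfg <- tiny_config(n_subjects = 24, seed = 91, sigma_resid = 0.18,
                     effects = list(fiso_mt_effect(magnitude = -1,
                                                   subject_sd = 0.5)))
  p <- generate_tract_profiles(cfg)
  m <- fit_segment_asca(p, "ATR_R", 2)
  sc <- predict_subject_scores(m, p)
  deltas <- interval_change_scores(sc, sessions = m$sessions)
  mags <- subject_magnitudes(p)
  rho <- cor(deltas$d23, mags$magnitude, method = "spearman")
  expect_gt(abs(rho), 0.8)
})
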