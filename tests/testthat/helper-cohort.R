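# small cohort configurations used across tests

tiny_metrics <- c("FISO", "FICVF", "ODI", "MT")

zero_unit_scales <- function(metrics) {
  list(means = setNames(rep(0, length(metrics)), metrics),
       scales = setNames(rep(1, length(metrics)), metrics))
}

# one tract, few segments, metrics on the z-scale directly
tiny_config <- function(n_subjects = 24, n_segments = 3, effects = list(),
                        sigma_subject = 1, sigma_resid = 0.4, ar_phi = 0,
                        seed = 1, metrics = tiny_metrics, tracts = "ATR_R",
                        ...) {
  zs <- zero_unit_scales(metrics)
  cohort_config(n_subjects = n_subjects, tracts = tracts,
                n_segments = n_segments, metrics = metrics,
                metric_means = zs$means, metric_scales = zs$scales,
                sigma_subject = sigma_subject, sigma_resid = sigma_resid,
                ar_phi = ar_phi, effects = effects, seed = seed, ...)
}

# single-template effect with a FISO/MT loading, unit norm by construction
fiso_mt_effect <- function(tract = "ATR_R", segments = 2, magnitude = -0.8,
                           subject_sd = 0.4) {
  effect_template(tract, segments,
                  c(FISO = 0.9, MT = -sqrt(1 - 0.81)),
                  group_magnitude = magnitude, subject_sd = subject_sd)
}

# analytic population session scores for a tiny_config with one template
# (metric variance = sigma_u^2 + sigma_r^2 + between-session effect variance;
#  standardized betas projected onto the unit PC1 direction)
population_scores <- function(loading, magnitude, subject_sd,
                              sigma_subject = 1, sigma_resid = 0.4,
                              n_sessions = 3) {
  lam <- loading / sqrt(sum(loading^2))
  em2 <- magnitude^2 + subject_sd^2
  f <- 1 / n_sessions
  eff_var <- lam^2 * (f * em2 - (f * magnitude)^2)
  sds <- sqrt(sigma_subject^2 + sigma_resid^2 + eff_var)
  beta3 <- magnitude * lam / sds
  v1 <- beta3 / sqrt(sum(beta3^2))
  j <- which.max(abs(v1))
  if (v1[j] < 0) v1 <- -v1
  c(0, 0, sum(beta3 * v1))
}
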