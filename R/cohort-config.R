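#' Default white-matter bundle panel
#'
#' The 29 motor-network bundles analyzed along-tract: the middle cerebellar
#' peduncle, bilateral inferior/superior cerebellar peduncles, frontopontine
#' and corticospinal tracts, anterior/superior thalamic radiations,
#' thalamo-premotor, striato-fronto-orbital and striato-premotor tracts,
#' superior longitudinal fascicles I-III, and four anterior callosal sectors
#' (rostrum, genu, rostral body, anterior midbody).
#'
#' @return Character vector of 29 bundle names.
#' @export
default_tracts <- function() {
  c("MCP",
    "ICP_L", "ICP_R", "SCP_L", "SCP_R",
    "FPT_L", "FPT_R", "CST_L", "CST_R",
    "ATR_L", "ATR_R", "STR_L", "STR_R",
    "T_PREM_L", "T_PREM_R", "ST_FO_L", "ST_FO_R", "ST_PREM_L", "ST_PREM_R",
    "SLF_I_L", "SLF_I_R", "SLF_II_L", "SLF_II_R", "SLF_III_L", "SLF_III_R",
    "CC_1", "CC_2", "CC_3", "CC_4")
}

#' Default microstructural metric panel
#'
#' Eight quantitative MRI metrics: NODDI free-water and intracellular volume
#' fractions (FISO, FICVF) and orientation dispersion (ODI); magnetization
#' transfer saturation (MT), longitudinal and effective transverse relaxation
#' rates (R1, R2*), proton density (PD); and the aggregate g-ratio (GRATIO).
#'
#' @return Character vector of metric names.
#' @export
default_metrics <- function() {
  c("FISO", "FICVF", "ODI", "MT", "R1", "R2s", "PD", "GRATIO")
}

# plausible white-matter baselines and native-unit scales (1 z-unit each)
default_metric_means <- function(metrics) {
  base <- c(FISO = 0.10, FICVF = 0.55, ODI = 0.25, MT = 3.5,
            R1 = 1.0, R2s = 20, PD = 70, GRATIO = 0.70)
  out <- base[metrics]
  out[is.na(out)] <- 1
  names(out) <- metrics
  out
}

default_metric_scales <- function(metrics) {
  base <- c(FISO = 0.02, FICVF = 0.03, ODI = 0.02, MT = 0.10,
            R1 = 0.02, R2s = 0.8, PD = 1.5, GRATIO = 0.01)
  out <- base[metrics]
  out[is.na(out)] <- 1
  names(out) <- metrics
  out
}

#' Describe a localized training effect on a tract
#'
#' An effect template places a multivariate change at specific segments of one
#' bundle: at the post-training session each affected metric moves by
#' `magnitude * loading` z-units (on average over subjects), while
#' `control_magnitude = 0` keeps the no-intervention interval flat, matching a
#' stable-control longitudinal design.
#'
#' @param tract Bundle name.
#' @param segments Integer vector of affected segment indices (1-based).
#' @param loading_pattern Named numeric vector of signed metric weights;
#'   normalized to unit Euclidean norm.
#' @param group_magnitude Mean effect size at the final session, z-units.
#' @param control_magnitude Mean effect at the middle session (default 0,
#'   i.e. a stable control period).
#' @param subject_sd SD of subject-level effect magnitudes, z-units.
#' @return An `effect_template` object.
#' @export
effect_template <- function(tract, segments, loading_pattern,
                            group_magnitude, control_magnitude = 0,
                            subject_sd = 0.4) {
  abort_if(is.null(names(loading_pattern)) || any(!nzchar(names(loading_pattern))),
           "loading_pattern must be a named numeric vector")
  nrm <- sqrt(sum(loading_pattern^2))
  abort_if(nrm == 0, "loading_pattern must be non-zero")
  abort_if(any(segments < 1) || any(segments != round(segments)),
           "segments must be positive integers")
  abort_if(subject_sd < 0, "subject_sd must be >= 0")
  structure(
    list(tract = tract, segments = as.integer(segments),
         loading_pattern = loading_pattern / nrm,
         group_magnitude = group_magnitude,
         control_magnitude = control_magnitude,
         subject_sd = subject_sd),
    class = "effect_template")
}

#' Default training-effect templates
#'
#' Five localized multivariate effects emulating the canonical pattern of
#' balance-training plasticity: a free-water-driven decrease in the right
#' anterior thalamic radiation, g-ratio-driven decreases in the right
#' frontopontine, thalamo-premotor and corticospinal tracts, and an
#' R2*/PD-driven increase in an inferior left corticospinal section.
#'
#' @param magnitude Absolute mean effect size at the final session (z-units).
#' @param subject_sd SD of subject-level magnitudes (z-units).
#' @return List of [effect_template()] objects.
#' @export
default_effects <- function(magnitude = 0.8, subject_sd = 0.4) {
  list(
    effect_template("ATR_R", 65:67,
                    c(FISO = 0.92, FICVF = -0.25, MT = 0.15, R1 = 0.15),
                    group_magnitude = -magnitude, subject_sd = subject_sd),
    effect_template("FPT_R", 50,
                    c(GRATIO = 0.85, MT = -0.35, R1 = -0.30, FICVF = 0.20),
                    group_magnitude = -magnitude, subject_sd = subject_sd),
    effect_template("T_PREM_R", 73:74,
                    c(GRATIO = 0.85, MT = -0.35, R1 = -0.30, FISO = 0.20),
                    group_magnitude = -magnitude, subject_sd = subject_sd),
    effect_template("CST_R", 53,
                    c(GRATIO = 0.80, MT = -0.40, R1 = -0.30, FICVF = 0.25),
                    group_magnitude = -magnitude, subject_sd = subject_sd),
    effect_template("CST_L", 88:89,
                    c(R2s = 0.70, PD = 0.65, R1 = 0.20, MT = 0.15),
                    group_magnitude = magnitude, subject_sd = subject_sd)
  )
}

#' Configure a synthetic longitudinal qMRI cohort
#'
#' Defines the study conditions the generator emulates: a within-subject
#' design with three MRI sessions four weeks apart (a no-intervention control
#' interval followed by a training interval), along-tract metric profiles
#' with between-subject random intercepts and AR(1) spatial noise, localized
#' training effects, a balance-learning behavioral record coupled to the
#' subjects' latent plasticity magnitudes, and a cortical neurite-dispersion
#' change driven by the same latent.
#'
#' @param n_subjects Number of subjects.
#' @param sessions Ordered session labels (baseline first).
#' @param tracts Bundle names.
#' @param n_segments Along-tract segments per bundle.
#' @param metrics Metric names (unique).
#' @param metric_means,metric_scales Named baseline value and native-unit
#'   scale (1 z-unit) per metric.
#' @param sigma_subject Between-subject random-intercept SD (z-units).
#' @param sigma_resid Residual SD (z-units), marginal for the AR(1) process.
#' @param ar_phi Along-tract AR(1) coefficient in `[0, 1)`.
#' @param effects List of [effect_template()] objects.
#' @param behavior_coupling_rho Target Spearman correlation between subject
#'   effect magnitudes and learning exponents, in `[-1, 1]`. With the default
#'   negative-going group effects, a negative value makes stronger learners
#'   show larger (more negative) microstructural change, so the pooled
#'   brain-behavior correlation carries the sign of the group trajectory.
#' @param behavior_a_mean,behavior_a_cv Power-law scale parameter: subject
#'   scales are `a_mean * exp(a_cv * N(0,1))` seconds.
#' @param behavior_b_scale,behavior_b_sigma Learning exponents are
#'   `b_scale * exp(b_sigma * z)` with `z` the coupled normal score, so
#'   exponents are positive and monotone in the copula.
#' @param behavior_noise_sd Trial-level noise SD (seconds).
#' @param cortical_gamma Slope linking the latent subject magnitude to the
#'   cortical ODI change score.
#' @param cortical_noise_sd SD of cortical change noise.
#' @param seed Master RNG seed; child seeds for each generator component are
#'   derived deterministically from it.
#' @return A `cohort_config` object (a validated list).
#' @export
cohort_config <- function(n_subjects = 24,
                          sessions = c("MRI1", "MRI2", "MRI3"),
                          tracts = default_tracts(),
                          n_segments = 98,
                          metrics = default_metrics(),
                          metric_means = default_metric_means(metrics),
                          metric_scales = default_metric_scales(metrics),
                          sigma_subject = 1.0,
                          sigma_resid = 0.4,
                          ar_phi = 0.7,
                          effects = default_effects(),
                          behavior_coupling_rho = -0.5,
                          behavior_a_mean = 10,
                          behavior_a_cv = 0.15,
                          behavior_b_scale = 0.3,
                          behavior_b_sigma = 0.35,
                          behavior_noise_sd = 1.5,
                          cortical_gamma = -1.82,
                          cortical_noise_sd = 1.5,
                          seed = 1L) {
  abort_if(n_subjects < 1, "n_subjects must be >= 1")
  abort_if(n_segments < 2, "n_segments must be >= 2")
  abort_if(length(sessions) < 2, "need at least 2 sessions")
  abort_if(anyDuplicated(metrics) > 0, "metric names must be unique")
  abort_if(anyDuplicated(tracts) > 0, "tract names must be unique")
  abort_if(!(ar_phi >= 0 && ar_phi < 1), "ar_phi must be in [0, 1)")
  abort_if(sigma_subject < 0 || sigma_resid < 0 || behavior_noise_sd < 0 ||
             cortical_noise_sd < 0, "all SDs must be >= 0")
  abort_if(abs(behavior_coupling_rho) > 1, "|behavior_coupling_rho| must be <= 1")
  abort_if(!all(metrics %in% names(metric_means)) ||
             !all(metrics %in% names(metric_scales)),
           "metric_means/metric_scales must name every metric")
  for (e in effects) {
    abort_if(!inherits(e, "effect_template"), "effects must be effect_template objects")
    abort_if(!e$tract %in% tracts,
             sprintf("effect template references unknown tract '%s'", e$tract))
    abort_if(!all(names(e$loading_pattern) %in% metrics),
             sprintf("effect template on '%s' references unknown metric(s): %s",
                     e$tract,
                     paste(setdiff(names(e$loading_pattern), metrics), collapse = ", ")))
    abort_if(any(e$segments > n_segments),
             sprintf("effect template on '%s' references segments > n_segments", e$tract))
  }
  structure(
    list(n_subjects = as.integer(n_subjects), sessions = sessions,
         tracts = tracts, n_segments = as.integer(n_segments),
         metrics = metrics,
         metric_means = metric_means[metrics],
         metric_scales = metric_scales[metrics],
         sigma_subject = sigma_subject, sigma_resid = sigma_resid,
         ar_phi = ar_phi, effects = effects,
         behavior_coupling_rho = behavior_coupling_rho,
         behavior_a_mean = behavior_a_mean, behavior_a_cv = behavior_a_cv,
         behavior_b_scale = behavior_b_scale,
         behavior_b_sigma = behavior_b_sigma,
         behavior_noise_sd = behavior_noise_sd,
         cortical_gamma = cortical_gamma,
         cortical_noise_sd = cortical_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects x %d sessions, %d tracts x %d segments, %d metrics\n",
              x$n_subjects, length(x$sessions), length(x$tracts),
              x$n_segments, length(x$metrics)))
  cat(sprintf("  sigma_subject %.2f, sigma_resid %.2f, ar_phi %.2f, %d effect template(s), seed %d\n",
              x$sigma_subject, x$sigma_resid, x$ar_phi, length(x$effects), x$seed))
  invisible(x)
}
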