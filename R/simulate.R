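# AR(1) series with marginal SD sigma, stationary start; columns are series
ar1_noise <- function(n_seg, n_series, phi, sigma) {
  if (sigma == 0 || n_series == 0) return(matrix(0, n_seg, n_series))
  x <- matrix(0, n_seg, n_series)
  x[1, ] <- rnorm(n_series, 0, sigma)
  if (n_seg > 1) {
    innov_sd <- sigma * sqrt(1 - phi^2)
    for (s in 2:n_seg) x[s, ] <- phi * x[s - 1, ] + rnorm(n_series, 0, innov_sd)
  }
  x
}

#' Generate a synthetic along-tract profile panel
#'
#' Simulates a complete balanced longitudinal panel of metric values at every
#' (subject, session, tract, segment, metric) key. Each value is
#' `mu_metric + scale_metric * (u_i + effect + e)` where `u_i` is a
#' subject-by-metric random intercept, `e` is AR(1)-correlated noise along
#' segments, and the effect term contributes
#' `(group_magnitude + subject_sd * delta_i) * loading` only at the segments
#' and sessions an [effect_template()] configures (`delta_i` is the subject's
#' shared standard-normal latent plasticity magnitude).
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `subject_id`, `session`, `tract`, `segment`,
#'   `metric`, `value`. The per-subject latent magnitudes used to scale the
#'   effects are attached as attribute `"magnitudes"` (see
#'   [subject_magnitudes()]).
#' @export
generate_tract_profiles <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed, 3)
  set.seed(seeds[1])

  n_sub <- config$n_subjects
  subjects <- sprintf("S%02d", seq_len(n_sub))
  sessions <- config$sessions
  metrics <- config$metrics
  n_met <- length(metrics)
  n_seg <- config$n_segments

  # shared latent plasticity magnitude per subject
  delta <- rnorm(n_sub)
  # subject-by-metric random intercepts (z-units), shared across sessions/tracts
  u <- matrix(rnorm(n_sub * n_met, 0, config$sigma_subject), n_sub, n_met,
              dimnames = list(subjects, metrics))

  # effect lookup per tract: list of (segments, session index, per-subject
  # magnitude, loading vector over metrics)
  eff_by_tract <- split(config$effects,
                        vapply(config$effects, function(e) e$tract, ""))

  last <- length(sessions)
  mid <- if (length(sessions) >= 3) seq(2, length(sessions) - 1) else integer(0)

  out <- vector("list", length(config$tracts))
  names(out) <- config$tracts
  for (tr in config$tracts) {
    # z-value array: segment x (subject x session x metric)
    n_series <- n_sub * length(sessions) * n_met
    z <- ar1_noise(n_seg, n_series, config$ar_phi, config$sigma_resid)
    dim(z) <- c(n_seg, n_sub, length(sessions), n_met)
    # add subject intercepts
    for (m in seq_len(n_met)) {
      z[, , , m] <- z[, , , m] + rep(u[, m], each = n_seg)
    }
    # add effects
    for (e in eff_by_tract[[tr]] %||% list()) {
      lam <- setNames(numeric(n_met), metrics)
      lam[names(e$loading_pattern)] <- e$loading_pattern
      m_i <- e$group_magnitude + e$subject_sd * delta
      for (m in which(lam != 0)) {
        z[e$segments, , last, m] <- z[e$segments, , last, m] +
          rep(m_i * lam[m], each = length(e$segments))
        if (e$control_magnitude != 0 && length(mid) > 0) {
          for (s in mid) {
            z[e$segments, , s, m] <- z[e$segments, , s, m] +
              e$control_magnitude * lam[m]
          }
        }
      }
    }
    # native units
    for (m in seq_len(n_met)) {
      z[, , , m] <- config$metric_means[m] + config$metric_scales[m] * z[, , , m]
    }
    out[[tr]] <- tibble::tibble(
      subject_id = rep(subjects, each = n_seg, times = length(sessions) * n_met),
      session = rep(sessions, each = n_seg * n_sub, times = n_met),
      tract = tr,
      segment = rep(seq_len(n_seg), times = n_sub * length(sessions) * n_met),
      metric = rep(metrics, each = n_seg * n_sub * length(sessions)),
      value = as.vector(z))
  }
  panel <- dplyr::bind_rows(out)
  panel <- dplyr::select(panel, "subject_id", "session", "tract",
                         "segment", "metric", "value")

  mag <- if (length(config$effects) > 0) {
    e1 <- config$effects[[1]]
    e1$group_magnitude + e1$subject_sd * delta
  } else delta
  attr(panel, "magnitudes") <- tibble::tibble(
    subject_id = subjects, latent = delta, magnitude = mag)
  panel
}

#' Latent subject magnitudes of a simulated panel
#'
#' @param panel A panel from [generate_tract_profiles()].
#' @return Tibble with `subject_id`, the standard-normal `latent`, and the
#'   effect-scaled `magnitude` (first template's `group_magnitude +
#'   subject_sd * latent`; the latent itself when no effects are configured).
#' @export
subject_magnitudes <- function(panel) {
  m <- attr(panel, "magnitudes")
  abort_if(is.null(m), "panel carries no latent magnitudes (not generated by generate_tract_profiles)")
  m
}

#' Generate synthetic balance-task records
#'
#' Eight training sessions of fifteen 30-s trials per subject. Trial balance
#' times follow `a_i * s^{b_i} + noise`, truncated to `[0, 30]` seconds.
#' Learning exponents `b_i > 0` are constructed through a Gaussian copula so
#' that their Spearman correlation with the supplied subject magnitudes
#' targets `behavior_coupling_rho` (rank correlation is what the downstream
#' brain-behavior stage consumes; for a bivariate-normal copula the required
#' normal-score correlation is `2 sin(pi rho / 6)`).
#'
#' @param config A [cohort_config()].
#' @param magnitudes Numeric vector of per-subject magnitudes, or the tibble
#'   from [subject_magnitudes()].
#' @param n_sessions,n_trials Training schedule (defaults 8 x 15).
#' @return Tibble with `subject_id`, `session`, `trial`, `balance_time_s`;
#'   the realized Spearman correlation is attached as attribute
#'   `"achieved_rho"`.
#' @export
generate_behavior <- function(config, magnitudes, n_sessions = 8, n_trials = 15) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.data.frame(magnitudes)) {
    subjects <- magnitudes$subject_id
    mag <- magnitudes$magnitude %||% magnitudes$latent
  } else {
    mag <- magnitudes
    subjects <- sprintf("S%02d", seq_along(mag))
  }
  n <- length(mag)
  abort_if(n != config$n_subjects, "magnitudes length must equal n_subjects")
  seeds <- derive_seeds(config$seed, 3)
  set.seed(seeds[2])

  rho_s <- config$behavior_coupling_rho
  r <- 2 * sin(pi * rho_s / 6)  # normal-score correlation for target Spearman
  if (sd(mag) == 0 && rho_s != 0) {
    warning("magnitudes have zero variance; coupling rho unreachable, generating independent exponents")
    z_m <- rnorm(n)
  } else {
    z_m <- qnorm((rank(mag, ties.method = "average") - 0.5) / n)
    z_m <- z_m / max(sd(z_m), 1e-12)
  }
  z_b <- r * z_m + sqrt(max(0, 1 - r^2)) * rnorm(n)
  b <- config$behavior_b_scale * exp(config$behavior_b_sigma * z_b)
  a <- config$behavior_a_mean * exp(config$behavior_a_cv * rnorm(n))

  if (config$behavior_b_sigma == 0 && rho_s != 0) {
    warning("behavior_b_sigma = 0: exponents are constant, coupling rho unreachable")
  }
  achieved <- suppressWarnings(cor(b, mag, method = "spearman"))

  grid <- tidyr::expand_grid(subject_id = subjects,
                             session = seq_len(n_sessions),
                             trial = seq_len(n_trials))
  idx <- match(grid$subject_id, subjects)
  mu <- a[idx] * grid$session^b[idx]
  val <- mu + rnorm(nrow(grid), 0, config$behavior_noise_sd)
  grid$balance_time_s <- pmin(30, pmax(0, val))
  attr(grid, "achieved_rho") <- achieved
  attr(grid, "exponents") <- tibble::tibble(subject_id = subjects, a = a, b = b)
  grid
}

#' Generate synthetic cortical neurite-dispersion change scores
#'
#' Models the per-subject post-training change in cortical orientation
#' dispersion as a linear response to the latent white-matter plasticity
#' magnitude: `odi_change = gamma * m_i + N(0, cortical_noise_sd)`.
#'
#' @inheritParams generate_behavior
#' @return Tibble with `subject_id`, `odi_change`.
#' @export
generate_cortical_response <- function(config, magnitudes) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.data.frame(magnitudes)) {
    subjects <- magnitudes$subject_id
    mag <- magnitudes$magnitude %||% magnitudes$latent
  } else {
    mag <- magnitudes
    subjects <- sprintf("S%02d", seq_along(mag))
  }
  seeds <- derive_seeds(config$seed, 3)
  set.seed(seeds[3])
  tibble::tibble(
    subject_id = subjects,
    odi_change = config$cortical_gamma * mag +
      rnorm(length(mag), 0, config$cortical_noise_sd))
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running all three generators under one master seed.
#'
#' @param config A [cohort_config()].
#' @return List with elements `profiles`, `behavior`, `cortical`,
#'   `magnitudes`, and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  profiles <- generate_tract_profiles(config)
  mags <- subject_magnitudes(profiles)
  behavior <- generate_behavior(config, mags)
  cortical <- generate_cortical_response(config, mags)
  structure(list(profiles = profiles, behavior = behavior,
                 cortical = cortical, magnitudes = mags, config = config),
            class = "tractplast_cohort")
}

#' @export
print.tractplast_cohort <- function(x, ...) {
  cat("<tractplast_cohort>\n")
  cat(sprintf("  profiles: %s rows; behavior: %s rows; cortical: %d subjects\n",
              format(nrow(x$profiles), big.mark = ","),
              format(nrow(x$behavior), big.mark = ","), nrow(x$cortical)))
  invisible(x)
}
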