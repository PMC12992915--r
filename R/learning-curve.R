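#' Fit a power-law learning curve to one subject's balance trials
#'
#' Averages balance times within each training session and fits
#' `mean_s = a * s^b` by nonlinear least squares, initialized from the
#' log-log linear fit (making the procedure deterministic given the data).
#' An optional three-parameter form `c + a * s^b` is available.
#'
#' @param data Data frame with `session` and `balance_time_s` columns
#'   (trial-level rows are averaged within session).
#' @param offset Also estimate an additive offset `c`.
#' @return A `learning_curve_fit` with fields `a`, `b` (and `c` if
#'   requested), residual `sigma`, `converged`, and the session means.
#' @export
fit_power_law <- function(data, offset = FALSE) {
  abort_if(!all(c("session", "balance_time_s") %in% names(data)),
           "data needs columns session, balance_time_s")
  means <- data |>
    dplyr::group_by(s = .data$session) |>
    dplyr::summarise(y = mean(.data$balance_time_s), .groups = "drop") |>
    dplyr::arrange(.data$s)
  abort_if(nrow(means) < 3, "need >= 3 sessions")

  # log-log initialization (exact on noise-free power-law data)
  start <- if (all(means$y > 0)) {
    ll <- lm(log(y) ~ log(s), data = means)
    list(a = exp(coef(ll)[[1]]), b = coef(ll)[[2]])
  } else list(a = max(mean(means$y), 1e-6), b = 0)
  if (offset) start$c <- 0

  form <- if (offset) y ~ c + a * s^b else y ~ a * s^b
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = means, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(a = start$a, b = start$b, c = if (offset) start$c,
                sigma = NA_real_, converged = FALSE,
                diagnostics = conditionMessage(fit), means = means)
  } else {
    cf <- coef(fit)
    rs <- resid(fit)
    out <- list(a = cf[["a"]], b = cf[["b"]],
                c = if (offset) cf[["c"]],
                sigma = sqrt(sum(rs^2) / max(1, nrow(means) - length(cf))),
                converged = fit$convInfo$isConv %||% TRUE,
                diagnostics = NULL, means = means)
  }
  structure(out, class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat(sprintf("<learning_curve_fit> a = %.3f, b = %.3f%s, sigma = %.3f, converged: %s\n",
              x$a, x$b,
              if (!is.null(x$c)) sprintf(", c = %.3f", x$c) else "",
              x$sigma, x$converged))
  invisible(x)
}

#' Fit learning curves for every subject
#'
#' @param behavior Trial-level behavior table (`subject_id`, `session`,
#'   `trial`, `balance_time_s`).
#' @param offset Passed to [fit_power_law()].
#' @return Tibble with one row per subject: `a`, `b`, `sigma`, `converged`.
#' @export
fit_learning_curves <- function(behavior, offset = FALSE) {
  behavior |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_power_law(d, offset = offset)
      tibble::tibble(a = f$a, b = f$b, sigma = f$sigma, converged = f$converged)
    }) |>
    dplyr::ungroup()
}

#' Group-level test of the learning exponent
#'
#' One-sample t test of the per-subject power-law exponents against zero
#' (df = n - 1). The one-sided p-value in the hypothesized direction
#' (exponents greater than zero, i.e. performance improves with practice)
#' and the two-sided p-value are both reported.
#'
#' @param fits Tibble from [fit_learning_curves()] (or any data frame with a
#'   `b` column); non-converged fits are dropped.
#' @return One-row tibble: `estimate`, `t`, `df`, `p_greater`, `p_two_sided`.
#' @export
group_exponent_test <- function(fits) {
  b <- fits$b
  if (!is.null(fits$converged)) b <- b[fits$converged]
  abort_if(length(b) < 2, "need >= 2 converged fits")
  if (sd(b) == 0) {
    warning("zero variance of exponents: test undefined")
    return(tibble::tibble(estimate = mean(b), t = NA_real_,
                          df = length(b) - 1,
                          p_greater = NA_real_, p_two_sided = NA_real_))
  }
  tt <- t.test(b, mu = 0)
  tibble::tibble(
    estimate = unname(tt$estimate),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_greater = pt(unname(tt$statistic), df = unname(tt$parameter),
                   lower.tail = FALSE),
    p_two_sided = tt$p.value)
}
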