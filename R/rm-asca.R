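seg_sessions <- function(panel) {
  attr(panel, "session_levels") %||% sort(unique(panel$session))
}

#' Standardize one tract segment's observations across metrics
#'
#' Z-scores each metric over all (subject, session) observations of the
#' segment, making metrics comparable before the multivariate decomposition.
#' The means/SDs are stored for later de-standardization and subject-score
#' prediction. Zero-variance metrics are excluded with a warning.
#'
#' @param panel Tract-profile tibble.
#' @param tract,segment Segment to extract.
#' @return Tibble `subject_id`, `session`, `metric`, `outcome` with
#'   attribute `"scale"` (tibble `metric`, `mean`, `sd`).
#' @export
standardize_panel <- function(panel, tract, segment) {
  seg <- segment
  obs <- dplyr::filter(panel, .data$tract == !!tract, .data$segment == !!seg)
  abort_if(nrow(obs) == 0, "no observations for this tract/segment")
  scale_tbl <- obs |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  dead <- scale_tbl$metric[scale_tbl$sd == 0 | is.na(scale_tbl$sd)]
  if (length(dead) > 0) {
    warning(sprintf("excluding zero-variance metric(s): %s",
                    paste(dead, collapse = ", ")))
    obs <- dplyr::filter(obs, !.data$metric %in% dead)
    scale_tbl <- dplyr::filter(scale_tbl, !.data$metric %in% dead)
  }
  out <- obs |>
    dplyr::left_join(scale_tbl, by = "metric") |>
    dplyr::mutate(outcome = (.data$value - .data$mean) / .data$sd) |>
    dplyr::select("subject_id", "session", "metric", "outcome")
  attr(out, "scale") <- scale_tbl
  attr(out, "session_levels") <- seg_sessions(panel)
  out
}

#' Per-metric linear mixed model for one segment
#'
#' REML fit of `outcome ~ time + (1 | subject)` with the baseline session as
#' reference, the longitudinal model underlying the segment-wise
#' decomposition. Fixed time effects are returned in z-units together with
#' the subject-intercept and residual variance components. Singular fits
#' (subject variance at the zero boundary) are flagged, not errors.
#'
#' @param obs Standardized observations from [standardize_panel()].
#' @param metric Which metric to fit.
#' @return List with `beta` (named, one per non-baseline session),
#'   `varcomp` (`subject`, `residual`), and `singular`.
#' @export
fit_segment_lmm <- function(obs, metric) {
  lev <- attr(obs, "session_levels") %||% sort(unique(obs$session))
  d <- dplyr::filter(obs, .data$metric == !!metric)
  abort_if(nrow(d) == 0, "unknown metric")
  abort_if(length(unique(d$subject_id)) < 2, "need >= 2 subjects")
  d$time <- factor(d$session, levels = lev)
  fit <- suppressMessages(lme4::lmer(
    outcome ~ time + (1 | subject_id), data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  fe <- lme4::fixef(fit)
  beta <- fe[-1]
  names(beta) <- lev[-1]
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(beta = beta,
       varcomp = c(subject = vc$vcov[vc$grp == "subject_id"],
                   residual = vc$vcov[vc$grp == "Residual"]),
       singular = lme4::isSingular(fit))
}

# balanced complete panel? every subject x session exactly once per metric
.is_balanced <- function(obs, lev) {
  tab <- table(obs$subject_id, obs$session, obs$metric)
  all(tab == 1) && all(lev %in% colnames(tab))
}

#' Build the fixed time-effect matrix
#'
#' One row per (subject, session) observation, one column per metric; each
#' entry is the fitted fixed effect of that observation's session for that
#' metric (zero for the baseline under reference coding).
#'
#' @param beta Matrix of fixed effects, rows = non-baseline sessions,
#'   columns = metrics.
#' @param keys Tibble of observation keys (`subject_id`, `session`).
#' @param sessions Ordered session labels (baseline first).
#' @return Numeric matrix, `nrow(keys)` x `ncol(beta)`.
#' @export
build_time_effect_matrix <- function(beta, keys, sessions) {
  full <- rbind(0, beta)
  rownames(full) <- sessions
  m <- full[match(keys$session, sessions), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' PCA of a time-effect matrix
#'
#' Singular value decomposition without additional centering: under
#' reference coding the baseline rows are zero, so the origin anchors the
#' baseline and component scores read as change trajectories. The sign of
#' each component is fixed so its largest-magnitude loading is positive.
#'
#' @param effect_matrix Matrix from [build_time_effect_matrix()] (or any
#'   observations x metrics effect matrix).
#' @param keys Optional observation keys; when given, per-session scores are
#'   the unique session-row projections.
#' @param sessions Ordered session labels.
#' @return List with `loadings` (metrics x components, unit columns),
#'   `explained_variance`, `scores` (sessions x components when `keys`
#'   given, else row scores), and `degenerate` (all-zero input flag).
#' @export
decompose_effects <- function(effect_matrix, keys = NULL, sessions = NULL) {
  p <- ncol(effect_matrix)
  if (all(effect_matrix == 0)) {
    k <- min(dim(effect_matrix))
    return(list(loadings = matrix(0, p, k,
                                  dimnames = list(colnames(effect_matrix), NULL)),
                explained_variance = rep(0, k),
                scores = NULL, degenerate = TRUE))
  }
  sv <- svd(effect_matrix)
  keep <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[keep]
  v <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|loading| metric positive per component
  for (k in seq_len(ncol(v))) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) v[, k] <- -v[, k]
  }
  rownames(v) <- colnames(effect_matrix)
  explvar <- d^2 / sum(sv$d^2)
  scores <- if (!is.null(keys) && !is.null(sessions)) {
    uniq <- effect_matrix[match(sessions, keys$session), , drop = FALSE]
    sc <- uniq %*% v
    rownames(sc) <- sessions
    sc
  } else effect_matrix %*% v
  list(loadings = v, explained_variance = explvar, scores = scores,
       degenerate = FALSE)
}

# 3-d array (subjects x sessions x metrics) of raw values; NULL if unbalanced
.panel_array <- function(panel, tract, segment) {
  seg <- segment
  obs <- dplyr::filter(panel, .data$tract == !!tract, .data$segment == !!seg)
  if (nrow(obs) == 0) return(NULL)
  lev <- seg_sessions(panel)
  subs <- sort(unique(obs$subject_id))
  mets <- unique(obs$metric)
  if (nrow(obs) != length(subs) * length(lev) * length(mets)) return(NULL)
  arr <- array(NA_real_, c(length(subs), length(lev), length(mets)),
               dimnames = list(subs, lev, mets))
  arr[cbind(match(obs$subject_id, subs), match(obs$session, lev),
            match(obs$metric, mets))] <- obs$value
  if (anyNA(arr)) return(NULL)
  arr
}

# standardize + session-mean fixed effects + SVD, on a balanced array.
# On balanced complete data the GLS (mixed-model) fixed-effect estimates
# equal session-mean differences, so this is exact, not an approximation.
.asca_fast <- function(arr) {
  n <- dim(arr)[1]; S <- dim(arr)[2]; p <- dim(arr)[3]
  mu <- apply(arr, 3, mean)
  sdv <- apply(arr, 3, sd)
  sdv[sdv < 1e-300] <- NA
  z <- sweep(sweep(arr, 3, mu, "-"), 3, sdv, "/")
  z[is.na(z)] <- 0  # zero-variance metric carries no signal
  sess_means <- apply(z, c(2, 3), mean)              # S x p
  beta <- sweep(sess_means, 2, sess_means[1, ], "-") # baseline-referenced
  dec <- decompose_effects(beta, keys = NULL, sessions = NULL)
  scores <- if (dec$degenerate) {
    matrix(0, S, ncol(dec$loadings),
           dimnames = list(dimnames(arr)[[2]], NULL))
  } else {
    sc <- beta %*% dec$loadings
    rownames(sc) <- dimnames(arr)[[2]]
    sc
  }
  list(beta = beta[-1, , drop = FALSE], scores = scores,
       loadings = dec$loadings, explained_variance = dec$explained_variance,
       scale = tibble::tibble(metric = dimnames(arr)[[3]], mean = mu,
                              sd = apply(arr, 3, sd)),
       degenerate = dec$degenerate)
}

#' Fit the segment-wise multivariate longitudinal model
#'
#' The segment-level repeated-measures ASCA fit: each metric is z-scored
#' over the segment's observations and modeled by a linear mixed model with
#' session as fixed effect and a subject random intercept; the fixed
#' time-effect matrix is then decomposed by PCA into session scores and
#' metric loadings. On balanced complete data the fixed effects equal
#' session-mean differences exactly and a fast closed-form path is used;
#' otherwise each metric is fitted with `lme4`.
#'
#' @param panel Tract-profile tibble.
#' @param tract,segment Segment to model.
#' @param method `"auto"` (fast path when balanced), or `"lmm"` to force the
#'   mixed-model fit.
#' @return A `segment_asca` object: `beta` (non-baseline sessions x
#'   metrics), `scores` (sessions x components), `loadings` (metrics x
#'   components, unit norm), `explained_variance`, `scale`, bookkeeping.
#' @export
fit_segment_asca <- function(panel, tract, segment, method = c("auto", "lmm")) {
  method <- match.arg(method)
  lev <- seg_sessions(panel)
  arr <- if (method == "auto") .panel_array(panel, tract, segment) else NULL
  if (!is.null(arr)) {
    core <- .asca_fast(arr)
    res <- list(tract = tract, segment = segment, sessions = lev,
                metrics = core$scale$metric, beta = core$beta,
                scores = core$scores, loadings = core$loadings,
                explained_variance = core$explained_variance,
                scale = core$scale, n_subjects = dim(arr)[1],
                method = "balanced-exact", degenerate = core$degenerate)
    return(structure(res, class = "segment_asca"))
  }
  obs <- standardize_panel(panel, tract, segment)
  mets <- unique(obs$metric)
  beta <- vapply(mets, function(m) fit_segment_lmm(obs, m)$beta,
                 numeric(length(lev) - 1))
  beta <- matrix(beta, nrow = length(lev) - 1,
                 dimnames = list(lev[-1], mets))
  keys <- dplyr::distinct(obs, .data$subject_id, .data$session)
  em <- build_time_effect_matrix(beta, keys, lev)
  colnames(em) <- mets
  dec <- decompose_effects(em, keys = keys, sessions = lev)
  structure(list(tract = tract, segment = segment, sessions = lev,
                 metrics = mets, beta = beta,
                 scores = dec$scores, loadings = dec$loadings,
                 explained_variance = dec$explained_variance,
                 scale = attr(obs, "scale"),
                 n_subjects = length(unique(obs$subject_id)),
                 method = "lmm", degenerate = dec$degenerate),
            class = "segment_asca")
}

#' @export
print.segment_asca <- function(x, ...) {
  cat(sprintf("<segment_asca> %s segment %s (%d subjects, %d metrics)\n",
              x$tract, paste(x$segment, collapse = "-"), x$n_subjects,
              length(x$metrics)))
  if (!x$degenerate) {
    cat(sprintf("  PC1 explains %.1f%%; scores: %s\n",
                100 * x$explained_variance[1],
                paste(sprintf("%s %.2f", x$sessions, x$scores[, 1]),
                      collapse = ", ")))
  }
  invisible(x)
}

# ---- BCa machinery -------------------------------------------------------

# BCa interval for one statistic from bootstrap draws + jackknife values
bca_ci <- function(theta_hat, theta_boot, theta_jack, level = 0.95) {
  theta_boot <- theta_boot[is.finite(theta_boot)]
  B <- length(theta_boot)
  if (B == 0 || diff(range(theta_boot)) == 0) {
    v <- if (B > 0) theta_boot[1] else theta_hat
    return(c(v, v))
  }
  prop <- (sum(theta_boot < theta_hat) + 0.5 * sum(theta_boot == theta_hat)) / B
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- qnorm(prop)
  jm <- mean(theta_jack)
  num <- sum((jm - theta_jack)^3)
  den <- 6 * sum((jm - theta_jack)^2)^1.5
  a <- if (den == 0) 0 else num / den
  alpha <- (1 - level) / 2
  za <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + za) / (1 - a * (z0 + za)))
  unname(quantile(theta_boot, probs = adj, names = FALSE, type = 7))
}

# PC1 statistics (session scores then loadings), sign-aligned to reference
.asca_stat <- function(core, ref_loadings) {
  l1 <- core$loadings[, 1]
  s1 <- core$scores[, 1]
  if (sum(l1 * ref_loadings) < 0) {
    l1 <- -l1; s1 <- -s1
  }
  c(s1, l1)
}

#' Cluster-bootstrap BCa intervals for segment scores and loadings
#'
#' Resamples subjects with replacement, reruns the full
#' standardize-model-decompose pipeline on every replicate (so the intervals
#' reflect all estimated quantities), sign-aligns each replicate's first
#' component to the point estimate by loading dot product, and forms 95%
#' bias-corrected and accelerated intervals, with acceleration from a
#' leave-one-subject-out jackknife.
#'
#' @param panel Tract-profile tibble.
#' @param tract,segment Segment to model.
#' @param B Bootstrap replicates (1000 for reporting; smaller for
#'   simulation studies).
#' @param seed RNG seed for reproducible resampling.
#' @param level Interval level.
#' @return A `segment_asca_boot`: the point `model` plus a `ci` tibble with
#'   one row per PC1 session score and metric loading (`kind`, `label`,
#'   `estimate`, `conf_low`, `conf_high`), and the failure count.
#' @export
bootstrap_asca <- function(panel, tract, segment, B = 1000, seed = NULL,
                           level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  model <- fit_segment_asca(panel, tract, segment)
  abort_if(model$n_subjects < 5, "need >= 5 subjects for the cluster bootstrap")
  arr <- .panel_array(panel, tract, segment)
  ref <- model$loadings[, 1]
  S <- length(model$sessions)
  p <- length(model$metrics)
  n <- model$n_subjects

  one_rep <- if (!is.null(arr)) {
    function(idx) .asca_stat(.asca_fast(arr[idx, , , drop = FALSE]), ref)
  } else {
    seg <- segment
    obs_all <- dplyr::filter(panel, .data$tract == !!tract, .data$segment == !!seg)
    subs <- sort(unique(obs_all$subject_id))
    by_sub <- split(obs_all, obs_all$subject_id)
    lev <- seg_sessions(panel)
    function(idx) {
      rep_panel <- dplyr::bind_rows(lapply(seq_along(idx), function(j) {
        d <- by_sub[[subs[idx[j]]]]
        d$subject_id <- sprintf("b%03d", j)
        d
      }))
      attr(rep_panel, "session_levels") <- lev
      m <- fit_segment_asca(rep_panel, tract, segment, method = "lmm")
      .asca_stat(m, ref)
    }
  }

  boot_mat <- matrix(NA_real_, B, S + p)
  n_fail <- 0
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    st <- tryCatch(one_rep(idx), error = function(e) NULL)
    if (is.null(st)) n_fail <- n_fail + 1 else boot_mat[b, ] <- st
  }
  abort_if(n_fail > 0.1 * B,
           sprintf("bootstrap failure rate %.1f%% exceeds 10%%", 100 * n_fail / B))
  boot_mat <- boot_mat[stats::complete.cases(boot_mat), , drop = FALSE]

  jack_mat <- t(vapply(seq_len(n), function(i) {
    tryCatch(one_rep(setdiff(seq_len(n), i)),
             error = function(e) rep(NA_real_, S + p))
  }, numeric(S + p)))
  jack_mat <- jack_mat[stats::complete.cases(jack_mat), , drop = FALSE]

  est <- .asca_stat(model, ref)
  ci <- t(vapply(seq_len(S + p), function(j) {
    bca_ci(est[j], boot_mat[, j], jack_mat[, j], level = level)
  }, numeric(2)))
  out <- tibble::tibble(
    kind = rep(c("score", "loading"), c(S, p)),
    label = c(model$sessions, model$metrics),
    estimate = est, conf_low = ci[, 1], conf_high = ci[, 2])
  structure(list(model = model, ci = out, B = B, n_fail = n_fail,
                 level = level, seed = seed),
            class = "segment_asca_boot")
}

#' @export
print.segment_asca_boot <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d bootstrap replicates (%d failed), %.0f%% BCa intervals:\n",
              x$B, x$n_fail, 100 * x$level))
  print(x$ci, n = nrow(x$ci))
  invisible(x)
}

.overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

#' Classify a segment from its score confidence intervals
#'
#' Applies the triple interval-overlap rule for a plastic segment:
#' the baseline and control-session intervals overlap (stable control
#' period), while the final session's interval overlaps neither
#' (`change_13` and `change_23`). `plastic` requires all three.
#'
#' @param x A `segment_asca_boot`, or a data frame with columns `conf_low`,
#'   `conf_high` and one row per session in order (baseline, control,
#'   post-training).
#' @param ... Unused.
#' @return One-row tibble of logical flags `stable_control`, `change_13`,
#'   `change_23`, `plastic`.
#' @export
classify_segment <- function(x, ...) UseMethod("classify_segment")

#' @export
classify_segment.segment_asca_boot <- function(x, ...) {
  sc <- dplyr::filter(x$ci, .data$kind == "score")
  classify_segment(sc[c("conf_low", "conf_high")])
}

#' @export
classify_segment.data.frame <- function(x, ...) {
  abort_if(nrow(x) < 3, "need intervals for three sessions")
  ci <- lapply(1:3, function(i) c(x$conf_low[i], x$conf_high[i]))
  stable <- .overlaps(ci[[1]], ci[[2]])
  c13 <- !.overlaps(ci[[3]], ci[[1]])
  c23 <- !.overlaps(ci[[3]], ci[[2]])
  tibble::tibble(stable_control = stable, change_13 = c13, change_23 = c23,
                 plastic = stable && c13 && c23)
}

#' Predict per-subject component scores
#'
#' Projects each subject's standardized metric vector at each session onto
#' the model's first-component loadings, yielding individual latent change
#' trajectories (standardization uses the means/SDs stored in the model).
#'
#' @param model A `segment_asca` (or the `model` of a `segment_asca_boot`).
#' @param panel Tract-profile tibble containing the model's segment.
#' @return Tibble `subject_id`, `session`, `score` (`NA` with a message
#'   where a subject-session lacks metrics).
#' @export
predict_subject_scores <- function(model, panel) {
  if (inherits(model, "segment_asca_boot")) model <- model$model
  seg <- model$segment
  obs <- dplyr::filter(panel, .data$tract == model$tract, .data$segment %in% seg)
  if (length(seg) > 1) {  # merged section: average raw values across segments
    obs <- obs |>
      dplyr::group_by(.data$subject_id, .data$session, .data$metric) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  z <- obs |>
    dplyr::inner_join(model$scale, by = "metric") |>
    dplyr::mutate(zv = (.data$value - .data$mean) / .data$sd)
  l1 <- model$loadings[, 1]
  out <- z |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::summarise(
      score = if (dplyr::n() == length(l1))
        sum(.data$zv * l1[match(.data$metric, model$metrics)])
      else NA_real_,
      .groups = "drop")
  if (anyNA(out$score)) {
    message(sprintf("%d subject-session(s) with missing metrics: score set to NA",
                    sum(is.na(out$score))))
  }
  out
}

#' Screen every tract segment
#'
#' Runs [bootstrap_asca()] and [classify_segment()] over all (tract,
#' segment) units of a panel (optionally restricted), collecting PC1
#' summaries and plasticity flags.
#'
#' @param panel Tract-profile tibble (typically after [trim_and_filter()]).
#' @param tracts,segments Optional restriction.
#' @param B Bootstrap replicates per segment.
#' @param seed Master seed; per-segment seeds are derived from it.
#' @param level Interval level.
#' @return Tibble with one row per unit: flags, `explvar1`, list-columns
#'   `loadings` (named PC1 vector) and `boot` (the fitted object).
#' @export
screen_segments <- function(panel, tracts = NULL, segments = NULL,
                            B = 500, seed = 1, level = 0.95) {
  units <- dplyr::distinct(panel, .data$tract, .data$segment) |>
    dplyr::arrange(.data$tract, .data$segment)
  if (!is.null(tracts)) units <- dplyr::filter(units, .data$tract %in% tracts)
  if (!is.null(segments)) units <- dplyr::filter(units, .data$segment %in% segments)
  seeds <- derive_seeds(seed, nrow(units))
  res <- purrr::pmap(list(units$tract, units$segment, seeds),
                     function(tr, sg, sd_i) {
                       bt <- bootstrap_asca(panel, tr, sg, B = B, seed = sd_i,
                                            level = level)
                       fl <- classify_segment(bt)
                       dplyr::bind_cols(
                         tibble::tibble(tract = tr, segment = sg),
                         fl,
                         tibble::tibble(
                           explvar1 = bt$model$explained_variance[1],
                           loadings = list(bt$model$loadings[, 1]),
                           boot = list(bt)))
                     })
  dplyr::bind_rows(res)
}
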