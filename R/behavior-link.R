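cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

#' Merge adjacent plastic segments with similar factor structure
#'
#' For interpretability, neighboring plastic segments whose first-component
#' loading vectors are similar (absolute cosine at or above `cosine_min`)
#' are merged into one tract section; the raw metric values of merged
#' segments are averaged per (subject, session, metric) and the segment
#' model is refitted (with bootstrap) on the averaged data.
#'
#' @param screen Output of [screen_segments()].
#' @param panel The tract-profile tibble the screen was run on.
#' @param cosine_min Minimum pairwise loading cosine for merging.
#' @param B,seed Bootstrap settings for the refits.
#' @return Tibble with one row per merged section: `tract`, `segments`
#'   (list), `label` (e.g. `"65-67"`), and list-column `boot` with the
#'   refitted `segment_asca_boot`.
#' @export
merge_adjacent_segments <- function(screen, panel, cosine_min = 0.9,
                                    B = 500, seed = 1) {
  plastic <- dplyr::filter(screen, .data$plastic) |>
    dplyr::arrange(.data$tract, .data$segment)
  if (nrow(plastic) == 0) {
    return(tibble::tibble(tract = character(), segments = list(),
                          label = character(), boot = list()))
  }
  groups <- list()
  for (tr in unique(plastic$tract)) {
    d <- dplyr::filter(plastic, .data$tract == tr)
    cur <- list(segs = d$segment[1], load = d$loadings[[1]])
    flush_ <- function(cur) {
      groups[[length(groups) + 1]] <<- list(tract = tr, segments = cur$segs)
    }
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        adjacent <- d$segment[i] == cur$segs[length(cur$segs)] + 1
        similar <- abs(cosine_sim(d$loadings[[i]], cur$load)) >= cosine_min
        if (adjacent && similar) {
          cur$segs <- c(cur$segs, d$segment[i])
        } else {
          flush_(cur)
          cur <- list(segs = d$segment[i], load = d$loadings[[i]])
        }
      }
    }
    flush_(cur)
  }
  seeds <- derive_seeds(seed, length(groups))
  rows <- purrr::imap(groups, function(g, i) {
    segs <- g$segments
    label <- if (length(segs) > 1)
      sprintf("%d-%d", min(segs), max(segs)) else as.character(segs)
    sub <- dplyr::filter(panel, .data$tract == g$tract,
                         .data$segment %in% segs)
    merged <- sub |>
      dplyr::group_by(.data$subject_id, .data$session, .data$metric) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(tract = g$tract, segment = min(segs))
    attr(merged, "session_levels") <- seg_sessions(panel)
    bt <- bootstrap_asca(merged, g$tract, min(segs), B = B, seed = seeds[i])
    bt$model$segment <- segs
    tibble::tibble(tract = g$tract, segments = list(segs), label = label,
                   boot = list(bt))
  })
  dplyr::bind_rows(rows)
}

#' Interval change scores from per-subject session scores
#'
#' The two intervals relevant to training effects: `d13` = post-training
#' minus baseline, `d23` = post-training minus pre-training.
#'
#' @param scores Tibble from [predict_subject_scores()] (columns
#'   `subject_id`, `session`, `score`).
#' @param sessions Ordered session labels; defaults to sorted unique.
#' @return Tibble `subject_id`, `d13`, `d23` (`NA` where a session score is
#'   missing).
#' @export
interval_change_scores <- function(scores, sessions = NULL) {
  lev <- sessions %||% sort(unique(scores$session))
  abort_if(length(lev) < 3, "need three sessions")
  wide <- tidyr::pivot_wider(scores, names_from = "session",
                             values_from = "score")
  out <- tibble::tibble(
    subject_id = wide$subject_id,
    d13 = wide[[lev[3]]] - wide[[lev[1]]],
    d23 = wide[[lev[3]]] - wide[[lev[2]]])
  n_miss <- sum(!complete.cases(out))
  if (n_miss > 0) message(sprintf("%d subject(s) with a missing interval score", n_miss))
  out
}

#' Spearman rank correlation
#'
#' Average ranks for ties; requires n >= 4; zero-variance input gives `NA`
#' with a warning.
#'
#' @param x,y Numeric vectors.
#' @return Spearman's rho.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  abort_if(sum(ok) < 4, "need n >= 4 complete pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x[ok], y[ok], method = "spearman")
}

#' Olkin-Pratt pooled correlation point estimate
#'
#' Applies the first-order Olkin-Pratt unbiased correction to each
#' correlation, `G_i = r_i (1 + (1 - r_i^2) / (2 (n_i - 3)))`, then pools
#' with fixed-effect weights `w_i = n_i`.
#'
#' @param r_list Correlations (each `|r| < 1`; exact +/-1 passes through
#'   with a warning).
#' @param n_list Sample sizes (each > 4).
#' @return Pooled estimate `G`.
#' @export
pool_point_estimate <- function(r_list, n_list) {
  abort_if(length(r_list) != length(n_list), "r_list and n_list lengths differ")
  abort_if(any(n_list <= 4), "each n must be > 4")
  g <- r_list
  ok <- abs(r_list) < 1
  if (any(!ok)) warning("|r| = 1: correction degenerate, passing through")
  g[ok] <- r_list[ok] * (1 + (1 - r_list[ok]^2) / (2 * (n_list[ok] - 3)))
  sum(n_list * g) / sum(n_list)
}

#' Confidence interval and p-values for a pooled correlation
#'
#' Fixed-effect normal-approximation inference for an Olkin-Pratt pooled
#' correlation: per-study variance `v_i = (1 - G^2)^2 / (n_i - 1)`, pooled
#' variance `V = sum(w_i^2 v_i) / (sum w_i)^2` with `w_i = n_i`, interval
#' `G +/- z_{level} sqrt(V)`, and normal p-values (one-sided in the
#' hypothesized direction, plus two-sided).
#'
#' @param g_pooled Pooled estimate (|G| < 1).
#' @param n_list Per-correlation sample sizes.
#' @param direction Hypothesized sign of the effect, `"negative"` or
#'   `"positive"`; set before computing p from the group-level trajectory.
#' @param level Interval level.
#' @return One-row tibble: `g_pooled`, `se`, `ci_low`, `ci_high`,
#'   `p_one_sided`, `p_two_sided`.
#' @export
pooled_ci_p <- function(g_pooled, n_list, direction = c("negative", "positive"),
                        level = 0.95) {
  direction <- match.arg(direction)
  abort_if(abs(g_pooled) >= 1, "|G| must be < 1")
  abort_if(any(n_list <= 1), "each n must be > 1")
  v <- (1 - g_pooled^2)^2 / (n_list - 1)
  w <- n_list
  V <- sum(w^2 * v) / sum(w)^2
  se <- sqrt(V)
  z <- qnorm(1 - (1 - level) / 2)
  zstat <- g_pooled / se
  p_one <- if (direction == "negative") pnorm(zstat) else pnorm(-zstat)
  tibble::tibble(g_pooled = g_pooled, se = se,
                 ci_low = g_pooled - z * se, ci_high = g_pooled + z * se,
                 p_one_sided = p_one,
                 p_two_sided = 2 * pnorm(-abs(zstat)))
}

#' Pool interval brain-behavior correlations for one tract section
#'
#' Computes Spearman correlations between each interval's latent change
#' score and the learning exponent, pools them by the Olkin-Pratt
#' fixed-effect rule, and attaches the CI and p-values.
#'
#' @param scores Per-subject session scores ([predict_subject_scores()]).
#' @param fits Learning-curve fits ([fit_learning_curves()]), matched by
#'   `subject_id`.
#' @param direction `"auto"` (sign of the group score change from baseline
#'   to post-training), `"negative"`, or `"positive"`.
#' @param sessions Ordered session labels.
#' @return One-row tibble: `r_13`, `r_23`, `n_13`, `n_23`, `direction`, and
#'   the [pooled_ci_p()] columns.
#' @export
link_behavior <- function(scores, fits, direction = "auto", sessions = NULL) {
  lev <- sessions %||% sort(unique(scores$session))
  deltas <- interval_change_scores(scores, sessions = lev)
  d <- dplyr::inner_join(deltas, fits[c("subject_id", "b")], by = "subject_id")
  r13 <- spearman_cor(d$d13, d$b)
  r23 <- spearman_cor(d$d23, d$b)
  n13 <- sum(is.finite(d$d13) & is.finite(d$b))
  n23 <- sum(is.finite(d$d23) & is.finite(d$b))
  if (identical(direction, "auto")) {
    grp <- scores |>
      dplyr::group_by(.data$session) |>
      dplyr::summarise(m = mean(.data$score, na.rm = TRUE), .groups = "drop")
    chg <- grp$m[grp$session == lev[3]] - grp$m[grp$session == lev[1]]
    direction <- if (chg < 0) "negative" else "positive"
  }
  g <- pool_point_estimate(c(r13, r23), c(n13, n23))
  dplyr::bind_cols(
    tibble::tibble(r_13 = r13, r_23 = r23, n_13 = n13, n_23 = n23,
                   direction = direction),
    pooled_ci_p(g, c(n13, n23), direction = direction))
}
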