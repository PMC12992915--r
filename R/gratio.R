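#' Aggregate g-ratio from MT and NODDI volume fractions
#'
#' Computes the voxel/segment-wise aggregate g-ratio from magnetization
#' transfer saturation (a myelin proxy) and NODDI intracellular and isotropic
#' volume fractions. With myelin volume fraction `MVF = alpha * MT` and axonal
#' volume fraction `AVF = (1 - MVF) * (1 - FISO) * FICVF`, the default form is
#' the standard `g = sqrt(1 - MVF/FVF) = sqrt(AVF / (MVF + AVF))` with total
#' fiber volume `FVF = MVF + AVF`. Setting `literal = TRUE` instead evaluates
#' `sqrt(1 - MVF/AVF)`, a variant that omits MVF from the denominator's fiber
#' volume; it is provided for comparability and is not the default because it
#' is inconsistent with the `g = sqrt(1 - MVF/FVF)` identity.
#'
#' Invalid inputs (`alpha * MT >= 1`, zero fiber volume, or a negative
#' radicand under `literal = TRUE`) yield `NA` rather than being clamped.
#'
#' @param mt Magnetization transfer saturation (percent units).
#' @param ficvf Intracellular volume fraction in `[0, 1]`.
#' @param fiso Isotropic (free-water) volume fraction in `[0, 1]`.
#' @param alpha Calibration factor mapping MT to myelin volume fraction
#'   (non-negative scalar).
#' @param literal Use the alternative `sqrt(1 - MVF/AVF)` form.
#' @return Numeric vector of g-ratio values in `[0, 1]` (element-wise over
#'   recycled inputs), `NA` where undefined.
#' @export
compute_g <- function(mt, ficvf, fiso, alpha, literal = FALSE) {
  abort_if(length(alpha) != 1 || !is.finite(alpha), "alpha must be a finite scalar")
  abort_if(alpha < 0, "domain error: alpha must be >= 0")
  n <- max(length(mt), length(ficvf), length(fiso))
  mt <- rep_len(mt, n); ficvf <- rep_len(ficvf, n); fiso <- rep_len(fiso, n)
  mvf <- alpha * mt
  avf <- (1 - mvf) * (1 - fiso) * ficvf
  fvf <- mvf + avf
  bad <- !is.finite(mvf) | !is.finite(avf) | mvf >= 1 | mvf < 0 | fvf <= 0
  g <- rep(NA_real_, n)
  ok <- !bad
  if (literal) {
    rad <- 1 - mvf[ok] / avf[ok]
    g[ok] <- ifelse(rad >= 0 & is.finite(rad), sqrt(rad), NA_real_)
  } else {
    g[ok] <- sqrt(avf[ok] / fvf[ok])
  }
  g
}

#' Calibrate the MT-to-myelin scaling factor against a reference g-ratio
#'
#' Closed-form inversion anchoring the aggregate g-ratio in a reference
#' region (the splenium of the corpus callosum) to a histology-based value
#' `g_star` (default 0.70). With `A0 = (1 - FISO) * FICVF`, the required
#' myelin volume fraction is `m = A0 (1 - g*^2) / (A0 (1 - g*^2) + g*^2)` and
#' `alpha = m / MT`. Vectorized over subjects; the cohort-level factor is the
#' median of per-subject values (see [cohort_alpha()]).
#'
#' @param roi_mt,roi_ficvf,roi_fiso Reference-ROI mean MT, FICVF, FISO per
#'   subject.
#' @param g_star Reference g-ratio in `(0, 1]`.
#' @return Per-subject `alpha` values; [compute_g()] with these returns
#'   `g_star` exactly.
#' @export
calibrate_alpha <- function(roi_mt, roi_ficvf, roi_fiso, g_star = 0.70) {
  abort_if(!(g_star > 0 && g_star <= 1), "g_star must be in (0, 1]")
  abort_if(any(!is.finite(roi_mt) | !is.finite(roi_ficvf) | !is.finite(roi_fiso)),
           "ROI means must be finite")
  a0 <- (1 - roi_fiso) * roi_ficvf
  abort_if(any(a0 <= 0),
           "calibration error: (1 - FISO) * FICVF must be > 0 (no solution)")
  g2 <- g_star^2
  m <- a0 * (1 - g2) / (a0 * (1 - g2) + g2)
  m / roi_mt
}

#' Cohort calibration factor
#'
#' The median of per-subject calibration factors, used to compute all
#' subjects' g-ratio maps with a single `alpha`.
#'
#' @param alphas Per-subject calibration factors.
#' @return Median alpha.
#' @export
cohort_alpha <- function(alphas) median(alphas, na.rm = TRUE)

#' Sensitivity of g-ratio maps to the reference value
#'
#' Recalibrates `alpha` for each reference g-ratio on a grid, recomputes the
#' g map over the supplied voxels/segments, and reports Pearson correlations
#' between the resulting maps across all valid voxels. Smooth monotone
#' reparameterization by `g_star` implies near-perfect correlations within a
#' physiologically plausible grid.
#'
#' @param voxels Data frame with columns `mt`, `ficvf`, `fiso` (one row per
#'   voxel or segment).
#' @param roi Named list/vector of reference-ROI means (`mt`, `ficvf`,
#'   `fiso`); defaults to the column means of `voxels`.
#' @param g_star_grid Reference values to scan (default 0.68-0.72).
#' @return Correlation matrix between the g maps at each grid value
#'   (dimnames = grid). Degenerate (constant) maps give `NA` with a warning.
#' @export
sensitivity_scan <- function(voxels, roi = NULL,
                             g_star_grid = seq(0.68, 0.72, by = 0.01)) {
  need <- c("mt", "ficvf", "fiso")
  abort_if(!all(need %in% names(voxels)),
           "voxels must have columns mt, ficvf, fiso")
  abort_if(length(g_star_grid) < 1, "need at least one grid point")
  roi <- roi %||% lapply(voxels[need], mean, na.rm = TRUE)
  maps <- vapply(g_star_grid, function(gs) {
    a <- calibrate_alpha(roi$mt, roi$ficvf, roi$fiso, g_star = gs)
    compute_g(voxels$mt, voxels$ficvf, voxels$fiso, alpha = a)
  }, numeric(nrow(voxels)))
  maps <- matrix(maps, nrow = nrow(voxels),
                 dimnames = list(NULL, format(g_star_grid)))
  ok <- complete.cases(maps)
  abort_if(sum(ok) < 3, "need at least 3 valid voxels")
  if (length(g_star_grid) == 1) {
    return(matrix(1, 1, 1, dimnames = list(colnames(maps), colnames(maps))))
  }
  sds <- apply(maps[ok, , drop = FALSE], 2, sd)
  if (any(sds == 0)) warning("constant g map(s): correlations undefined, reported as NA")
  suppressWarnings(cor(maps[ok, , drop = FALSE]))
}
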