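#' Monte Carlo familywise null for correlated significance criteria
#'
#' Estimates the chance of the observed number of tract segments passing all
#' significance criteria when no true effect exists. Per iteration, each
#' segment receives `k` equicorrelated standard-normal z-scores (one-factor
#' construction `z_j = sqrt(rho) W + sqrt(1 - rho) e_j`, giving unit
#' marginals and pairwise correlation `rho`); the least extreme (smallest
#' absolute) z is retained, reflecting that all criteria must hold
#' simultaneously, and the segment counts as a false positive when the
#' retained value exceeds `z_thresh` in magnitude. The Monte Carlo p-value
#' is the proportion of iterations with at least `observed` false positives
#' (no continuity correction).
#'
#' @param n_iter Iterations (default 10,000).
#' @param n_segments Segment-level tests per iteration (default 2,320 =
#'   29 tracts x 80 segments).
#' @param k Criteria per segment (default 4).
#' @param rho Pairwise correlation of the criterion z-scores, `[0, 1)`.
#' @param z_thresh Two-sided significance threshold (default 1.96).
#' @param observed Empirically observed count of passing segments.
#' @param seed RNG seed.
#' @param chunk Iterations simulated per vectorized block.
#' @return An `mc_null` object: per-iteration `counts`, `p`, the count
#'   histogram, and the configuration.
#' @export
mc_null <- function(n_iter = 10000, n_segments = 2320, k = 4, rho = 0.5,
                    z_thresh = 1.96, observed = 9, seed = NULL, chunk = 250) {
  abort_if(!(rho >= 0 && rho < 1), "rho must be in [0, 1)")
  abort_if(k < 1, "k must be >= 1")
  abort_if(z_thresh <= 0, "z_thresh must be > 0")
  abort_if(observed < 0, "observed must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sr <- sqrt(rho); se <- sqrt(1 - rho)
  counts <- integer(n_iter)
  done <- 0L
  while (done < n_iter) {
    m <- min(chunk, n_iter - done)
    W <- matrix(rnorm(n_segments * m), n_segments, m)
    minabs <- matrix(Inf, n_segments, m)
    for (j in seq_len(k)) {
      z <- sr * W + se * matrix(rnorm(n_segments * m), n_segments, m)
      minabs <- pmin(minabs, abs(z))
    }
    counts[done + seq_len(m)] <- colSums(minabs > z_thresh)
    done <- done + m
  }
  hist_tbl <- tibble::as_tibble(table(count = counts)) |>
    dplyr::mutate(count = as.integer(.data$count)) |>
    dplyr::rename(n_iterations = "n")
  structure(list(counts = counts,
                 p = mean(counts >= observed),
                 histogram = hist_tbl,
                 config = list(n_iter = n_iter, n_segments = n_segments,
                               k = k, rho = rho, z_thresh = z_thresh,
                               observed = observed, seed = seed)),
            class = "mc_null")
}

#' @export
print.mc_null <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mc_null> %s iterations, %s segments, k = %d, rho = %.2f, |z| > %.2f\n",
              format(cfg$n_iter, big.mark = ","),
              format(cfg$n_segments, big.mark = ","), cfg$k, cfg$rho,
              cfg$z_thresh))
  cat(sprintf("  P(count >= %d) = %.4f  (mean count %.2f)\n",
              cfg$observed, x$p, mean(x$counts)))
  invisible(x)
}

#' Semi-analytic per-segment pass probability
#'
#' Probability that the minimum absolute value of `k` equicorrelated
#' standard normals exceeds the threshold, by 1-D numerical integration
#' over the shared factor: conditional on `W = w` the criteria are
#' independent with exceedance `q(w)`, so the pass probability is
#' `E[q(W)^k]`. Serves as the independent oracle for [mc_null()].
#'
#' @inheritParams mc_null
#' @return Scalar probability.
#' @export
mc_pass_probability <- function(k = 4, rho = 0.5, z_thresh = 1.96) {
  abort_if(!(rho >= 0 && rho < 1), "rho must be in [0, 1)")
  if (rho == 0) return((2 * pnorm(-z_thresh))^k)
  sr <- sqrt(rho); se <- sqrt(1 - rho)
  f <- function(w) {
    q <- pnorm((sr * w - z_thresh) / se) + pnorm((-z_thresh - sr * w) / se)
    q^k * dnorm(w)
  }
  integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

#' Binomial tail cross-check for the Monte Carlo p-value
#'
#' Segments are independent under the null, so the false-positive count is
#' Binomial(`n_segments`, `p_pass`); this returns `P(count >= observed)`.
#'
#' @inheritParams mc_null
#' @param p_pass Per-segment pass probability, e.g. from
#'   [mc_pass_probability()].
#' @return Tail probability.
#' @export
mc_binomial_p <- function(observed, n_segments = 2320,
                          p_pass = mc_pass_probability()) {
  pbinom(observed - 1, n_segments, p_pass, lower.tail = FALSE)
}
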