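#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @name tidiers
#' @title Broom-style tidiers for fitted objects
#' @description `tidy()` returns the per-term detail of a fitted object as a
#'   tibble; `glance()` returns a one-row model summary.
#' @param x A fitted object from this package.
#' @param ... Unused.
NULL

#' @rdname tidiers
#' @export
tidy.segment_asca <- function(x, ...) {
  k <- ncol(x$loadings)
  dplyr::bind_rows(
    tidyr::expand_grid(component = seq_len(k), label = x$sessions) |>
      dplyr::mutate(kind = "score",
                    value = as.vector(x$scores[, seq_len(k), drop = FALSE])),
    tidyr::expand_grid(component = seq_len(k), label = x$metrics) |>
      dplyr::mutate(kind = "loading",
                    value = as.vector(x$loadings[, seq_len(k), drop = FALSE]))
  ) |>
    dplyr::select("component", "kind", "label", "value")
}

#' @rdname tidiers
#' @export
glance.segment_asca <- function(x, ...) {
  seg <- if (length(x$segment) > 1)
    paste(range(x$segment), collapse = "-") else as.character(x$segment)
  tibble::tibble(tract = x$tract,
                 segment = seg,
                 n_subjects = x$n_subjects,
                 n_metrics = length(x$metrics),
                 explvar_pc1 = x$explained_variance[1],
                 method = x$method)
}

#' @rdname tidiers
#' @export
tidy.segment_asca_boot <- function(x, ...) x$ci

#' @rdname tidiers
#' @export
glance.segment_asca_boot <- function(x, ...) {
  dplyr::bind_cols(glance(x$model),
                   tibble::tibble(B = x$B, n_fail = x$n_fail,
                                  level = x$level),
                   classify_segment(x))
}

#' @rdname tidiers
#' @export
tidy.learning_curve_fit <- function(x, ...) {
  terms <- c("a", "b", if (!is.null(x$c)) "c")
  tibble::tibble(term = terms,
                 estimate = c(x$a, x$b, x$c))
}

#' @rdname tidiers
#' @export
glance.learning_curve_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, n_sessions = nrow(x$means),
                 converged = x$converged)
}

#' @rdname tidiers
#' @export
tidy.robust_fit <- function(x, ...) x$coef

#' @rdname tidiers
#' @export
glance.robust_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, pseudo_f = x$pseudo_f, df1 = x$df1, df2 = x$df2,
                 p_value = x$p_value, scale = x$scale,
                 condition_number = x$condition_number, n = x$n)
}

#' @rdname tidiers
#' @export
tidy.mc_null <- function(x, ...) x$histogram

#' @rdname tidiers
#' @export
glance.mc_null <- function(x, ...) {
  tibble::tibble(p = x$p, mean_count = mean(x$counts),
                 max_count = max(x$counts),
                 n_iter = x$config$n_iter, n_segments = x$config$n_segments,
                 k = x$config$k, rho = x$config$rho,
                 z_thresh = x$config$z_thresh, observed = x$config$observed)
}

#' @rdname tidiers
#' @export
tidy.change_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @rdname tidiers
#' @export
glance.change_pca <- function(x, ...) {
  tibble::tibble(n = x$n, p = nrow(x$loadings),
                 explvar_pc1 = x$explained_variance[1],
                 eigenvalue_1 = x$eigenvalues[1])
}

#' @rdname tidiers
#' @export
tidy.factorability <- function(x, ...) {
  tibble::tibble(variable = names(x$kmo_per_var), kmo = unname(x$kmo_per_var))
}

#' @rdname tidiers
#' @export
glance.factorability <- function(x, ...) {
  tibble::tibble(kmo_overall = x$kmo_overall,
                 bartlett_chi2 = x$bartlett_chi2,
                 bartlett_df = x$bartlett_df, bartlett_p = x$bartlett_p,
                 determinant = x$determinant, det_ok = x$det_ok,
                 n = x$n, p = x$p)
}
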