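profile_cols <- c("subject_id", "session", "tract", "segment", "metric", "value")

#' Validate a tract-profile panel
#'
#' Checks the long-format schema (`subject_id`, `session`, `tract`,
#' `segment`, `metric`, `value`), key uniqueness, and value finiteness.
#' Rows with non-finite values are dropped with a reported count.
#'
#' @param panel Data frame in long tract-profile format.
#' @param session_levels Ordered session labels; defaults to the sorted
#'   unique sessions present.
#' @return Validated tibble (invisibly messaged about dropped rows).
#' @export
validate_profiles <- function(panel, session_levels = NULL) {
  missing_cols <- setdiff(profile_cols, names(panel))
  abort_if(length(missing_cols) > 0,
           sprintf("schema error: missing column(s) %s",
                   paste(missing_cols, collapse = ", ")))
  panel <- tibble::as_tibble(panel)[profile_cols]
  abort_if(!is.numeric(panel$value), "schema error: 'value' must be numeric")
  abort_if(!is.numeric(panel$segment), "schema error: 'segment' must be numeric")

  bad <- !is.finite(panel$value)
  if (any(bad)) {
    message(sprintf("dropping %d row(s) with non-finite values", sum(bad)))
    panel <- panel[!bad, ]
  }
  key <- paste(panel$subject_id, panel$session, panel$tract,
               panel$segment, panel$metric, sep = "\r")
  dup <- duplicated(key)
  abort_if(any(dup),
           sprintf("integrity error: duplicate key (subject %s, session %s, tract %s, segment %s, metric %s)",
                   panel$subject_id[dup][1], panel$session[dup][1],
                   panel$tract[dup][1], panel$segment[dup][1],
                   panel$metric[dup][1]))
  lev <- session_levels %||% sort(unique(panel$session))
  attr(panel, "session_levels") <- lev
  panel
}

#' Read a tract-profile table
#'
#' Reads a TSV/CSV with the long tract-profile schema and validates it.
#' The delimiter is inferred from the file extension unless given.
#'
#' @param path File path.
#' @param delim Field delimiter; default `"\t"` for `.tsv`, `","` for `.csv`.
#' @param session_levels Optional ordered session labels.
#' @return Validated tibble of observations.
#' @export
read_profiles <- function(path, delim = NULL, session_levels = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_profiles(raw, session_levels)
}

#' Write a tract-profile table as TSV
#'
#' @param panel Tract-profile tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(panel, path) {
  readr::write_tsv(panel[profile_cols], path, progress = FALSE)
  invisible(path)
}

#' Read / write behavioral balance-task records
#'
#' TSV with columns `subject_id`, `session`, `trial`, `balance_time_s`.
#'
#' @param path File path.
#' @return Tibble of trial records.
#' @export
read_behavior <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "session", "trial", "balance_time_s")
  missing_cols <- setdiff(need, names(out))
  abort_if(length(missing_cols) > 0,
           sprintf("schema error: missing column(s) %s",
                   paste(missing_cols, collapse = ", ")))
  out
}

#' @rdname read_behavior
#' @param behavior Behavior tibble to write.
#' @export
write_behavior <- function(behavior, path) {
  readr::write_tsv(behavior[c("subject_id", "session", "trial", "balance_time_s")],
                   path, progress = FALSE)
  invisible(path)
}

#' Trim tract profiles to the central segments and filter subjects
#'
#' Restricts each tract to the centered run of `n_keep` segments, excluding
#' the anatomically heterogeneous start and end regions (for 98 segments and
#' `n_keep = 80`: segments 10-89, 1-based), and removes listed subjects
#' entirely. Requires an even overhang so trimming is symmetric; the
#' operation is idempotent.
#'
#' @param panel Tract-profile tibble.
#' @param n_keep Number of central segments to retain per tract.
#' @param exclude_subjects Subject ids to drop (e.g. a sex-based sensitivity
#'   subgroup).
#' @return Trimmed tibble.
#' @export
trim_and_filter <- function(panel, n_keep = 80, exclude_subjects = character()) {
  rng <- range(panel$segment)
  n_seg <- rng[2] - rng[1] + 1
  abort_if(n_keep > n_seg, "n_keep exceeds the number of segments present")
  over <- n_seg - n_keep
  abort_if(over %% 2 != 0,
           sprintf("configuration error: overhang %d is odd; centered trimming needs (n_segments - n_keep) even", over))
  lo <- rng[1] + over / 2
  out <- dplyr::filter(panel,
                       .data$segment >= lo, .data$segment <= lo + n_keep - 1,
                       !.data$subject_id %in% exclude_subjects)
  attr(out, "session_levels") <- attr(panel, "session_levels")
  attr(out, "magnitudes") <- attr(panel, "magnitudes")
  out
}

#' Count segment-level test units in a panel
#'
#' @param panel Tract-profile tibble.
#' @return Number of distinct (tract, segment) units.
#' @export
n_segment_units <- function(panel) {
  nrow(dplyr::distinct(panel, .data$tract, .data$segment))
}
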