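#' Scoring configuration for the r'-wave algorithm
#'
#' The algorithm awards one point for each of four criteria met at its
#' cut-off (all comparisons inclusive): beta-angle >= 40 degrees,
#' alpha-angle >= 24 degrees, DBT-5mm >= 120 ms and DBT-iso >= 80 ms. The
#' resulting 0--4 score predicts a positive provocation test at
#' score >= `score_cut` (default 2). Cut-offs and optional per-criterion
#' weights are configurable for sensitivity analysis.
#'
#' @param beta_cut_deg,alpha_cut_deg,dbt5_cut_ms,dbtiso_cut_ms Criterion
#'   cut-offs (defaults 40, 24, 120, 80).
#' @param score_cut Score threshold for a positive prediction, in 1..4
#'   (default 2).
#' @param weights Numeric length-4 vector of per-criterion points
#'   (default all 1).
#' @return An object of class `score_config`.
#' @export
score_config <- function(beta_cut_deg = 40, alpha_cut_deg = 24,
                         dbt5_cut_ms = 120, dbtiso_cut_ms = 80,
                         score_cut = 2, weights = c(1, 1, 1, 1)) {
  cuts <- c(beta_cut_deg, alpha_cut_deg, dbt5_cut_ms, dbtiso_cut_ms)
  if (any(is.nan(cuts)) || any(cuts <= 0))
    stop("cut-offs must be positive")
  if (!score_cut %in% 1:4) stop("score_cut must be in 1..4")
  if (length(weights) != 4L || any(weights < 0))
    stop("weights must be 4 non-negative numbers")
  structure(list(beta_cut_deg = beta_cut_deg, alpha_cut_deg = alpha_cut_deg,
                 dbt5_cut_ms = dbt5_cut_ms, dbtiso_cut_ms = dbtiso_cut_ms,
                 score_cut = score_cut, weights = weights),
            class = "score_config")
}

#' @export
print.score_config <- function(x, ...) {
  cat(sprintf(paste0("r'-wave score config: beta >= %g deg, alpha >= %g deg, ",
                     "DBT-5mm >= %g ms, DBT-iso >= %g ms; positive at ",
                     "score >= %g\n"),
              x$beta_cut_deg, x$alpha_cut_deg, x$dbt5_cut_ms,
              x$dbtiso_cut_ms, x$score_cut))
  invisible(x)
}

#' Score one patient with the r'-wave algorithm
#'
#' Applies the four criterion cut-offs to a patient's major feature values
#' and sums the met criteria into the 0--4 score. A patient without any
#' measurable r'-wave defaults to score 0 and a negative prediction
#' (`basis = "unmeasurable_default"`): the absence of a measurable r' is
#' treated as evidence against the Brugada pattern. An individually missing
#' criterion counts as not met and is noted.
#'
#' @param features A [aggregate_patient()] result, or a list/one-row
#'   data.frame with fields `beta_deg`, `alpha_deg`, `dbt5_ms`, `dbtiso_ms`
#'   (and optionally `any_measurable`).
#' @param config A [score_config()].
#' @return An object of class `rwave_score`: criterion flags, `score`,
#'   `prediction` ("positive"/"negative"), `basis`, and `notes`.
#' @examples
#' f <- list(beta_deg = 53.1, alpha_deg = 41.4,
#'           dbt5_ms = 247.5, dbtiso_ms = 107.9, any_measurable = TRUE)
#' score_patient(f)  # all four criteria met: score 4, positive
#' @export
score_patient <- function(features, config = score_config()) {
  stopifnot(inherits(config, "score_config"))
  vals <- c(beta = as.numeric(features$beta_deg %||% NA),
            alpha = as.numeric(features$alpha_deg %||% NA),
            dbt5 = as.numeric(features$dbt5_ms %||% NA),
            dbtiso = as.numeric(features$dbtiso_ms %||% NA))
  any_meas <- features$any_measurable %||% any(!is.na(vals))
  if (!isTRUE(any_meas)) {
    return(structure(list(beta_pos = FALSE, alpha_pos = FALSE,
                          dbt5_pos = FALSE, dbtiso_pos = FALSE,
                          score = 0, prediction = "negative",
                          basis = "unmeasurable_default", notes = character()),
                     class = "rwave_score"))
  }
  cuts <- c(config$beta_cut_deg, config$alpha_cut_deg,
            config$dbt5_cut_ms, config$dbtiso_cut_ms)
  flags <- !is.na(vals) & vals >= cuts
  notes <- if (any(is.na(vals)))
    paste0("missing criterion treated as not met: ",
           paste(names(vals)[is.na(vals)], collapse = ", "))
  else character()
  score <- sum(config$weights[flags])
  structure(list(beta_pos = unname(flags[1L]), alpha_pos = unname(flags[2L]),
                 dbt5_pos = unname(flags[3L]), dbtiso_pos = unname(flags[4L]),
                 score = score,
                 prediction = if (score >= config$score_cut) "positive"
                              else "negative",
                 basis = "measured", notes = notes),
            class = "rwave_score")
}

#' @export
print.rwave_score <- function(x, ...) {
  met <- c("beta", "alpha", "DBT-5mm", "DBT-iso")[
    c(x$beta_pos, x$alpha_pos, x$dbt5_pos, x$dbtiso_pos)]
  cat(sprintf("r'-wave score %g -> %s (%s)\n", x$score, x$prediction, x$basis))
  cat("  criteria met:", if (length(met)) paste(met, collapse = ", ")
                         else "none", "\n")
  if (length(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

#' Score a cohort feature table
#'
#' Row-wise application of [score_patient()]; the integer score column is
#' the continuous marker used when the algorithm itself is entered into ROC
#' analysis.
#'
#' @param features data.frame with the columns of [read_features()] (at
#'   least `patient_id`, `beta_deg`, `alpha_deg`, `dbt5_ms`, `dbtiso_ms`).
#' @param config A [score_config()].
#' @return data.frame: `patient_id`, the four criterion flags, `score`,
#'   `prediction`, `basis` (plus `scbpt_label` if present in the input).
#' @export
score_cohort <- function(features, config = score_config()) {
  if (!is.data.frame(features) || nrow(features) == 0L)
    stop("`features` must be a non-empty data.frame")
  rows <- lapply(seq_len(nrow(features)), function(i) {
    f <- as.list(features[i, ])
    if (is.null(f$any_measurable)) {
      meas <- unlist(f[c("measurable_ii", "measurable_iii", "measurable_iv")])
      f$any_measurable <- if (all(is.na(meas)))
        any(!is.na(unlist(f[c("beta_deg", "alpha_deg",
                              "dbt5_ms", "dbtiso_ms")])))
      else any(meas, na.rm = TRUE)
    }
    s <- score_patient(f, config)
    data.frame(patient_id = as.character(f$patient_id %||% i),
               beta_pos = s$beta_pos, alpha_pos = s$alpha_pos,
               dbt5_pos = s$dbt5_pos, dbtiso_pos = s$dbtiso_pos,
               score = s$score, prediction = s$prediction, basis = s$basis)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if ("scbpt_label" %in% names(features))
    out$scbpt_label <- features$scbpt_label
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
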