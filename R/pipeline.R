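#' Run configuration for the extraction/evaluation pipeline
#'
#' Collects every tunable used by the end-to-end pipeline so that no
#' hidden constants enter a run: calibration, beat-window and limb-band
#' settings, scoring cut-offs, and the evaluation mode that decides how
#' patients without a measurable r'-wave enter single-criterion ROC
#' analyses ("measurable_only" drops them, "all_patients" ranks them below
#' every measured value).
#'
#' @param calibration An [ecg_calibration()].
#' @param pre_ms,post_ms QRS window half-widths for [detect_beats()].
#' @param band Limb-fit vertical band for [fit_limbs()].
#' @param score A [score_config()].
#' @param eval_mode "measurable_only" or "all_patients".
#' @param seed Optional integer seed, echoed into reports.
#' @return An object of class `run_config`.
#' @export
run_config <- function(calibration = ecg_calibration(), pre_ms = 80,
                       post_ms = 120, band = c(0.2, 0.8),
                       score = score_config(),
                       eval_mode = c("measurable_only", "all_patients"),
                       seed = NULL) {
  structure(list(calibration = calibration, pre_ms = pre_ms,
                 post_ms = post_ms, band = band, score = score,
                 eval_mode = match.arg(eval_mode), seed = seed),
            class = "run_config")
}

#' Extract per-patient features from a set of records
#'
#' Runs beat detection, r'-wave location and triangle geometry on every
#' channel of every record and aggregates to per-patient major values.
#' Unreadable inputs are skipped and logged; the run fails only if no
#' record is readable.
#'
#' @param records List of [ecg_record()] objects, or character paths
#'   (`.csv` or WFDB `.hea`) read via [read_record()].
#' @param lead_map Passed to [read_record()] when paths are given.
#' @param config A [run_config()].
#' @return List with `features` (per-patient data.frame in the
#'   [read_features()] layout, without labels), `beat_geometry` (per-beat
#'   data.frame), and `log` (per-input status data.frame with a `status`
#'   of "ok" or "failed").
#' @export
run_extract <- function(records, lead_map = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (length(records) == 0L) stop("no input records")
  load_one <- function(x) {
    if (inherits(x, "ecg_record")) return(x)
    fmt <- if (grepl("\\.hea$", x)) "wfdb" else "csv"
    read_record(x, fmt, lead_map, config$calibration)
  }
  feats <- list(); geoms <- list(); log <- list()
  for (i in seq_along(records)) {
    id_hint <- if (is.character(records[[i]])) basename(records[[i]])
               else paste0("record", i)
    res <- tryCatch({
      rec <- load_one(records[[i]])
      g <- do.call(rbind, lapply(seq_len(ncol(rec$signals)), function(ch)
        extract_rprime(rec, ch, config$pre_ms, config$post_ms,
                       band = config$band)))
      pf <- aggregate_patient(g)
      if (!is.null(g) && nrow(g))
        g <- cbind(patient_id = rec$patient_id, g)
      list(id = rec$patient_id, g = g, pf = pf, ok = TRUE, msg = "ok")
    }, error = function(e)
      list(id = id_hint, g = NULL, pf = NULL, ok = FALSE,
           msg = conditionMessage(e)))
    log[[i]] <- data.frame(input = id_hint, status = if (res$ok) "ok"
                           else "failed", message = res$msg)
    if (!res$ok) next
    geoms[[length(geoms) + 1L]] <- res$g
    pf <- res$pf
    feats[[length(feats) + 1L]] <- data.frame(
      patient_id = res$id, beta_deg = pf$beta_deg, alpha_deg = pf$alpha_deg,
      dbt5_ms = pf$dbt5_ms, dbtiso_ms = pf$dbtiso_ms, ratio = pf$ratio,
      measurable_ii = pf$measurable_by_ic[["II"]],
      measurable_iii = pf$measurable_by_ic[["III"]],
      measurable_iv = pf$measurable_by_ic[["IV"]])
  }
  if (!length(feats)) stop("no readable input records")
  list(features = do.call(rbind, c(feats, list(make.row.names = FALSE))),
       beat_geometry = do.call(rbind, c(geoms, list(make.row.names = FALSE))),
       log = do.call(rbind, c(log, list(make.row.names = FALSE))))
}

marker_columns <- c(beta = "beta_deg", alpha = "alpha_deg",
                    dbt5 = "dbt5_ms", dbtiso = "dbtiso_ms", ratio = "ratio")

#' Full diagnostic-accuracy evaluation of a labelled cohort
#'
#' Scores every patient with the r'-wave algorithm and evaluates the five
#' single criteria plus the composite score: per-marker ROC/AUC with
#' DeLong CI, the pairwise DeLong comparison matrix, Youden-index
#' cut-offs, sensitivity/specificity of the score prediction, McNemar's
#' test against the provocation-test outcome, and (when replicate ratings
#' are supplied) observer-agreement ICCs. Deterministic given inputs and
#' config.
#'
#' @param features Labelled feature table ([read_features()] layout with
#'   `scbpt_label`).
#' @param config A [run_config()].
#' @param ratings Optional named list of subjects-by-raters matrices for
#'   [icc_agreement()].
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `scores.csv` and the input features there.
#' @return An object of class `rwave_report`: list with `config_echo`,
#'   `n_pos`, `n_neg`, `scores`, `roc` (per-marker [roc_auc()] results),
#'   `delong` (pairwise p-value matrix), `youden`, `sens_spec`, `mcnemar`
#'   and optional `icc`.
#' @export
run_full <- function(features, config = run_config(), ratings = NULL,
                     out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!"scbpt_label" %in% names(features) || all(is.na(features$scbpt_label)))
    stop("features must carry scbpt_label outcomes")
  labels <- check_labels(features$scbpt_label)
  scores <- score_cohort(features, config$score)
  na_action <- if (config$eval_mode == "all_patients") "lowest" else "exclude"
  markers <- c(lapply(marker_columns, function(cn) features[[cn]]),
               list(score = scores$score))
  roc <- lapply(markers, function(mk) roc_auc(mk, labels, na_action))
  nm <- names(markers)
  dl <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
    mi <- markers[[i]]; mj <- markers[[j]]
    if (na_action == "lowest") {
      mi[is.na(mi)] <- min(mi, na.rm = TRUE) - 1
      mj[is.na(mj)] <- min(mj, na.rm = TRUE) - 1
    }
    dl[i, j] <- dl[j, i] <- delong_compare(mi, mj, labels)$p_two_sided
  }
  youden <- lapply(markers, function(mk) youden_cut(mk, labels))
  pred <- as.integer(scores$prediction == "positive")
  ss <- sens_spec(pred, labels)
  mcn <- mcnemar(pred, labels)
  icc <- if (!is.null(ratings)) lapply(ratings, icc_agreement)
  report <- structure(
    list(config_echo = list(
           eval_mode = config$eval_mode, seed = config$seed,
           score = unclass(config$score),
           calibration = unclass(config$calibration)[c("paper_speed", "gain")],
           band = config$band),
         n_pos = sum(labels == 1), n_neg = sum(labels == 0),
         scores = scores, roc = roc, delong = dl, youden = youden,
         sens_spec = ss, mcnemar = mcn, icc = icc),
    class = "rwave_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    write_features(features, file.path(out_dir, "features.csv"))
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# JSON-friendly view of a report (drops the per-threshold ROC curves)
report_to_list <- function(report) {
  list(config = report$config_echo,
       n_pos = report$n_pos, n_neg = report$n_neg,
       aucs = lapply(report$roc, function(r)
         list(auc = r$auc, se = r$se_delong,
              ci95 = as.numeric(r$ci95))),
       delong_p = apply(report$delong, 1L, as.list, simplify = FALSE),
       youden = lapply(report$youden, unclass),
       sens_spec = report$sens_spec,
       mcnemar = unclass(report$mcnemar),
       icc = if (!is.null(report$icc))
         lapply(report$icc, function(ic)
           list(icc = ic$icc, ci95 = as.numeric(ic$ci95))))
}

#' @export
print.rwave_report <- function(x, ...) {
  cat(sprintf("r'-wave algorithm evaluation: %d positive / %d negative\n",
              x$n_pos, x$n_neg))
  cat("AUCs (DeLong 95% CI):\n")
  for (nm in names(x$roc)) {
    r <- x$roc[[nm]]
    cat(sprintf("  %-7s %.3f (%.3f-%.3f)\n", nm, r$auc,
                r$ci95[1L], r$ci95[2L]))
  }
  cat(sprintf("score >= %g: sensitivity %.3f, specificity %.3f\n",
              x$config_echo$score$score_cut,
              x$sens_spec$sensitivity, x$sens_spec$specificity))
  invisible(x)
}
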