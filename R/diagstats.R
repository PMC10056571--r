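#' @title Diagnostic accuracy statistics
#' @description
#' Empirical ROC/AUC with DeLong variance and confidence interval, paired
#' DeLong AUC comparison, Youden-index cut-off selection, sensitivity and
#' specificity, McNemar's test against a gold standard, and two-way
#' absolute-agreement intraclass correlation for observer agreement — the
#' statistics used to evaluate predictors of a positive sodium channel
#' blocker provocation test.
#' @name diagstats
NULL

check_labels <- function(labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (anyNA(labels)) stop("labels must be binary (0/1 or logical)")
  if (!any(labels == 1) || !any(labels == 0))
    stop("need at least one positive and one negative label")
  labels
}

# DeLong placement values: for each positive, the fraction of negatives it
# outranks (ties get half credit), and symmetrically for negatives.
delong_placements <- function(markers, labels) {
  pos <- markers[labels == 1]
  neg <- markers[labels == 0]
  m <- length(pos); n <- length(neg)
  # midranks over the pooled sample give O((m+n) log(m+n)) placements
  all_r <- rank(c(pos, neg), ties.method = "average")
  pos_r <- rank(pos, ties.method = "average")
  neg_r <- rank(neg, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - pos_r) / n            # P(pos_i > random neg)
  v01 <- 1 - (all_r[m + seq_len(n)] - neg_r) / m    # P(pos > neg_j)
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' Empirical ROC curve and AUC with DeLong variance
#'
#' The AUC is the Mann-Whitney statistic (ties get half credit); its
#' standard error comes from the DeLong placement-value variance and the
#' 95% CI is the Wald interval clipped to \[0, 1\]. Higher marker values
#' must indicate the positive class.
#'
#' @param markers Numeric marker values (may contain `NA`; see
#'   `na_action`).
#' @param labels Binary outcome (1/TRUE = positive test).
#' @param na_action How to treat `NA` markers (e.g. patients without a
#'   measurable r'-wave): "exclude" (default) drops them; "lowest" ranks
#'   them below every observed value (tied among themselves).
#' @return An object of class `roc_result`: `auc`, `se_delong`, `ci95`,
#'   `curve` (threshold, sensitivity, specificity), `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(1, 3, 0, 2), c(1, 1, 0, 0))$auc  # 0.75
#' @export
roc_auc <- function(markers, labels, na_action = c("exclude", "lowest")) {
  na_action <- match.arg(na_action)
  if (length(markers) != length(labels)) stop("length mismatch")
  if (anyNA(markers)) {
    if (na_action == "exclude") {
      keep <- !is.na(markers)
      markers <- markers[keep]; labels <- labels[keep]
    } else {
      markers[is.na(markers)] <- min(markers, na.rm = TRUE) - 1
    }
  }
  labels <- check_labels(labels)
  pl <- delong_placements(markers, labels)
  s10 <- if (pl$m > 1L) stats::var(pl$v10) else 0
  s01 <- if (pl$n > 1L) stats::var(pl$v01) else 0
  se <- sqrt(s10 / pl$m + s01 / pl$n)
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * stats::qnorm(0.975) * se))
  thr <- c(-Inf, sort(unique(markers)), Inf)
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t)
      mean(markers[labels == 1] >= t), 0),
    specificity = vapply(thr, function(t)
      mean(markers[labels == 0] < t), 0))
  structure(list(auc = pl$auc, se_delong = se, ci95 = ci, curve = curve,
                 n_pos = pl$m, n_neg = pl$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (DeLong SE %.3f; 95%% CI %.3f-%.3f); %d pos / %d neg\n",
              x$auc, x$se_delong, x$ci95[1L], x$ci95[2L], x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(1 - x$curve$specificity, x$curve$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Compare two paired AUCs by the DeLong method
#'
#' Both markers must be measured on the same patients. The variance of the
#' AUC difference uses the DeLong covariance of the paired placement
#' values; the p-value is two-sided normal.
#'
#' @param markers_a,markers_b Paired marker vectors.
#' @param labels Binary outcome.
#' @return An object of class `delong_comparison`: `auc_a`, `auc_b`,
#'   `delta`, `se_delta`, `z`, `p_two_sided`.
#' @export
delong_compare <- function(markers_a, markers_b, labels) {
  if (length(markers_a) != length(markers_b) ||
      length(markers_a) != length(labels))
    stop("length mismatch: paired markers required")
  keep <- !is.na(markers_a) & !is.na(markers_b)
  markers_a <- markers_a[keep]; markers_b <- markers_b[keep]
  labels <- check_labels(labels[keep])
  pa <- delong_placements(markers_a, labels)
  pb <- delong_placements(markers_b, labels)
  delta <- pa$auc - pb$auc
  var_delta <- stats::var(pa$v10 - pb$v10) / pa$m +
    stats::var(pa$v01 - pb$v01) / pa$n
  se <- sqrt(max(var_delta, 0))
  if (se == 0) {
    z <- 0; p <- if (abs(delta) < 1e-15) 1 else 0
  } else {
    z <- delta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 se_delta = se, z = z, p_two_sided = p),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.3f vs %.3f, delta %.3f (SE %.3f), z %.2f, p %.4g\n",
              x$auc_a, x$auc_b, x$delta, x$se_delta, x$z, x$p_two_sided))
  invisible(x)
}

#' Youden-index optimal cut-off
#'
#' Scans candidate thresholds (midpoints of adjacent sorted unique marker
#' values, plus -Inf and +Inf) for the one maximizing J = sensitivity +
#' specificity - 1, with "positive at marker >= threshold". Ties are broken
#' toward the lowest threshold, which maximizes sensitivity.
#'
#' @param markers Numeric marker values.
#' @param labels Binary outcome.
#' @return An object of class `youden_result`: `best_threshold`, `J`,
#'   `sensitivity`, `specificity`.
#' @export
youden_cut <- function(markers, labels) {
  keep <- !is.na(markers)
  markers <- markers[keep]
  labels <- check_labels(labels[keep])
  u <- sort(unique(markers))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  pos <- markers[labels == 1]; neg <- markers[labels == 0]
  best <- NULL
  for (t in cand) {
    sens <- mean(pos >= t)
    spec <- mean(neg < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$J + 1e-12)
      best <- list(best_threshold = t, J = j,
                   sensitivity = sens, specificity = spec)
  }
  structure(best, class = "youden_result")
}

#' @export
print.youden_result <- function(x, ...) {
  cat(sprintf("Youden cut-off >= %.4g: J %.3f (sens %.3f, spec %.3f)\n",
              x$best_threshold, x$J, x$sensitivity, x$specificity))
  invisible(x)
}

#' Sensitivity and specificity of binary predictions
#'
#' @param predictions Binary predictions (1/TRUE = predicted positive).
#' @param labels Binary outcome.
#' @return List with `sensitivity`, `specificity` and the confusion counts
#'   `tp`, `fp`, `tn`, `fn`. A class absent from `labels` yields `NA` for
#'   the corresponding rate, with a warning.
#' @examples
#' # 9/10 positives detected, 83/100 negatives correctly negative
#' p <- c(rep(1, 9), 0, rep(1, 17), rep(0, 83))
#' y <- c(rep(1, 10), rep(0, 100))
#' sens_spec(p, y)
#' @export
sens_spec <- function(predictions, labels) {
  predictions <- as.integer(as.logical(predictions) | predictions == 1)
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(predictions) != length(labels)) stop("length mismatch")
  tp <- sum(predictions == 1 & labels == 1)
  fn <- sum(predictions == 0 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  fp <- sum(predictions == 1 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive labels: sensitivity undefined"); NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no negative labels: specificity undefined"); NA_real_
  }
  list(sensitivity = sens, specificity = spec,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' McNemar's test against a gold standard
#'
#' Tests lack of agreement between binary predictions and the gold
#' standard using the discordant pairs b (predicted positive, gold
#' negative) and c (predicted negative, gold positive). For b + c < 25 the
#' exact two-sided binomial test is used; otherwise the continuity-
#' corrected chi-squared statistic `(|b - c| - 1)^2 / (b + c)` on 1 df.
#'
#' @param predictions Binary predictions.
#' @param gold Binary gold-standard outcome.
#' @return An object of class `mcnemar_result`: `b`, `c`, `statistic`,
#'   `p`, `method` ("exact" or "chi2_cc").
#' @export
mcnemar <- function(predictions, gold) {
  predictions <- as.integer(as.logical(predictions) | predictions == 1)
  gold <- as.integer(as.logical(gold) | gold == 1)
  if (length(predictions) != length(gold)) stop("length mismatch")
  b <- sum(predictions == 1 & gold == 0)
  cc <- sum(predictions == 0 & gold == 1)
  nd <- b + cc
  if (nd == 0) {
    res <- list(b = b, c = cc, statistic = 0, p = 1, method = "exact")
  } else if (nd < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), nd, 0.5))
    stat <- (abs(b - cc) - 1)^2 / nd
    res <- list(b = b, c = cc, statistic = stat, p = p, method = "exact")
  } else {
    stat <- (abs(b - cc) - 1)^2 / nd
    res <- list(b = b, c = cc, statistic = stat,
                p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                method = "chi2_cc")
  }
  structure(res, class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar (%s): b %d, c %d, statistic %.3f, p %.4g\n",
              x$method, x$b, x$c, x$statistic, x$p))
  invisible(x)
}

#' Intraclass correlation for observer agreement
#'
#' ICC for a two-way model with absolute agreement on single measurements
#' (ICC(A,1) in McGraw-Wong terms), computed from the two-way ANOVA mean
#' squares, with the standard F-based 95% confidence interval. Used for
#' intra- and inter-observer agreement of the r'-wave criteria.
#'
#' @param ratings Numeric matrix or data.frame, subjects in rows, raters
#'   in columns; complete, at least 5 subjects and 2 raters.
#' @return An object of class `icc_result`: `icc`, `ci95`, `model`,
#'   `n_subjects`, `n_raters`.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("need at least 5 subjects")
  if (k < 2L) stop("need at least 2 raters")
  if (anyNA(ratings)) stop("ratings table must be complete")
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  grand <- mean(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0 || (msr <= mse && msc <= mse && msr == 0))
    stop("zero between-subject variance: ICC undefined")
  icc <- (msr - mse) / denom
  # McGraw-Wong F-based interval for ICC(A,1)
  alpha <- 0.05
  a <- (k * icc) / (n * (1 - icc))
  bq <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + bq * mse)^2 /
    ((a * msc)^2 / (k - 1) + (bq * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  structure(list(icc = icc, ci95 = c(lower, min(1, upper)),
                 model = "two-way, absolute agreement, single measurement",
                 n_subjects = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) %.3f (95%% CI %.3f-%.3f), %d subjects x %d raters\n",
              x$icc, x$ci95[1L], x$ci95[2L], x$n_subjects, x$n_raters))
  invisible(x)
}
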