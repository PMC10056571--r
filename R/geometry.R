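#' @title r'-wave triangle geometry
#' @description
#' The r'-wave of a Brugada type-2 (saddleback) pattern is the terminal
#' positive deflection of the QRS in leads V1/V2. Its shape is quantified by
#' the triangle formed by extending the upslope and downslope of the wave on
#' standard-calibration ECG paper (25 mm/s, 10 mm/mV):
#' \itemize{
#'   \item beta-angle: angle between the upslope and downslope lines;
#'   \item alpha-angle: angle between a vertical line and the downslope;
#'   \item DBT-5mm: duration of the triangle base cut by a horizontal line
#'     5 mm below the apex;
#'   \item DBT-iso: duration of the base cut at the isoelectric line;
#'   \item base/height ratio: DBT-iso (in mm) over the apex height h (mm).
#' }
#' Writing theta for the angle between the upslope and the vertical, the
#' identities \code{beta = theta + alpha},
#' \code{dbt5 = ms_per_mm * 5 * (tan theta + tan alpha)},
#' \code{dbtiso = ms_per_mm * h * (tan theta + tan alpha)} and
#' \code{ratio = tan theta + tan alpha} hold exactly and are enforced by
#' construction.
#' @name rwave-geometry
NULL

# moving-average smoother used only for peak *detection*; fits use raw samples
smooth_ma <- function(x, k) {
  if (k <= 1L) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2L))
  # fill filter NAs at the edges with the raw values
  y[is.na(y)] <- x[is.na(y)]
  y
}

# indices of strict-then-plateau local maxima of x within [from, to]
local_maxima <- function(x, from = 1L, to = length(x)) {
  lo <- max(2L, from); hi <- min(length(x) - 1L, to)
  if (lo > hi) return(integer(0))
  idx <- lo:hi
  idx[x[idx] > x[idx - 1L] & x[idx] >= x[idx + 1L]]
}

local_minima <- function(x, from = 1L, to = length(x)) {
  lo <- max(2L, from); hi <- min(length(x) - 1L, to)
  if (lo > hi) return(integer(0))
  idx <- lo:hi
  idx[x[idx] < x[idx - 1L] & x[idx] <= x[idx + 1L]]
}

# local maxima that survive a prominence filter: of any neighbouring pair
# whose valley comes within `prom` of the lower peak, the lower peak is
# discarded. Suppresses noise bumps riding on the wave limbs.
prominent_maxima <- function(x, from, to, prom) {
  cand <- local_maxima(x, from, to)
  while (length(cand) > 1L) {
    drop <- NA_integer_
    for (i in seq_len(length(cand) - 1L)) {
      valley <- min(x[cand[i]:cand[i + 1L]])
      lo <- if (x[cand[i]] <= x[cand[i + 1L]]) i else i + 1L
      if (x[cand[lo]] - valley < prom) { drop <- lo; break }
    }
    if (is.na(drop)) break
    cand <- cand[-drop]
  }
  cand
}

prominent_minima <- function(x, from, to, prom)
  prominent_maxima(-x, from, to, prom)

#' Detect beats in a channel
#'
#' R peaks are located with a smoothed-derivative threshold detector
#' (rectified, integrated slope with a 200 ms refractory period). Each beat
#' gets a QRS window of configurable half-widths around the R peak and a
#' per-beat isoelectric baseline estimated as the median of a 40 ms
#' PR-segment window ending 40 ms before QRS onset.
#'
#' @param record An [ecg_record()].
#' @param channel Channel index.
#' @param pre_ms,post_ms QRS window half-widths around the R peak
#'   (defaults 80 and 120 ms).
#' @param refractory_ms Minimum R-R separation (default 200 ms).
#' @return List of beats; each beat is a list with `window` (index range),
#'   `r_peak`, `qrs_onset`, `qrs_offset` (sample indices) and `baseline_mV`.
#'   A flat or empty signal yields an empty list.
#' @export
detect_beats <- function(record, channel = 1L, pre_ms = 80, post_ms = 120,
                         refractory_ms = 200) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$signals[, channel]
  fs <- record$sampling_rate
  if (length(x) < 2 * fs) stop("need at least 2 s of signal")
  if (diff(range(x)) < 0.1) return(list())  # flat strip: nothing to detect
  k <- max(1L, round(0.010 * fs))           # 10 ms derivative smoothing
  d <- smooth_ma(c(0, diff(x)) * fs, k)     # mV/s
  energy <- smooth_ma(d^2, max(1L, round(0.030 * fs)))
  thr <- 0.25 * max(energy)
  refr <- round(refractory_ms / 1000 * fs)
  peaks <- integer(0)
  i <- 1L
  n <- length(x)
  while (i <= n) {
    if (energy[i] > thr) {
      j <- min(n, i + refr)
      seg <- i:j
      peaks <- c(peaks, seg[which.max(x[seg])])
      i <- j + 1L
    } else i <- i + 1L
  }
  pre <- round(pre_ms / 1000 * fs)
  post <- round(post_ms / 1000 * fs)
  bwin <- round(0.040 * fs)                 # 40 ms baseline window
  lapply(seq_along(peaks), function(ib) {
    r <- peaks[ib]
    onset <- max(1L, r - pre)
    offset <- min(n, r + post)
    w_lo <- if (ib == 1L) 1L else peaks[ib - 1L] + post + 1L
    w_hi <- if (ib == length(peaks)) n else peaks[ib + 1L] - pre - 1L
    base_to <- onset - bwin          # ends 40 ms before onset
    base_from <- base_to - bwin + 1L
    baseline <- if (base_from >= 1L) stats::median(x[base_from:base_to])
                else stats::median(x[max(1L, w_lo):onset])
    list(window = c(max(1L, w_lo), max(offset, min(n, w_hi))),
         r_peak = r, qrs_onset = onset, qrs_offset = offset,
         baseline_mV = baseline)
  })
}

#' Locate the r'-wave candidate apex within a beat
#'
#' The r' is the terminal positive deflection: the last local maximum in
#' the window from the R peak to the QRS offset whose (lightly smoothed)
#' height above the beat baseline exceeds a candidate gate of 0.05 mV. The
#' stricter measurability rule ([is_measurable()]) is applied separately.
#' J-point elevation without a discrete peak yields no candidate.
#'
#' @param beat A beat from [detect_beats()].
#' @param x Channel signal vector (mV).
#' @param fs Sampling rate (Hz).
#' @param min_height_mV Candidate gate (default 0.05 mV).
#' @return Apex sample index, or `NA_integer_` if no candidate.
#' @export
locate_rprime <- function(beat, x, fs, min_height_mV = 0.05) {
  k <- max(1L, round(0.010 * fs))
  xs <- smooth_ma(x, k)
  cand <- prominent_maxima(xs, beat$r_peak + 1L, beat$qrs_offset,
                           prom = min_height_mV)
  cand <- cand[xs[cand] - beat$baseline_mV > min_height_mV]
  if (!length(cand)) return(NA_integer_)
  apex_s <- cand[length(cand)]
  # refine on the raw signal around the smoothed peak
  lo <- max(1L, apex_s - k)
  hi <- min(length(x), apex_s + k)
  (lo:hi)[which.max(x[lo:hi])]
}

#' r'-wave measurability rule
#'
#' An r'-wave is measurable when its amplitude above baseline exceeds
#' 0.1 mV (1 mm) and the descending part after the apex also exceeds
#' 0.1 mV. Both comparisons are strict.
#'
#' @param height_mV Apex height above baseline, mV.
#' @param descent_mV Drop from apex to the following trough, mV.
#' @param threshold_mV Amplitude threshold (default 0.1 mV).
#' @return Logical.
#' @examples
#' is_measurable(0.15, 0.12)  # TRUE
#' is_measurable(0.10, 0.30)  # FALSE: strictly greater than is required
#' @export
is_measurable <- function(height_mV, descent_mV, threshold_mV = 0.1) {
  stopifnot(height_mV >= 0, descent_mV >= 0)
  (height_mV > threshold_mV) & (descent_mV > threshold_mV)
}

#' Fit the r'-wave limbs
#'
#' Each limb (upslope before the apex, downslope after it) is fitted by
#' least squares to the samples lying in a vertical band between the apex
#' and the adjacent local minimum (default the 20--80% band of that
#' vertical range), regressing paper-mm x on paper-mm y so the fitted slope
#' is the tangent of the angle from vertical. The band excludes apex
#' rounding and foot curvature. A limb with fewer than 3 samples in its
#' band fails, which marks the beat unmeasurable.
#'
#' @param beat A beat from [detect_beats()].
#' @param apex Apex sample index.
#' @param x Channel signal (mV).
#' @param fs Sampling rate (Hz).
#' @param calibration An [ecg_calibration()].
#' @param band Vertical band as fractions of the apex-to-minimum range
#'   (default `c(0.2, 0.8)`).
#' @return List with `up` and `down` limbs, each a list
#'   `(angle_deg, anchor_x_mm, anchor_y_mm)` with y measured from the beat
#'   baseline, or `NULL` on fit failure.
#' @export
fit_limbs <- function(beat, apex, x, fs, calibration = ecg_calibration(),
                      band = c(0.2, 0.8)) {
  stopifnot(length(band) == 2L, band[1L] < band[2L])
  ms_mm <- calibration$ms_per_mm
  mv_mm <- calibration$mV_per_mm
  y_mm <- (x - beat$baseline_mV) / mv_mm
  x_mm <- (seq_along(x) - 1L) / fs * 1000 / ms_mm
  w <- beat$window
  k <- max(1L, round(0.010 * fs))
  xs <- smooth_ma(x, k)
  refine_min <- function(i) {
    lo <- max(1L, i - k); hi <- min(length(x), i + k)
    (lo:hi)[which.min(x[lo:hi])]
  }
  mins_before <- prominent_minima(xs, max(w[1L], beat$r_peak), apex - 1L,
                                  prom = 0.05)
  mins_after <- prominent_minima(xs, apex + 1L, w[2L], prom = 0.05)
  if (!length(mins_before) || !length(mins_after)) return(NULL)
  m_up <- refine_min(mins_before[length(mins_before)])  # preceding minimum
  m_dn <- refine_min(mins_after[1L])                    # following minimum
  if (m_up >= apex || m_dn <= apex) return(NULL)
  # regress voltage on time (time is exact, voltage carries the noise) and
  # convert the mm-frame slope dy/dx to the angle from vertical. Samples are
  # selected into the band by the smoothed trajectory so that inclusion does
  # not correlate with the raw noise (which would flatten the fitted slope).
  ys_mm <- (xs - beat$baseline_mV) / mv_mm
  fit_one <- function(idx_from, idx_to, y_lo, y_hi) {
    idx <- idx_from:idx_to
    sel <- idx[ys_mm[idx] >= y_lo & ys_mm[idx] <= y_hi]
    if (length(sel) < 3L || length(unique(x_mm[sel])) < 2L) return(NULL)
    fit <- stats::lm.fit(cbind(1, x_mm[sel]), y_mm[sel])
    list(slope = unname(fit$coefficients[2L]),
         anchor_x = mean(x_mm[sel]), anchor_y = mean(y_mm[sel]))
  }
  rng_up <- y_mm[apex] - y_mm[m_up]
  up <- fit_one(m_up, apex,
                y_mm[m_up] + band[1L] * rng_up, y_mm[m_up] + band[2L] * rng_up)
  rng_dn <- y_mm[apex] - y_mm[m_dn]
  dn <- fit_one(apex, m_dn,
                y_mm[m_dn] + band[1L] * rng_dn, y_mm[m_dn] + band[2L] * rng_dn)
  if (is.null(up) || is.null(dn)) return(NULL)
  # upslope rises (dy/dx > 0), downslope falls (dy/dx < 0)
  theta_up <- 90 - atan(up$slope) * 180 / pi
  alpha <- 90 - atan(-dn$slope) * 180 / pi
  clip <- function(a, nm) {
    if (a < 0) { warning(nm, " angle below 0 deg; clipped"); 0 }
    else if (a >= 90) { warning(nm, " angle at/above 90 deg; clipped"); 89.999 }
    else a
  }
  list(up = list(angle_deg = clip(theta_up, "upslope"),
                 anchor_x_mm = up$anchor_x, anchor_y_mm = up$anchor_y),
       down = list(angle_deg = clip(alpha, "downslope"),
                   anchor_x_mm = dn$anchor_x, anchor_y_mm = dn$anchor_y))
}

#' Compute the r'-wave triangle geometry from fitted limbs
#'
#' The triangle apex is the intersection of the two fitted limb lines
#' (which may sit slightly above the sampled maximum); the apex height h is
#' measured from this intersection to the isoelectric line. All criteria
#' follow in closed form from the two angles and h.
#'
#' @param limbs Limb pair from [fit_limbs()] (y relative to the isoelectric
#'   line).
#' @param calibration An [ecg_calibration()].
#' @return An object of class `rprime_geometry` with fields `apex_x_mm`,
#'   `apex_y_mm`, `h_mm`, `theta_up_deg`, `alpha_deg`, `beta_deg`,
#'   `dbt5_ms`, `dbtiso_ms`, `ratio`, `measurable`.
#' @export
compute_geometry <- function(limbs, calibration = ecg_calibration()) {
  up <- limbs$up; dn <- limbs$down
  t_up <- tan(up$angle_deg * pi / 180)
  t_dn <- tan(dn$angle_deg * pi / 180)
  denom <- t_up + t_dn
  if (denom < 1e-12)
    stop("limb lines are parallel (both vertical); no apex")
  # upslope: x = ax_u + t_up*(y - ay_u); downslope: x = ax_d - t_dn*(y - ay_d)
  y_apex <- (dn$anchor_x_mm - up$anchor_x_mm +
             t_up * up$anchor_y_mm + t_dn * dn$anchor_y_mm) / denom
  x_apex <- up$anchor_x_mm + t_up * (y_apex - up$anchor_y_mm)
  measurable <- y_apex > 0
  h <- y_apex
  geom <- structure(
    list(apex_x_mm = x_apex, apex_y_mm = y_apex, h_mm = h,
         theta_up_deg = up$angle_deg, alpha_deg = dn$angle_deg,
         beta_deg = up$angle_deg + dn$angle_deg,
         dbt5_ms = calibration$ms_per_mm * 5 * denom,
         dbtiso_ms = calibration$ms_per_mm * h * denom,
         ratio = denom, measurable = measurable),
    class = "rprime_geometry")
  geom
}

#' @export
print.rprime_geometry <- function(x, ...) {
  cat(sprintf(
    "r'-wave geometry: beta %.1f deg (theta %.1f + alpha %.1f), h %.2f mm\n",
    x$beta_deg, x$theta_up_deg, x$alpha_deg, x$h_mm))
  cat(sprintf("  DBT-5mm %.1f ms, DBT-iso %.1f ms, base/height %.2f%s\n",
              x$dbt5_ms, x$dbtiso_ms, x$ratio,
              if (x$measurable) "" else "  [unmeasurable]"))
  invisible(x)
}

#' Extract per-beat r'-wave geometry from a channel
#'
#' Runs the full per-beat pipeline: beat detection, r' candidate location,
#' measurability gating, limb fitting and triangle geometry. Beats without
#' a measurable r' (no candidate, amplitude/descent gate failed, limb fit
#' failed, or apex below the isoelectric line) appear with
#' `measurable = FALSE` and `NA` geometry.
#'
#' @param record An [ecg_record()].
#' @param channel Channel index.
#' @param pre_ms,post_ms,refractory_ms Passed to [detect_beats()].
#' @param band Passed to [fit_limbs()].
#' @return data.frame, one row per beat: `lead`, `ic_level`, `beat_index`,
#'   `beta_deg`, `alpha_deg`, `theta_up_deg`, `h_mm`, `dbt5_ms`,
#'   `dbtiso_ms`, `ratio`, `measurable`.
#' @export
extract_rprime <- function(record, channel = 1L, pre_ms = 80, post_ms = 120,
                           refractory_ms = 200, band = c(0.2, 0.8)) {
  stopifnot(inherits(record, "ecg_record"))
  pl <- record$placements[[channel]]
  x <- record$signals[, channel]
  fs <- record$sampling_rate
  cal <- record$calibration
  beats <- detect_beats(record, channel, pre_ms, post_ms, refractory_ms)
  empty_row <- function(i) data.frame(
    lead = pl$lead, ic_level = pl$ic_level, beat_index = i,
    beta_deg = NA_real_, alpha_deg = NA_real_, theta_up_deg = NA_real_,
    h_mm = NA_real_, dbt5_ms = NA_real_, dbtiso_ms = NA_real_,
    ratio = NA_real_, measurable = FALSE)
  rows <- lapply(seq_along(beats), function(i) {
    beat <- beats[[i]]
    apex <- locate_rprime(beat, x, fs)
    if (is.na(apex)) return(empty_row(i))
    if (apex >= beat$window[2L]) return(empty_row(i))
    height <- x[apex] - beat$baseline_mV
    descent <- x[apex] - min(x[(apex + 1L):beat$window[2L]])
    if (!is_measurable(max(height, 0), max(descent, 0)))
      return(empty_row(i))
    limbs <- fit_limbs(beat, apex, x, fs, cal, band)
    if (is.null(limbs)) return(empty_row(i))
    g <- tryCatch(compute_geometry(limbs, cal), error = function(e) NULL)
    if (is.null(g) || !g$measurable) return(empty_row(i))
    data.frame(lead = pl$lead, ic_level = pl$ic_level, beat_index = i,
               beta_deg = g$beta_deg, alpha_deg = g$alpha_deg,
               theta_up_deg = g$theta_up_deg, h_mm = g$h_mm,
               dbt5_ms = g$dbt5_ms, dbtiso_ms = g$dbtiso_ms,
               ratio = g$ratio, measurable = TRUE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Aggregate per-beat geometry to per-patient features
#'
#' For each lead placement (lead, intercostal level) the criteria are
#' averaged over its measurable beats; the patient's "major" value of each
#' criterion is the maximum of these per-placement means, taken
#' independently per criterion. An intercostal level counts as measurable
#' when any beat in V1 or V2 at that level is measurable.
#'
#' @param beat_geometry data.frame as returned by [extract_rprime()]
#'   (possibly rbind-ed over channels), or an empty data.frame.
#' @return An object of class `patient_features`: list with `beta_deg`,
#'   `alpha_deg`, `dbt5_ms`, `dbtiso_ms`, `ratio` (major values, `NA` when
#'   nothing is measurable), `measurable_by_ic` (named logical for II, III,
#'   IV) and `any_measurable`.
#' @export
aggregate_patient <- function(beat_geometry) {
  crit <- c("beta_deg", "alpha_deg", "dbt5_ms", "dbtiso_ms", "ratio")
  meas_ic <- c(II = FALSE, III = FALSE, IV = FALSE)
  empty <- structure(
    c(stats::setNames(as.list(rep(NA_real_, length(crit))), crit),
      list(measurable_by_ic = meas_ic, any_measurable = FALSE)),
    class = "patient_features")
  if (is.null(beat_geometry) || nrow(beat_geometry) == 0L) return(empty)
  g <- beat_geometry[beat_geometry$measurable %in% TRUE, , drop = FALSE]
  if (nrow(g) == 0L) return(empty)
  for (lvl in unique(as.character(g$ic_level))) meas_ic[lvl] <- TRUE
  key <- interaction(g$lead, g$ic_level, drop = TRUE)
  majors <- lapply(crit, function(cn) {
    max(tapply(g[[cn]], key, mean))
  })
  structure(
    c(stats::setNames(majors, crit),
      list(measurable_by_ic = meas_ic, any_measurable = TRUE)),
    class = "patient_features")
}

#' @export
print.patient_features <- function(x, ...) {
  if (!x$any_measurable) {
    cat("patient features: no measurable r'-wave\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("patient features (major values): beta %.1f deg, ",
                     "alpha %.1f deg,\n  DBT-5mm %.1f ms, DBT-iso %.1f ms, ",
                     "base/height %.2f\n"),
              x$beta_deg, x$alpha_deg, x$dbt5_ms, x$dbtiso_ms, x$ratio))
  cat("  measurable at ic level:",
      paste(names(x$measurable_by_ic)[x$measurable_by_ic], collapse = ", "),
      "\n")
  invisible(x)
}
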