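#' ECG paper calibration
#'
#' Defines the printed-paper coordinate frame in which all r'-wave geometry
#' (angles, triangle base durations) is measured. At the standard calibration
#' of 25 mm/s and 10 mm/mV, 1 mm on paper corresponds to 40 ms horizontally
#' and 0.1 mV vertically. Angle-based criteria depend on this aspect ratio,
#' so the calibration is carried explicitly by every record and geometry
#' computation.
#'
#' @param paper_speed Paper speed in mm per second. Default 25.
#' @param gain Vertical gain in mm per mV. Default 10 (i.e. 1 mV = 1 cm).
#' @return An object of class `ecg_calibration` with fields `paper_speed`,
#'   `gain`, `ms_per_mm` (milliseconds per horizontal mm) and `mV_per_mm`
#'   (millivolts per vertical mm).
#' @examples
#' cal <- ecg_calibration()
#' cal$ms_per_mm  # 40
#' cal$mV_per_mm  # 0.1
#' @export
ecg_calibration <- function(paper_speed = 25, gain = 10) {
  if (!is.numeric(paper_speed) || length(paper_speed) != 1L || paper_speed <= 0)
    stop("`paper_speed` must be a single positive number (mm/s)")
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0)
    stop("`gain` must be a single positive number (mm/mV)")
  structure(
    list(paper_speed = paper_speed, gain = gain,
         ms_per_mm = 1000 / paper_speed, mV_per_mm = 1 / gain),
    class = "ecg_calibration"
  )
}

#' @export
print.ecg_calibration <- function(x, ...) {
  cat(sprintf("ECG calibration: %g mm/s, %g mm/mV (1 mm = %g ms x %g mV)\n",
              x$paper_speed, x$gain, x$ms_per_mm, x$mV_per_mm))
  invisible(x)
}

#' Convert a channel to paper-millimetre coordinates
#'
#' Maps a sampled voltage trace into the calibrated paper frame:
#' `x_mm = t_ms / ms_per_mm`, `y_mm = v_mV / mV_per_mm`. The mapping is
#' linear and invertible (see [from_paper_mm()]).
#'
#' @param record An [ecg_record()].
#' @param channel Channel index (1-based).
#' @return A data.frame with columns `x_mm` and `y_mm`.
#' @export
to_paper_mm <- function(record, channel = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  if (channel < 1L || channel > ncol(record$signals))
    stop("invalid channel index: ", channel)
  cal <- record$calibration
  n <- nrow(record$signals)
  t_ms <- (seq_len(n) - 1L) / record$sampling_rate * 1000
  data.frame(x_mm = t_ms / cal$ms_per_mm,
             y_mm = record$signals[, channel] / cal$mV_per_mm)
}

#' Invert the paper-mm mapping
#'
#' @param xy_mm data.frame with columns `x_mm`, `y_mm` as produced by
#'   [to_paper_mm()].
#' @param calibration An [ecg_calibration()].
#' @return data.frame with columns `t_ms`, `v_mV`.
#' @export
from_paper_mm <- function(xy_mm, calibration = ecg_calibration()) {
  stopifnot(inherits(calibration, "ecg_calibration"))
  data.frame(t_ms = xy_mm$x_mm * calibration$ms_per_mm,
             v_mV = xy_mm$y_mm * calibration$mV_per_mm)
}
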