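#' Lead placement descriptor
#'
#' The right precordial leads V1 and V2 can be recorded at the standard
#' fourth intercostal space or at the higher third and second spaces; higher
#' placements increase the detectability of the r'-wave. A placement is the
#' pair (lead, intercostal level).
#'
#' @param lead "V1" or "V2".
#' @param ic_level Intercostal level: "II", "III" or "IV".
#' @return An object of class `lead_placement`.
#' @examples
#' lead_placement("V1", "IV")
#' @export
lead_placement <- function(lead, ic_level) {
  lead <- match.arg(toupper(lead), c("V1", "V2"))
  ic_level <- match.arg(toupper(ic_level), c("II", "III", "IV"))
  structure(list(lead = lead, ic_level = ic_level), class = "lead_placement")
}

#' @export
print.lead_placement <- function(x, ...) {
  cat(sprintf("%s @ %s intercostal space\n", x$lead, x$ic_level))
  invisible(x)
}

# Accepts a lead_placement or a compact "V1@IV" string.
as_lead_placement <- function(x) {
  if (inherits(x, "lead_placement")) return(x)
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(x, "@", fixed = TRUE)[[1L]]
    if (length(parts) == 2L) return(lead_placement(parts[1L], parts[2L]))
  }
  stop("cannot interpret lead placement: ", deparse(x))
}

placement_key <- function(p) paste0(p$lead, "@", p$ic_level)

#' Calibrated multi-lead ECG record
#'
#' Container for a uniformly sampled, voltage-calibrated ECG trace with lead
#' placement metadata. Voltages are always stored in mV; all geometry is
#' computed in the paper-mm frame defined by the attached calibration.
#'
#' @param signals Numeric matrix, one column per channel, in mV.
#' @param sampling_rate Sampling rate in Hz; must be at least 250 Hz so that
#'   limb slopes can be estimated from several samples.
#' @param placements List of [lead_placement()] (or "V1@IV"-style strings),
#'   one per channel.
#' @param calibration An [ecg_calibration()].
#' @param patient_id Opaque patient identifier.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signals, sampling_rate, placements,
                       calibration = ecg_calibration(),
                       patient_id = "unknown") {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (!all(is.finite(signals))) stop("signal voltages must be finite")
  if (sampling_rate < 250)
    stop("sampling rate ", sampling_rate,
         " Hz is below the supported minimum of 250 Hz")
  placements <- lapply(placements, as_lead_placement)
  if (length(placements) != ncol(signals))
    stop("need one lead placement per channel")
  structure(
    list(signals = signals, sampling_rate = sampling_rate,
         placements = placements, calibration = calibration,
         patient_id = as.character(patient_id),
         duration = nrow(signals) / sampling_rate),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record '%s': %d channel(s), %g Hz, %.2f s\n",
              x$patient_id, ncol(x$signals), x$sampling_rate, x$duration))
  for (i in seq_along(x$placements))
    cat(sprintf("  [%d] %s@%s\n", i, x$placements[[i]]$lead,
                x$placements[[i]]$ic_level))
  invisible(x)
}

#' Read an ECG record from CSV or WFDB
#'
#' CSV input must have a time column (first column; seconds or milliseconds,
#' auto-detected from the median step: a step below 0.1 is taken as seconds)
#' and one voltage column per lead, in mV. WFDB input is a header/signal
#' file pair (format 16). Channels not covered by `lead_map` are skipped
#' with a warning; non-uniform time steps and sampling rates below 250 Hz
#' are rejected.
#'
#' @param path File path (for WFDB, the `.hea` header or the record name).
#' @param format "csv" or "wfdb".
#' @param lead_map Named list mapping channel names (CSV column names or
#'   WFDB signal descriptions) to [lead_placement()] objects or "V1@IV"
#'   strings.
#' @param calibration An [ecg_calibration()].
#' @param patient_id Patient identifier; defaults to the file base name.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"), lead_map,
                        calibration = ecg_calibration(), patient_id = NULL) {
  format <- match.arg(format)
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv")
    read_record_csv(path, lead_map, calibration, patient_id)
  else
    read_record_wfdb(path, lead_map, calibration, patient_id)
}

read_record_csv <- function(path, lead_map, calibration, patient_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2L) stop("CSV must have a time column and >=1 lead column")
  tt <- as.numeric(tab[[1L]])
  steps <- diff(tt)
  if (length(steps) < 1L || any(steps <= 0))
    stop("non-uniform sampling: time column must be strictly increasing")
  med <- stats::median(steps)
  if (any(abs(steps - med) > pmax(1e-9, 1e-4 * med)))
    stop("non-uniform sampling: irregular time steps detected")
  step_s <- if (med < 0.1) med else med / 1000  # autodetect s vs ms
  fs <- 1 / step_s
  keep <- intersect(names(tab)[-1L], names(lead_map))
  skipped <- setdiff(names(tab)[-1L], names(lead_map))
  if (length(skipped))
    warning("skipping unmapped channel(s): ", paste(skipped, collapse = ", "))
  if (!length(keep)) stop("lead_map covers no channel in ", path)
  sig <- as.matrix(tab[keep])
  ecg_record(sig, fs, lead_map[keep], calibration, patient_id)
}

#' Write an ECG record to CSV
#'
#' One time column (seconds) plus one mV column per channel, named by
#' placement ("V1@IV", ...).
#'
#' @param record An [ecg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  n <- nrow(record$signals)
  out <- data.frame(time_s = (seq_len(n) - 1L) / record$sampling_rate)
  for (i in seq_along(record$placements))
    out[[placement_key(record$placements[[i]])]] <- record$signals[, i]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# --- Minimal WFDB support (header + format-16 signal file) ------------------
# Covers single-segment records with all signals interleaved in one .dat
# file, 16-bit little-endian samples, gain in adu/mV. Sufficient for
# round-tripping digitized strips; other storage formats are rejected.

read_record_wfdb <- function(path, lead_map, calibration, patient_id) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  head_fields <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(head_fields[2L])
  fs <- as.numeric(head_fields[3L])
  nsamp <- as.integer(head_fields[4L])
  sig_lines <- lines[seq_len(nsig) + 1L]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    gain_spec <- f[3L]
    baseline <- 0
    gain_part <- sub("/.*$", "", gain_spec)
    if (grepl("\\(", gain_part)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gain_part))
      gain_part <- sub("\\(.*$", "", gain_part)
    }
    list(file = f[1L], fmt = f[2L], gain = as.numeric(gain_part),
         baseline = baseline,
         desc = if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ")
                else NA_character_)
  }
  sigs <- lapply(sig_lines, parse_sig)
  for (i in seq_len(nsig))
    if (is.na(sigs[[i]]$desc)) sigs[[i]]$desc <- paste0("sig", i)
  if (!all(vapply(sigs, function(s) s$fmt, "") == "16"))
    stop("only WFDB format 16 is supported")
  dat_files <- unique(vapply(sigs, function(s) s$file, ""))
  if (length(dat_files) != 1L)
    stop("only single signal-file WFDB records are supported")
  dat_path <- file.path(dirname(hea), dat_files)
  if (!file.exists(dat_path)) stop("file not found: ", dat_path)
  raw <- readBin(dat_path, what = "integer", n = nsig * nsamp,
                 size = 2L, signed = TRUE, endian = "little")
  mat <- matrix(as.double(raw), ncol = nsig, byrow = TRUE)
  for (i in seq_len(nsig))
    mat[, i] <- (mat[, i] - sigs[[i]]$baseline) / sigs[[i]]$gain
  descs <- vapply(sigs, function(s) s$desc, "")
  colnames(mat) <- descs
  keep <- intersect(descs, names(lead_map))
  skipped <- setdiff(descs, names(lead_map))
  if (length(skipped))
    warning("skipping unmapped channel(s): ", paste(skipped, collapse = ", "))
  if (!length(keep)) stop("lead_map covers no channel in ", hea)
  ecg_record(mat[, keep, drop = FALSE], fs, lead_map[keep],
             calibration, patient_id)
}

#' Write an ECG record as a WFDB record (format 16)
#'
#' @param record An [ecg_record()].
#' @param path Record path without extension; writes `path.hea` and
#'   `path.dat`.
#' @param gain ADC gain in adu per mV (default 200).
#' @return The header path, invisibly.
#' @export
write_record_wfdb <- function(record, path, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  nsig <- ncol(record$signals)
  nsamp <- nrow(record$signals)
  rec_name <- basename(path)
  adu <- round(record$signals * gain)
  if (any(abs(adu) > 32767))
    stop("signal exceeds 16-bit range at gain ", gain, " adu/mV")
  hea <- c(sprintf("%s %d %g %d", rec_name, nsig, record$sampling_rate, nsamp),
           vapply(seq_len(nsig), function(i) {
             sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
                     rec_name, gain, as.integer(adu[1L, i]),
                     placement_key(record$placements[[i]]))
           }, ""))
  writeLines(hea, paste0(path, ".hea"))
  inter <- as.integer(t(adu))  # sample-interleaved
  writeBin(inter, paste0(path, ".dat"), size = 2L, endian = "little")
  invisible(paste0(path, ".hea"))
}

# --- Per-patient feature tables ---------------------------------------------

feature_columns <- c("patient_id", "beta_deg", "alpha_deg", "dbt5_ms",
                     "dbtiso_ms", "ratio", "measurable_ii", "measurable_iii",
                     "measurable_iv", "scbpt_label")

#' Write a per-patient feature table
#'
#' Writes one row per patient with the documented column order:
#' `patient_id, beta_deg, alpha_deg, dbt5_ms, dbtiso_ms, ratio,
#' measurable_ii, measurable_iii, measurable_iv, scbpt_label`. Values that
#' could not be measured (no measurable r'-wave) are written as empty
#' fields, never as zeros.
#'
#' @param features data.frame with (a subset of) the documented columns;
#'   `patient_id` is required.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  if (!is.data.frame(features) || nrow(features) == 0L)
    stop("`features` must be a non-empty data.frame")
  if (!"patient_id" %in% names(features))
    stop("`features` must have a patient_id column")
  out <- features
  for (col in setdiff(feature_columns, names(out))) out[[col]] <- NA
  out <- out[feature_columns]
  for (col in c("measurable_ii", "measurable_iii", "measurable_iv"))
    out[[col]] <- as.logical(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-patient feature table
#'
#' Inverse of [write_features()]; empty fields become `NA`.
#'
#' @param path CSV path.
#' @return data.frame with the documented feature columns.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, na.strings = "",
                         colClasses = c(patient_id = "character"))
  missing_cols <- setdiff(feature_columns, names(tab))
  if (length(missing_cols))
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("measurable_ii", "measurable_iii", "measurable_iv"))
    tab[[col]] <- as.logical(tab[[col]])
  tab[feature_columns]
}
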