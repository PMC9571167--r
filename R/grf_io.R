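#' Construct a GRF trial
#'
#' A trial is a tibble with one row per sample: a `time` column (seconds,
#' uniform spacing `1/fs`) plus force channels `R1..R5` and `L1..L5` (one per
#' insole sensor, same order as the layout labels). Forces must be
#' non-negative; negative readings (FSR noise) are clamped to zero with a
#' warning that counts the affected samples.
#'
#' @param data Data frame with columns `time, R1..R5, L1..L5`.
#' @param fs Sampling rate in Hz (default 100).
#' @param subject_id Optional subject identifier.
#' @param group One of `"healthy"`, `"stroke"`, `"unknown"`.
#' @return A tibble of class `grf_trial` with attributes `fs`, `subject_id`,
#'   `group`.
#' @export
grf_trial <- function(data, fs = 100, subject_id = NA_character_,
                      group = c("unknown", "healthy", "stroke")) {
  group <- match.arg(group)
  cols <- trial_columns()
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(paste0("trial is missing columns: ", paste(missing, collapse = ", ")),
          class = "gaitpolar_format_error")
  }
  data <- tibble::as_tibble(data)[cols]
  if (nrow(data) == 0L) abort("empty trial (0 samples)", class = "gaitpolar_format_error")
  if (!is.finite(fs) || fs <= 0) abort("fs must be > 0", class = "gaitpolar_format_error")
  dt <- diff(data$time)
  if (nrow(data) > 1L && any(abs(dt - 1 / fs) > 0.01 / fs)) {
    abort("non-uniform sample times (spacing deviates from 1/fs by > 1%)",
          class = "gaitpolar_timing_error")
  }
  force_cols <- setdiff(cols, "time")
  fmat <- as.matrix(data[force_cols])
  if (any(!is.finite(fmat))) abort("non-finite force values", class = "gaitpolar_format_error")
  n_neg <- sum(fmat < 0)
  if (n_neg > 0) {
    warn(paste0("clamped ", n_neg, " negative force reading(s) to 0"),
         class = "gaitpolar_clamp_warning")
    fmat[fmat < 0] <- 0
    data[force_cols] <- tibble::as_tibble(fmat)
  }
  structure(data,
            class = c("grf_trial", class(tibble::tibble()))) |>
    set_trial_attrs(fs = fs, subject_id = subject_id, group = group)
}

set_trial_attrs <- function(x, fs, subject_id, group) {
  attr(x, "fs") <- fs
  attr(x, "subject_id") <- subject_id
  attr(x, "group") <- group
  x
}

trial_columns <- function() c("time", paste0("R", 1:5), paste0("L", 1:5))

#' @export
print.grf_trial <- function(x, ...) {
  cat("<grf_trial> ", nrow(x), " samples @ ", attr(x, "fs"), " Hz",
      if (!is.na(attr(x, "subject_id"))) paste0(", subject ", attr(x, "subject_id")),
      ", group ", attr(x, "group"), "\n", sep = "")
  NextMethod()
}

#' Read / write a GRF trial CSV
#'
#' The CSV dialect is comma-separated UTF-8 with a required header
#' `time,R1,R2,R3,R4,R5,L1,L2,L3,L4,L5`; time is in seconds in column 1.
#' `write_trial()` keeps full float precision so that
#' `read_trial(write_trial(x))` reproduces `x` to machine precision.
#'
#' @param path CSV file path.
#' @param layout `sensor_layout` used to validate the channel count.
#' @param fs Sampling rate (Hz); checked against the time column.
#' @param subject_id,group Passed to [grf_trial()].
#' @return `read_trial()` returns a `grf_trial`; `write_trial()` returns
#'   `path` invisibly.
#' @export
read_trial <- function(path, layout = default_sensor_layout(), fs = 100,
                       subject_id = NA_character_, group = "unknown") {
  if (!file.exists(path)) abort(paste0("trial file not found: ", path), class = "gaitpolar_io_error")
  stopifnot(inherits(layout, "sensor_layout"))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  grf_trial(df, fs = fs, subject_id = subject_id, group = group)
}

#' @rdname read_trial
#' @param trial A `grf_trial`.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "grf_trial"))
  if (nrow(trial) == 0L) abort("refusing to write an empty trial", class = "gaitpolar_format_error")
  readr::write_csv(tibble::as_tibble(trial), path, progress = FALSE)
  invisible(path)
}
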