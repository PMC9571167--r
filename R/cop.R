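#' Signed medial-lateral centre of pressure (COPx)
#'
#' Pools all ten sensors (both feet, signed coordinates) and computes, per
#' sample,
#' \deqn{COPx = \frac{\sum_i F_i x_i}{\sum_i F_i} \cdot \frac{100}{x_{5th\,meta}}}
#' so the result is a percentage of the fifth-metatarsal coordinate. Because
#' right-foot coordinates are positive and left-foot ones negative, the sign
#' of COPx encodes the stance side: positive during right-foot stance,
#' negative during left-foot stance, yielding one signed, sinusoid-like
#' waveform per stride.
#'
#' Samples whose total force falls at or below `force_floor` (flight or idle
#' insole) are flagged invalid and carry forward the last valid COPx value.
#'
#' @param trial A [grf_trial()].
#' @param layout A [sensor_layout()] matching the trial's channels.
#' @param force_floor Total-force floor below which a sample is invalid.
#'   Default: 2% of the trial's 95th-percentile total force.
#' @return A tibble of class `copx_series` with columns `t`, `copx`
#'   (signed %), `valid`; attribute `fs`.
#' @examples
#' tr <- generate_trial(gait_template(n_strides = 5, seed = 1))$trial
#' cop <- compute_copx(tr)
#' range(cop$copx)
#' @export
compute_copx <- function(trial, layout = default_sensor_layout(), force_floor = NULL) {
  stopifnot(inherits(trial, "grf_trial"), inherits(layout, "sensor_layout"))
  fmat <- as.matrix(tibble::as_tibble(trial)[setdiff(trial_columns(), "time")])
  xi <- c(layout$positions_right, layout$positions_left)
  total <- rowSums(fmat)
  if (is.null(force_floor)) {
    force_floor <- 0.02 * quantile(total, 0.95, names = FALSE)
  }
  if (force_floor < 0) abort("force_floor must be >= 0", class = "gaitpolar_format_error")
  valid <- total > force_floor
  if (!any(valid)) abort("no stance detected: all samples below the force floor",
                         class = "gaitpolar_signal_error")
  copx <- rep(NA_real_, length(total))
  copx[valid] <- (fmat[valid, , drop = FALSE] %*% xi) / total[valid] * 100 / layout$x5th_meta
  # carry the last valid value across invalid gaps (leading gap: first valid value)
  filled <- copx
  idx <- cumsum(valid)
  first_valid <- which(valid)[1]
  filled[idx == 0] <- copx[first_valid]
  pos <- which(valid)
  filled[!valid & idx > 0] <- copx[pos][idx[!valid & idx > 0]]
  structure(
    tibble::tibble(t = trial$time, copx = filled, valid = valid),
    class = c("copx_series", class(tibble::tibble())),
    fs = attr(trial, "fs")
  )
}

#' Maximal constant-sign stance segments of a COPx series
#'
#' Partitions the series into maximal runs of constant COPx sign; positive
#' runs are right-foot stance (`side = "R"`), negative runs left-foot stance
#' (`"L"`). Exactly-zero samples attach to the following run (deterministic
#' tie-break); leading zeros attach to the first signed run.
#'
#' @param cop A `copx_series`.
#' @return Tibble with columns `side`, `start`, `end` (sample indices,
#'   inclusive); zero rows if the series never takes a sign.
#' @export
stance_sign_segments <- function(cop) {
  stopifnot(inherits(cop, "copx_series"))
  s <- sign(cop$copx)
  # zeros take the sign of the next signed sample
  nz <- s != 0
  if (!any(nz)) return(tibble::tibble(side = character(), start = integer(), end = integer()))
  nxt <- rev(cummin(rev(ifelse(nz, seq_along(s), Inf))))
  nxt[!is.finite(nxt)] <- max(which(nz)) # trailing zeros attach to the last run
  s <- s[nxt]
  r <- rle(s)
  stop_i <- cumsum(r$lengths)
  start_i <- stop_i - r$lengths + 1L
  tibble::tibble(
    side = ifelse(r$values > 0, "R", "L"),
    start = start_i,
    end = stop_i
  )
}
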