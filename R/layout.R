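#' Sensor layout for a five-sensor insole pair
#'
#' A layout records the signed medial-lateral coordinate of each insole
#' pressure sensor in the subject frame: lateral is positive for the right
#' foot and negative for the left. The fifth-metatarsal sensor is the
#' outermost one; its coordinate magnitude (`x5th_meta`) normalises the
#' centre of pressure so that a fully fifth-metatarsal-loaded right foot
#' reads COPx = 100%.
#'
#' @param positions_right Numeric vector of 5 signed medial-lateral sensor
#'   coordinates (mm) for the right foot, ordered as `labels`.
#' @param positions_left Coordinates for the left foot; defaults to the
#'   sign-mirrored right-foot coordinates.
#' @param labels Anatomical sensor names; must contain `"heel"` (used by
#'   heel-strike detection).
#' @return An object of class `sensor_layout`: a list with fields
#'   `positions_right`, `positions_left`, `x5th_meta`, `labels`.
#' @examples
#' layout <- default_sensor_layout()
#' layout$x5th_meta
#' @export
sensor_layout <- function(positions_right,
                          positions_left = -positions_right,
                          labels = c("big_toe", "met1", "met5", "cuboid", "heel")) {
  positions_right <- as.numeric(positions_right)
  positions_left <- as.numeric(positions_left)
  if (length(positions_right) != 5L || length(positions_left) != 5L) {
    abort("a sensor layout needs exactly 5 coordinates per foot", class = "gaitpolar_format_error")
  }
  if (length(labels) != 5L || !"heel" %in% labels) {
    abort("layout labels must name 5 sensors and include 'heel'", class = "gaitpolar_format_error")
  }
  if (any(!is.finite(positions_right)) || any(!is.finite(positions_left))) {
    abort("sensor coordinates must be finite", class = "gaitpolar_format_error")
  }
  if (!all(abs(positions_left + positions_right) < 1e-9)) {
    warn("positions_left is not the exact mirror of positions_right")
  }
  x5 <- abs(positions_right[match("met5", labels) %||% 3L])
  if (!"met5" %in% labels) x5 <- max(abs(positions_right))
  if (x5 <= 0) abort("fifth-metatarsal coordinate must be non-zero", class = "gaitpolar_format_error")
  structure(
    list(
      positions_right = positions_right,
      positions_left = positions_left,
      x5th_meta = x5,
      labels = labels
    ),
    class = "sensor_layout"
  )
}

#' Default synthetic insole layout
#'
#' Coordinates (mm, medial-lateral) for an adult-sized insole with sensors on
#' the big toe, first metatarsal, fifth metatarsal, cuboid and heel. The
#' magnitudes are chosen so the lateral COP sweep during stance (heel ->
#' cuboid/fifth metatarsal -> first metatarsal -> toe) is time-symmetric,
#' which makes the pooled COPx of a symmetric stride sinusoid-like. Real
#' studies scale coordinates to the wearer's foot; any user-supplied layout
#' can be used instead via [sensor_layout()] or [read_layout()].
#'
#' @return A `sensor_layout`.
#' @export
default_sensor_layout <- function() {
  sensor_layout(positions_right = c(big_toe = 20, met1 = 36, met5 = 48, cuboid = 36, heel = 20))
}

#' Read or write a sensor layout as JSON
#'
#' The JSON carries `positions_right`, `positions_left`, `x5th_meta` and
#' `labels` explicitly, keeping trials self-contained.
#'
#' @param path File path.
#' @return `read_layout()` returns a `sensor_layout`; `write_layout()` returns
#'   `path` invisibly.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) abort(paste0("layout file not found: ", path), class = "gaitpolar_io_error")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("positions_right", "positions_left", "labels")) {
    if (is.null(x[[f]])) abort(paste0("layout JSON missing field '", f, "'"), class = "gaitpolar_format_error")
  }
  sensor_layout(x$positions_right, x$positions_left, labels = x$labels)
}

#' @rdname read_layout
#' @param layout A `sensor_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "sensor_layout"))
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat("<sensor_layout> 5 sensors/foot, x5th_meta =", x$x5th_meta, "mm\n")
  cat("  right:", paste0(x$labels, "=", x$positions_right, collapse = " "), "\n")
  cat("  left: ", paste0(x$labels, "=", x$positions_left, collapse = " "), "\n")
  invisible(x)
}
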