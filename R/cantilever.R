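#' Cantilever specification
#'
#' Describes the microcantilever used to confine a cell: its spring constant,
#' the mounting tilt of the instrument, whether the lever carries a polymer
#' wedge cancelling that tilt (true parallel-plate confinement), and optionally
#' the optical-lever deflection sensitivity used to convert photodiode voltage
#' into force.
#'
#' @param k Spring constant in N/m. The screens here were run with nominally
#'   0.3 N/m tipless levers.
#' @param tilt_deg Mounting tilt of the cantilever in degrees (default 10,
#'   the fixed tilt of the rig the assay was developed on). Ignored for
#'   wedged levers.
#' @param wedged Logical; `TRUE` when the lever carries a wedge that cancels
#'   the tilt, giving parallel-plate confinement.
#' @param deflection_sensitivity Optional optical lever sensitivity in m/V;
#'   required only when traces are recorded as photodiode voltage.
#'
#' @return An object of class `cantilever_spec`.
#' @examples
#' cantilever_spec(k = 0.3)
#' cantilever_spec(k = 0.3, wedged = TRUE)
#' @export
cantilever_spec <- function(k = 0.3, tilt_deg = 10, wedged = FALSE,
                            deflection_sensitivity = NULL) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    abort("`k` must be a single positive number (N/m).",
          class = "mitomech_invalid_input")
  }
  if (!is.numeric(tilt_deg) || length(tilt_deg) != 1L ||
      tilt_deg < 0 || tilt_deg >= 90) {
    abort("`tilt_deg` must lie in [0, 90).", class = "mitomech_invalid_input")
  }
  if (!is.null(deflection_sensitivity)) {
    if (!is.numeric(deflection_sensitivity) || length(deflection_sensitivity) != 1L ||
        deflection_sensitivity <= 0) {
      abort("`deflection_sensitivity` must be a single positive number (m/V).",
            class = "mitomech_invalid_input")
    }
  }
  structure(
    list(k = k, tilt_deg = tilt_deg, wedged = isTRUE(wedged),
         deflection_sensitivity = deflection_sensitivity),
    class = "cantilever_spec"
  )
}

#' @export
print.cantilever_spec <- function(x, ...) {
  cat("<cantilever_spec>\n")
  cat(sprintf("  k: %g N/m; tilt: %g deg; wedged: %s\n",
              x$k, x$tilt_deg, x$wedged))
  if (!is.null(x$deflection_sensitivity)) {
    cat(sprintf("  deflection sensitivity: %g m/V\n", x$deflection_sensitivity))
  }
  invisible(x)
}
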