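#' Midplane radius from cross-sectional area
#'
#' Converts the measured midplane cross-sectional area of a confined cell into
#' the corresponding midplane radius. Two conventions are exposed: `"circle"`
#' (the area of a circle, `A_m = pi * r_m^2`, the default) and `"as_printed"`
#' (`A_m = 2 * pi * r_m^2`), which some published descriptions of the
#' cortical-shell model use. The factor only rescales radii by `sqrt(2)` and
#' cancels in any treated-vs-control comparison; `"circle"` is the
#' geometrically consistent choice and the default throughout this package.
#'
#' @param A_m Midplane cross-sectional area in um^2 (vectorized).
#' @param convention `"circle"` or `"as_printed"`.
#' @return Midplane radius `r_m` in um.
#' @examples
#' radius_from_midplane_area(25 * pi)            # 5 um
#' radius_from_midplane_area(50 * pi, "as_printed")
#' @export
radius_from_midplane_area <- function(A_m, convention = c("circle", "as_printed")) {
  convention <- match.arg(convention)
  if (!is.numeric(A_m) || any(!is.finite(A_m)) || any(A_m <= 0)) {
    abort("`A_m` must be positive and finite (um^2).",
          class = "mitomech_invalid_input")
  }
  denom <- if (convention == "circle") pi else 2 * pi
  sqrt(A_m / denom)
}

#' Cell height at the center axis
#'
#' The preset cantilever height is corrected for the force-induced cantilever
#' deflection (`F/k`) and, for non-wedged levers, for the instrument tilt: a
#' lever tilted by `tilt_deg` sits higher at the cell center than at its tip by
#' `tan(tilt) * (r_m + x)`, where `x` is the distance from the lever tip to the
#' cell edge. Wedged levers realize true parallel-plate confinement and need no
#' tilt term.
#'
#' @param h_set Preset cantilever height in um.
#' @param F Rounding force in N (vectorized with `h_set`, `r_m`, `x`).
#' @param spec A [cantilever_spec()].
#' @param r_m Midplane radius in um (ignored for wedged levers).
#' @param x Tip-to-cell-edge distance in um (0 for wedged levers).
#' @return Corrected cell height `h` in um.
#' @examples
#' spec <- cantilever_spec(k = 0.3)
#' cell_height(14, 60e-9, spec, r_m = 10, x = 15)
#' @export
cell_height <- function(h_set, F, spec, r_m = 0, x = 0) {
  stopifnot(inherits(spec, "cantilever_spec"))
  if (any(!is.finite(h_set)) || any(h_set <= 0)) {
    abort("`h_set` must be positive (um).", class = "mitomech_invalid_input")
  }
  if (any(!is.finite(F)) || any(F < 0)) {
    abort("`F` must be non-negative (N).", class = "mitomech_invalid_input")
  }
  deflection_um <- F / spec$k * 1e6   # m -> um
  h <- h_set + deflection_um
  if (!spec$wedged) {
    h <- h + tan(spec$tilt_deg * pi / 180) * (r_m + x)
  }
  h
}

#' Contact radius and contact area
#'
#' Under the circular-side-profile idealization the cell touches the plates on
#' a disk of radius `r_c = r_m - h/2`. Tangency (`r_m = h/2`) yields a zero
#' contact radius; `r_m < h/2` means the cell cannot span the confinement and
#' is an error.
#'
#' @param r_m Midplane radius in um (vectorized).
#' @param h Cell height in um.
#' @return A tibble with columns `r_c` (um) and `A_c` (um^2).
#' @examples
#' contact_geometry(10, 10)
#' @export
contact_geometry <- function(r_m, h) {
  if (any(!is.finite(h)) || any(h <= 0)) {
    abort("`h` must be positive (um).", class = "mitomech_invalid_input")
  }
  if (any(r_m < h / 2)) {
    abort("cell does not span confinement: r_m < h/2.",
          class = "mitomech_impossible_geometry")
  }
  r_c <- r_m - h / 2
  tibble(r_c = r_c, A_c = pi * r_c^2)
}

#' Rounding pressure from force and contact area
#'
#' Law-of-Laplace readout: the excess intracellular pressure equals the
#' rounding force divided by the cell-cantilever contact area.
#'
#' @param F Rounding force in N (vectorized).
#' @param A_c Contact area in um^2.
#' @return Pressure `P` in Pa.
#' @examples
#' rounding_pressure(50e-9, pi * 5^2)
#' @export
rounding_pressure <- function(F, A_c) {
  if (any(!is.finite(A_c)) || any(A_c <= 0)) {
    abort("undefined pressure: contact area must be positive (cell not in contact).",
          class = "mitomech_no_contact")
  }
  F / (A_c * 1e-12)   # um^2 -> m^2
}

#' Volume of a plate-confined cell with circular side profiles
#'
#' The confined cell is modelled as a cylinder of radius `r_c` and height `h`
#' plus the rim swept by a half-disk of radius `r = h/2` revolved about the
#' cell axis (Pappus' second centroid theorem):
#' `V = pi*h*r_c^2 + 2*pi*(r_c + 4r/(3*pi)) * (pi*r^2/2)`.
#' At tangency (`r_m = h/2`) this collapses exactly to the sphere volume.
#'
#' @param r_m Midplane radius in um (vectorized with `h`).
#' @param h Cell height in um.
#' @return Cell volume `V` in um^3.
#' @examples
#' cell_volume(10, 10)
#' cell_volume(5, 10)   # sphere of radius 5
#' @export
cell_volume <- function(r_m, h) {
  if (any(!is.finite(h)) || any(h <= 0)) {
    abort("`h` must be positive (um).", class = "mitomech_invalid_input")
  }
  if (any(r_m < h / 2)) {
    abort("impossible geometry: r_m < h/2.",
          class = "mitomech_impossible_geometry")
  }
  r <- h / 2
  r_c <- r_m - r
  pi * h * r_c^2 + 2 * pi * (r_c + 4 * r / (3 * pi)) * (pi * r^2 / 2)
}

#' Contact radius from volume and height
#'
#' Inverts [cell_volume()] at a fixed height: given the cell volume and the
#' confinement height, returns the unique non-negative contact radius. With
#' `r = h/2` the volume is a quadratic in `r_c`,
#' `pi*h*r_c^2 + pi^2*r^2*r_c + (4/3)*pi*r^3 - V = 0`,
#' solved in closed form. Volumes below the tangent-sphere bound
#' `(4/3)*pi*(h/2)^3` are unreachable at that height.
#'
#' @param V Cell volume in um^3 (vectorized with `h`).
#' @param h Cell height in um.
#' @return Contact radius `r_c` in um.
#' @examples
#' invert_volume(cell_volume(10, 10), 10)   # 5
#' @export
invert_volume <- function(V, h) {
  if (any(!is.finite(h)) || any(h <= 0)) {
    abort("`h` must be positive (um).", class = "mitomech_invalid_input")
  }
  r <- h / 2
  v_sphere <- (4 / 3) * pi * r^3
  if (any(V < v_sphere * (1 - 1e-12))) {
    abort("height unreachable: volume below the tangent-sphere bound.",
          class = "mitomech_height_unreachable")
  }
  a <- pi * h
  b <- pi^2 * r^2
  cc <- pmin(v_sphere - V, 0)   # clamp tiny positive residue at tangency
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

#' Per-cell mechanics from equilibrium force and midplane area
#'
#' The tidy front end to the geometry chain. Takes a data frame with one row
#' per measured cell and columns `F_eq_N` (equilibrium rounding force, N),
#' `A_m_um2` (midplane cross-sectional area, um^2), `h_set_um` (preset
#' cantilever height, um) and optionally `x_um` (tip-to-cell-edge distance,
#' um; taken as 0 when absent, as for wedged levers), and appends the derived
#' geometry and physics: `r_m_um`, `h_um`, `r_c_um`, `A_c_um2`, `P_Pa`,
#' `V_um3`.
#'
#' @param cells Data frame of per-cell measurements (see Details).
#' @param spec A [cantilever_spec()] shared by all rows.
#' @param convention Midplane area convention, see
#'   [radius_from_midplane_area()].
#' @return The input as a tibble with derived columns appended.
#' @examples
#' spec <- cantilever_spec(k = 0.3, wedged = TRUE)
#' cells <- tibble::tibble(F_eq_N = 5e-8, A_m_um2 = 320, h_set_um = 12)
#' compute_mechanics(cells, spec)
#' @export
compute_mechanics <- function(cells, spec,
                              convention = c("circle", "as_printed")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(cells), inherits(spec, "cantilever_spec"))
  needed <- c("F_eq_N", "A_m_um2", "h_set_um")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "mitomech_invalid_input")
  }
  cells <- as_tibble(cells)
  x_um <- if ("x_um" %in% names(cells)) cells$x_um else 0
  r_m <- radius_from_midplane_area(cells$A_m_um2, convention)
  h <- cell_height(cells$h_set_um, cells$F_eq_N, spec, r_m = r_m, x = x_um)
  cg <- contact_geometry(r_m, h)
  dplyr::mutate(
    cells,
    r_m_um = r_m,
    h_um = h,
    r_c_um = cg$r_c,
    A_c_um2 = cg$A_c,
    P_Pa = rounding_pressure(.data$F_eq_N, cg$A_c),
    V_um3 = cell_volume(r_m, h)
  )
}
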