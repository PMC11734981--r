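# Tumor readouts: surface coverage, tumor radius, healthy-tissue recession,
# plus the conservation diagnostics tracked along a run.

#' Surface coverage
#'
#' The fraction of the tissue domain occupied by cancer cells:
#' `SC = (1/S) integral of theta_c dA`, evaluated by grid quadrature
#' (`(2/R^2) int theta_c r dr` in the radial reduction).  Reported as a
#' fraction; multiply by 100 for the percent scale used in output tables.
#'
#' @param theta_c_field Cancer volume fraction per cell.
#' @param grid A `crtsim_grid`.
#' @return Value in `[0, 1]`.
#' @export
surface_coverage <- function(theta_c_field, grid) {
  grid_integrate(theta_c_field, grid) / (pi * grid$R_tissue^2)
}

#' Tumor radius
#'
#' The outermost radius at which the cancer volume fraction reaches the
#' critical value (default 0.01), located by linear interpolation between
#' adjacent cell centers.  If no cell reaches the threshold the radius is 0
#' and the result carries attribute `detected = FALSE`.
#'
#' @param theta_c_field Cancer volume fraction per cell.
#' @param grid A `crtsim_grid`.
#' @param threshold Detection threshold on `theta_c`.
#' @return Radius (length units) with attribute `detected`.
#' @export
tumor_radius <- function(theta_c_field, grid, threshold = 0.01) {
  r <- grid$cell_centers
  above <- theta_c_field >= threshold
  if (!any(above)) {
    return(structure(0, detected = FALSE))
  }
  k <- max(which(above))  # outermost cell at or above threshold
  if (k == grid$n) {
    return(structure(r[k], detected = TRUE))
  }
  # crossing between centers k and k+1
  f1 <- theta_c_field[k]; f2 <- theta_c_field[k + 1]
  rt <- if (f1 == f2) r[k] else r[k] + (f1 - threshold) / (f1 - f2) * grid$dr
  structure(min(rt, grid$R_tissue), detected = TRUE)
}

#' Healthy-tissue recession
#'
#' `phi(t) = (1 - int theta_h(t) dA / int theta_h(0) dA) * 100`: the percent
#' loss of domain-integrated healthy-cell content relative to the start of
#' the simulation.
#'
#' @param theta_h_field Current healthy volume fraction per cell.
#' @param theta_h0_field Initial healthy volume fraction per cell.
#' @param grid A `crtsim_grid`.
#' @return Percent recession (can be negative if healthy content grows).
#' @export
healthy_recession <- function(theta_h_field, theta_h0_field, grid) {
  denom <- grid_integrate(theta_h0_field, grid)
  if (denom <= 0) {
    stop("initial healthy-cell integral is zero", call. = FALSE)
  }
  (1 - grid_integrate(theta_h_field, grid) / denom) * 100
}

# One metrics row for the given state.
metrics_row <- function(state, grid, theta_h0, mass0) {
  theta <- state$theta
  novoid <- max(abs(rowSums(theta) - 1))
  mass <- sum(grid$cell_volumes * rowSums(theta))
  data.frame(
    t = state$time,
    SC = surface_coverage(theta[, "c"], grid),
    R_t = as.numeric(tumor_radius(theta[, "c"], grid)),
    phi = healthy_recession(theta[, "h"], theta_h0, grid),
    mass_total = mass,
    mass_err = mass - mass0,
    novoid_max_err = novoid
  )
}
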