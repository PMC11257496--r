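# Reaction-diffusion fields: forward-Euler finite differences with a 5-point
# Laplacian and zero-flux (reflecting) boundaries. Species diffuse freely
# across cell bodies; decay is uniform everywhere.

#' Create a chemical field
#'
#' @param species Species name (one of [field_species()], or any label).
#' @param width,height Lattice dimensions in pixels.
#' @param D Diffusion coefficient, pixel^2/MCS.
#' @param decay Decay rate, 1/MCS.
#' @param init Initial concentration (scalar or matrix).
#' @return A list of class `chemical_field` with `grid` (concentration),
#'   `pending` (per-pixel secretion rates, concentration/MCS), `D`, `decay`.
#' @export
chemical_field <- function(species, width, height, D = 0.25, decay = 0.005,
                           init = 0) {
  grid <- matrix(0, width, height)
  grid[] <- init
  f <- list(species = species, grid = grid,
            pending = matrix(0, width, height), D = D, decay = decay)
  class(f) <- "chemical_field"
  f
}

#' Solver discretisation for the explicit field stepper
#'
#' @param substeps_per_mcs Forward-Euler substeps per MCS; the effective time
#'   step is `1/substeps_per_mcs` MCS.
#' @param fields Optional list of [chemical_field()]s checked against the
#'   stability bound `D * dt <= 0.25` (5-point Laplacian, dx = 1 pixel).
#' @return A list of class `field_step_config`.
#' @export
field_step_config <- function(substeps_per_mcs = 1L, fields = NULL) {
  dt <- 1 / substeps_per_mcs
  if (!is.null(fields)) {
    for (f in fields) {
      if (f$D * dt > 0.25 + 1e-12)
        stop(sprintf("field %s violates stability: D*dt = %.3f > 0.25",
                     f$species, f$D * dt))
      ## von Neumann bound including decay (checkerboard mode)
      if (8 * f$D * dt + f$decay * dt > 2 + 1e-12)
        stop(sprintf("field %s violates stability: 8*D*dt + decay*dt > 2",
                     f$species))
    }
  }
  structure(list(substeps_per_mcs = as.integer(substeps_per_mcs), dt = dt),
            class = "field_step_config")
}

#' Advance chemical fields by whole MCS
#'
#' Each MCS applies `substeps_per_mcs` forward-Euler substeps of diffusion
#' and decay, adds the pending secretion sources at their per-MCS rates, and
#' clips concentrations at zero. Pending sources are reset afterwards unless
#' `reset_sources = FALSE`.
#'
#' @param fields A list of [chemical_field()]s (or a single one).
#' @param config A [field_step_config()].
#' @param n_mcs Number of MCS to advance.
#' @param reset_sources Reset pending sources after application.
#' @return The updated field list (single field returned as a field).
#' @export
step_fields <- function(fields, config = field_step_config(), n_mcs = 1L,
                        reset_sources = TRUE) {
  single <- inherits(fields, "chemical_field")
  if (single) fields <- list(fields)
  field_step_config(config$substeps_per_mcs, fields)  # re-check stability
  out <- lapply(fields, function(f) {
    g <- f$grid + 0  # force a private copy before in-place stepping
    .diffuse_field_cpp(g, f$D, f$decay, f$pending, config$substeps_per_mcs,
                       as.integer(n_mcs))
    f$grid <- g
    if (reset_sources) f$pending[] <- 0
    f
  })
  if (single) out[[1]] else out
}

#' Accumulate a secretion source over a cell's footprint
#'
#' Distributes a whole-cell secretion rate uniformly over the cell's pixels
#' (default) or deposits it all at the centre-of-mass pixel; either way the
#' total added mass per MCS equals `rate`.
#'
#' @param field A [chemical_field()].
#' @param sim Simulation state (for the cell's pixels/COM).
#' @param id Cell id.
#' @param rate Whole-cell secretion rate, concentration/MCS (non-negative).
#' @param mode `"whole_cell"` or `"com_pixel"`.
#' @return The field with updated pending sources.
#' @export
add_secretion <- function(field, sim, id, rate,
                          mode = c("whole_cell", "com_pixel")) {
  mode <- match.arg(mode)
  if (rate < 0) stop("secretion rate must be non-negative; use uptake_at_com")
  if (rate == 0) return(field)
  if (mode == "whole_cell") {
    pix <- which(sim$grid == id)
    if (!length(pix)) stop("add_secretion: cell has no pixels")
    field$pending[pix] <- field$pending[pix] + rate / length(pix)
  } else {
    cp <- com_pixel(sim, id)
    field$pending[cp[1], cp[2]] <- field$pending[cp[1], cp[2]] + rate
  }
  field
}

#' Remove chemical locally at a cell's centre of mass
#'
#' Models local inhibitor activity (e.g. TIMP) by reducing the concentration
#' at the cell's COM pixel by `amount`, floored at zero.
#'
#' @param field A [chemical_field()] or a plain concentration matrix.
#' @param sim Simulation state.
#' @param id Cell id.
#' @param amount Amount to remove (non-negative).
#' @return The updated field (same shape as the input).
#' @export
uptake_at_com <- function(field, sim, id, amount) {
  if (amount < 0) stop("uptake amount must be non-negative")
  cp <- com_pixel(sim, id)
  if (inherits(field, "chemical_field")) {
    field$grid[cp[1], cp[2]] <- max(0, field$grid[cp[1], cp[2]] - amount)
  } else {
    field[cp[1], cp[2]] <- max(0, field[cp[1], cp[2]] - amount)
  }
  field
}

#' Concentration at a cell's centre of mass
#'
#' Samples the field at the pixel nearest the cell's centre of mass,
#' rounding half up in each axis.
#'
#' @inheritParams uptake_at_com
#' @return Concentration at the COM pixel.
#' @export
value_at_com <- function(field, sim, id) {
  cp <- com_pixel(sim, id)
  g <- if (inherits(field, "chemical_field")) field$grid else field
  g[cp[1], cp[2]]
}
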