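#' Space/time unit calibration for the lattice
#'
#' The lattice is calibrated so that a freely migrating cell moving at the
#' reference speed of 0.1 pixel/MCS corresponds to the peak dermal fibroblast
#' migration speed of 40 um/h. With 3 um per pixel this fixes one Monte Carlo
#' step (MCS) at 0.3 * 3600 / 40 = 27 seconds.
#'
#' @param microns_per_pixel Lattice resolution in micrometres per pixel.
#' @param reference_cell_speed Calibrated free-cell speed in pixel/MCS.
#' @param reference_migration_speed Reference biological migration speed in
#'   um/h.
#' @return A list of class `unit_calibration` with the inputs and the derived
#'   `seconds_per_mcs`.
#' @examples
#' cal <- unit_calibration()
#' cal$seconds_per_mcs  # 27
#' @export
unit_calibration <- function(microns_per_pixel = 3,
                             reference_cell_speed = 0.1,
                             reference_migration_speed = 40) {
  stopifnot(microns_per_pixel > 0, reference_cell_speed > 0,
            reference_migration_speed > 0)
  cal <- list(
    microns_per_pixel = microns_per_pixel,
    reference_cell_speed = reference_cell_speed,
    reference_migration_speed = reference_migration_speed,
    seconds_per_mcs = reference_cell_speed * microns_per_pixel * 3600 /
      reference_migration_speed
  )
  class(cal) <- "unit_calibration"
  cal
}

#' Convert Monte Carlo steps to seconds
#'
#' @param n_mcs Number of MCS (non-negative).
#' @param cal A [unit_calibration()] object.
#' @return Elapsed model time in seconds.
#' @export
mcs_to_seconds <- function(n_mcs, cal = unit_calibration()) {
  if (any(n_mcs < 0)) stop("n_mcs must be non-negative")
  n_mcs * cal$seconds_per_mcs
}

#' Convert days of model time to Monte Carlo steps
#'
#' @param days Model time in days.
#' @param cal A [unit_calibration()] object.
#' @return Number of MCS (not rounded).
#' @export
days_to_mcs <- function(days, cal = unit_calibration()) {
  if (any(days < 0)) stop("days must be non-negative")
  days * 86400 / cal$seconds_per_mcs
}

#' @rdname days_to_mcs
#' @param n_mcs Number of MCS.
#' @export
mcs_to_days <- function(n_mcs, cal = unit_calibration()) {
  mcs_to_seconds(n_mcs, cal) / 86400
}
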