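#' @title Cell type and field codes
#' @description Integer codes used on the lattice and in per-cell vectors.
#'   Medium is 0 and never owns a cell record.
#' @export
cell_types <- function() {
  c(Medium = 0L, Fibroblast = 1L, Myofibroblast = 2L, Macrophage = 3L,
    SenescentMyofibroblast = 4L, InflammatorySenescent = 5L, ECM = 6L)
}

#' @rdname cell_types
#' @export
field_species <- function() c("PDGF", "CSF", "MMP", "INF")

# contact-census neighbour categories (4-neighbour faces)
CAT <- c(medium = 1L, fibroblast = 2L, myofibroblast = 3L, macrophage = 4L,
         sen_fibrogenic = 5L, sen_fibrolytic = 6L, ecm = 7L)

#' Default model parameters
#'
#' All constants of the model in one nested list: effective-energy terms,
#' reaction-diffusion coefficients, and the biological rule thresholds and
#' rates. Field concentrations are in arbitrary units, so only the ratios of
#' secretion rates, decay constants and thresholds matter.
#'
#' Probabilities (`psnc`, `pmf`, `mu`, `clear_inf`) are expressed per model
#' step of 1000 MCS (7.5 h at 27 s/MCS) -- the same unit in which the
#' senescence onset constraint `tsen` is given (baseline 12, i.e. 3.75 days)
#' -- and are converted internally to per-evaluation hazards at the 100-MCS
#' rule cadence.
#'
#' @return A nested list with components `cadence`, `prob_step`,
#'   `sample_every`, `geometry`, `energy`, `fields` and `rules`.
#' @export
default_params <- function() {
  ct <- cell_types()
  nt <- length(ct)                      # includes medium
  ## contact energies J (energy per 8-neighbour face), symmetric over types.
  ## Hierarchy: cell-medium > cell-cell, ECM adhesive to (myo)fibroblasts.
  J <- matrix(12, nt, nt, dimnames = list(names(ct), names(ct)))
  J["Medium", ] <- J[, "Medium"] <- 16
  J["Medium", "Medium"] <- 0
  J["Macrophage", "Medium"] <- J["Medium", "Macrophage"] <- 10
  J["Fibroblast", "Fibroblast"] <- 8
  J["Myofibroblast", "Myofibroblast"] <- 5
  J["Fibroblast", "Myofibroblast"] <- J["Myofibroblast", "Fibroblast"] <- 8
  J["Fibroblast", "ECM"] <- J["ECM", "Fibroblast"] <- 6
  J["Myofibroblast", "ECM"] <- J["ECM", "Myofibroblast"] <- 6
  J["SenescentMyofibroblast", "ECM"] <- J["ECM", "SenescentMyofibroblast"] <- 8
  J["InflammatorySenescent", "ECM"] <- J["ECM", "InflammatorySenescent"] <- 8
  J["ECM", "ECM"] <- 8

  ## chemotaxis strengths lambda per (type, field); fibroblasts and
  ## myofibroblasts follow PDGF (boosted while touching ECM), macrophages
  ## follow the inflammatory SASP field.
  chem <- matrix(0, nt, 4, dimnames = list(names(ct), field_species()))
  chem["Fibroblast", "PDGF"] <- 20
  chem["Myofibroblast", "PDGF"] <- 20
  chem["Macrophage", "INF"] <- 100

  tv <- c(Medium = 0, Fibroblast = 64, Myofibroblast = 64, Macrophage = 64,
          SenescentMyofibroblast = 64, InflammatorySenescent = 64, ECM = 16)
  lv <- c(Medium = 0, Fibroblast = 2, Myofibroblast = 2, Macrophage = 2,
          SenescentMyofibroblast = 2, InflammatorySenescent = 2, ECM = 10)
  ls <- c(Medium = 0, Fibroblast = 0.2, Myofibroblast = 0.2, Macrophage = 0.2,
          SenescentMyofibroblast = 0.2, InflammatorySenescent = 0.2, ECM = 0.5)

  list(
    cadence = 100L,        # MCS between rule evaluations (~45 min)
    prob_step = 1000L,    # MCS per probability/TSEN time-base unit (7.5 h)
    sample_every = 500L,   # MCS between time-series samples
    geometry = list(
      width = 200L, height = 200L,
      pixel_size = 3,                  # um/pixel
      cell_side = 8L,                  # typical cell is 8x8 pixels
      ecm_side = 4L,                   # granularity of the initial dermal ECM
      wound_fraction = 0.4,            # central square, fraction of domain
      fibroblast_fraction = 0.5,       # dermal blocks: fibroblast vs ECM
      macrophage_density = 0.15,       # wound blocks initially occupied
      preexisting_density = 0          # inflammatory senescent cells / wound px
    ),
    energy = list(
      Tm = 8.5,   # calibrated so a free cell moves ~0.1 pixel/MCS
      J = J,
      chem = chem,
      chem_pdgf_ecm = 40,  # elevated PDGF chemotaxis while in ECM contact
      target_volume = tv,
      lambda_volume = lv,
      lambda_surface = ls,
      connectivity_penalty = 0   # optional global fragmentation penalty, off
    ),
    fields = list(
      D = c(PDGF = 0.2, CSF = 0.2, MMP = 0.2, INF = 0.2),       # px^2/MCS
      decay = c(PDGF = 0.005, CSF = 0.005, MMP = 0.02, INF = 0.015), # 1/MCS
      substeps = 1L             # forward-Euler substeps per MCS
    ),
    rules = list(
      ## Monod growth (pixels of target volume per 100-MCS evaluation)
      Gmax_F = 2.5, Gmax_MF = 3.0, Gmax_M = 2.2,
      PDGF0 = 0.5, CSF0 = 0.15,
      TCI = 0.04,                # contact-inhibition threshold on Rs
      ## thresholds (field arbitrary units; ECMthr in 4-neighbour faces)
      PDGFf = 0.15, SNCthr = 0.6, MMPthr = 0.5, ECMthr = 4,
      INFthr = 0.25, CSF1thr = 0.02,
      ## probabilities per 1000-MCS step
      PMF = 0.4, PSNC = 0.15, mu = 0.005,
      ## senescent clearance: both immune pathways carry the same hazard
      clear_phago = 0.1, clear_inf = 0.1,
      TSEN = 12,                # onset of primary senescence, 1000-MCS units
      TNIS = 3,                 # fibrogenic SASP phase duration, days
      mac_grace_days = 4,       # CSF1-withdrawal apoptosis grace period
      ## ECM deposition (pixels per 1000-MCS step); myofibroblast rate is
      ## double the fibroblast rate
      ECM_Fib = 4,
      ecm_seed_volume = 4,      # deposited ECM seeds grow to 2x2
      ## secretion rates (field units per MCS per cell, whole-cell deposit)
      sec_mac_pdgf = 1.0, sec_mac_mmp = 1.2,
      sec_fib_csf = 3.0,
      sec_myo_pdgf = 0.5, sec_myo_csf = 1.0,
      sec_sen_pdgf = 1.0, sec_sen_csf = 1.0, sec_sen_inf = 3.0,
      sec_sen_mmp = 2.0,
      dedifferentiation = FALSE, p_dediff = 0
    )
  )
}

#' Scenario presets
#'
#' The five model configurations: healthy baseline, chronic wound from a high
#' senescence probability, fibrotic wound from absent senescence, fibrotic
#' wound from delayed senescence onset, and chronic wound from pre-existing
#' inflammatory senescent cells.
#'
#' @param name One of `"healthy"`, `"chronic_high_psnc"`, `"fibrotic_no_snc"`,
#'   `"fibrotic_delayed"`, `"chronic_preexisting"`.
#' @param lattice Integer vector `c(width, height)` in pixels.
#' @param days Run length in model days.
#' @param replicates Number of replicate runs (replicate k uses seed
#'   `seed + k - 1`).
#' @param seed Base random seed.
#' @return A list of class `scenario_config` with fields `name`, `psnc`,
#'   `tsen` (1000-MCS units), `preexisting_density`, `lattice`, `days`,
#'   `replicates`, `seed`.
#' @export
scenario_config <- function(name = c("healthy", "chronic_high_psnc",
                                     "fibrotic_no_snc", "fibrotic_delayed",
                                     "chronic_preexisting"),
                            lattice = c(200L, 200L), days = 18,
                            replicates = 3L, seed = 1L) {
  name <- match.arg(name)
  base_tsen <- 12
  cfg <- list(name = name, psnc = 0.15, tsen = base_tsen,
              preexisting_density = 0,
              lattice = as.integer(lattice), days = days,
              replicates = as.integer(replicates), seed = as.integer(seed))
  if (name == "chronic_high_psnc") cfg$psnc <- 0.75
  if (name == "fibrotic_no_snc") cfg$psnc <- 0
  if (name == "fibrotic_delayed") cfg$tsen <- days_to_tsen_units(15)
  if (name == "chronic_preexisting") cfg$preexisting_density <- 1 / 250
  class(cfg) <- "scenario_config"
  cfg
}

# TSEN is expressed in 1000-MCS blocks: 12 units = 12,000 MCS = 3.75 days.
days_to_tsen_units <- function(days, cal = unit_calibration()) {
  days_to_mcs(days, cal) / 1000
}

tsen_units_to_mcs <- function(u) u * 1000

# convert a per-1000-MCS probability to a per-evaluation hazard at `cadence`
hazard_per_eval <- function(p, cadence, prob_step = 1000L) {
  stopifnot(all(p >= 0 & p <= 1))
  1 - (1 - p)^(cadence / prob_step)
}

#' Validate a parameter set
#'
#' Checks invariants (probabilities in range, positive thresholds, stability
#' of the explicit diffusion scheme) and fails with a descriptive error
#' before a run starts.
#'
#' @param params A parameter list as produced by [default_params()].
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  r <- params$rules
  for (pn in c("PMF", "PSNC", "mu", "clear_inf")) {
    v <- r[[pn]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("parameter %s = %s is not a probability in [0, 1]", pn,
                   format(v)))
  }
  if (r$TNIS <= 0) stop("TNIS must be positive")
  thr <- c(r$PDGFf, r$SNCthr, r$MMPthr, r$ECMthr, r$INFthr, r$CSF1thr)
  if (any(thr < 0)) stop("all thresholds must be non-negative")
  if (params$energy$Tm <= 0) stop("membrane fluctuation amplitude Tm must be > 0")
  if (!isTRUE(all.equal(params$energy$J, t(params$energy$J))))
    stop("contact energy matrix J must be symmetric")
  dt <- 1 / params$fields$substeps
  if (any(params$fields$D * dt > 0.25 + 1e-12))
    stop("diffusion stability violated: require D * dt <= 0.25; ",
         "increase fields$substeps")
  ## von Neumann bound including decay: the checkerboard mode must not be
  ## amplified, i.e. 8*D*dt + decay*dt <= 2
  if (any(8 * params$fields$D * dt + params$fields$decay * dt > 2 + 1e-12))
    stop("diffusion stability violated: require 8*D*dt + decay*dt <= 2; ",
         "increase fields$substeps")
  if (params$cadence %% 1 != 0 || params$cadence <= 0)
    stop("cadence must be a positive integer number of MCS")
  invisible(params)
}

# deep-merge override list into params (names must already exist)
merge_params <- function(params, overrides) {
  if (length(overrides) == 0) return(params)
  for (nm in names(overrides)) {
    if (!nm %in% names(params))
      stop(sprintf("unknown parameter '%s'", nm))
    if (is.list(params[[nm]]) && is.list(overrides[[nm]])) {
      params[[nm]] <- merge_params(params[[nm]], overrides[[nm]])
    } else if (is.atomic(params[[nm]]) && !is.null(names(params[[nm]])) &&
               length(names(overrides[[nm]])) > 0) {
      ## partial by-name override of a named vector (e.g. one field's D)
      ov <- unlist(overrides[[nm]])
      bad <- setdiff(names(ov), names(params[[nm]]))
      if (length(bad))
        stop(sprintf("unknown parameter '%s'", bad[1]))
      params[[nm]][names(ov)] <- ov
    } else {
      params[[nm]] <- overrides[[nm]]
    }
  }
  params
}
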