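# The per-interval biological state machine. Rules are evaluated every
# `cadence` MCS (default 100, ~45 min) in a fixed order:
#   squeezed-cell retirement -> census -> ECM degradation -> macrophages ->
#   fibroblasts -> myofibroblast fates (tension apoptosis -> inflammation
#   apoptosis -> primary senescence) -> senescent secretion + secondary
#   induction -> senescent clearance -> division -> ECM deposition ->
#   secretion-source rebuild -> bookkeeping resync.
# All stochastic draws use fixed-length runif vectors so a run is fully
# determined by its seed.

#' Monod (saturating) growth increment
#'
#' `g = g_max * c / (c + K)`: growth of the target volume as a saturating
#' function of the limiting growth factor's concentration at the cell's
#' centre of mass (PDGF for fibroblasts and myofibroblasts, CSF1 for
#' macrophages).
#'
#' @param conc Concentration (non-negative).
#' @param g_max Maximum growth increment, pixels per evaluation interval.
#' @param half_max Concentration at which growth is half-maximal (positive).
#' @return Target-volume increment(s).
#' @export
monod_growth <- function(conc, g_max, half_max) {
  if (half_max <= 0) stop("half_max must be positive")
  if (any(conc < 0)) stop("concentration must be non-negative")
  g_max * conc / (conc + half_max)
}

#' Contact inhibition of growth
#'
#' Growth is arrested while the free-surface fraction `Rs` is below the
#' threshold `TCI` (strictly: frozen iff `Rs < TCI`, with the boundary
#' `Rs == TCI` counted as frozen). Frozen cells keep their current target
#' volume.
#'
#' @param rs Free-surface fraction(s), see [compute_rs()].
#' @param tci Contact-inhibition threshold.
#' @return Logical: `TRUE` where growth is frozen.
#' @export
apply_contact_inhibition <- function(rs, tci) rs <= tci

#' Is primary senescence permitted at time t?
#'
#' The senescence time constraint acts as an onset: CCN1-mediated primary
#' senescence of myofibroblasts is permitted once `t >= TSEN`. A larger
#' `TSEN` therefore delays the appearance of senescent cells.
#'
#' @param t_mcs Current simulation time in MCS.
#' @param tsen_mcs Onset time in MCS.
#' @return Logical.
#' @export
senescence_window <- function(t_mcs, tsen_mcs) t_mcs >= tsen_mcs

# target-volume growth is limited to a small margin ahead of the realised
# volume: a cell that cannot physically enlarge does not accumulate
# unbounded expansion pressure against its neighbours
grow_tvol <- function(tvol, vol, g, margin = 4) {
  pmax(tvol, pmin(tvol + g, vol + margin))
}

# cell ids found in the 4-neighbourhood of a set of pixel indices
neighbour_ids <- function(sim, pix) {
  W <- sim$W; H <- sim$H
  x <- ((pix - 1L) %% W) + 1L
  y <- ((pix - 1L) %/% W) + 1L
  out <- integer(0)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nx <- x + d[1]; ny <- y + d[2]
    ok <- nx >= 1L & nx <= W & ny >= 1L & ny <= H
    out <- c(out, sim$grid[cbind(nx[ok], ny[ok])])
  }
  out
}

record_event <- function(sim, ids, event) {
  if (is.null(sim$record_events) || !isTRUE(sim$record_events)) return()
  if (!length(ids)) return()
  sim$events[[length(sim$events) + 1L]] <-
    data.frame(time_mcs = sim$time_mcs, cell_id = ids, event = event)
}

# one evaluation of the full state machine
apply_rules <- function(sim) {
  p <- sim$params; r <- p$rules; ct <- cell_types()
  t_mcs <- sim$time_mcs
  hz <- function(prob) hazard_per_eval(prob, p$cadence, p$prob_step)
  tnis_mcs <- days_to_mcs(r$TNIS)
  tsen_mcs <- tsen_units_to_mcs(r$TSEN)
  n <- sim$n_ids
  if (n == 0L) return(invisible(sim))
  idx <- seq_len(n)

  ## retire cells squeezed to zero volume during the Metropolis phase
  squeezed <- idx[sim$alive[idx] & sim$volume[idx] <= 0]
  retire_cells(sim, squeezed, clear_pixels = FALSE)

  type <- sim$type[idx]
  alive <- sim$alive[idx] & sim$volume[idx] > 0

  ## update SASP phase before the census so neighbour categories are current
  senm_all <- alive & type == ct[["SenescentMyofibroblast"]]
  sim$phase[idx[senm_all]] <-
    ifelse(t_mcs - sim$t_sen[idx[senm_all]] < tnis_mcs, 1L, 2L)

  ## contact census (4-neighbour shared faces by neighbour category)
  catv <- integer(n)
  catv[type == ct[["Fibroblast"]]] <- CAT[["fibroblast"]]
  catv[type == ct[["Myofibroblast"]]] <- CAT[["myofibroblast"]]
  catv[type == ct[["Macrophage"]]] <- CAT[["macrophage"]]
  catv[type == ct[["SenescentMyofibroblast"]] & sim$phase[idx] == 1L] <-
    CAT[["sen_fibrogenic"]]
  catv[type == ct[["SenescentMyofibroblast"]] & sim$phase[idx] == 2L] <-
    CAT[["sen_fibrolytic"]]
  catv[type == ct[["InflammatorySenescent"]]] <- CAT[["sen_fibrolytic"]]
  catv[type == ct[["ECM"]]] <- CAT[["ecm"]]
  cen <- .cpm_census_cpp(sim$grid, catv, length(CAT), CAT[["medium"]])
  contact <- cen$contact
  ecm_ct <- contact[, CAT[["ecm"]]]
  mac_ct <- contact[, CAT[["macrophage"]]]

  ## field values at each live cell's COM pixel
  fv <- matrix(NA_real_, n, 4)
  la <- idx[alive]
  if (length(la)) {
    cp <- com_pixel(sim, la)
    for (f in 1:4) fv[la, f] <- sim$fields[[f]][cp]
    in_wound <- logical(n); in_wound[la] <- sim$wound_mask[cp]
  } else in_wound <- logical(n)
  fPDGF <- fv[, 1]; fCSF <- fv[, 2]; fMMP <- fv[, 3]; fINF <- fv[, 4]

  ## contact inhibition (frozen cells keep their current target volume)
  frozen <- logical(n)
  frozen[la] <- apply_contact_inhibition(compute_rs(sim, la), r$TCI)
  sim$frozen[idx] <- frozen

  remove <- logical(n)
  sen_start <- alive &
    (type %in% ct[c("SenescentMyofibroblast", "InflammatorySenescent")])

  ## --- ECM degradation: MMP at COM strictly above MMPthr removes the cell
  ecm <- alive & type == ct[["ECM"]]
  deg <- ecm & fMMP > r$MMPthr
  remove[deg] <- TRUE
  record_event(sim, idx[deg], "ecm_degraded")

  ## --- macrophages: polarisation, growth, survival
  mac <- alive & type == ct[["Macrophage"]]
  m1 <- mac & fINF > r$INFthr
  rate_pdgf <- numeric(n); rate_csf <- numeric(n)
  rate_mmp <- numeric(n); rate_inf <- numeric(n)
  grace_over <- t_mcs >= days_to_mcs(r$mac_grace_days)
  if (grace_over) remove[mac & fCSF < r$CSF1thr] <- TRUE
  u <- stats::runif(n)
  remove[mac & u < hz(r$mu)] <- TRUE
  mac_live <- mac & !remove
  rate_mmp[mac_live & m1] <- rate_mmp[mac_live & m1] + r$sec_mac_mmp
  rate_pdgf[mac_live & !m1] <- rate_pdgf[mac_live & !m1] + r$sec_mac_pdgf
  ecm_touch <- mac_live & ecm_ct > 0
  rate_mmp[ecm_touch] <- rate_mmp[ecm_touch] + r$sec_mac_mmp
  gmac <- mac_live & !frozen
  sim$tvol[idx[gmac]] <- grow_tvol(sim$tvol[idx[gmac]], sim$volume[idx[gmac]],
    monod_growth(fCSF[gmac], r$Gmax_M, r$CSF0))

  ## --- fibroblasts: activation, secretion, growth, differentiation
  fib <- alive & type == ct[["Fibroblast"]]
  act <- fib & fPDGF > r$PDGFf
  newly_act <- act & !sim$activated[idx]
  sim$activated[idx[fib]] <- act[fib]
  record_event(sim, idx[newly_act], "activated")
  u <- stats::runif(n)
  remove[act & u < hz(r$mu)] <- TRUE
  fib_live <- fib & !remove
  act_live <- act & !remove
  rate_csf[act_live & mac_ct > 0] <- r$sec_fib_csf
  sim$ecm_budget[idx[act_live]] <- sim$ecm_budget[idx[act_live]] +
    r$ECM_Fib * p$cadence / p$prob_step
  gfib <- fib_live & !frozen
  sim$tvol[idx[gfib]] <- grow_tvol(sim$tvol[idx[gfib]], sim$volume[idx[gfib]],
    monod_growth(fPDGF[gfib], r$Gmax_F, r$PDGF0))
  u <- stats::runif(n)
  differ <- act_live & ecm_ct > r$ECMthr & in_wound & u < hz(r$PMF)
  if (any(differ)) {
    ids <- idx[differ]
    sim$type[ids] <- ct[["Myofibroblast"]]
    record_event(sim, ids, "differentiated")
  }

  ## --- myofibroblast fates, in order: tension apoptosis -> secondary
  ## senescence -> inflammation apoptosis -> primary senescence. Secondary
  ## (juxtacrine/paracrine) induction precedes inflammation apoptosis:
  ## paracrine induction and inflammation apoptosis are gated by the same
  ## INF threshold, so an apoptosis-first order would leave the paracrine
  ## route unreachable.
  myo <- alive & type == ct[["Myofibroblast"]] & !remove  # pre-differentiation
  tension <- myo & ecm_ct < r$ECMthr
  remove[tension] <- TRUE
  record_event(sim, idx[tension], "apoptosis:tension")
  jux <- myo & !remove & contact[, CAT[["sen_fibrogenic"]]] > 0 &
    fPDGF > r$SNCthr
  para <- myo & !remove & !jux & contact[, CAT[["sen_fibrolytic"]]] > 0 &
    fINF > r$INFthr
  for (mech in c(2L, 3L)) {
    sel <- if (mech == 2L) jux else para
    if (!any(sel)) next
    ids <- idx[sel]
    sim$type[ids] <- ct[["SenescentMyofibroblast"]]
    sim$phase[ids] <- 1L
    sim$t_sen[ids] <- t_mcs
    sim$mechanism[ids] <- mech
    nm <- if (mech == 2L) "juxtacrine" else "paracrine"
    sim$cum_induct[[nm]] <- sim$cum_induct[[nm]] + length(ids)
    record_event(sim, ids, paste0("senesced:", nm))
  }
  conv <- jux | para
  inflam <- myo & !remove & !conv & fINF > r$INFthr
  remove[inflam] <- TRUE
  record_event(sim, idx[inflam], "apoptosis:inflammation")
  u <- stats::runif(n)
  window <- senescence_window(t_mcs, tsen_mcs)
  prim <- myo & !remove & !conv & window & ecm_ct > r$ECMthr & u < hz(r$PSNC)
  if (any(prim)) {
    ids <- idx[prim]
    sim$type[ids] <- ct[["SenescentMyofibroblast"]]
    sim$phase[ids] <- 1L
    sim$t_sen[ids] <- t_mcs
    sim$mechanism[ids] <- 1L
    sim$cum_induct[["primary_CCN1"]] <-
      sim$cum_induct[["primary_CCN1"]] + length(ids)
    record_event(sim, ids, "senesced:primary_CCN1")
  }
  surv <- myo & !remove & !prim & !conv
  ## TIMP abstraction: local MMP uptake at the COM pixel
  if (any(surv)) {
    cp <- com_pixel(sim, idx[surv])
    sim$fields$MMP[cp] <- pmax(0, sim$fields$MMP[cp] - r$MMPthr)
  }
  rate_pdgf[surv] <- rate_pdgf[surv] + r$sec_myo_pdgf
  rate_csf[surv & mac_ct > 0] <- rate_csf[surv & mac_ct > 0] + r$sec_myo_csf
  prod <- surv & fPDGF > r$PDGFf
  sim$ecm_budget[idx[prod]] <- sim$ecm_budget[idx[prod]] +
    2 * r$ECM_Fib * p$cadence / p$prob_step
  gmyo <- surv & !frozen
  sim$tvol[idx[gmyo]] <- grow_tvol(sim$tvol[idx[gmyo]], sim$volume[idx[gmyo]],
    monod_growth(fPDGF[gmyo], r$Gmax_MF, r$PDGF0))

  ## --- senescent programme: two-phase SASP secretion
  senm <- alive & !remove & sim$type[idx] == ct[["SenescentMyofibroblast"]]
  infs <- alive & !remove & type == ct[["InflammatorySenescent"]]
  fibrogenic <- senm & (t_mcs - sim$t_sen[idx] < tnis_mcs)
  fibrolytic <- (senm & !fibrogenic) | infs
  rate_pdgf[fibrogenic] <- rate_pdgf[fibrogenic] + r$sec_sen_pdgf
  sim$ecm_budget[idx[fibrogenic]] <- sim$ecm_budget[idx[fibrogenic]] +
    2 * r$ECM_Fib * p$cadence / p$prob_step
  rate_csf[fibrolytic] <- rate_csf[fibrolytic] + r$sec_sen_csf
  rate_inf[fibrolytic] <- rate_inf[fibrolytic] + r$sec_sen_inf
  rate_mmp[fibrolytic] <- rate_mmp[fibrolytic] + r$sec_sen_mmp

  ## --- clearance of cells that entered the interval senescent: certain on
  ## macrophage contact (phagocytosis), else probabilistic under inflammation
  u <- stats::runif(n)
  phago <- sen_start & !remove & mac_ct > 0 & u < hz(r$clear_phago)
  remove[phago] <- TRUE
  record_event(sim, idx[phago], "cleared:phagocytosis")
  u <- stats::runif(n)
  immune <- sen_start & !remove & fINF > r$INFthr & u < hz(r$clear_inf)
  remove[immune] <- TRUE
  record_event(sim, idx[immune], "cleared:inflammation")

  retire_cells(sim, idx[remove], clear_pixels = TRUE)

  ## --- mitosis at doubling volume
  growing <- ct[c("Fibroblast", "Myofibroblast", "Macrophage")]
  base_tv <- sim$params$energy$target_volume
  tnames <- names(ct)[sim$type[idx] + 1L]
  basev <- unname(base_tv[tnames])
  cand <- idx[sim$alive[idx] & sim$type[idx] %in% growing &
                sim$volume[idx] >= 2 * basev]
  for (id in cand) {
    did <- maybe_divide(sim, id)
    if (!is.na(did)) record_event(sim, id, "divided")
  }
  n <- sim$n_ids; idx <- seq_len(n)
  ## cap target volumes at the doubling volume
  tnames <- names(ct)[sim$type[idx] + 1L]
  basev <- unname(base_tv[tnames])
  sim$tvol[idx] <- pmin(sim$tvol[idx], 2 * basev)
  sim$tsurf[idx] <- 4 * sqrt(pmax(sim$tvol[idx], 1))

  ## --- materialise ECM deposition on adjacent medium pixels
  seedv <- r$ecm_seed_volume
  dep <- which(sim$alive[idx] & sim$ecm_budget[idx] >= seedv)
  for (id in dep) {
    px <- if (id <= length(cen$medium_adj)) cen$medium_adj[id] else 0L
    if (px == 0L || sim$grid[px] != 0L) {
      ## no free medium face: thicken an adjacent ECM cell instead (matrix
      ## growth), letting the existing matrix expand on its own free side
      if (id <= nrow(contact) && contact[id, CAT[["ecm"]]] > 0) {
        cpx <- which(sim$grid == id)
        nb <- unique(c(neighbour_ids(sim, cpx)))
        nb <- nb[nb > 0]
        nb <- nb[sim$type[nb] == ct[["ECM"]] & sim$alive[nb]]
        if (length(nb)) {
          ncp <- com_pixel(sim, nb)
          nb <- nb[sim$wound_mask[ncp]]
        }
        nb <- nb[sim$tvol[nb] < 2 * sim$params$energy$target_volume[["ECM"]]]
        if (length(nb)) {
          tgt <- nb[1]
          sim$tvol[tgt] <- sim$tvol[tgt] + seedv
          sim$tsurf[tgt] <- 4 * sqrt(sim$tvol[tgt])
          sim$ecm_budget[id] <- sim$ecm_budget[id] - seedv
          record_event(sim, id, "ecm_deposited")
        }
      }
    } else {
      ## paint a compact block of up to seedv medium pixels around the
      ## anchor so fresh ECM is not immediately squeezed out
      x <- ((px - 1L) %% sim$W) + 1L
      y <- ((px - 1L) %/% sim$W) + 1L
      side <- ceiling(sqrt(seedv))
      xs <- pmin(pmax(x:(x + side - 1L), 1L), sim$W)
      ys <- pmin(pmax(y:(y + side - 1L), 1L), sim$H)
      blk <- as.matrix(expand.grid(unique(xs), unique(ys)))
      free <- sim$grid[blk] == 0L
      blk <- blk[free, , drop = FALSE]
      if (nrow(blk) > seedv) blk <- blk[seq_len(seedv), , drop = FALSE]
      if (nrow(blk) > 0) {
        eid <- new_cell_record(sim, ct[["ECM"]], tvol = seedv)
        sim$grid[blk] <- eid
        sim$ecm_budget[id] <- sim$ecm_budget[id] - seedv
        record_event(sim, id, "ecm_deposited")
      }
    }
    ## no adjacent medium: deposition skipped this interval, budget capped
    sim$ecm_budget[id] <- min(sim$ecm_budget[id], 2 * seedv)
  }
  n <- sim$n_ids; idx <- seq_len(n)

  ## --- rebuild whole-cell secretion source rates (field units/MCS/pixel)
  rates <- list(rate_pdgf, rate_csf, rate_mmp, rate_inf)
  occ <- which(sim$grid != 0L)
  gid <- sim$grid[occ]
  vol_now <- tabulate(gid, nbins = n)
  for (f in 1:4) {
    sim$sources[[f]][] <- 0
    rt <- rates[[f]]
    m <- length(rt)
    sec_ids <- which(rt > 0 & sim$alive[seq_len(m)] & vol_now[seq_len(m)] > 0)
    if (length(sec_ids)) {
      per_px <- numeric(n)
      per_px[sec_ids] <- rt[sec_ids] / vol_now[sec_ids]
      w <- per_px[gid]
      nz <- w > 0
      sim$sources[[f]][occ[nz]] <- w[nz]
    }
  }

  ## --- refresh bookkeeping and chemotaxis rows
  resync_bookkeeping(sim)
  n <- sim$n_ids; idx <- seq_len(n)
  sim$chem_lam[idx, ] <- sim$params$energy$chem[sim$type[idx] + 1L, ]
  nc <- nrow(contact)
  boost <- idx[sim$alive[idx] &
                 sim$type[idx] %in% ct[c("Fibroblast", "Myofibroblast")]]
  boost <- boost[boost <= nc]
  boost <- boost[ecm_ct[boost] > 0]
  sim$chem_lam[boost, 1] <- sim$params$energy$chem_pdgf_ecm
  invisible(sim)
}
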