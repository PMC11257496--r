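# The per-interval biological state machine: growth law, contact inhibition,
# threshold gating, the two-phase senescence programme, secondary induction,
# clearance and ECM turnover.

quiet_params <- function() {
  ## parameters with all stochastic/background mechanisms off so individual
  ## rules can be exercised in isolation
  p <- default_params()
  p$rules$mu <- 0; p$rules$PMF <- 0; p$rules$PSNC <- 0
  p$rules$clear_phago <- 0; p$rules$clear_inf <- 0
  p$rules$Gmax_F <- 0; p$rules$Gmax_MF <- 0; p$rules$Gmax_M <- 0
  p$rules$ECM_Fib <- 0
  p$rules$mac_grace_days <- 0
  p$rules$CSF1thr <- 0
  p
}

interval <- function(sim) { woundcpm:::apply_rules(sim); invisible(sim) }

test_that("Monod growth has the half-saturation and limiting behaviour", {
  expect_equal(monod_growth(0.5, 2, 0.5), 1)      # conc = K -> g_max/2
  expect_equal(monod_growth(0, 2, 0.5), 0)
  expect_equal(monod_growth(4.5, 2, 0.5), 1.8)    # 9K -> 0.9 g_max
  expect_error(monod_growth(1, 2, 0), "half_max")
  expect_error(monod_growth(-1, 2, 1), "non-negative")
  ## strict monotonicity in concentration
  g <- monod_growth(seq(0, 5, by = 0.25), 2, 0.5)
  expect_true(all(diff(g) > 0))
})

test_that("contact inhibition freezes growth at and below the threshold", {
  expect_false(apply_contact_inhibition(1, 0.2))    # isolated cell grows
  expect_true(apply_contact_inhibition(0, 0.2))     # enclosed cell frozen
  expect_true(apply_contact_inhibition(0.2, 0.2))   # boundary counts frozen
  expect_false(apply_contact_inhibition(0.2001, 0.2))
})

test_that("the senescence time constraint acts as an onset", {
  expect_false(senescence_window(0, days_to_mcs(3.75)))
  expect_true(senescence_window(days_to_mcs(16), days_to_mcs(15)))
  expect_true(senescence_window(0, 0))  # degenerate window: always open
  ## larger TSEN means strictly later onset
  t <- days_to_mcs(10)
  expect_true(senescence_window(t, days_to_mcs(9)))
  expect_false(senescence_window(t, days_to_mcs(11)))
})

test_that("macrophage polarisation switches on the inflammation threshold", {
  p <- quiet_params()
  for (inf in c(0, p$rules$INFthr + 0.01)) {
    sim <- empty_state(16, 16, p)
    id <- add_rect_cell(sim, "Macrophage", 5:8, 5:8)
    sim$fields$INF[] <- inf
    interval(sim)
    if (inf > p$rules$INFthr) {
      expect_gt(sum(sim$sources$MMP), 0)     # M1: proteinase
      expect_equal(sum(sim$sources$PDGF), 0)
    } else {
      expect_equal(sum(sim$sources$MMP), 0)  # M2: growth factor
      expect_gt(sum(sim$sources$PDGF), 0)
    }
  }
})

test_that("macrophages secrete MMP on ECM contact and die of CSF1 withdrawal", {
  p <- quiet_params()
  sim <- empty_state(16, 16, p)
  mac <- add_rect_cell(sim, "Macrophage", 5:8, 5:8)
  ecm <- add_rect_cell(sim, "ECM", 9:10, 5:8)  # shares a face with the mac
  interval(sim)
  expect_gt(sum(sim$sources$MMP), 0)  # M2 but touching ECM
  ## CSF1 below threshold after the grace period removes the macrophage
  p2 <- quiet_params(); p2$rules$CSF1thr <- 0.5
  sim2 <- empty_state(16, 16, p2)
  mac2 <- add_rect_cell(sim2, "Macrophage", 5:8, 5:8)
  sim2$time_mcs <- days_to_mcs(5)  # grace period over
  interval(sim2)
  expect_false(sim2$alive[mac2])
})

test_that("fibroblast activation, contact-gated CSF1 and differentiation", {
  p <- quiet_params()
  ## quiescent below the PDGF threshold: no CSF1, no activation
  sim <- empty_state(16, 16, p)
  fib <- add_rect_cell(sim, "Fibroblast", 5:8, 5:8)
  mac <- add_rect_cell(sim, "Macrophage", 9:12, 5:8)
  interval(sim)
  expect_false(sim$activated[fib])
  expect_equal(sum(sim$sources$CSF), 0)
  ## above threshold with macrophage contact: activation + CSF1 secretion
  sim$fields$PDGF[] <- p$rules$PDGFf + 0.1
  interval(sim)
  expect_true(sim$activated[fib])
  expect_gt(sum(sim$sources$CSF), 0)
  ## probability-one differentiation needs ECM contact above ECMthr and the
  ## cell inside the wound region
  p2 <- quiet_params(); p2$rules$PMF <- 1
  sim2 <- empty_state(24, 24, p2)
  fib2 <- add_rect_cell(sim2, "Fibroblast", 9:12, 9:14)
  ecm2 <- add_rect_cell(sim2, "ECM", 13:14, 9:14)  # 6 shared faces > ECMthr
  sim2$wound_mask[] <- TRUE
  sim2$fields$PDGF[] <- p2$rules$PDGFf + 0.1
  ## only 4 shared faces (= ECMthr): strict inequality, no differentiation
  p3 <- quiet_params(); p3$rules$PMF <- 1; p3$rules$ECMthr <- 4
  sim2$params <- p3
  woundcpm:::resync_bookkeeping(sim2)
  interval(sim2)
  expect_equal(sim2$type[fib2], cell_types()[["Myofibroblast"]])
})

test_that("myofibroblast fate order: tension, inflammation, senescence", {
  ct <- cell_types()
  ## (1) ECM contact below threshold: tension-release apoptosis
  p <- quiet_params()
  sim <- empty_state(16, 16, p)
  myo <- add_rect_cell(sim, "Myofibroblast", 5:8, 5:8)
  interval(sim)
  expect_false(sim$alive[myo])
  ## (2) inflammation above threshold removes the cell even with ECM support
  sim2 <- empty_state(16, 16, p)
  myo2 <- add_rect_cell(sim2, "Myofibroblast", 5:8, 5:8)
  ecm2 <- add_rect_cell(sim2, "ECM", 9:10, 4:9)
  sim2$fields$INF[] <- p$rules$INFthr + 0.1
  interval(sim2)
  expect_false(sim2$alive[myo2])
  ## (3) probability-one senescence inside the open window
  p3 <- quiet_params(); p3$rules$PSNC <- 1
  sim3 <- empty_state(16, 16, p3)
  myo3 <- add_rect_cell(sim3, "Myofibroblast", 5:8, 5:8)
  ecm3 <- add_rect_cell(sim3, "ECM", 9:10, 5:10)
  ecm3b <- add_rect_cell(sim3, "ECM", 5:8, 9:10)  # 8 shared faces > ECMthr
  sim3$time_mcs <- woundcpm:::tsen_units_to_mcs(p3$rules$TSEN) + 100
  interval(sim3)
  expect_equal(sim3$type[myo3], ct[["SenescentMyofibroblast"]])
  expect_equal(sim3$phase[myo3], 1L)  # fibrogenic phase first
  expect_equal(unname(sim3$cum_induct[["primary_CCN1"]]), 1L)
  ## outside the window the same cell stays a myofibroblast
  sim4 <- empty_state(16, 16, p3)
  myo4 <- add_rect_cell(sim4, "Myofibroblast", 5:8, 5:8)
  ecm4 <- add_rect_cell(sim4, "ECM", 9:10, 4:9)
  interval(sim4)  # t = 0 < TSEN onset
  expect_equal(sim4$type[myo4], ct[["Myofibroblast"]])
})

test_that("the SASP programme switches from fibrogenic to fibrolytic at TNIS", {
  p <- quiet_params()
  tnis <- days_to_mcs(p$rules$TNIS)
  mk <- function(age_mcs) {
    sim <- empty_state(16, 16, p)
    id <- woundcpm:::new_cell_record(sim, cell_types()[["SenescentMyofibroblast"]],
                                     phase = 1L, mechanism = 1L, t_sen = 0)
    sim$grid[5:8, 5:8] <- id
    woundcpm:::resync_bookkeeping(sim)
    sim$time_mcs <- age_mcs
    interval(sim)
    sim
  }
  young <- mk(tnis - 200)  # just before the switch
  expect_gt(sum(young$sources$PDGF), 0)
  expect_equal(sum(young$sources$CSF) + sum(young$sources$INF) +
                 sum(young$sources$MMP), 0)
  old <- mk(tnis + 200)    # just after the switch
  expect_equal(sum(old$sources$PDGF), 0)
  expect_gt(sum(old$sources$CSF), 0)
  expect_gt(sum(old$sources$INF), 0)
  expect_gt(sum(old$sources$MMP), 0)
  ## pre-existing inflammatory senescent cells always secrete the
  ## fibrolytic set
  sim <- empty_state(16, 16, p)
  id <- woundcpm:::new_cell_record(sim, cell_types()[["InflammatorySenescent"]],
                                   phase = 2L, mechanism = 4L)
  sim$grid[5:8, 5:8] <- id
  woundcpm:::resync_bookkeeping(sim)
  interval(sim)
  expect_gt(sum(sim$sources$INF), 0)
  expect_gt(sum(sim$sources$CSF), 0)
  expect_gt(sum(sim$sources$MMP), 0)
})

test_that("juxtacrine and paracrine secondary senescence are threshold-gated", {
  ct <- cell_types()
  mk <- function(phase, pdgf, inf, sncthr = 0.5) {
    p <- quiet_params()
    p$rules$SNCthr <- sncthr
    sim <- empty_state(20, 20, p)
    sen <- woundcpm:::new_cell_record(sim, ct[["SenescentMyofibroblast"]],
                                      phase = phase, mechanism = 1L,
                                      t_sen = if (phase == 1L) sim$time_mcs
                                              else -days_to_mcs(10))
    sim$grid[5:8, 5:8] <- sen
    myo <- woundcpm:::new_cell_record(sim, ct[["Myofibroblast"]])
    sim$grid[9:12, 5:8] <- myo    # shares faces with the senescent cell
    ecm <- woundcpm:::new_cell_record(sim, ct[["ECM"]], tvol = 16)
    sim$grid[9:12, 9:10] <- ecm   # ECM support (> ECMthr faces)
    woundcpm:::resync_bookkeeping(sim)
    sim$fields$PDGF[] <- pdgf
    sim$fields$INF[] <- inf
    interval(sim)
    list(sim = sim, myo = myo)
  }
  ## fibrogenic neighbour + PDGF above SNCthr: juxtacrine conversion
  r <- mk(1L, pdgf = 0.6, inf = 0)
  expect_equal(r$sim$type[r$myo], ct[["SenescentMyofibroblast"]])
  expect_equal(r$sim$mechanism[r$myo], 2L)
  ## fibrogenic neighbour but PDGF below SNCthr: no conversion
  r2 <- mk(1L, pdgf = 0.4, inf = 0)
  expect_equal(r2$sim$type[r2$myo], ct[["Myofibroblast"]])
  ## effectively infinite SNCthr blocks juxtacrine induction entirely
  r3 <- mk(1L, pdgf = 100, inf = 0, sncthr = Inf)
  expect_equal(r3$sim$type[r3$myo], ct[["Myofibroblast"]])
  ## fibrolytic neighbour + INF above INFthr: paracrine conversion, and the
  ## converted cell starts its own fibrogenic phase
  r4 <- mk(2L, pdgf = 0, inf = 0.3)
  expect_equal(r4$sim$type[r4$myo], ct[["SenescentMyofibroblast"]])
  expect_equal(r4$sim$mechanism[r4$myo], 3L)
  expect_equal(r4$sim$phase[r4$myo], 1L)
  expect_equal(r4$sim$t_sen[r4$myo], r4$sim$time_mcs)
})

test_that("senescent clearance: phagocytosis on contact, inflammation chance", {
  ct <- cell_types()
  mk <- function(mac_contact, inf, p_phago = 1, p_inf = 1) {
    p <- quiet_params()
    p$rules$clear_phago <- p_phago; p$rules$clear_inf <- p_inf
    sim <- empty_state(20, 20, p)
    sen <- woundcpm:::new_cell_record(sim, ct[["SenescentMyofibroblast"]],
                                      phase = 1L, mechanism = 1L)
    sim$grid[5:8, 5:8] <- sen
    if (mac_contact) {
      mac <- woundcpm:::new_cell_record(sim, ct[["Macrophage"]])
      sim$grid[9:12, 5:8] <- mac
    }
    woundcpm:::resync_bookkeeping(sim)
    sim$fields$INF[] <- inf
    set.seed(1)
    interval(sim)
    list(sim = sim, sen = sen)
  }
  r <- mk(TRUE, 0)
  expect_false(r$sim$alive[r$sen])            # phagocytosed
  expect_equal(unname(r$sim$cum_cleared), 1L)
  r2 <- mk(FALSE, 0)
  expect_true(r2$sim$alive[r2$sen])           # isolated, no INF: persists
  r3 <- mk(FALSE, 0.5)
  expect_false(r3$sim$alive[r3$sen])          # probability-one INF clearance
})

test_that("ECM degradation follows the strict MMP threshold", {
  p <- quiet_params()
  mk <- function(mmp) {
    sim <- empty_state(12, 12, p)
    id <- add_rect_cell(sim, "ECM", 5:8, 5:8, tvol = 16)
    sim$fields$MMP[] <- mmp
    interval(sim)
    list(sim = sim, id = id)
  }
  r <- mk(p$rules$MMPthr)          # exactly at threshold: retained
  expect_true(r$sim$alive[r$id])
  r2 <- mk(p$rules$MMPthr + 1e-6)  # strictly above: removed
  expect_false(r2$sim$alive[r2$id])
  ## uniform MMP far above threshold clears all ECM in one interval each
  sim <- empty_state(20, 20, p)
  ids <- c(add_rect_cell(sim, "ECM", 2:5, 2:5, tvol = 16),
           add_rect_cell(sim, "ECM", 8:11, 8:11, tvol = 16),
           add_rect_cell(sim, "ECM", 14:17, 14:17, tvol = 16))
  sim$fields$MMP[] <- 10
  sim$params$fields$decay[] <- 0   # keep MMP high
  k <- 0
  while (any(sim$alive[ids]) && k < 5) { interval(sim); k <- k + 1 }
  expect_false(any(sim$alive[ids]))
})

test_that("TIMP abstraction reduces MMP at the myofibroblast COM", {
  p <- quiet_params()
  sim <- empty_state(16, 16, p)
  myo <- add_rect_cell(sim, "Myofibroblast", 5:8, 5:8)
  ecm <- add_rect_cell(sim, "ECM", 9:10, 4:9)
  sim$fields$MMP[] <- 1
  cp <- woundcpm:::com_pixel(sim, myo)
  interval(sim)
  expect_equal(sim$fields$MMP[cp[1], cp[2]], 1 - p$rules$MMPthr,
               tolerance = 1e-9)
})

test_that("without senescence probability no senescent cells ever appear", {
  cfg <- scenario_config("fibrotic_no_snc", lattice = c(64L, 64L), days = 4.5)
  out <- run_simulation(cfg, seed = 6)
  expect_true(all(out$timeseries$senescent == 0))
  expect_true(all(out$timeseries$induct_primary == 0))
  expect_true(all(out$timeseries$induct_juxtacrine == 0))
  expect_true(all(out$timeseries$induct_paracrine == 0))
})

test_that("the senescence counting identity holds at every sample", {
  cfg <- scenario_config("healthy", lattice = c(80L, 80L), days = 6)
  out <- run_simulation(cfg, seed = 8)
  ts <- out$timeseries
  lhs <- ts$induct_primary + ts$induct_juxtacrine + ts$induct_paracrine +
    ts$induct_preexisting - ts$cleared
  expect_equal(lhs, ts$senescent)
})
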