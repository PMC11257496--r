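# Simulation state lives in an environment so the compiled kernel can update
# the lattice and the per-cell bookkeeping vectors in place. Per-cell vectors
# are indexed by cell id; retired ids keep volume 0 and are never reused.

new_state <- function(width, height, params) {
  sim <- new.env(parent = emptyenv())
  sim$W <- as.integer(width)
  sim$H <- as.integer(height)
  sim$grid <- matrix(0L, width, height)
  sim$wound_mask <- matrix(FALSE, width, height)
  sim$params <- params
  sim$time_mcs <- 0
  sim$n_ids <- 0L
  cap <- 256L
  sim$capacity <- cap
  for (nm in c("volume", "surface", "msurface", "sumx", "sumy",
               "tvol", "lamv", "tsurf", "lams", "t_sen", "ecm_budget"))
    assign(nm, numeric(cap), envir = sim)
  sim$type <- integer(cap)
  sim$phase <- integer(cap)      # 0 none, 1 fibrogenic, 2 fibrolytic
  sim$mechanism <- integer(cap)  # 0 none, 1 primary, 2 juxtacrine,
                                 # 3 paracrine, 4 preexisting
  sim$alive <- logical(cap)
  sim$activated <- logical(cap)
  sim$frozen <- logical(cap)
  sim$chem_lam <- matrix(0, cap, 4)
  nf <- length(field_species())
  sim$fields <- lapply(seq_len(nf), function(i) matrix(0, width, height))
  names(sim$fields) <- field_species()
  sim$sources <- lapply(seq_len(nf), function(i) matrix(0, width, height))
  names(sim$sources) <- field_species()
  sim$cum_induct <- c(primary_CCN1 = 0L, juxtacrine = 0L, paracrine = 0L,
                      preexisting = 0L)
  sim$cum_cleared <- 0L
  sim$events <- NULL
  sim
}

grow_capacity <- function(sim, need) {
  while (sim$capacity < need) {
    old <- sim$capacity
    cap <- old * 2L
    for (nm in c("volume", "surface", "msurface", "sumx", "sumy",
                 "tvol", "lamv", "tsurf", "lams", "t_sen", "ecm_budget")) {
      v <- get(nm, envir = sim)
      length(v) <- cap
      v[is.na(v)] <- 0
      assign(nm, v, envir = sim)
    }
    for (nm in c("type", "phase", "mechanism")) {
      v <- get(nm, envir = sim)
      length(v) <- cap
      v[is.na(v)] <- 0L
      assign(nm, v, envir = sim)
    }
    for (nm in c("alive", "activated", "frozen")) {
      v <- get(nm, envir = sim)
      length(v) <- cap
      v[is.na(v)] <- FALSE
      assign(nm, v, envir = sim)
    }
    cl <- matrix(0, cap, 4)
    cl[seq_len(old), ] <- sim$chem_lam
    sim$chem_lam <- cl
    sim$capacity <- cap
  }
  invisible(sim)
}

# allocate a cell record; pixels are painted separately by the caller
new_cell_record <- function(sim, type, tvol = NULL, phase = 0L,
                            mechanism = 0L, t_sen = 0) {
  id <- sim$n_ids + 1L
  grow_capacity(sim, id)
  sim$n_ids <- id
  en <- sim$params$energy
  tn <- names(cell_types())[type + 1L]
  sim$type[id] <- as.integer(type)
  if (is.null(tvol)) tvol <- en$target_volume[[tn]]
  sim$tvol[id] <- tvol
  sim$lamv[id] <- en$lambda_volume[[tn]]
  sim$lams[id] <- en$lambda_surface[[tn]]
  sim$tsurf[id] <- 4 * sqrt(tvol)
  sim$alive[id] <- TRUE
  sim$phase[id] <- as.integer(phase)
  sim$mechanism[id] <- as.integer(mechanism)
  sim$t_sen[id] <- t_sen
  sim$chem_lam[id, ] <- base_chem_row(sim$params, type)
  id
}

base_chem_row <- function(params, type) {
  params$energy$chem[type + 1L, ]
}

# refresh volume/surface/medium-surface/COM bookkeeping from the grid
resync_bookkeeping <- function(sim) {
  if (sim$n_ids == 0L) return(invisible(sim))
  rc <- .cpm_recount_cpp(sim$grid, sim$n_ids)
  n <- sim$n_ids
  sim$volume[seq_len(n)] <- rc$volume
  sim$surface[seq_len(n)] <- rc$surface
  sim$msurface[seq_len(n)] <- rc$msurface
  sim$sumx[seq_len(n)] <- rc$sumx
  sim$sumy[seq_len(n)] <- rc$sumy
  gone <- seq_len(n)[sim$alive[seq_len(n)] & rc$volume == 0]
  if (length(gone)) retire_cells(sim, gone, clear_pixels = FALSE)
  invisible(sim)
}

# mark cells dead; senescent deaths count toward the clearance total so the
# senescence counting identity holds at every sample
retire_cells <- function(sim, ids, clear_pixels = TRUE) {
  if (!length(ids)) return(invisible(sim))
  sen <- cell_types()[c("SenescentMyofibroblast", "InflammatorySenescent")]
  sim$cum_cleared <- sim$cum_cleared + sum(sim$type[ids] %in% sen)
  sim$alive[ids] <- FALSE
  if (clear_pixels) {
    sim$grid[sim$grid %in% ids] <- 0L
    sim$volume[ids] <- 0
  }
  invisible(sim)
}

live_ids <- function(sim, type = NULL) {
  n <- sim$n_ids
  if (n == 0L) return(integer(0))
  ok <- sim$alive[seq_len(n)] & sim$volume[seq_len(n)] > 0
  if (!is.null(type)) ok <- ok & sim$type[seq_len(n)] %in% type
  which(ok)
}

# centre-of-mass pixel (rounding half up per axis, clamped to the lattice)
com_pixel <- function(sim, ids) {
  v <- sim$volume[ids]
  cx <- sim$sumx[ids] / v
  cy <- sim$sumy[ids] / v
  cbind(pmin(pmax(floor(cx + 0.5), 1), sim$W),
        pmin(pmax(floor(cy + 0.5), 1), sim$H))
}

#' Free-surface fraction of a cell
#'
#' `Rs = s(sigma)_medium / s(sigma)`: the fraction of a cell's boundary faces
#' that touch medium rather than neighbouring cells. Contact inhibition
#' freezes growth when `Rs` falls below the threshold `TCI`.
#'
#' @param sim A simulation state.
#' @param ids Cell ids.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
compute_rs <- function(sim, ids) {
  s <- sim$surface[ids]
  if (any(s <= 0))
    stop("compute_rs: live cell with zero surface")
  sim$msurface[ids] / s
}

#' Construct the initial wounded-tissue state
#'
#' Builds a dermal layer tiled with fibroblasts and ECM around a contiguous
#' central wound populated by M2 macrophages (and, for the pre-existing
#' senescence scenario, inflammatory senescent cells). All chemical fields
#' start at zero.
#'
#' @param scenario A [scenario_config()].
#' @param params Model parameters ([default_params()]).
#' @return A simulation state environment.
#' @export
build_initial_state <- function(scenario, params = default_params()) {
  validate_params(params)
  W <- scenario$lattice[1]; H <- scenario$lattice[2]
  g <- params$geometry
  side <- g$cell_side
  if (W < 3 * side || H < 3 * side)
    stop("lattice too small for the declared geometry")
  sim <- new_state(W, H, params)
  ## central square wound covering wound_fraction of the domain
  ws <- round(sqrt(g$wound_fraction) * c(W, H))
  x0 <- floor((W - ws[1]) / 2) + 1L; x1 <- x0 + ws[1] - 1L
  y0 <- floor((H - ws[2]) / 2) + 1L; y1 <- y0 + ws[2] - 1L
  sim$wound_mask[x0:x1, y0:y1] <- TRUE

  ct <- cell_types()
  bx <- seq(1L, W - side + 1L, by = side)
  by <- seq(1L, H - side + 1L, by = side)
  for (x in bx) {
    for (y in by) {
      xs <- x:(x + side - 1L); ys <- y:(y + side - 1L)
      in_wound <- sim$wound_mask[xs, ys]
      if (mean(in_wound) > 0.5) {
        ## wound block: macrophage with probability macrophage_density
        if (stats::runif(1) < g$macrophage_density) {
          id <- new_cell_record(sim, ct[["Macrophage"]])
          blk <- sim$grid[xs, ys]; blk[in_wound] <- id
          sim$grid[xs, ys] <- blk
        }
      } else {
        ## dermal block: one fibroblast or a tile of ECM cells, clipped to
        ## the dermis so the wound starts free of fibroblasts and ECM
        if (stats::runif(1) < g$fibroblast_fraction) {
          id <- new_cell_record(sim, ct[["Fibroblast"]])
          blk <- sim$grid[xs, ys]; blk[!in_wound] <- id
          sim$grid[xs, ys] <- blk
        } else {
          es <- g$ecm_side
          for (ex in seq(x, x + side - 1L, by = es)) {
            for (ey in seq(y, y + side - 1L, by = es)) {
              exs <- ex:(min(ex + es - 1L, W)); eys <- ey:(min(ey + es - 1L, H))
              iw <- sim$wound_mask[exs, eys]
              if (all(iw)) next
              id <- new_cell_record(sim, ct[["ECM"]])
              blk <- sim$grid[exs, eys]; blk[!iw] <- id
              sim$grid[exs, eys] <- blk
            }
          }
        }
      }
    }
  }
  ## pre-existing inflammatory senescent cells seeded uniformly in the wound
  n_pre <- round(scenario$preexisting_density * sum(sim$wound_mask))
  if (n_pre > 0) {
    free_blocks <- list()
    for (x in bx) for (y in by) {
      xs <- x:(x + side - 1L); ys <- y:(y + side - 1L)
      if (all(sim$wound_mask[xs, ys]) && all(sim$grid[xs, ys] == 0L))
        free_blocks[[length(free_blocks) + 1L]] <- c(x, y)
    }
    if (length(free_blocks)) {
      pick <- sample(seq_along(free_blocks), min(n_pre, length(free_blocks)))
      for (k in pick) {
        x <- free_blocks[[k]][1]; y <- free_blocks[[k]][2]
        id <- new_cell_record(sim, ct[["InflammatorySenescent"]],
                              phase = 2L, mechanism = 4L)
        sim$grid[x:(x + side - 1L), y:(y + side - 1L)] <- id
      }
      sim$cum_induct[["preexisting"]] <- length(pick)
    }
  }
  resync_bookkeeping(sim)
  sim
}

#' Write a colour-mapped PNG snapshot of the cell lattice
#'
#' @param sim Simulation state.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_snapshot <- function(sim, path) {
  ## fixed per-type colour map: medium white, fibroblast blue, myofibroblast
  ## green, macrophage brown, senescent pink, inflammatory senescent red,
  ## ECM yellow
  cols <- rbind(c(1, 1, 1), c(0.2, 0.4, 0.9), c(0.2, 0.75, 0.3),
                c(0.6, 0.4, 0.2), c(1, 0.6, 0.8), c(0.9, 0.1, 0.1),
                c(0.95, 0.85, 0.3))
  tt <- ifelse(sim$grid == 0L, 0L, sim$type[pmax(sim$grid, 1L)])
  img <- array(0, dim = c(sim$H, sim$W, 3))
  for (ch in 1:3)
    img[, , ch] <- t(matrix(cols[tt + 1L, ch], sim$W, sim$H))
  png::writePNG(img, path)
  invisible(path)
}
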