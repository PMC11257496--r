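# Cellular Potts engine: energy evaluation, Metropolis dynamics, division.

#' Boltzmann acceptance probability for a pixel-copy attempt
#'
#' Energy-lowering moves are always accepted; energy-raising moves are
#' accepted with probability `exp(-dH / Tm)`, where `Tm` is the membrane
#' fluctuation amplitude.
#'
#' @param dH Energy change of the proposed copy.
#' @param Tm Membrane fluctuation amplitude (must be positive).
#' @return Probability in `[0, 1]`.
#' @examples
#' accept_probability(-5, 10)  # 1
#' accept_probability(10, 10)  # exp(-1)
#' @export
accept_probability <- function(dH, Tm) {
  if (any(Tm <= 0)) stop("membrane fluctuation amplitude Tm must be > 0")
  ifelse(dH <= 0, 1, exp(-dH / Tm))
}

#' Incremental energy change of a pixel-copy attempt
#'
#' Computes `dH = H(after) - H(before)` for copying cell `source_id` (0 for
#' medium) into `target`, evaluating only the volume, surface, contact and
#' chemotaxis terms that touch the flipped pixel. Copying onto a pixel the
#' source already occupies is a null attempt and is signalled as an error.
#'
#' @param sim Simulation state.
#' @param target Integer `c(x, y)` pixel coordinate (1-based).
#' @param source_id Cell id to copy in (0 = medium).
#' @param source_pixel Optional `c(x, y)` of the neighbouring source pixel;
#'   required for the chemotaxis term, which biases extensions of chemotaxing
#'   cells toward higher attractant concentration.
#' @return The energy change (scalar).
#' @export
delta_energy <- function(sim, target, source_id, source_pixel = NULL) {
  if (is.null(source_pixel)) source_pixel <- c(-1L, -1L)
  n <- max(sim$n_ids, 1L)
  idx <- seq_len(n)
  .cpm_delta_energy_cpp(sim$grid, as.integer(target[1]),
                        as.integer(target[2]), as.integer(source_id),
                        sim$type[idx], sim$volume[idx], sim$surface[idx],
                        sim$tvol[idx], sim$lamv[idx], sim$tsurf[idx],
                        sim$lams[idx], sim$params$energy$J,
                        sim$chem_lam[idx, , drop = FALSE],
                        unname(sim$fields),
                        as.integer(source_pixel[1]),
                        as.integer(source_pixel[2]))
}

#' Advance the lattice by whole Monte Carlo steps
#'
#' One MCS performs `width x height` pixel-copy attempts (random target pixel,
#' random 8-neighbour source), each accepted with [accept_probability()],
#' followed by one MCS of reaction-diffusion for the four chemical fields
#' (secretion sources applied at their per-MCS rates). Volume, surface,
#' medium-surface and centre-of-mass bookkeeping is updated incrementally.
#'
#' @param sim Simulation state.
#' @param n_mcs Number of Monte Carlo steps to perform.
#' @param diffuse Also step the chemical fields (default `TRUE`).
#' @return `sim`, invisibly; the state is modified in place.
#' @export
monte_carlo_step <- function(sim, n_mcs = 1L, diffuse = TRUE) {
  if (sim$n_ids == 0L) {
    sim$time_mcs <- sim$time_mcs + n_mcs
    return(invisible(sim))
  }
  fp <- sim$params$fields
  D <- unname(fp$D); dec <- unname(fp$decay)
  src <- unname(sim$sources)
  if (!diffuse) {
    D[] <- 0; dec[] <- 0
    src <- lapply(src, function(m) matrix(0, sim$W, sim$H))
  }
  kseed <- floor(stats::runif(1) * 2147483647)
  n <- sim$n_ids
  idx <- seq_len(n)
  .cpm_advance_cpp(sim$grid, sim$type[idx], sim$volume, sim$surface,
                   sim$msurface, sim$sumx, sim$sumy, sim$tvol, sim$lamv,
                   sim$tsurf, sim$lams, sim$params$energy$J,
                   sim$chem_lam[idx, , drop = FALSE], unname(sim$fields),
                   D, dec, src, as.integer(fp$substeps),
                   sim$params$energy$Tm, as.integer(n_mcs), kseed)
  sim$time_mcs <- sim$time_mcs + n_mcs
  invisible(sim)
}

#' Divide a cell that has reached its doubling volume
#'
#' Cells of the growing types divide once their actual volume reaches twice
#' the base target volume of the type, splitting along a random line through
#' the centre of mass. Both daughters keep the parent's type and state flags
#' and receive the base target volume. Below the doubling volume this is a
#' no-op.
#'
#' @param sim Simulation state.
#' @param id Cell id.
#' @param max_retries Retries with a fresh axis if a split is degenerate.
#' @return The id of the new daughter, or `NA` if no division occurred.
#' @export
maybe_divide <- function(sim, id, max_retries = 10L) {
  growing <- cell_types()[c("Fibroblast", "Myofibroblast", "Macrophage")]
  if (!sim$type[id] %in% growing) return(NA_integer_)
  tn <- names(cell_types())[sim$type[id] + 1L]
  base_tv <- sim$params$energy$target_volume[[tn]]
  if (sim$volume[id] < 2 * base_tv) return(NA_integer_)
  pix <- which(sim$grid == id)
  if (length(pix) < 2) return(NA_integer_)
  x <- ((pix - 1L) %% sim$W) + 1L
  y <- ((pix - 1L) %/% sim$W) + 1L
  cx <- mean(x); cy <- mean(y)
  for (try in seq_len(max_retries)) {
    th <- stats::runif(1, 0, pi)
    side <- (x - cx) * cos(th) + (y - cy) * sin(th) >= 0
    if (any(side) && !all(side)) {
      did <- new_cell_record(sim, sim$type[id], tvol = base_tv,
                             phase = sim$phase[id],
                             mechanism = sim$mechanism[id],
                             t_sen = sim$t_sen[id])
      sim$activated[did] <- sim$activated[id]
      sim$grid[pix[side]] <- did
      sim$tvol[id] <- base_tv
      sim$tsurf[id] <- 4 * sqrt(base_tv)
      ## refresh bookkeeping for the two halves from the grid
      rc <- .cpm_recount_cpp(sim$grid, sim$n_ids)
      for (i in c(id, did)) {
        sim$volume[i] <- rc$volume[i]; sim$surface[i] <- rc$surface[i]
        sim$msurface[i] <- rc$msurface[i]
        sim$sumx[i] <- rc$sumx[i]; sim$sumy[i] <- rc$sumy[i]
      }
      return(did)
    }
  }
  NA_integer_
}

# full-Hamiltonian evaluation (volume + surface + contact terms), used as a
# debug cross-check of the incremental kernel
cpm_hamiltonian <- function(sim) {
  n <- sim$n_ids
  idx <- seq_len(n)
  rc <- .cpm_recount_cpp(sim$grid, n)
  H <- sum(sim$lamv[idx] * (rc$volume - sim$tvol[idx])^2 * (rc$volume > 0)) +
    sum(sim$lams[idx] * (rc$surface - sim$tsurf[idx])^2 * (rc$volume > 0))
  J <- sim$params$energy$J
  W <- sim$W; Hh <- sim$H
  off <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (o in off) {
    xs <- seq_len(W - abs(o[1]))
    ys <- seq_len(Hh - abs(o[2]))
    if (o[2] < 0) {
      a <- sim$grid[xs, ys + 1, drop = FALSE]
      b <- sim$grid[xs + o[1], ys, drop = FALSE]
    } else {
      a <- sim$grid[xs, ys, drop = FALSE]
      b <- sim$grid[xs + o[1], ys + o[2], drop = FALSE]
    }
    diff <- a != b
    ta <- ifelse(a == 0L, 0L, sim$type[pmax(a, 1L)])
    tb <- ifelse(b == 0L, 0L, sim$type[pmax(b, 1L)])
    H <- H + sum(J[cbind(ta[diff] + 1L, tb[diff] + 1L)])
  }
  H
}
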