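# Configuration loading, output writing, format helpers.

#' Load and validate a run configuration from YAML
#'
#' A minimal config names only the scenario; everything else resolves to
#' defaults. Recognised top-level keys: `scenario`, `seed`, `days`,
#' `lattice`, `replicates`, `overrides` (merged into the parameter list),
#' `sample_every`. Unknown keys and out-of-range values are rejected before
#' any simulation starts.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with `scenario`
#'   (a [scenario_config()]) and `params` (fully resolved).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("scenario", "seed", "days", "lattice", "replicates",
             "overrides", "sample_every")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  scn <- scenario_config(
    name = if (is.null(raw$scenario)) "healthy" else raw$scenario,
    lattice = if (is.null(raw$lattice)) c(200L, 200L) else
      as.integer(unlist(raw$lattice)),
    days = if (is.null(raw$days)) 18 else raw$days,
    replicates = if (is.null(raw$replicates)) 3L else raw$replicates,
    seed = if (is.null(raw$seed)) 1L else raw$seed)
  params <- default_params()
  params$rules$PSNC <- scn$psnc
  params$rules$TSEN <- scn$tsen
  if (!is.null(raw$overrides))
    params <- merge_params(params, raw$overrides)
  if (!is.null(raw$sample_every))
    params$sample_every <- as.integer(raw$sample_every)
  validate_params(params)
  structure(list(scenario = scn, params = params), class = "run_config")
}

# wide time series -> long format (time_mcs, time_days, metric, value)
ts_to_long <- function(ts) {
  metrics <- setdiff(names(ts), c("time_mcs", "time_days"))
  do.call(rbind, lapply(metrics, function(m)
    tibble::tibble(time_mcs = ts$time_mcs, time_days = ts$time_days,
                   metric = m, value = ts[[m]])))
}

provenance_header <- function(config) {
  c("# woundcpm run output",
    sprintf("# scenario: %s", config$scenario$name),
    sprintf("# seed: %s", config$seed),
    sprintf("# psnc: %s  tsen: %s  preexisting_density: %s",
            config$scenario$psnc, config$scenario$tsen,
            config$scenario$preexisting_density),
    sprintf("# lattice: %sx%s  days: %s", config$scenario$lattice[1],
            config$scenario$lattice[2], config$scenario$days))
}

#' Write run outputs to a directory
#'
#' Writes the long-format time-series CSV (with a provenance comment
#' header), the resolved configuration as YAML, the event log if recorded,
#' and an optional final-state snapshot PNG. Files are written atomically
#' (temp file + rename).
#'
#' @param result A result list from [run_simulation()].
#' @param dir Output directory (created if needed).
#' @param snapshot Also write a PNG of the final lattice.
#' @return The directory path, invisibly.
#' @export
write_outputs <- function(result, dir, snapshot = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
  }
  atomically(file.path(dir, "timeseries.csv"), function(p) {
    con <- file(p, "w")
    writeLines(provenance_header(result$config), con)
    utils::write.csv(ts_to_long(result$timeseries), con, row.names = FALSE)
    close(con)
  })
  atomically(file.path(dir, "config.yaml"), function(p) {
    cfg <- result$config
    yaml::write_yaml(list(
      scenario = unclass(cfg$scenario), seed = cfg$seed,
      params = list(rules = cfg$params$rules,
                    cadence = cfg$params$cadence,
                    sample_every = cfg$params$sample_every,
                    fields = lapply(cfg$params$fields, as.list),
                    geometry = cfg$params$geometry)), p)
  })
  if (!is.null(result$events))
    atomically(file.path(dir, "events.csv"), function(p)
      utils::write.csv(result$events, p, row.names = FALSE))
  if (snapshot)
    write_snapshot(result$state, file.path(dir, "final_state.png"))
  invisible(dir)
}

#' Read a long-format time-series CSV back into wide form
#'
#' @param path CSV written by [write_outputs()].
#' @return A wide tibble as produced by [record_sample()].
#' @export
read_timeseries <- function(path) {
  long <- utils::read.csv(path, comment.char = "#")
  metrics <- unique(long$metric)
  base <- unique(long[, c("time_mcs", "time_days")])
  base <- base[order(base$time_mcs), ]
  out <- tibble::as_tibble(base)
  for (m in metrics) {
    sub <- long[long$metric == m, ]
    out[[m]] <- sub$value[match(out$time_mcs, sub$time_mcs)]
  }
  out
}

#' Write a sweep's label matrix as JSON
#'
#' @param sweep Result of [run_sweep()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_label_matrix <- function(sweep, path) {
  jsonlite::write_json(list(
    psnc = rownames(sweep$labels), columns = colnames(sweep$labels),
    labels = sweep$labels), path, matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}
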