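#' Write / read a trace
#'
#' CSV with columns `time_ms`, `V_mV`, `Cai_uM`, `F_active`, `F_total`,
#' `L_frac`, `cycle`.  With `cache = TRUE` an additional compact binary cache
#' (`.rds`) with identical content is written next to the CSV.
#'
#' @param trace A `cardio_trace`.
#' @param path Output CSV path.
#' @param cache Also write a binary cache.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, cache = FALSE) {
  readr::write_csv(as.data.frame(trace), path)
  if (cache) saveRDS(trace, paste0(tools::file_path_sans_ext(path), ".rds"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  rds <- paste0(tools::file_path_sans_ext(path), ".rds")
  if (file.exists(rds)) return(readRDS(rds))
  df <- readr::read_csv(path, show_col_types = FALSE)
  structure(tibble::as_tibble(df), status = "ok",
            class = c("cardio_trace", class(tibble::tibble())))
}

#' Write a population table
#'
#' One flat row per model: scaling factors, biomarkers, abnormality flag and
#' status.
#'
#' @param population Population tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population <- function(population, path) {
  readr::write_csv(as.data.frame(population), path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE))
}

#' Run configuration
#'
#' A serializable description of a full pipeline run; a run is reproducible
#' from (config, seed, package version).
#'
#' @param seed Master seed.
#' @param n_per_wave Simulator runs per wave.
#' @param cloud_size Wave-1 candidate-cloud size.
#' @param augment_floor Augmentation floor.
#' @param threshold Implausibility threshold.
#' @param window Emulator training window.
#' @param wave_cap Maximum waves.
#' @param n_population Models drawn for the initial population.
#' @param preload_lengths,afterloads Mechanical-test protocol lists.
#' @param drug_multipliers Concentration grid for drug sweeps.
#' @param n_cycles,dt Cell-model cycles and sampling step.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_per_wave = 300, cloud_size = 1e6,
                       augment_floor = 1e5, threshold = 3, window = 4,
                       wave_cap = 60, n_population = 1000,
                       preload_lengths = c(0.90, 0.85, 0.80),
                       afterloads = c(0.25, 0.5, 0.75),
                       drug_multipliers = c(0.1, 0.3, 1, 3, 10, 30, 100),
                       n_cycles = 200, dt = 0.5) {
  structure(as.list(environment()), class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in intersect(names(vals), names(cfg))) cfg[[nm]] <- vals[[nm]]
  cfg
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# manifest written next to every CLI output
.write_manifest <- function(dir, config, extra = list()) {
  man <- c(list(
    package_version = as.character(utils::packageVersion("cardiopop")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}
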