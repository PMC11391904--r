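## Run configuration: a single YAML file with one schema version and one
## block per component. Unknown keys are rejected before any compute.

.config_schema <- list(
  schema_version = "scalar",
  seed = "scalar",
  paths = c("output_dir", "dataset", "checkpoint"),
  representation = c("kind", "n_features", "n_interactions", "cutoff",
                     "n_radial_basis", "seed"),
  heads = c("energies", "forces", "nacs", "dipoles", "nac_mode"),
  loss = c("t_E", "t_F", "t_C", "t_mu", "phase_mode", "atomistic"),
  training = c("epochs", "patience", "lr", "batch_size", "seed"),
  dynamics = c("dt_fs", "n_substeps", "t_max_fs", "decoherence",
               "decoherence_c", "frustrated", "energy_drift_abort",
               "seed", "n_traj", "initial_state"),
  spectra = c("fwhm_ev", "pairs"),
  synthetic = c("model", "n_samples", "scheme", "seed", "phase_corruption",
                "fractions")
)

#' Read and validate a run configuration file
#'
#' YAML with blocks `representation`, `heads`, `loss`, `training`,
#' `dynamics`, `spectra`, `synthetic`, `paths` and top-level
#' `schema_version` and `seed`. Unknown blocks or keys are rejected with a
#' list of the offending names.
#'
#' @param path YAML file path.
#' @return validated named list of class `ndn_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
validate_run_config <- function(cfg) {
  bad <- setdiff(names(cfg), names(.config_schema))
  if (length(bad)) {
    stop("config schema error: unknown block(s) ",
         paste(bad, collapse = ", "), "; allowed: ",
         paste(names(.config_schema), collapse = ", "))
  }
  for (blk in names(cfg)) {
    allowed <- .config_schema[[blk]]
    if (identical(allowed, "scalar")) next
    badk <- setdiff(names(cfg[[blk]]), allowed)
    if (length(badk)) {
      stop("config schema error in block '", blk, "': unknown key(s) ",
           paste(badk, collapse = ", "), "; allowed: ",
           paste(allowed, collapse = ", "))
    }
  }
  structure(cfg, class = "ndn_run_config")
}

## stable content hash (polynomial rolling hash over the serialized object)
config_hash <- function(obj) {
  raw <- serialize(obj, NULL, version = 2)
  b <- as.integer(raw)
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a run manifest next to outputs
#'
#' Records the configuration hash, seed, package version and produced
#' files, so any run can be reproduced and verified.
#'
#' @param dir output directory.
#' @param config configuration list used.
#' @param seed integer seed used.
#' @param outputs character vector of produced file names.
#' @return manifest file path, invisibly.
#' @export
write_manifest <- function(dir, config, seed, outputs = character(0)) {
  man <- list(config_hash = config_hash(config), seed = seed,
              package = "namdnet",
              version = as.character(utils::packageVersion("namdnet")),
              r_version = R.version.string,
              outputs = outputs)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
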