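# Run configuration: a flat, typed, schema-checked YAML file.

.config_schema <- list(
  seed = "integer",
  system = list(
    kind = "character",             # double_well | harmonic | cg_helix
    n_res = "integer",
    barrier_height = "numeric", half_separation = "numeric",
    force_constant = "numeric", mass = "numeric",
    bond_k = "numeric", angle_k = "numeric", torsion_k = "numeric",
    contact_eps = "numeric", repulsion_sigma = "numeric"
  ),
  simulation = list(
    timestep = "numeric", temperature = "numeric",
    collision_frequency = "numeric", n_steps = "integer",
    save_interval = "integer", heat_ramp_steps = "integer",
    minimize_first = "logical"
  ),
  boost = list(
    mode = "character",             # none | dihedral | total | dual
    a1 = "numeric", a2 = "numeric",
    n_res_effective = "integer", n_atom_effective = "integer",
    prerun_steps = "integer", burn_in_frac = "numeric",
    dual_composition = "character",
    E_P = "numeric", alpha_P = "numeric", E_D = "numeric", alpha_D = "numeric"
  ),
  analysis = list(
    native = "character",           # "ideal_helix" or a PDB path
    contact_cutoff = "numeric", min_seq_sep = "integer",
    selection = "integer", bins = "integer"
  ),
  output = list(dir = "character", prefix = "character")
)

.check_block <- function(block, schema, where) {
  unknown <- setdiff(names(block), names(schema))
  if (length(unknown) > 0)
    stop(sprintf("unknown config key '%s' at %s", unknown[1],
                 paste0(where, ".", unknown[1])), call. = FALSE)
  for (k in names(block)) {
    if (is.list(schema[[k]])) {
      if (!is.list(block[[k]]))
        stop(sprintf("config key %s.%s must be a block", where, k),
             call. = FALSE)
      .check_block(block[[k]], schema[[k]], paste0(where, ".", k))
    } else {
      want <- schema[[k]]
      v <- block[[k]]
      ok <- switch(want,
                   integer = is.numeric(v) && all(v == round(v)),
                   numeric = is.numeric(v),
                   character = is.character(v),
                   logical = is.logical(v))
      if (!ok)
        stop(sprintf("config key %s.%s must be %s", where, k, want),
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read and validate a run configuration
#'
#' YAML with blocks `system`, `simulation`, `boost`, `analysis`, `output`
#' and a top-level `seed`. Unknown keys are rejected with their location;
#' values are type-checked against the schema.
#'
#' @param path YAML config file
#' @return validated config list (class `run_config`)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  .check_block(cfg, .config_schema, "config")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config", source = normalizePath(path))
}

#' Build the model system described by a config
#' @param cfg a `run_config`
#' @return a `model_system`
#' @export
config_system <- function(cfg) {
  sb <- cfg$system
  if (is.null(sb$kind)) stop("config.system.kind is required")
  args <- sb[setdiff(names(sb), "kind")]
  switch(sb$kind,
         double_well = do.call(make_double_well, args),
         harmonic = do.call(make_harmonic, args),
         cg_helix = do.call(make_cg_helix, args),
         stop("unknown system kind: ", sb$kind))
}

#' Build a [simulation_config()] from a config
#' @param cfg a `run_config`
#' @param boost_mode override for the boost mode
#' @param seed override for the seed
#' @return a `simulation_config`
#' @export
config_simulation <- function(cfg, boost_mode = NULL, seed = NULL) {
  sim <- cfg$simulation
  if (is.null(sim)) sim <- list()
  if (is.null(boost_mode))
    boost_mode <- if (!is.null(cfg$boost$mode)) cfg$boost$mode else "none"
  comp <- if (!is.null(cfg$boost$dual_composition)) cfg$boost$dual_composition
          else "additive"
  do.call(simulation_config,
          c(sim, list(boost_mode = boost_mode, dual_composition = comp,
                      seed = if (is.null(seed)) cfg$seed else seed)))
}

# provenance block written next to every run's outputs
.write_provenance <- function(cfg, boost, dir, prefix) {
  prov <- list(
    config_source = attr(cfg, "source"),
    config_sha = .digest_config(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("boostmd")),
    r_version = R.version.string,
    boost = if (is.null(boost)) NULL else unclass(boost))
  path <- file.path(dir, paste0(prefix, "_provenance.json"))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# order-stable fingerprint of the config content (polynomial rolling hash
# over the serialization; provenance only, not cryptographic)
.digest_config <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
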