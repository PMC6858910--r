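## ---------------------------------------------------------------------------
## Experiment configuration: a JSON file with mesh / tensor / solver /
## localization / observation sections, validated strictly (unknown keys are
## rejected so typos cannot silently fall back to defaults).
## ---------------------------------------------------------------------------

config_schema <- list(
  mesh = c("n_cells", "path"),
  tensor = c("name", "path"),
  solver = c("eps", "f", "g", "newton_tol", "newton_max_iter",
             "linear_rel_tol", "linear_abs_tol"),
  localization = c("ell", "theta", "alpha_bt", "tol_rel", "tol_abs",
                   "max_iter", "max_backtracks", "stagnation_fraction",
                   "include_S0", "radii"),
  observation = c("case", "m", "xi", "seed", "idw_power"),
  truth_midpoints = NULL, initial_midpoints = NULL, out_dir = NULL)

config_defaults <- function() {
  list(mesh = list(n_cells = 64L),
       tensor = list(name = "benchmark2d"),
       solver = list(eps = 0.1, f = 1, g = 0),
       localization = list(radii = 0.1),
       observation = list(case = "RI", m = 26L, xi = 0.3, seed = 1L),
       truth_midpoints = NULL, initial_midpoints = NULL, out_dir = ".")
}

#' Load and validate an experiment configuration
#'
#' Reads a JSON configuration, applies documented defaults for missing
#' optional keys and rejects unknown keys by name.
#'
#' @param path JSON file path.
#' @return validated configuration list of class \code{eik_expconfig}.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(raw)
}

#' @rdname load_config
#' @param raw a configuration list (as parsed from JSON).
#' @export
validate_config <- function(raw) {
  bad <- setdiff(names(raw), names(config_schema))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (sec in intersect(names(raw), names(config_schema))) {
    allowed <- config_schema[[sec]]
    if (!is.null(allowed) && is.list(raw[[sec]])) {
      badk <- setdiff(names(raw[[sec]]), allowed)
      if (length(badk))
        stop("unknown configuration key(s) in '", sec, "': ",
             paste(badk, collapse = ", "))
    }
  }
  cfg <- config_defaults()
  for (sec in names(raw)) {
    if (is.list(raw[[sec]]) && is.list(cfg[[sec]])) {
      for (k in names(raw[[sec]]))
        if (!is.null(raw[[sec]][[k]])) cfg[[sec]][[k]] <- raw[[sec]][[k]]
    } else if (!is.null(raw[[sec]])) {
      cfg[[sec]] <- raw[[sec]]
    }
  }
  if (!is.null(cfg$truth_midpoints))
    cfg$truth_midpoints <- matrix(unlist(cfg$truth_midpoints), ncol = 2L,
                                  byrow = is.list(cfg$truth_midpoints))
  if (!is.null(cfg$initial_midpoints))
    cfg$initial_midpoints <- matrix(unlist(cfg$initial_midpoints), ncol = 2L,
                                    byrow = is.list(cfg$initial_midpoints))
  structure(cfg, class = "eik_expconfig")
}

#' Save an experiment configuration
#'
#' @param cfg configuration list.
#' @param path output JSON path.
#' @export
save_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

## materialize configured objects --------------------------------------------

config_mesh <- function(cfg) {
  if (!is.null(cfg$mesh$path)) read_mesh_text(cfg$mesh$path)
  else unit_square_mesh(cfg$mesh$n_cells)
}

config_tensor <- function(cfg) {
  if (!is.null(cfg$tensor$path))
    per_cell_tensor(as.matrix(utils::read.csv(cfg$tensor$path)))
  else switch(cfg$tensor$name,
              benchmark2d = benchmark2d_tensor(),
              identity = constant_tensor(diag(2)),
              stop("unknown tensor name: ", cfg$tensor$name))
}

config_solver <- function(cfg) do.call(solver_params, cfg$solver)

config_localization <- function(cfg) {
  keys <- setdiff(names(cfg$localization), "radii")
  do.call(localization_config, cfg$localization[keys])
}
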