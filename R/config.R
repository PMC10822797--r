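#' Read a run configuration
#'
#' Configurations are JSON with up to four blocks: `params` (fields of
#' [model_params()]), `weights` ([score_weights()]), `simulation`
#' ([sim_config()]) and `solver` (arguments of [build_grids()] /
#' [solve_policy()]: `dx`, `de`, `x_max`, `n_quad`).  Unspecified keys
#' take the package defaults.
#'
#' @param path JSON file path, or `NULL` for an all-defaults
#'   configuration.
#' @return A list with elements `params`, `weights`, `sim`, `solver`.
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("params", "weights", "simulation", "solver")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config block(s): ",
                            paste(unknown, collapse = ", "))
  params <- do.call(model_params, as.list(raw$params))
  weights <- do.call(score_weights, as.list(raw$weights))
  sim <- do.call(sim_config, as.list(raw$simulation))
  solver <- as.list(raw$solver)
  bad <- setdiff(names(solver), c("dx", "de", "x_max", "n_quad"))
  if (length(bad)) stop("unknown solver setting(s): ",
                        paste(bad, collapse = ", "))
  list(params = params, weights = weights, sim = sim, solver = solver)
}

#' Write the fully resolved configuration of a run
#'
#' Every CLI run echoes its resolved parameters, weights, simulation
#' settings and seed into the output directory so results are
#' reproducible from the artifacts alone.
#'
#' @param cfg a list as returned by [read_config()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(
    list(params = unclass(cfg$params), weights = unclass(cfg$weights),
         simulation = unclass(cfg$sim), solver = cfg$solver),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
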