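#' Default run configuration
#'
#' Bundles the design, field geometry, population parameters and master seed
#' that define one simulated experiment, in a JSON-serialisable structure.
#'
#' @param design A [design_spec()].
#' @param geometry A [field_geometry()].
#' @param population A [population_params()].
#' @param master_seed Integer master seed (overrides `design$seed`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = design_spec(), geometry = field_geometry(),
                       population = population_params(),
                       master_seed = design$seed) {
  design$seed <- as.integer(master_seed)
  structure(list(design = design, geometry = geometry,
                 population = population,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Read and validate a run configuration from JSON
#'
#' Any subset of the keys `design`, `geometry`, `population` and
#' `master_seed` may be given; missing keys take the package defaults.
#' Validation errors name the offending field.
#'
#' @param path Path to a JSON file.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(raw), c("design", "geometry", "population",
                               "master_seed"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))

  design <- .build_from(raw$design, design_spec, "design")
  geometry <- .build_from(raw$geometry, field_geometry, "geometry")
  pop_args <- raw$population
  for (f in c("b_sym_mean", "b_sym_sd", "s_mean", "s_sd")) {
    if (!is.null(pop_args[[f]])) pop_args[[f]] <- unlist(pop_args[[f]])
  }
  for (f in c("conj_mean", "conj_sd")) {
    if (!is.null(pop_args[[f]])) pop_args[[f]] <- unlist(pop_args[[f]])
  }
  population <- .build_from(pop_args, population_params, "population")
  seed <- if (!is.null(raw$master_seed)) raw$master_seed else design$seed
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed)) {
    stop("config field 'master_seed' must be a single integer")
  }
  run_config(design, geometry, population, master_seed = seed)
}

.build_from <- function(args, constructor, what) {
  if (is.null(args)) return(constructor())
  known <- names(formals(constructor))
  bad <- setdiff(names(args), known)
  if (length(bad)) {
    stop(sprintf("unknown field(s) in config '%s': %s", what,
                 paste(bad, collapse = ", ")))
  }
  tryCatch(do.call(constructor, args),
           error = function(e) stop(sprintf("invalid config '%s': %s", what,
                                            conditionMessage(e)),
                                    call. = FALSE))
}

#' Write a run configuration to JSON
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- lapply(config, function(el) {
    if (is.list(el)) lapply(unclass(el), .json_ready) else el
  })
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# named atomic vectors must serialize as JSON objects, not bare arrays
.json_ready <- function(x) {
  if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
}

#' Persist / reload a cohort parameter file
#'
#' @param cohort List of [observer_params()].
#' @param path JSON path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a list of
#'   `observer_params`.
#' @export
write_cohort <- function(cohort, path) {
  jsonlite::write_json(lapply(cohort,
                              function(o) lapply(unclass(o), .json_ready)),
                       path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(o) {
    observer_params(s = unlist(o$s), b_sym = unlist(o$b_sym),
                    lapse = o$lapse,
                    conj_accuracy = unlist(o$conj_accuracy),
                    id = o$id,
                    seed = if (!is.null(o$seed)) o$seed else NULL)
  })
}
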