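#' Serialise parameter objects to YAML or JSON
#'
#' Design, observer, population, physiology and study configurations
#' round-trip through structured text files; the dialect is chosen by file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param x A `design_config`, `observer_params`, `population_params`,
#'   `physio_effect_params`, or `study_config`.
#' @param path Output file.
#' @returns `path` invisibly; `read_config()` returns the re-validated
#'   object.
#' @export
write_config <- function(x, path) {
  payload <- list(type = class(x)[1], fields = strip_params(unclass(x)))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(payload, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    stop_config("unsupported config extension (use .yaml or .json): ", path)
  }
  invisible(path)
}

strip_params <- function(x) {
  lapply(x, function(v) {
    if (inherits(v, c("design_config", "observer_params", "population_params",
                      "physio_effect_params"))) {
      list(type = class(v)[1], fields = strip_params(unclass(v)))
    } else v
  })
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  payload <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_config("unsupported config extension (use .yaml or .json): ", path)
  }
  rebuild_params(payload)
}

rebuild_params <- function(payload) {
  ctor <- switch(payload$type,
                 design_config = design_config,
                 observer_params = observer_params,
                 population_params = population_params,
                 physio_effect_params = physio_effect_params,
                 study_config = study_config,
                 stop_config("unknown config type: ", payload$type))
  fields <- lapply(payload$fields, function(v) {
    if (is.list(v) && !is.null(v$type) && !is.null(v$fields)) {
      rebuild_params(v)
    } else if (is.list(v) && all(vapply(v, is.numeric, TRUE))) {
      unlist(v)
    } else v
  })
  fields <- fields[names(fields) %in% names(formals(ctor))]
  do.call(ctor, fields)
}
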