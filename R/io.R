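# CSV and config file handling. All files are plain UTF-8 CSV with dot
# decimal separators and unit-suffixed headers to prevent unit confusion.

carcass_required_cols <- c("id", "sex", "hot_weight_kg", "f2_mm", "m2_mm")
carcass_numeric_cols <- c("hot_weight_kg", "f2_mm", "m2_mm",
                          "ytd_true", "ypd_obs", "ypd", "ytd", "lmp_ref")

#' Read a carcass measurement table
#'
#' Reads a carcass CSV (columns `id`, `sex`, `hot_weight_kg`, `f2_mm`,
#' `m2_mm`, optionally `ytd_true`, `ypd_obs` and derived columns) with
#' strict schema validation: missing columns, non-numeric measurement
#' fields (including comma-decimal values) and duplicate ids are reported
#' with the offending column and row numbers.
#'
#' @param path path to a CSV file.
#' @return a `carcass_population` data frame.
#' @export
read_carcass_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(carcass_required_cols, names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in intersect(carcass_numeric_cols, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf(
        "non-numeric value in column '%s' at row %d: \"%s\" (dot-decimal dialect required)",
        col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    raw[[col]] <- v
  }
  dup <- which(duplicated(raw$id))
  if (length(dup))
    stop(sprintf("duplicate carcass id \"%s\" at row %d", raw$id[dup[1]],
                 dup[1]), call. = FALSE)
  class(raw) <- c("carcass_population", "data.frame")
  raw
}

#' Write a carcass table to CSV
#'
#' Plain UTF-8 CSV, dot decimals, full double precision (the write/read
#' round trip is lossless well beyond 6 significant digits).
#'
#' @param x a carcass data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_carcass_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML or JSON configuration (by file extension) mirroring the
#' pipeline's parameters and fills in package defaults for anything not
#' given. Recognized top-level keys: `seed`, `population` (fields of
#' [population_params()]), `plan` (`fat_breaks`, `weight_breaks`,
#' `required_counts`, `required_subsample`), `sf_round`, `calibration`
#' (`n_components`, `folds`, `limit`), and `equations`
#' (`old`/`new`, each `"2011"`, `"2023"` or a list with `intercept`,
#' `coef_f2`, `coef_m2`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config` list accepted by [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be .yaml, .yml or .json", call. = FALSE))
  pipeline_config(
    seed = raw$seed,
    population = raw$population,
    plan = raw$plan,
    sf_round = raw$sf_round,
    calibration = raw$calibration,
    equations = raw$equations
  )
}

resolve_equation <- function(x, default_year) {
  if (is.null(x)) return(cgm_equation(default_year))
  if (inherits(x, "prediction_equation")) return(x)
  if (is.character(x) || is.numeric(x)) {
    x <- sub("^builtin:", "", as.character(x))
    return(cgm_equation(x))
  }
  if (is.list(x))
    return(prediction_equation(x$intercept, x$coef_f2, x$coef_m2,
                               label = x$label %||% "config"))
  stop("cannot interpret equation specification", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a pipeline configuration
#'
#' Programmatic constructor for the configuration consumed by
#' [run_pipeline()]; every argument may be `NULL` to take the package
#' default.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param population a [population_params()] object or a named list of its
#'   fields (`n` defaults to 20000).
#' @param plan a [stratification_plan()] or list of its fields.
#' @param sf_round decimals for the scaling factor (default 2).
#' @param calibration list with `n_components`, `folds`, `limit`.
#' @param equations list with `old` and `new` entries (see
#'   [read_pipeline_config()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, population = NULL, plan = NULL,
                            sf_round = 2, calibration = NULL,
                            equations = NULL) {
  seed <- as.integer(seed %||% 1L)
  if (!inherits(population, "population_params")) {
    population <- population %||% list()
    population$n <- population$n %||% 20000L
    population <- do.call(population_params, population)
  }
  if (!inherits(plan, "stratification_plan")) {
    plan <- plan %||% list()
    if (!is.null(plan$required_counts))
      plan$required_counts <- matrix(unlist(plan$required_counts),
                                     nrow = length(plan$weight_breaks %||%
                                                     c(60, 84.4, 105.5, 120)) - 1,
                                     byrow = TRUE)
    if (!is.null(plan$required_subsample))
      plan$required_subsample <- matrix(unlist(plan$required_subsample),
                                        nrow = nrow(plan$required_counts),
                                        byrow = TRUE)
    plan <- do.call(stratification_plan, plan)
  }
  calibration <- calibration %||% list()
  structure(list(
    seed = seed,
    population = population,
    plan = plan,
    sf_round = sf_round %||% 2,
    n_components = calibration$n_components %||% 2,
    folds = calibration$folds,
    limit = calibration$limit %||% 2.5,
    eq_old = resolve_equation(equations$old, "2011"),
    eq_new = equations$new  # NULL = use the freshly fitted equation
  ), class = "pipeline_config")
}
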