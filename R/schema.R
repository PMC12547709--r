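#' Describe one covariate column
#'
#' A schema entry records how a covariate is typed and which role it plays in
#' the modelling pipeline. Continuous covariates carry no levels; binary and
#' categorical covariates carry an ordered level set whose first element is
#' the reference level used when building design matrices.
#'
#' @param name Column name (unique within a schema).
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param unit Free-text unit label (e.g. `"kg"`, `"months"`).
#' @param levels Ordered character vector of levels; required for binary
#'   (exactly 2) and categorical (at least 2) covariates, forbidden for
#'   continuous ones.
#' @param role One of `"baseline"`, `"longitudinal-derived"`, `"outcome"`,
#'   `"id"`, `"meta"`.
#' @return A list of class `"schema_entry"`.
#' @export
schema_entry <- function(name, kind = c("continuous", "binary", "categorical"),
                         unit = "", levels = NULL,
                         role = c("baseline", "longitudinal-derived",
                                  "outcome", "id", "meta")) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous" && !is.null(levels))
    stop("continuous covariate '", name, "' must not declare levels")
  if (kind == "binary" && length(levels) != 2L)
    stop("binary covariate '", name, "' needs exactly 2 levels")
  if (kind == "categorical" && length(levels) < 2L)
    stop("categorical covariate '", name, "' needs >= 2 levels")
  structure(list(name = name, kind = kind, unit = unit,
                 levels = levels, role = role),
            class = "schema_entry")
}

#' Assemble a covariate schema
#'
#' @param ... `schema_entry` objects (or a single list of them).
#' @return Object of class `"covariate_schema"`: a named list of entries.
#' @export
covariate_schema <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && !inherits(entries[[1L]], "schema_entry"))
    entries <- entries[[1L]]
  nm <- vapply(entries, function(e) e$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate covariate names in schema: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(entries) <- nm
  structure(entries, class = "covariate_schema")
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("<covariate_schema> ", length(x), " covariates\n", sep = "")
  for (e in x) {
    lv <- if (is.null(e$levels)) "" else
      paste0(" {", paste(e$levels, collapse = ","), "}")
    cat(sprintf("  %-22s %-11s %-22s %s%s\n", e$name, e$kind, e$role,
                e$unit, lv))
  }
  invisible(x)
}

#' Names of schema covariates, optionally filtered by kind or role
#' @param schema A `covariate_schema`.
#' @param kind,role Optional filters.
#' @export
schema_names <- function(schema, kind = NULL, role = NULL) {
  keep <- vapply(schema, function(e) {
    (is.null(kind) || e$kind %in% kind) && (is.null(role) || e$role %in% role)
  }, logical(1))
  names(schema)[keep]
}

#' The default ALS baseline covariate schema
#'
#' Ten baseline covariates used throughout: six continuous (age at onset,
#' diagnostic delay, ALSFRS-R slope, FVC %predicted, premorbid weight,
#' weight at diagnosis), two binary (sex, C9orf72 status) and two
#' categorical (site of onset, cohort).
#'
#' @param cohorts Character vector of cohort labels.
#' @return A `covariate_schema`.
#' @export
als_schema <- function(cohorts = c("BEL", "IRE", "SHE", "SPA", "NLD")) {
  covariate_schema(
    schema_entry("age_onset", "continuous", "years"),
    schema_entry("diagnostic_delay_months", "continuous", "months"),
    schema_entry("alsfrs_slope", "continuous", "points/month"),
    schema_entry("fvc_pct", "continuous", "% predicted"),
    schema_entry("premorbid_weight_kg", "continuous", "kg"),
    schema_entry("weight_dx_kg", "continuous", "kg"),
    schema_entry("sex", "binary", levels = c("male", "female")),
    schema_entry("c9orf72", "binary", levels = c("negative", "positive")),
    schema_entry("site_onset", "categorical",
                 levels = c("bulbar", "spinal", "other")),
    schema_entry("cohort", "categorical", levels = cohorts)
  )
}

#' Read a covariate schema from a YAML or JSON config file
#'
#' The file maps column name to a list with `kind`, and optionally `unit`,
#' `levels`, `role`.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return A `covariate_schema`.
#' @export
read_schema <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported schema format: .", ext))
  entries <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    schema_entry(nm, kind = e$kind,
                 unit = if (is.null(e$unit)) "" else e$unit,
                 levels = if (is.null(e$levels)) NULL else unlist(e$levels),
                 role = if (is.null(e$role)) "baseline" else e$role)
  })
  covariate_schema(entries)
}
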