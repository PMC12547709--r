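#' One patient's static covariates and longitudinal weight series
#'
#' Times are integer days from diagnosis (diagnosis = day 0). Missing
#' covariate values are encoded as `NA` — an out-of-band sentinel, never an
#' in-band number.
#'
#' @param id Patient identifier (character scalar).
#' @param covariates Named list of covariate values (`NA` = missing).
#' @param weights Data frame with columns `t_days` (integer days from
#'   diagnosis) and `kg` (positive weight); sorted by `t_days` on creation.
#' @param gastrostomy_day Optional day of gastrostomy placement (>= 0).
#' @param censor_day Optional last follow-up day (>= 0).
#' @return A list of class `"patient_record"`.
#' @export
patient_record <- function(id, covariates = list(),
                           weights = data.frame(t_days = integer(),
                                                kg = numeric()),
                           gastrostomy_day = NA_real_,
                           censor_day = NA_real_) {
  stopifnot(length(id) == 1L)
  weights <- as.data.frame(weights)[, c("t_days", "kg")]
  if (nrow(weights)) weights <- weights[order(weights$t_days), , drop = FALSE]
  rownames(weights) <- NULL
  if (!is.na(gastrostomy_day) && gastrostomy_day < 0)
    stop("gastrostomy_day must be >= 0 for patient ", id)
  if (!is.na(censor_day) && censor_day < 0)
    stop("censor_day must be >= 0 for patient ", id)
  structure(list(id = as.character(id), covariates = covariates,
                 weights = weights,
                 gastrostomy_day = as.numeric(gastrostomy_day),
                 censor_day = as.numeric(censor_day)),
            class = "patient_record")
}

#' A cohort: schema + patient records + provenance tag
#'
#' @param schema A `covariate_schema`.
#' @param records List of `patient_record`s with unique ids.
#' @param provenance Free-text source tag.
#' @return A list of class `"cohort_table"`.
#' @export
cohort_table <- function(schema, records, provenance = "") {
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate patient id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- lapply(records, function(r)
    setdiff(names(r$covariates), names(schema)))
  bad <- unique(unlist(bad))
  if (length(bad))
    stop("covariates not in schema: ", paste(bad, collapse = ", "))
  names(records) <- ids
  structure(list(schema = schema, records = records, provenance = provenance),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  nw <- sum(vapply(x$records, function(r) nrow(r$weights), integer(1)))
  cat("<cohort_table> ", length(x$records), " patients, ", nw,
      " weight points", if (nzchar(x$provenance))
        paste0(" [", x$provenance, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
length.cohort_table <- function(x) length(x$records)

#' Static covariates of a cohort as a data frame
#'
#' Categorical/binary covariates come back as factors with the schema's
#' level order; continuous as numeric. Row order follows the record order.
#'
#' @param tbl A `cohort_table`.
#' @param include_followup Also include `gastrostomy_day` and `censor_day`.
#' @return Data frame with one row per patient, first column `id`.
#' @export
cohort_static_df <- function(tbl, include_followup = FALSE) {
  nm <- names(tbl$schema)
  cols <- lapply(nm, function(v) {
    vals <- lapply(tbl$records, function(r) {
      x <- r$covariates[[v]]
      if (is.null(x)) NA else x
    })
    e <- tbl$schema[[v]]
    if (e$kind == "continuous") as.numeric(unlist(vals))
    else factor(as.character(unlist(vals)), levels = e$levels)
  })
  names(cols) <- nm
  out <- data.frame(id = names(tbl$records), cols,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (include_followup) {
    out$gastrostomy_day <- vapply(tbl$records,
                                  function(r) r$gastrostomy_day, numeric(1))
    out$censor_day <- vapply(tbl$records, function(r) r$censor_day,
                             numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Longitudinal weight series of a cohort as a long data frame
#' @param tbl A `cohort_table`.
#' @return Data frame with columns `id`, `t_days`, `kg`.
#' @export
cohort_long_df <- function(tbl) {
  rows <- lapply(tbl$records, function(r) {
    if (!nrow(r$weights)) return(NULL)
    data.frame(id = r$id, r$weights, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(id = character(), t_days = numeric(),
                                      kg = numeric())
  rownames(out) <- NULL
  out
}

.read_delim_auto <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", comment.char = "",
                    fileEncoding = "UTF-8")
}

.num_or_warn <- function(x, what) {
  y <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(trimws(x)) & is.na(y) &
                 !(trimws(x) %in% c("NA", "NaN")))
  if (length(bad))
    warning(length(bad), " unparseable numeric cell(s) in ", what,
            " set to missing (e.g. '", x[bad[1L]], "')", call. = FALSE)
  y
}

#' Read a cohort from static and longitudinal delimited files
#'
#' Both files must be UTF-8 delimited text (comma or, for `.tsv`, tab) with
#' a header row and an `id` column. The longitudinal file needs `t_days`
#' and `weight_kg` columns, or a `date` column paired with a
#' `diagnosis_date` column in the static file (dates are converted to days
#' from diagnosis on read). Optional static columns: `gastrostomy_day`,
#' `censor_day`. Unparseable numeric cells become missing with a warning;
#' longitudinal rows whose id is absent from the static file are skipped
#' with a warning; a duplicated id in the static file is a hard error.
#'
#' @param static_path,longitudinal_path File paths.
#' @param schema A `covariate_schema` describing the static covariates.
#' @param provenance Source tag stored on the result.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(static_path, longitudinal_path, schema,
                        provenance = basename(static_path)) {
  st <- .read_delim_auto(static_path)
  lg <- .read_delim_auto(longitudinal_path)
  if (!"id" %in% names(st)) stop("static file misses mandatory column: id")
  if (!"id" %in% names(lg))
    stop("longitudinal file misses mandatory column: id")
  if (anyDuplicated(st$id))
    stop("duplicate id in static file: ",
         paste(unique(st$id[duplicated(st$id)]), collapse = ", "))

  if (!"t_days" %in% names(lg)) {
    if (!("date" %in% names(lg) && "diagnosis_date" %in% names(st)))
      stop("longitudinal file misses mandatory column: t_days ",
           "(or date + static diagnosis_date)")
    dx <- as.Date(st$diagnosis_date)[match(lg$id, st$id)]
    lg$t_days <- as.numeric(as.Date(lg$date) - dx)
  }
  if (!"weight_kg" %in% names(lg))
    stop("longitudinal file misses mandatory column: weight_kg")

  orphan <- !(lg$id %in% st$id)
  if (any(orphan)) {
    warning(sum(orphan), " longitudinal row(s) with id absent from static ",
            "file skipped", call. = FALSE)
    lg <- lg[!orphan, , drop = FALSE]
  }
  t_days <- .num_or_warn(lg$t_days, "longitudinal t_days")
  kg <- .num_or_warn(lg$weight_kg, "longitudinal weight_kg")
  keep <- !is.na(t_days) & !is.na(kg)
  if (any(!keep))
    warning(sum(!keep), " longitudinal point(s) dropped (missing time or ",
            "weight)", call. = FALSE)
  lg <- data.frame(id = lg$id[keep], t_days = t_days[keep], kg = kg[keep],
                   stringsAsFactors = FALSE)

  cont <- schema_names(schema, kind = "continuous")
  for (v in intersect(cont, names(st))) st[[v]] <- .num_or_warn(st[[v]], v)
  for (v in c("gastrostomy_day", "censor_day"))
    if (v %in% names(st)) st[[v]] <- .num_or_warn(st[[v]], v)

  long_split <- split(seq_len(nrow(lg)), lg$id)
  records <- lapply(seq_len(nrow(st)), function(i) {
    covs <- lapply(names(schema), function(v)
      if (v %in% names(st)) {
        x <- st[[v]][i]
        if (is.character(x) && (!nzchar(trimws(x)) || trimws(x) == "NA"))
          NA else x
      } else NA)
    names(covs) <- names(schema)
    idx <- long_split[[st$id[i]]]
    w <- if (is.null(idx)) data.frame(t_days = numeric(), kg = numeric())
         else lg[idx, c("t_days", "kg")]
    patient_record(st$id[i], covs, w,
      gastrostomy_day = if ("gastrostomy_day" %in% names(st))
        st$gastrostomy_day[i] else NA_real_,
      censor_day = if ("censor_day" %in% names(st)) st$censor_day[i]
        else NA_real_)
  })
  cohort_table(schema, records, provenance = provenance)
}

#' Write a cohort back to static and longitudinal delimited files
#'
#' Numeric cells are formatted with 15 significant digits so that a
#' read/write round trip reproduces values to well below 1e-9.
#'
#' @param tbl A `cohort_table`.
#' @param static_path,longitudinal_path Output paths (format by extension).
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(tbl, static_path, longitudinal_path) {
  fmt <- function(df) {
    for (v in names(df))
      if (is.numeric(df[[v]]))
        df[[v]] <- formatC(df[[v]], digits = 15, format = "g")
    df
  }
  st <- cohort_static_df(tbl, include_followup = TRUE)
  sep1 <- if (tolower(tools::file_ext(static_path)) %in% c("tsv", "tab"))
    "\t" else ","
  sep2 <- if (tolower(tools::file_ext(longitudinal_path)) %in%
                c("tsv", "tab")) "\t" else ","
  utils::write.table(fmt(st), static_path, sep = sep1, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  lg <- cohort_long_df(tbl)
  names(lg)[names(lg) == "kg"] <- "weight_kg"
  utils::write.table(fmt(lg), longitudinal_path,
                     sep = sep2, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(c(static_path, longitudinal_path))
}

#' Validate a cohort against its schema and structural invariants
#'
#' Reporting only — never throws. Checks per record: positive weights,
#' weight times sorted and non-missing, unknown categorical levels,
#' negative follow-up days.
#'
#' @param tbl A `cohort_table`.
#' @return Data frame (`id`, `rule`, `message`); zero rows iff valid.
#' @export
validate_cohort <- function(tbl) {
  out <- list()
  add <- function(id, rule, message)
    out[[length(out) + 1L]] <<- data.frame(id = id, rule = rule,
                                           message = message)
  for (r in tbl$records) {
    w <- r$weights
    if (nrow(w)) {
      if (any(!is.finite(w$kg) | w$kg <= 0))
        add(r$id, "nonpositive_weight",
            paste0("weight <= 0 at day ",
                   paste(w$t_days[!is.finite(w$kg) | w$kg <= 0],
                         collapse = ",")))
      if (is.unsorted(w$t_days))
        add(r$id, "unsorted_times", "weight times not sorted")
    }
    for (v in names(tbl$schema)) {
      e <- tbl$schema[[v]]
      x <- r$covariates[[v]]
      if (is.null(x) || length(x) != 1L || is.na(x)) next
      if (e$kind %in% c("binary", "categorical") &&
          !(as.character(x) %in% e$levels))
        add(r$id, "unknown_level",
            paste0(v, ": unknown level '", x, "'"))
      if (e$kind == "continuous" && !is.numeric(x))
        add(r$id, "non_numeric", paste0(v, ": non-numeric value"))
    }
    for (v in c("gastrostomy_day", "censor_day"))
      if (!is.na(r[[v]]) && r[[v]] < 0)
        add(r$id, "negative_day", paste0(v, " < 0"))
  }
  if (!length(out))
    return(data.frame(id = character(), rule = character(),
                      message = character()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
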