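#' Fit a design-matrix encoder on training covariates
#'
#' Records factor levels (and coerces characters to factors) so that new
#' data is expanded into exactly the same dummy columns: one 0/1 indicator
#' per non-reference level (`"col=level"`), reference = first level.
#' Continuous columns pass through unchanged; z-scoring is the model's
#' job, fitted on training folds only.
#'
#' @param df Data frame of covariates.
#' @return A list of class `"covariate_encoder"`.
#' @export
make_encoder <- function(df) {
  cols <- lapply(df, function(x) {
    if (is.numeric(x)) list(kind = "numeric")
    else list(kind = "factor",
              levels = if (is.factor(x)) levels(x) else sort(unique(x)))
  })
  structure(list(cols = cols, names = names(df)),
            class = "covariate_encoder")
}

#' Encode covariates into a numeric design matrix
#'
#' @param encoder A `covariate_encoder` from [make_encoder()].
#' @param df Data frame with the training columns.
#' @return Numeric matrix.
#' @export
encode_covariates <- function(encoder, df) {
  miss <- setdiff(encoder$names, names(df))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (v in encoder$names) {
    spec <- encoder$cols[[v]]
    if (spec$kind == "numeric") {
      out[[v]] <- as.numeric(df[[v]])
    } else {
      x <- as.character(df[[v]])
      unknown <- !is.na(x) & !(x %in% spec$levels)
      if (any(unknown))
        stop("unknown level(s) in ", v, ": ",
             paste(unique(x[unknown]), collapse = ", "))
      for (l in spec$levels[-1L])
        out[[paste0(v, "=", l)]] <- as.numeric(x == l)
    }
  }
  if (!length(out)) return(matrix(numeric(0), nrow(df), 0L))
  mat <- do.call(cbind, out)
  rownames(mat) <- NULL
  mat
}
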