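#' ThT fluorescence time series
#'
#' A single well's thioflavin-T time course: times in seconds and
#' either raw fluorescence (arbitrary units) or normalized fraction
#' aggregated. Times must be strictly increasing and non-negative with
#' at least 8 points so the sigmoid is resolvable; normalized values
#' may show small noise excursions outside [0, 1] (allowed range
#' [-0.1, 1.1]).
#'
#' The 8-point floor is enforced where it matters — at normalization
#' and fitting — so short files (e.g. endpoint exports) still parse.
#'
#' @param times time points, seconds, strictly increasing, >= 0.
#' @param values fluorescence (a.u.) or fraction aggregated.
#' @param replicate_id replicate label (default "r1").
#' @param condition condition label (default "unspecified").
#' @param protein_conc initial monomer concentration, M (NA if unknown).
#' @param is_normalized logical: are `values` fraction-aggregated?
#' @param normalization optional list recording the fluorescence -> f
#'   mapping (fields `f_base`, `f_plateau`), attached by
#'   [normalize_trace()].
#' @return An object of class `tht_series`.
#' @export
tht_series <- function(times, values, replicate_id = "r1",
                       condition = "unspecified", protein_conc = NA_real_,
                       is_normalized = FALSE, normalization = NULL) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (length(times) < 2L)
    stop("a ThT trace needs at least 2 points (got ", length(times), ")")
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and >= 0")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (isTRUE(is_normalized)) {
    ok <- is.na(values) | (values >= -0.1 & values <= 1.1)
    if (!all(ok))
      stop("normalized values must lie in [-0.1, 1.1]; offending index ",
           which(!ok)[1])
  }
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         replicate_id = replicate_id, condition = condition,
         protein_conc = protein_conc,
         is_normalized = isTRUE(is_normalized),
         normalization = normalization),
    class = "tht_series"
  )
}

#' @export
print.tht_series <- function(x, ...) {
  cat(sprintf("ThT time series '%s' / %s: %d points, t in [%g, %g] s, %s\n",
              x$condition, x$replicate_id, length(x$times),
              min(x$times), max(x$times),
              if (x$is_normalized) "normalized (fraction)" else "raw (a.u.)"))
  invisible(x)
}

#' @export
length.tht_series <- function(x) length(x$times)

#' Convert a ThT series to a data frame
#'
#' @param x a `tht_series`.
#' @param ... unused.
#' @return data.frame with columns `time_s`, `value`, `replicate_id`,
#'   `condition`.
#' @export
as.data.frame.tht_series <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values,
             replicate_id = x$replicate_id, condition = x$condition,
             stringsAsFactors = FALSE)
}
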