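#' Read a plate-reader time-course CSV
#'
#' Expected dialect: UTF-8 delimited text with a header row
#' `time_s, <well ids...>`, one row per reading, decimal points, times
#' in seconds (pass `times_in_minutes = TRUE` for files exported in
#' minutes; they are converted once at parse). Missing cells are
#' allowed and recorded as NA. Parse errors (non-monotone time column,
#' duplicate well ids, non-numeric cells) name the offending row or
#' column.
#'
#' @param path CSV file path.
#' @param times_in_minutes logical; convert a minutes column to
#'   seconds (default FALSE).
#' @param condition condition label stamped on every series.
#' @return list of `tht_series`, one per well column, named by well id.
#' @examples
#' path <- system.file("extdata", "synthetic_timecourse.csv",
#'                     package = "amylokin")
#' traces <- read_timecourse_csv(path, condition = "example")
#' traces$r1
#' @export
read_timecourse_csv <- function(path, times_in_minutes = FALSE,
                                condition = "unspecified") {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2L)
    stop("time-course file needs a time_s column plus >= 1 well column")
  if (names(raw)[1] != "time_s")
    stop("first column must be named 'time_s' (got '", names(raw)[1], "')")
  wells <- names(raw)[-1]
  dup <- wells[duplicated(wells)]
  if (length(dup))
    stop("duplicate well id(s) in header: ", paste(unique(dup), collapse = ", "))
  parse_col <- function(x, colname) {
    x[x == ""] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop("non-numeric cell in column '", colname, "', row ", bad[1],
           " (value '", x[bad[1]], "')")
    v
  }
  times <- parse_col(raw[[1]], "time_s")
  if (any(is.na(times))) stop("missing value in time_s column, row ",
                              which(is.na(times))[1])
  if (times_in_minutes) times <- times * 60
  if (is.unsorted(times, strictly = TRUE)) {
    i <- which(diff(times) <= 0)[1]
    stop("time_s column not strictly increasing at row ", i + 1L)
  }
  out <- lapply(wells, function(w)
    tht_series(times, parse_col(raw[[w]], w), replicate_id = w,
               condition = condition))
  names(out) <- wells
  out
}

#' Write ThT series to the time-course CSV dialect
#'
#' Inverse of [read_timecourse_csv()]: all series must share one time
#' grid; one column per series, named by replicate id.
#'
#' @param traces list of `tht_series` on a common time grid.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(traces, path) {
  stopifnot(is.list(traces), length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "tht_series")))
  tt <- traces[[1]]$times
  same <- vapply(traces, function(x)
    length(x$times) == length(tt) && all(x$times == tt), logical(1))
  if (!all(same)) stop("all traces must share one time grid")
  d <- data.frame(time_s = tt)
  ids <- vapply(traces, `[[`, character(1), "replicate_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  for (i in seq_along(traces)) d[[ids[i]]] <- traces[[i]]$values
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Round half away from zero (R's round() is half-to-even); report
# times are printed as integer seconds under this rule.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a screening report CSV
#'
#' One row per compound with percent inhibition/disaggregation
#' printed to 1 decimal, SEM to 2 decimals, replicate count and the
#' toxicity flag. Rounding happens only here, at the reporting layer.
#'
#' @param reports a `screen_report` data.frame (see [screen_plate()]),
#'   or several rbind-ed together. Must be non-empty.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(reports, path) {
  stopifnot(is.data.frame(reports))
  if (nrow(reports) == 0L) stop("empty report: nothing to write")
  out <- data.frame(
    compound = reports$compound,
    metric = reports$metric,
    percent = sprintf("%.1f", round_half_up(reports$percent, 1)),
    sem = sprintf("%.2f", round_half_up(reports$sem, 2)),
    n = reports$n,
    toxic = reports$toxic,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a kinetic-parameter report CSV
#'
#' One row per fitted condition: rate constants to 4 significant
#' figures, characteristic times as integer seconds (round half up),
#' residual RMS and convergence flag.
#'
#' @param fits named list of `agg_fit` objects (names = condition
#'   labels) or a single fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinetic_report <- function(fits, path) {
  if (inherits(fits, "agg_fit")) fits <- list(fit = fits)
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "agg_fit")))
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, `[[`, character(1), "condition")
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(
      condition = nm,
      k_n = signif(f$params$k_n, 4),
      k_e = signif(f$params$k_e, 4),
      rho = signif(f$rho_hat, 4),
      k = signif(f$k_hat, 4),
      t0 = round_half_up(f$times$t0),
      t_half = round_half_up(f$times$t_half),
      t1 = round_half_up(f$times$t1),
      rms = signif(f$residual_rms, 3),
      converged = f$converged,
      n_points = f$n_points,
      n_replicates = f$n_replicates,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write a run configuration (YAML)
#'
#' A run configuration ties a pipeline invocation together: input
#' paths, the well -> role/compound plate layout, protein
#' concentration, metric kind, fitting strategy, toxicity threshold,
#' output directory and seed. Round-trips losslessly through YAML.
#'
#' @param path YAML file path.
#' @return `read_run_config`: the validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a run-config list (see [validate_run_config()]).
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks the structural invariants: positive protein concentration,
#' known metric kind and fitting strategy, and a plate layout in which
#' every well maps to a role (compound wells to a compound id).
#'
#' @param config a named list.
#' @return The config, invisibly, or an error naming the defect.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  required <- c("protein_conc_M", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("run config missing field(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(config$protein_conc_M) || config$protein_conc_M <= 0)
    stop("protein_conc_M must be > 0")
  if (!is.null(config$metric_kind) &&
      !config$metric_kind %in% c("inhibition_in_vitro", "disaggregation",
                                 "inhibition_in_cellulo"))
    stop("unknown metric_kind: ", config$metric_kind)
  if (!is.null(config$strategy) &&
      !config$strategy %in% c("averaged", "pooled"))
    stop("unknown fitting strategy: ", config$strategy)
  if (!is.null(config$layout)) {
    for (w in names(config$layout)) {
      entry <- config$layout[[w]]
      if (is.null(entry$role))
        stop("layout entry for well '", w, "' has no role")
      if (identical(entry$role, "compound") && is.null(entry$compound))
        stop("layout entry for well '", w,
             "' is a compound well without a compound id")
    }
  }
  invisible(config)
}
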