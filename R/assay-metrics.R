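#' Percent inhibition of aggregation (in vitro ThT endpoint)
#'
#' Two-point normalization of a 24 h endpoint fluorescence reading
#' between the aggregated positive control (DMSO, 0% inhibition) and a
#' monomer/dye blank (100% inhibition):
#' `100 * (control - compound) / (control - blank)`.
#' When no blank was run the blank defaults to 0 a.u. (raw control
#' ratio). Values are never clipped: aggregation promoters come out
#' negative and stay visible.
#'
#' @param compound_f endpoint fluorescence with compound, a.u.
#' @param aggregated_control_f aggregated (DMSO) control fluorescence.
#' @param monomer_blank_f monomer/blank fluorescence (default 0).
#' @return Percent inhibition (may be < 0 or > 100). Vectorised over
#'   `compound_f`.
#' @export
inhibition_in_vitro <- function(compound_f, aggregated_control_f,
                                monomer_blank_f = 0) {
  check_anchors(aggregated_control_f, monomer_blank_f,
                "aggregated control", "monomer blank")
  100 * (aggregated_control_f - compound_f) /
    (aggregated_control_f - monomer_blank_f)
}

#' Percent disaggregation of preformed fibrils
#'
#' Fractional loss of fibril-bound ThT signal after incubating
#' preformed fibers with a compound, normalized between the untreated
#' fibril control (0%) and the monomer control (100%):
#' `100 * (fibril - after) / (fibril - monomer)`.
#'
#' @param after_f fluorescence after 24 h incubation with compound.
#' @param fibril_control_f untreated fibril control fluorescence.
#' @param monomer_f monomer (never-aggregated) control fluorescence.
#' @return Percent disaggregation, unclipped. Vectorised over `after_f`.
#' @export
disaggregation_percent <- function(after_f, fibril_control_f, monomer_f) {
  check_anchors(fibril_control_f, monomer_f,
                "fibril control", "monomer control")
  100 * (fibril_control_f - after_f) / (fibril_control_f - monomer_f)
}

#' Percent inhibition in the in cellulo ThS screen
#'
#' Bacterial inclusion-body screen arithmetic: the induced culture
#' with DMSO only defines 0% inhibition (maximal amyloid level) and
#' the non-induced culture defines 100% (minimal level):
#' `100 * (induced_dmso - sample) / (induced_dmso - no_inducer)`.
#'
#' @param sample_f ThS fluorescence of the induced culture with compound.
#' @param induced_dmso_f induced DMSO control (0% anchor).
#' @param no_inducer_f non-induced control (100% anchor).
#' @return Percent inhibition, unclipped. Vectorised over `sample_f`.
#' @export
inhibition_in_cellulo <- function(sample_f, induced_dmso_f, no_inducer_f) {
  check_anchors(induced_dmso_f, no_inducer_f,
                "induced DMSO control", "no-inducer control")
  100 * (induced_dmso_f - sample_f) / (induced_dmso_f - no_inducer_f)
}

check_anchors <- function(high, low, high_name, low_name) {
  stopifnot(is.numeric(high), is.numeric(low))
  if (any(high <= low))
    stop("degenerate plate: ", high_name, " (", high,
         ") does not exceed ", low_name, " (", low, ")")
  invisible(TRUE)
}

#' Mean and SEM over assay replicates
#'
#' Arithmetic mean and standard error of the mean (sample SD with n-1
#' denominator over sqrt(n)) of replicate percent values. A single
#' replicate yields SEM 0 with `single_replicate = TRUE`.
#'
#' @param values numeric vector of replicate percents, n >= 1.
#' @return list with `mean`, `sem`, `n`, `single_replicate`.
#' @examples
#' aggregate_replicates(c(40, 50, 60))  # mean 50, SEM 10/sqrt(3)
#' @export
aggregate_replicates <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) == 0L) stop("no replicate values supplied")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n == 1L) 0 else stats::sd(values) / sqrt(n),
       n = n,
       single_replicate = n == 1L)
}

#' Flag compound toxicity from bacterial growth (OD620)
#'
#' Growth control for the in cellulo screen: a compound is flagged as
#' potentially toxic (its apparent inhibition unreliable) when the
#' culture's OD620 falls below `threshold_ratio` of the control
#' culture's OD620 (strict inequality; default ratio 0.8).
#'
#' @param sample_od620 OD620 of the compound-treated culture.
#' @param control_od620 OD620 of the control culture, > 0.
#' @param threshold_ratio growth-ratio cutoff (default 0.8).
#' @return logical flag, TRUE when growth is suppressed.
#' @export
toxicity_flag <- function(sample_od620, control_od620,
                          threshold_ratio = 0.8) {
  stopifnot(is.numeric(sample_od620), is.numeric(control_od620))
  if (any(control_od620 <= 0)) stop("control OD620 must be > 0")
  sample_od620 / control_od620 < threshold_ratio
}

#' Compare kinetic fits of a treated condition against control
#'
#' Fold decreases of the rate constants,
#' `fold_k_n = k_n(control) / k_n(treated)` (and likewise `fold_k_e`),
#' and absolute increments of the characteristic times,
#' `delta = treated - control`, for lag, half and end times.
#'
#' @param control,treated converged `agg_fit` objects.
#' @return list with `fold_k_n`, `fold_k_e`, `delta_t0`,
#'   `delta_t_half`, `delta_t1`.
#' @export
compare_kinetics <- function(control, treated) {
  stopifnot(inherits(control, "agg_fit"), inherits(treated, "agg_fit"))
  if (!control$converged || !treated$converged)
    stop("compare_kinetics requires converged fits on both sides")
  list(
    fold_k_n = control$params$k_n / treated$params$k_n,
    fold_k_e = control$params$k_e / treated$params$k_e,
    delta_t0 = treated$times$t0 - control$times$t0,
    delta_t_half = treated$times$t_half - control$times$t_half,
    delta_t1 = treated$times$t1 - control$times$t1
  )
}

#' Summarize an endpoint plate into per-compound screen reports
#'
#' Applies the metric appropriate to `metric_kind` to every compound
#' record of a plate (a `plate_record` data frame), then aggregates
#' compound replicates into mean +/- SEM. Replicates model independent
#' experiments, each run with its own controls: when every replicate
#' index carries its own control records, each compound reading is
#' normalized against the anchors of the same replicate (so
#' plate-to-plate anchor variability propagates into the replicate
#' spread and hence the SEM); otherwise anchors are pooled across the
#' plate. For the in cellulo screen a toxicity flag is set from OD620
#' when present.
#'
#' @param plate a data.frame of plate records (see [plate_record()]).
#' @param metric_kind one of `"inhibition_in_vitro"`,
#'   `"disaggregation"`, `"inhibition_in_cellulo"`.
#' @param toxicity_threshold OD620 growth-ratio cutoff (default 0.8).
#' @return A `screen_report` data.frame: one row per compound with
#'   columns `compound`, `metric`, `percent`, `sem`, `n`, `toxic`.
#' @export
screen_plate <- function(plate,
                         metric_kind = c("inhibition_in_vitro",
                                         "disaggregation",
                                         "inhibition_in_cellulo"),
                         toxicity_threshold = 0.8) {
  metric_kind <- match.arg(metric_kind)
  stopifnot(is.data.frame(plate),
            all(c("well", "role", "compound", "fluorescence") %in%
                  names(plate)))
  roles_needed <- switch(metric_kind,
    inhibition_in_vitro = c(high = "positive_control",
                            low = "monomer_blank"),
    disaggregation = c(high = "positive_control", low = "monomer_blank"),
    inhibition_in_cellulo = c(high = "induced_dmso_control",
                              low = "no_inducer_control"))
  if (!"replicate" %in% names(plate)) plate$replicate <- 1L
  anchor <- function(role, rep = NULL, required = TRUE) {
    sel <- plate$role == role
    if (!is.null(rep)) sel <- sel & plate$replicate == rep
    v <- plate$fluorescence[sel]
    if (length(v) == 0L) {
      if (required) stop("plate has no '", role, "' records")
      return(NA_real_)
    }
    mean(v)
  }
  low_required <- metric_kind != "inhibition_in_vitro"
  cmp <- plate[plate$role == "compound", , drop = FALSE]
  if (nrow(cmp) == 0L) stop("plate has no compound records")
  # pair anchors by replicate when every compound replicate has them
  paired <- all(vapply(unique(cmp$replicate), function(r)
    any(plate$role == roles_needed[["high"]] & plate$replicate == r) &&
      (!low_required ||
         any(plate$role == roles_needed[["low"]] & plate$replicate == r)),
    logical(1)))
  percent_of <- function(f, rep) {
    r <- if (paired) rep else NULL
    high <- anchor(roles_needed[["high"]], r)
    low <- anchor(roles_needed[["low"]], r, required = low_required)
    if (is.na(low)) low <- 0
    switch(metric_kind,
           inhibition_in_vitro = inhibition_in_vitro(f, high, low),
           disaggregation = disaggregation_percent(f, high, low),
           inhibition_in_cellulo = inhibition_in_cellulo(f, high, low))
  }
  has_od <- "od620" %in% names(plate) && any(is.finite(plate$od620))
  ctrl_od <- if (has_od && metric_kind == "inhibition_in_cellulo")
    mean(plate$od620[plate$role == "induced_dmso_control"]) else NA_real_
  rows <- lapply(split(cmp, cmp$compound), function(d) {
    pct <- mapply(percent_of, d$fluorescence, d$replicate)
    agg <- aggregate_replicates(pct)
    toxic <- if (is.finite(ctrl_od))
      any(toxicity_flag(d$od620, ctrl_od, toxicity_threshold)) else FALSE
    data.frame(compound = d$compound[1], metric = metric_kind,
               percent = agg$mean, sem = agg$sem, n = agg$n,
               toxic = toxic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screen_report", "data.frame")
  out
}
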