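#' Plate record constructor
#'
#' One endpoint measurement: a well, its role on the plate, an
#' optional compound id, the fluorescence reading and (for in cellulo
#' screens) the OD620 growth reading. Roles are drawn from the closed
#' set used by the three assay families.
#'
#' @param well well identifier(s).
#' @param role one of `positive_control`, `negative_control`,
#'   `monomer_blank`, `no_inducer_control`, `induced_dmso_control`,
#'   `compound`.
#' @param fluorescence endpoint fluorescence, a.u., >= 0.
#' @param compound compound id (required for role `"compound"`).
#' @param od620 OD620 absorbance (in cellulo only; default NA).
#' @param replicate replicate index (default 1).
#' @return data.frame of plate records.
#' @export
plate_record <- function(well, role, fluorescence, compound = NA_character_,
                         od620 = NA_real_, replicate = 1L) {
  roles <- c("positive_control", "negative_control", "monomer_blank",
             "no_inducer_control", "induced_dmso_control", "compound")
  if (!all(role %in% roles))
    stop("unknown role(s): ", paste(setdiff(role, roles), collapse = ", "))
  if (any(fluorescence < 0)) stop("fluorescence must be >= 0")
  d <- data.frame(well = well, role = role, compound = compound,
                  fluorescence = fluorescence, od620 = od620,
                  replicate = replicate, stringsAsFactors = FALSE)
  bad <- d$role == "compound" & (is.na(d$compound) | d$compound == "")
  if (any(bad))
    stop("compound records need a compound id (well ",
         paste(d$well[bad], collapse = ", "), ")")
  d
}

#' Generator configuration for synthetic ThT time courses
#'
#' Describes the simulated plate-reader experiment: the underlying
#' kinetic parameters, the sampling grid (default one reading every
#' 300 s, i.e. each 5 min), multiplicative Gaussian noise with
#' coefficient of variation `noise_cv` (default 0.05, matching
#' replicate standard errors below 5%), triplicate wells, and the
#' affine fluorescence map (baseline + amplitude * f).
#'
#' @param params a `kinetic_params` object.
#' @param t_span total simulated time, s.
#' @param t_step sampling interval, s (default 300).
#' @param noise_cv multiplicative noise CV as a fraction of the signal
#'   (default 0.05).
#' @param n_replicates wells per condition (default 3).
#' @param baseline fluorescence baseline, a.u. (default 100).
#' @param amplitude fluorescence amplitude of the transition, a.u.
#'   (default 1000).
#' @param seed master seed; each replicate draws from its own
#'   deterministic substream, so identical seeds give identical output.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(params, t_span, t_step = 300,
                             noise_cv = 0.05, n_replicates = 3L,
                             baseline = 100, amplitude = 1000,
                             seed = 1L) {
  stopifnot(inherits(params, "kinetic_params"),
            t_span > 0, t_step > 0, noise_cv >= 0, n_replicates >= 1,
            amplitude > 0, baseline >= 0)
  structure(
    list(params = params, t_span = t_span, t_step = t_step,
         noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
         baseline = baseline, amplitude = amplitude,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Per-replicate substream seed, kept well inside 32-bit range.
replicate_seed <- function(master, r) {
  (as.integer(master) %% 1000000L) * 1000L + as.integer(r)
}

#' Simulate replicate ThT aggregation time courses
#'
#' Forward-simulates the autocatalytic model on a uniform grid and
#' maps fraction to fluorescence as
#' `F(t) = baseline + amplitude * f(t) * (1 + eps) + eta`, with
#' `eps ~ N(0, noise_cv)` independent per point (multiplicative noise,
#' so the relative error is uniform across the sigmoid) and a small
#' additive noise floor `eta ~ N(0, 0.05 * noise_cv * amplitude)` so
#' pre-lag points are not noise-free. With `noise_cv = 0` the output
#' is exactly `baseline + amplitude * f(t)`. Deterministic under a
#' fixed seed; replicate r uses its own substream so any single
#' replicate can be regenerated independently.
#'
#' A warning is issued when `t_span < 2 * t_half`, where a subsequent
#' fit would be poorly constrained.
#'
#' @param config a `generator_config`.
#' @return list of `n_replicates` raw `tht_series`.
#' @examples
#' p <- kinetic_params(3.09e-5, 486.9, 1e-5)
#' cfg <- generator_config(p, t_span = 5000, noise_cv = 0, seed = 7)
#' traces <- generate_timecourse(cfg)
#' length(traces[[1]]$times)  # 0..5000 every 300 s -> 17 points
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$params
  tt <- seq(0, config$t_span, by = config$t_step)
  ct <- characteristic_times(p)
  if (config$t_span < 2 * ct$t_half)
    warning("t_span (", config$t_span, " s) < 2 * t_half (",
            round(2 * ct$t_half), " s): fit will be poorly constrained")
  f <- aggregated_fraction(p, tt)
  floor_sd <- 0.05 * config$noise_cv * config$amplitude
  lapply(seq_len(config$n_replicates), function(r) {
    vals <- config$baseline + config$amplitude * f
    if (config$noise_cv > 0) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(replicate_seed(config$seed, r))
      eps <- stats::rnorm(length(tt), 0, config$noise_cv)
      eta <- stats::rnorm(length(tt), 0, floor_sd)
      vals <- config$baseline + config$amplitude * f * (1 + eps) + eta
    }
    tht_series(tt, pmax(vals, 0), replicate_id = paste0("r", r),
               condition = "synthetic", protein_conc = p$a)
  })
}

# Save/restore the global RNG state so generators are seeded without
# clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic endpoint screening plate
#'
#' Builds control and compound records whose noiseless metric equals
#' the requested true percent, then applies multiplicative Gaussian
#' noise to every fluorescence reading. Anchors per metric kind:
#' \itemize{
#'   \item `inhibition_in_vitro`: aggregated positive control at
#'     `baseline + amplitude`, monomer blank at `baseline`.
#'   \item `disaggregation`: fibril control at `baseline + amplitude`,
#'     monomer control at `baseline`.
#'   \item `inhibition_in_cellulo`: induced DMSO control at
#'     `baseline + amplitude`, no-inducer control at `baseline`; all
#'     records carry OD620 1.0.
#' }
#' The compound well is placed at the linear-map preimage of the true
#' percent. True percents outside [-100, 200] are rejected as
#' unphysical for a generator.
#'
#' @param true_percents named numeric vector or list,
#'   compound id -> true percent.
#' @param metric_kind one of the three metric kinds (see
#'   [screen_plate()]).
#' @param noise_cv multiplicative noise CV (default 0.02).
#' @param seed master seed.
#' @param n_replicates replicates per record (default 3).
#' @param baseline,amplitude fluorescence anchors, a.u.
#' @return A plate data.frame (see [plate_record()]).
#' @export
generate_endpoint_plate <- function(true_percents,
                                    metric_kind = c("inhibition_in_vitro",
                                                    "disaggregation",
                                                    "inhibition_in_cellulo"),
                                    noise_cv = 0.02, seed = 1L,
                                    n_replicates = 3L,
                                    baseline = 100, amplitude = 1000) {
  metric_kind <- match.arg(metric_kind)
  true_percents <- unlist(true_percents)
  stopifnot(length(true_percents) >= 1L, !is.null(names(true_percents)),
            all(nzchar(names(true_percents))))
  if (any(true_percents < -100 | true_percents > 200))
    stop("true percents outside [-100, 200] are unphysical for the generator")
  high <- baseline + amplitude   # 0% anchor (full signal)
  low <- baseline                # 100% anchor (no signal)
  ctrl_roles <- switch(metric_kind,
    inhibition_in_vitro = c(high = "positive_control",
                            low = "monomer_blank"),
    disaggregation = c(high = "positive_control", low = "monomer_blank"),
    inhibition_in_cellulo = c(high = "induced_dmso_control",
                              low = "no_inducer_control"))
  in_cellulo <- metric_kind == "inhibition_in_cellulo"
  rows <- list()
  wid <- 0L
  add <- function(role, compound, true_f, rep) {
    wid <<- wid + 1L
    rows[[wid]] <<- plate_record(
      well = sprintf("W%02d", wid), role = role,
      fluorescence = true_f, compound = compound,
      od620 = if (in_cellulo) 1.0 else NA_real_, replicate = rep)
  }
  for (r in seq_len(n_replicates)) {
    add(ctrl_roles[["high"]], NA_character_, high, r)
    add(ctrl_roles[["low"]], NA_character_, low, r)
    for (cmp in names(true_percents)) {
      f_true <- high - true_percents[[cmp]] / 100 * (high - low)
      add("compound", cmp, f_true, r)
    }
  }
  plate <- do.call(rbind, rows)
  if (noise_cv > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(replicate_seed(seed, 0L))
    eps <- stats::rnorm(nrow(plate), 0, noise_cv)
    plate$fluorescence <- pmax(plate$fluorescence * (1 + eps), 0)
  }
  plate
}

#' Generate a fibril-disaggregation endpoint series over compound ratios
#'
#' Emulates mixing preformed fibrils with a compound at increasing
#' compound:protein ratios. The fraction of fibril signal removed at
#' ratio r is `1 - (1 - effect)^r`: equal to `effect` at the equimolar
#' 1:1 ratio and saturating monotonically toward 1 as the compound
#' excess grows, so reported disaggregation percents strictly increase
#' with ratio (for 0 < effect < 1). Fibril and monomer controls are
#' included; noise as in [generate_endpoint_plate()].
#'
#' @param params `kinetic_params` of the fibril-forming condition
#'   (recorded for provenance; the endpoint arithmetic only uses the
#'   fluorescence anchors).
#' @param compound_effect fraction of fibril signal removed at the 1:1
#'   ratio, in [0, 1].
#' @param ratios compound:protein molar ratios, non-empty, > 0.
#' @param compound compound id (default "cmp").
#' @param noise_cv,seed,n_replicates,baseline,amplitude as in
#'   [generate_endpoint_plate()].
#' @return A plate data.frame; compound wells are labelled
#'   `<compound>@<ratio>`.
#' @export
generate_disaggregation_series <- function(params, compound_effect, ratios,
                                           compound = "cmp",
                                           noise_cv = 0.02, seed = 1L,
                                           n_replicates = 3L,
                                           baseline = 100, amplitude = 1000) {
  stopifnot(inherits(params, "kinetic_params"), length(ratios) >= 1L,
            all(ratios > 0))
  if (compound_effect < 0) stop("compound_effect must be >= 0")
  if (compound_effect > 1) stop("compound_effect must be <= 1")
  pct <- 100 * (1 - (1 - compound_effect)^ratios)
  names(pct) <- paste0(compound, "@", ratios)
  generate_endpoint_plate(pct, metric_kind = "disaggregation",
                          noise_cv = noise_cv, seed = seed,
                          n_replicates = n_replicates,
                          baseline = baseline, amplitude = amplitude)
}
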