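#' Geometric (log-equidistant) concentration series
#'
#' Builds the n-point concentration series used on the screening plates:
#' points equally spaced in log10 between the two endpoints, endpoints
#' included. An 8-point series from 0.10 to 21.54 uM has common ratio
#' 10^(1/3), i.e. three points per decade.
#'
#' @param lowest lowest concentration (uM), > 0.
#' @param highest highest concentration (uM), > lowest.
#' @param n number of concentrations (>= 2), default 8.
#' @return strictly increasing numeric vector of length `n` whose first and
#'   last elements are exactly `lowest` and `highest`.
#' @examples
#' geometric_series(0.10, 21.54, 8)
#' @export
geometric_series <- function(lowest, highest, n = 8) {
  if (!is.numeric(lowest) || !is.numeric(highest) ||
    lowest <= 0 || highest <= lowest) {
    stop("need 0 < lowest < highest", call. = FALSE)
  }
  if (n < 2) stop("need at least 2 concentrations", call. = FALSE)
  out <- 10^seq(log10(lowest), log10(highest), length.out = n)
  out[1] <- lowest
  out[n] <- highest
  out
}

#' Hill occupancy function
#'
#' `hill(c) = 1 / (1 + (ec50/c)^slope)`; equals 1/2 at `c = ec50` for any
#' slope and rises from 0 to 1 with concentration.
#'
#' @param conc concentration(s), uM.
#' @param ec50 midpoint concentration, uM.
#' @param slope Hill slope (> 0).
#' @export
hill <- function(conc, ec50, slope) 1 / (1 + (ec50 / conc)^slope)

#' Concentration-response model for one condition
#'
#' Parametric truth underlying a simulated condition:
#' `response(c) = baseline * (1 + s * (max_fold_change - 1) * hill(c))` with
#' `s = +1` (induction) or `-1` (loss, e.g. viability), plus Gaussian noise.
#' The onset concentration -- the analogue of the point of departure -- is
#' where the noiseless effect first equals the 2-SD control band half-width
#' `2 * noise_sd`; either `ec50` or `onset_concentration` may be given and
#' the other is derived from that crossing.
#'
#' @param baseline solvent-control response level (> 0).
#' @param max_fold_change plateau fold change relative to baseline (>= 1);
#'   1 means a null (flat) condition.
#' @param hill_slope Hill slope (> 0).
#' @param noise_sd SD of the additive Gaussian well noise (>= 0).
#' @param direction `"increase"` (reporter induction) or `"decrease"`
#'   (viability-style loss).
#' @param ec50 midpoint concentration, uM.
#' @param onset_concentration true onset (PoD analogue), uM.
#' @return a `response_model` list with all fields populated (derived ones
#'   included; `onset_concentration` is `NA` when it cannot be defined, e.g.
#'   a flat or noiseless model).
#' @export
response_model <- function(baseline = 1, max_fold_change = 3, hill_slope = 2,
                           noise_sd = 0, direction = c("increase", "decrease"),
                           ec50 = NULL, onset_concentration = NULL) {
  direction <- match.arg(direction)
  stopifnot(baseline > 0, max_fold_change >= 1, hill_slope > 0, noise_sd >= 0)
  if (is.null(ec50) && is.null(onset_concentration)) {
    stop("supply `ec50` or `onset_concentration`", call. = FALSE)
  }
  # occupancy at which the deterministic effect equals the 2-SD band
  q <- if (max_fold_change > 1) {
    2 * noise_sd / (baseline * (max_fold_change - 1))
  } else {
    NA_real_
  }
  if (is.null(ec50)) {
    if (!is.finite(q) || q <= 0 || q >= 1) {
      stop(
        "cannot derive ec50 from onset: need max_fold_change > 1 and ",
        "0 < 2*noise_sd < baseline*(max_fold_change - 1)",
        call. = FALSE
      )
    }
    stopifnot(onset_concentration > 0)
    ec50 <- onset_concentration * ((1 - q) / q)^(1 / hill_slope)
  } else if (is.null(onset_concentration)) {
    onset_concentration <- if (is.finite(q) && q > 0 && q < 1) {
      ec50 * (q / (1 - q))^(1 / hill_slope)
    } else {
      NA_real_
    }
  }
  stopifnot(ec50 > 0)
  if (direction == "increase" && is.finite(onset_concentration) &&
    ec50 < onset_concentration) {
    stop("ec50 must be >= onset_concentration for an increasing model",
      call. = FALSE
    )
  }
  structure(list(
    baseline = baseline, max_fold_change = max_fold_change,
    hill_slope = hill_slope, noise_sd = noise_sd, direction = direction,
    ec50 = ec50, onset_concentration = onset_concentration
  ), class = "response_model")
}

#' Noiseless response of a model at given concentrations
#' @param model a [response_model].
#' @param conc concentrations, uM.
#' @return deterministic response values.
#' @export
model_response <- function(model, conc) {
  s <- if (model$direction == "increase") 1 else -1
  model$baseline *
    (1 + s * (model$max_fold_change - 1) * hill(conc, model$ec50, model$hill_slope))
}

#' Plate design for a simulated screen
#'
#' @param models culture-model identifiers (e.g. "2D-DMEM", "2D-AAGLY",
#'   "3D-DMEM", "3D-AAGLY").
#' @param reporters reporter identifiers (e.g. "p53", "p21", "BTG2").
#' @param compounds named list of concentration series; each series must be
#'   8 strictly increasing positive concentrations (the screen format).
#' @param durations exposure-duration labels (e.g. "24h", "48h", "72h").
#' @param n_replicates biological replicates per condition (>= 3).
#' @param solvent_control_wells solvent-control wells per condition
#'   (default 16, one full column of a 384-well plate -- the standard
#'   high-content-screening layout for solvent controls; the width of the
#'   2-SD control band is estimated from these wells, so too few of them
#'   makes the point-of-departure call unstable).
#' @return a `plate_design` list.
#' @export
plate_design <- function(models, reporters, compounds, durations = "24h",
                         n_replicates = 3, solvent_control_wells = 16) {
  if (is.null(names(compounds)) || any(!nzchar(names(compounds)))) {
    stop("`compounds` must be a named list of concentration series", call. = FALSE)
  }
  for (nm in names(compounds)) {
    cc <- compounds[[nm]]
    if (length(cc) != 8L || any(cc <= 0) || any(diff(cc) <= 0)) {
      stop(sprintf(
        "compound '%s': series must be 8 strictly increasing positive concentrations", nm
      ), call. = FALSE)
    }
  }
  if (n_replicates < 3) stop("need >= 3 biological replicates", call. = FALSE)
  stopifnot(solvent_control_wells >= 2)
  structure(list(
    models = models, reporters = reporters, compounds = compounds,
    durations = durations, n_replicates = n_replicates,
    solvent_control_wells = solvent_control_wells
  ), class = "plate_design")
}

#' Key identifying one (model, reporter, compound) condition
#' @param model,reporter,compound character identifiers.
#' @return `"model:reporter:compound"` string(s).
#' @export
condition_key <- function(model, reporter, compound) {
  paste(model, reporter, compound, sep = ":")
}

#' Simulate a well-level measurement table for a plate design
#'
#' For every (model, reporter, compound) condition, replicate and
#' concentration, emits one treated-well response drawn from the condition's
#' [response_model], plus solvent-control wells at baseline. Also returns
#' the analytic truth (onset concentration, ec50) per condition for
#' recovery studies.
#'
#' @param design a [plate_design].
#' @param models named list of [response_model]s keyed
#'   `"model:reporter:compound"` (see [condition_key]); every condition in
#'   the design must be present.
#' @param seed integer seed.
#' @param readout readout label written into the table (default `"gfp"`).
#' @return list with `wells` (data.frame: model, reporter, compound,
#'   concentration_uM, duration, replicate, well_type, readout, value) and
#'   `truth` (data.frame of the true onset and ec50 per condition).
#' @export
generate_response_table <- function(design, models, seed = 1L, readout = "gfp") {
  stopifnot(inherits(design, "plate_design"))
  combos <- expand.grid(
    model = design$models, reporter = design$reporters,
    compound = names(design$compounds), duration = design$durations,
    stringsAsFactors = FALSE
  )
  keys <- condition_key(combos$model, combos$reporter, combos$compound)
  missing <- setdiff(unique(keys), names(models))
  if (length(missing)) {
    stop(
      "no response model for condition(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }

  with_seed(seed, {
    rows <- vector("list", nrow(combos))
    for (j in seq_len(nrow(combos))) {
      cmb <- combos[j, ]
      m <- models[[condition_key(cmb$model, cmb$reporter, cmb$compound)]]
      conc <- design$compounds[[cmb$compound]]
      det <- model_response(m, conc)
      treated <- expand.grid(
        concentration_uM = conc, replicate = seq_len(design$n_replicates)
      )
      treated$value <- rep(det, design$n_replicates) +
        stats::rnorm(nrow(treated), 0, m$noise_sd)
      ctrl <- data.frame(
        concentration_uM = 0,
        replicate = seq_len(design$solvent_control_wells),
        value = m$baseline + stats::rnorm(design$solvent_control_wells, 0, m$noise_sd)
      )
      both <- rbind(
        cbind(treated, well_type = "treated"),
        cbind(ctrl, well_type = "solvent")
      )
      rows[[j]] <- data.frame(
        model = cmb$model, reporter = cmb$reporter, compound = cmb$compound,
        concentration_uM = both$concentration_uM, duration = cmb$duration,
        replicate = both$replicate, well_type = both$well_type,
        readout = readout, value = both$value,
        stringsAsFactors = FALSE
      )
    }
    wells <- do.call(rbind, rows)
    rownames(wells) <- NULL

    truth <- cbind(combos, data.frame(
      true_onset_uM = vapply(keys, function(k) models[[k]]$onset_concentration, 0),
      ec50_uM = vapply(keys, function(k) models[[k]]$ec50, 0),
      max_fold_change = vapply(keys, function(k) models[[k]]$max_fold_change, 0),
      direction = vapply(keys, function(k) models[[k]]$direction, ""),
      row.names = NULL
    ))
    list(wells = wells, truth = truth)
  })
}
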