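#' Concentration-response curve for one condition
#'
#' Bundles the treated-well responses over a concentration series with the
#' solvent-control wells that define the baseline and its variability.
#'
#' @param concentrations strictly increasing positive concentrations (uM).
#' @param responses treated responses: a numeric vector (one replicate per
#'   concentration), a matrix with one row per concentration, or a
#'   data.frame with columns `concentration` and `value`.
#' @param control_values solvent-control replicate values (nonempty).
#' @return a `response_curve` with derived `control_mean` and `control_sd`
#'   (the SD of the control replicate values).
#' @export
response_curve <- function(concentrations, responses, control_values) {
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop("concentrations must be positive and strictly increasing", call. = FALSE)
  }
  if (is.data.frame(responses)) {
    obs <- data.frame(
      concentration = responses$concentration,
      value = responses$value
    )
    if (!all(obs$concentration %in% concentrations)) {
      stop("response concentrations must come from the series", call. = FALSE)
    }
  } else if (is.matrix(responses)) {
    if (nrow(responses) != length(concentrations)) {
      stop("need one response row per concentration", call. = FALSE)
    }
    obs <- data.frame(
      concentration = rep(concentrations, ncol(responses)),
      value = as.numeric(responses)
    )
  } else {
    if (length(responses) != length(concentrations)) {
      stop("need one response per concentration", call. = FALSE)
    }
    obs <- data.frame(concentration = concentrations, value = as.numeric(responses))
  }
  if (!length(control_values)) stop("control set must be nonempty", call. = FALSE)
  structure(list(
    concentrations = concentrations,
    obs = obs,
    control_values = as.numeric(control_values),
    control_mean = mean(control_values),
    control_sd = stats::sd(control_values)
  ), class = "response_curve")
}

#' Build response curves from a tidy well table
#'
#' Splits a well-level table (as written by [generate_response_table()] or
#' the quantification summaries) into one [response_curve] per
#' (model, reporter, compound, duration) condition.
#'
#' @param wells data.frame with columns `model`, `reporter`, `compound`,
#'   `duration`, `concentration_uM`, `well_type`, `value`.
#' @return named list of [response_curve]s keyed
#'   `"model:reporter:compound:duration"`.
#' @export
curves_from_table <- function(wells) {
  key <- interaction(wells$model, wells$reporter, wells$compound,
    wells$duration,
    sep = ":", drop = TRUE
  )
  lapply(split(wells, key), function(d) {
    tr <- d[d$well_type == "treated", ]
    ctrl <- d[d$well_type == "solvent", "value"]
    response_curve(
      sort(unique(tr$concentration_uM)),
      data.frame(concentration = tr$concentration_uM, value = tr$value),
      ctrl
    )
  })
}

#' Fold change relative to the solvent control
#'
#' Divides every treated and control value by the solvent-control mean, so
#' the control mean becomes 1 and responses read as fold induction.
#'
#' @param curve a [response_curve] with positive `control_mean`.
#' @return the rescaled [response_curve].
#' @export
fold_change <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  if (!is.finite(curve$control_mean) || curve$control_mean <= 0) {
    stop("degenerate control: control mean must be positive", call. = FALSE)
  }
  response_curve(
    curve$concentrations,
    data.frame(
      concentration = curve$obs$concentration,
      value = curve$obs$value / curve$control_mean
    ),
    curve$control_values / curve$control_mean
  )
}

#' Min-max normalisation to [0, 1]
#'
#' `x -> (x - min) / (max - min)`. Applied per culture model before
#' profiles are compared across models. A zero-range (constant) input maps
#' to all zeros and is flagged via the `"degenerate"` attribute rather than
#' raising an error.
#'
#' @param x numeric vector (nonempty).
#' @return normalised vector with attribute `degenerate` (logical).
#' @export
min_max_normalize <- function(x) {
  if (!length(x)) stop("empty input", call. = FALSE)
  rng <- range(x)
  if (diff(rng) == 0) {
    return(structure(rep(0, length(x)), degenerate = TRUE))
  }
  structure((x - rng[1]) / diff(rng), degenerate = FALSE)
}

#' Loess configuration for concentration-response fitting
#'
#' @param span fraction of points in each local fit (default 0.5, i.e. a
#'   span of 2/4).
#' @param degree local polynomial degree (fixed at 1).
#' @param grid_points number of log-spaced grid points used for the
#'   band-crossing search (default 512; interpolation error is then far
#'   below one dilution step).
#' @return a `loess_config` list.
#' @export
loess_config <- function(span = 0.5, degree = 1, grid_points = 512) {
  stopifnot(span > 0, span <= 1, degree == 1, grid_points >= 16)
  structure(list(span = span, degree = degree, grid_points = grid_points),
    class = "loess_config"
  )
}

#' Loess fit of responses against log10 concentration
#'
#' Locally weighted degree-1 regression (tricube weights) of all replicate
#' responses on log10(concentration). Solvent controls (concentration 0)
#' are not part of the fit; they only define the control band.
#'
#' @param curve a [response_curve] with >= 4 distinct concentrations.
#' @param config a [loess_config].
#' @return a `loess_curve`: list with the `stats::loess` fit and the tested
#'   concentration range; evaluate with [predict_response()].
#' @export
fit_loess <- function(curve, config = loess_config()) {
  stopifnot(inherits(curve, "response_curve"))
  if (length(unique(curve$obs$concentration)) < 4L) {
    stop("need at least 4 distinct concentrations for a loess fit", call. = FALSE)
  }
  d <- data.frame(
    lx = log10(curve$obs$concentration),
    value = curve$obs$value
  )
  fit <- stats::loess(value ~ lx,
    data = d, span = config$span,
    degree = config$degree, family = "gaussian",
    surface = "direct"
  )
  structure(
    list(fit = fit, range = range(curve$concentrations)),
    class = "loess_curve"
  )
}

#' Evaluate a fitted loess curve at given concentrations
#' @param object a `loess_curve` from [fit_loess()].
#' @param conc concentrations (uM) within the tested range.
#' @return fitted response values.
#' @export
predict_response <- function(object, conc) {
  stopifnot(inherits(object, "loess_curve"))
  as.numeric(stats::predict(object$fit, newdata = data.frame(lx = log10(conc))))
}

#' Point of departure from a fitted concentration-response curve
#'
#' The PoD is the lowest concentration at which the loess-fitted response
#' curve leaves the solvent-control band, defined as the control mean plus
#' or minus two control standard deviations. The fitted curve is evaluated
#' on a log-spaced grid over the tested range; the crossing is interpolated
#' linearly in log10 concentration between the bracketing grid points. If
#' the fit already sits outside the band at the lowest tested
#' concentration, the PoD is censored at that concentration. A curve that
#' never leaves the band has no PoD (direction `"none"`); no value is ever
#' extrapolated beyond the tested range.
#'
#' @param curve a [response_curve].
#' @param config a [loess_config].
#' @param input `"fold_change"` (default; responses are divided by the
#'   control mean first) or `"raw"`.
#' @param sd_method `"control"` (default: SD of the solvent-control
#'   replicate values) or `"residual"` (residual SD of the loess fit).
#' @return a `pod_result`: list with `pod` (uM or `NA`), `direction`
#'   (`"positive"`, `"negative"`, `"none"`), `censored`, `threshold_upper`,
#'   `threshold_lower`, `control_mean`, `control_sd`.
#' @export
compute_pod <- function(curve, config = loess_config(),
                        input = c("fold_change", "raw"),
                        sd_method = c("control", "residual")) {
  input <- match.arg(input)
  sd_method <- match.arg(sd_method)
  if (input == "fold_change") curve <- fold_change(curve)
  m <- curve$control_mean
  fit <- fit_loess(curve, config)
  s <- if (sd_method == "control") {
    if (length(curve$control_values) < 2L) {
      stop("need >= 2 control values for the control-SD band", call. = FALSE)
    }
    curve$control_sd
  } else {
    stats::sd(stats::residuals(fit$fit))
  }
  upper <- m + 2 * s
  lower <- m - 2 * s

  lgrid <- seq(log10(fit$range[1]), log10(fit$range[2]),
    length.out = config$grid_points
  )
  f <- predict_response(fit, 10^lgrid)

  above <- f > upper
  below <- f < lower
  res <- function(pod, direction, censored) {
    structure(list(
      pod = pod, direction = direction, censored = censored,
      threshold_upper = upper, threshold_lower = lower,
      control_mean = m, control_sd = s
    ), class = "pod_result")
  }
  if (above[1] || below[1]) {
    return(res(fit$range[1], if (above[1]) "positive" else "negative", TRUE))
  }
  cross <- function(outside, threshold) {
    i <- which(outside)[1]
    if (is.na(i)) return(NA_real_)
    # linear interpolation in log10 between the bracketing grid points
    lx <- lgrid[i - 1] +
      (threshold - f[i - 1]) / (f[i] - f[i - 1]) * (lgrid[i] - lgrid[i - 1])
    10^lx
  }
  pod_up <- cross(above, upper)
  pod_dn <- cross(below, lower)
  if (is.na(pod_up) && is.na(pod_dn)) {
    return(res(NA_real_, "none", FALSE))
  }
  if (is.na(pod_dn) || (!is.na(pod_up) && pod_up <= pod_dn)) {
    res(pod_up, "positive", FALSE)
  } else {
    res(pod_dn, "negative", FALSE)
  }
}

#' @export
print.pod_result <- function(x, ...) {
  if (x$direction == "none") {
    cat("<pod_result> no departure within the tested range\n")
  } else {
    cat(sprintf(
      "<pod_result> PoD = %.4g uM (%s direction%s)\n", x$pod, x$direction,
      if (x$censored) ", censored at lowest tested concentration" else ""
    ))
  }
  invisible(x)
}

#' Absolute IC50 from a viability curve
#'
#' Fits a four-parameter log-logistic curve with the top plateau fixed at
#' 100% of solvent control and returns the concentration at which the
#' fitted curve crosses 50% viability (the absolute IC50, not the curve's
#' own midpoint). If the fitted curve does not reach 50% within the tested
#' concentration range the IC50 is undefined; values are never
#' extrapolated.
#'
#' @param curve a [response_curve] of viability readouts (e.g. ATP
#'   luminescence).
#' @param normalize divide responses by the control mean and express them
#'   as percent of control first (default `TRUE`; set `FALSE` if the
#'   responses already are percentages with control at 100).
#' @return an `ic50_result`: list with `ic50` (uM or `NA`), `defined`,
#'   `censored` (`"above"` when the fitted curve crosses 50% only beyond
#'   the highest tested concentration, `"below"` for a crossing under the
#'   lowest, `"none"` otherwise) with the censoring bound in
#'   `censored_bound`, and the fitted parameters (`bottom`, `hill`,
#'   `midpoint`).
#' @export
compute_ic50 <- function(curve, normalize = TRUE) {
  stopifnot(inherits(curve, "response_curve"))
  conc <- curve$obs$concentration
  y <- curve$obs$value
  if (normalize) {
    if (curve$control_mean <= 0) stop("degenerate control", call. = FALSE)
    y <- 100 * y / curve$control_mean
  }
  out <- function(ic50, pars, censored = "none", bound = NA_real_) {
    structure(list(
      ic50 = ic50, defined = is.finite(ic50), censored = censored,
      censored_bound = bound,
      bottom = pars[1], hill = pars[2], midpoint = pars[3]
    ), class = "ic50_result")
  }
  if (diff(range(y)) < 1e-9) {
    # flat viability: no crossing can exist
    return(out(NA_real_, c(NA, NA, NA)))
  }
  # fit on log10 concentration for conditioning; try several slope starts
  d <- data.frame(lx = log10(conc), y = y)
  le_guess <- d$lx[which.min(abs(y - (100 + min(y)) / 2))]
  fit <- NULL
  errs <- character(0)
  for (h0 in c(1, 0.5, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (100 - bottom) / (1 + 10^(h * (lx - le))),
        data = d,
        start = list(bottom = max(0, min(y)), le = le_guess, h = h0),
        lower = c(bottom = -100, le = min(d$lx) - 2, h = 0.05),
        upper = c(bottom = 100, le = max(d$lx) + 2, h = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) {
        errs <<- c(errs, conditionMessage(e))
        NULL
      }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("viability curve fit failed: ", paste(unique(errs), collapse = "; "),
      call. = FALSE
    )
  }
  p <- stats::coef(fit)
  bottom <- p[["bottom"]]; e <- 10^p[["le"]]; h <- p[["h"]]
  if (bottom >= 50) {
    return(out(NA_real_, c(bottom, h, e)))
  }
  c50 <- e * ((100 - bottom) / (50 - bottom) - 1)^(1 / h)
  if (!is.finite(c50)) {
    return(out(NA_real_, c(bottom, h, e)))
  }
  lo <- min(conc); hi <- max(conc)
  # snap numerically-exact boundary crossings onto the boundary
  if (c50 > hi && c50 <= hi * (1 + 1e-6)) c50 <- hi
  if (c50 < lo && c50 >= lo * (1 - 1e-6)) c50 <- lo
  if (c50 > hi) {
    return(out(NA_real_, c(bottom, h, e), censored = "above", bound = hi))
  }
  if (c50 < lo) {
    return(out(NA_real_, c(bottom, h, e), censored = "below", bound = lo))
  }
  out(c50, c(bottom, h, e))
}

#' @export
print.ic50_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<ic50_result> absolute IC50 = %.4g uM\n", x$ic50))
  } else if (identical(x$censored, "above")) {
    cat(sprintf("<ic50_result> absolute IC50 > %.4g uM (above tested range)\n",
      x$censored_bound))
  } else if (identical(x$censored, "below")) {
    cat(sprintf("<ic50_result> absolute IC50 < %.4g uM (below tested range)\n",
      x$censored_bound))
  } else {
    cat("<ic50_result> undefined within the tested range\n")
  }
  invisible(x)
}

#' PoD table for every condition in a well table
#'
#' @param wells tidy well table (see [curves_from_table()]).
#' @param config a [loess_config].
#' @param ... passed on to [compute_pod()].
#' @return data.frame with one row per condition: the condition key split
#'   into columns plus `pod_uM`, `direction`, `censored`.
#' @export
pod_table <- function(wells, config = loess_config(), ...) {
  curves <- curves_from_table(wells)
  rows <- lapply(names(curves), function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    p <- compute_pod(curves[[k]], config, ...)
    data.frame(
      model = parts[1], reporter = parts[2], compound = parts[3],
      duration = parts[4], pod_uM = p$pod, direction = p$direction,
      censored = p$censored, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
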