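#' Write a channel image or z-stack as 16-bit TIFF
#'
#' One file per channel; a z-stack becomes a multi-page TIFF with one page
#' per plane. Intensities are stored on the 16-bit scale (0--65535).
#'
#' @param x a [channel_image] or [z_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(x, path) {
  planes <- if (inherits(x, "z_stack")) x$planes else list(unclass(x))
  pages <- lapply(planes, function(p) {
    p <- clamp16(as.matrix(p)) / 65535
    attributes(p) <- list(dim = dim(p))
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit TIFF back into a channel image or z-stack
#'
#' @param path TIFF file path.
#' @param channel channel tag to attach.
#' @param step plane spacing in micrometres (used only for multi-page
#'   files).
#' @return a [channel_image] (single page) or [z_stack] (multi-page).
#' @export
read_channel_tiff <- function(path, channel = c("hoechst", "gfp", "pi"),
                              step = 30) {
  channel <- match.arg(channel)
  pages <- tiff::readTIFF(path, all = TRUE)
  planes <- lapply(pages, function(p) round(p * 65535))
  if (length(planes) == 1L) {
    channel_image(planes[[1]], channel = channel)
  } else {
    z_stack(planes, channel = channel, step = step)
  }
}

#' Write a label map as TIFF plus a sidecar object table
#'
#' The label map goes into a 16-bit TIFF (labels stored directly as pixel
#' values); object-level ground truth or measurements go into a CSV next to
#' it.
#'
#' @param map a [label_map].
#' @param path TIFF path; the sidecar CSV gets the same stem with
#'   `"_objects.csv"` appended when `objects` is given.
#' @param objects optional data.frame of per-object rows.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(map, path, objects = NULL) {
  m <- unclass(map)
  attributes(m) <- list(dim = dim(m))
  if (max(m) > 65535) stop("too many labels for 16-bit storage", call. = FALSE)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  if (!is.null(objects)) {
    utils::write.csv(objects, sub("\\.tiff?$", "_objects.csv", path),
      row.names = FALSE
    )
  }
  invisible(path)
}

#' Read a label map written by [write_label_tiff()]
#' @param path TIFF path.
#' @param kind label-map kind.
#' @return a [label_map].
#' @export
read_label_tiff <- function(path, kind = c("nuclei", "cytoplasm", "spheroid")) {
  kind <- match.arg(kind)
  m <- round(tiff::readTIFF(path) * 65535)
  label_map(m, kind = kind)
}

#' Read a plate simulation config from YAML
#'
#' The YAML holds a `design` block (models, reporters, durations,
#' n_replicates, solvent_control_wells, and per-compound `lowest`,
#' `highest`, `n` concentration ranges) and a `response_models` list with
#' one entry per model/reporter/compound condition giving the
#' [response_model()] parameters. Conditions not listed fall back to the
#' optional `default_response` block.
#'
#' @param path YAML file path.
#' @return list with `design` (a [plate_design]) and `models` (named list
#'   of [response_model]s), ready for [generate_response_table()].
#' @export
read_plate_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$design)) stop("config needs a `design` block", call. = FALSE)
  d <- cfg$design
  compounds <- lapply(d$compounds, function(cc) {
    geometric_series(cc$lowest, cc$highest, if (is.null(cc$n)) 8 else cc$n)
  })
  design <- plate_design(
    models = unlist(d$models), reporters = unlist(d$reporters),
    compounds = compounds,
    durations = if (is.null(d$durations)) "24h" else unlist(d$durations),
    n_replicates = if (is.null(d$n_replicates)) 3 else d$n_replicates,
    solvent_control_wells = if (is.null(d$solvent_control_wells)) 16 else d$solvent_control_wells
  )
  build <- function(pars) do.call(response_model, pars)
  models <- list()
  for (entry in cfg$response_models) {
    key <- condition_key(entry$model, entry$reporter, entry$compound)
    pars <- entry[setdiff(names(entry), c("model", "reporter", "compound"))]
    models[[key]] <- build(pars)
  }
  if (!is.null(cfg$default_response)) {
    combos <- expand.grid(
      model = design$models, reporter = design$reporters,
      compound = names(design$compounds), stringsAsFactors = FALSE
    )
    for (j in seq_len(nrow(combos))) {
      key <- condition_key(combos$model[j], combos$reporter[j], combos$compound[j])
      if (is.null(models[[key]])) models[[key]] <- build(cfg$default_response)
    }
  }
  list(design = design, models = models)
}

#' Simulate a plate from a YAML config
#'
#' One-call entry point: read the config, generate the well table and,
#' optionally, write it to CSV.
#'
#' @param config path to a YAML config (see [read_plate_config()]) or the
#'   list it returns.
#' @param seed integer seed.
#' @param out optional CSV path for the well table.
#' @return the list from [generate_response_table()].
#' @export
simulate_plate <- function(config, seed = 1L, out = NULL) {
  if (is.character(config)) config <- read_plate_config(config)
  res <- generate_response_table(config$design, config$models, seed = seed)
  if (!is.null(out)) utils::write.csv(res$wells, out, row.names = FALSE)
  res
}
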