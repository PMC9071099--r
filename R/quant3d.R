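#' Maximum-intensity projection of a z-stack
#'
#' Pointwise maximum over planes; the channel tag is preserved. Spheroid
#' quantification works on the projection of each channel, matching an
#' acquisition protocol that projects the z-stack before 2D analysis.
#'
#' @param stack a [z_stack].
#' @return a [channel_image] of the projected intensities.
#' @export
max_project <- function(stack) {
  if (!inherits(stack, "z_stack")) stop("`stack` must be a z_stack", call. = FALSE)
  if (n_planes(stack) < 1L) stop("empty stack", call. = FALSE)
  proj <- Reduce(pmax, stack$planes)
  channel_image(proj, channel = stack$channel)
}

#' Segment spheroids from a Hoechst projection
#'
#' Thresholds the projected Hoechst signal, fills holes (spheroid cores can
#' be dim in projection), labels connected components and removes debris
#' below `min_area`.
#'
#' @param projection Hoechst [channel_image] (typically from
#'   [max_project()]).
#' @param threshold intensity cutoff, or `"auto"` for Otsu's threshold.
#' @param min_area minimum component area in px (default 200).
#' @return a [label_map] of kind `"spheroid"` with consecutive labels.
#' @export
segment_spheroids <- function(projection, threshold = "auto", min_area = 200) {
  stopifnot(inherits(projection, "channel_image"))
  if (img_channel(projection) != "hoechst") {
    stop("spheroid segmentation runs on the hoechst channel", call. = FALSE)
  }
  x <- unclass(projection)
  attributes(x) <- list(dim = dim(x))
  thr <- if (identical(threshold, "auto")) otsu_threshold(x) else as.numeric(threshold)
  mask <- EBImage::Image(x >= thr)
  mask <- EBImage::fillHull(mask)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(mask)))
  storage.mode(lab) <- "integer"
  lab <- prune_labels(lab, min_area = min_area)
  label_map(lab, kind = "spheroid")
}

#' Per-spheroid GFP intensity and PI-positive area
#'
#' For each spheroid label: mean GFP over the spheroid's projected pixels
#' and the fraction of those pixels whose projected PI signal is at or
#' above the PI threshold.
#'
#' @param spheroids [label_map] of kind `"spheroid"`.
#' @param gfp_projection GFP [channel_image] (same shape).
#' @param pi_projection PI [channel_image] (same shape).
#' @param pi_threshold intensity cutoff or `"auto"` for Otsu on the PI
#'   projection.
#' @return data.frame with `label`, `area`, `mean_gfp`,
#'   `pi_area_fraction`.
#' @export
measure_spheroids <- function(spheroids, gfp_projection, pi_projection,
                              pi_threshold = "auto") {
  if (!all(dim(spheroids) == dim(gfp_projection)) ||
    !all(dim(spheroids) == dim(pi_projection))) {
    stop("spheroid map and projections must share one shape", call. = FALSE)
  }
  lab <- as.integer(spheroids)
  g <- as.numeric(gfp_projection)
  p <- unclass(pi_projection)
  attributes(p) <- list(dim = dim(p))
  thr <- if (identical(pi_threshold, "auto")) otsu_threshold(p) else as.numeric(pi_threshold)
  pos <- as.numeric(p) >= thr
  k <- max(lab, 0L)
  if (k == 0L) {
    return(data.frame(
      label = integer(0), area = integer(0),
      mean_gfp = numeric(0), pi_area_fraction = numeric(0)
    ))
  }
  area <- tabulate(lab[lab > 0L], nbins = k)
  gsum <- as.numeric(rowsum(g[lab > 0L], lab[lab > 0L], reorder = TRUE))
  pcount <- tabulate(lab[lab > 0L & pos], nbins = k)
  data.frame(
    label = seq_len(k),
    area = area,
    mean_gfp = gsum / area,
    pi_area_fraction = pcount / area
  )
}

#' Well-level summary over spheroids
#'
#' Reports both the per-spheroid records and their unweighted well mean, so
#' either convention (per spheroid, or averaged per well) is available.
#'
#' @param records data.frame from [measure_spheroids()].
#' @param metadata optional named list appended as columns.
#' @return one-row data.frame with `n_spheroids`, `mean_gfp`,
#'   `mean_pi_area_fraction`, `total_area` and a `flagged` column for empty
#'   wells.
#' @export
summarize_spheroids <- function(records, metadata = NULL) {
  n <- nrow(records)
  out <- data.frame(
    n_spheroids = n,
    mean_gfp = if (n) mean(records$mean_gfp) else NA_real_,
    mean_pi_area_fraction = if (n) mean(records$pi_area_fraction) else NA_real_,
    total_area = if (n) sum(records$area) else 0L,
    flagged = n == 0L
  )
  if (!is.null(metadata)) out <- cbind(out, as.data.frame(metadata))
  out
}

#' Quantify one spheroid well end to end
#'
#' Projects all three channels (pointwise maximum), segments spheroids on
#' the Hoechst projection and measures GFP and PI per spheroid.
#'
#' @param hoechst,gfp,pi [z_stack]s of the three channels.
#' @param threshold Hoechst threshold or `"auto"`.
#' @param pi_threshold PI threshold or `"auto"`.
#' @param min_area minimum spheroid area in px.
#' @return list with `spheroids` (records), `summary`, `masks`
#'   ([label_map]) and the three projections.
#' @export
quantify_spheroids <- function(hoechst, gfp, pi, threshold = "auto",
                               pi_threshold = "auto", min_area = 200) {
  hp <- max_project(hoechst)
  gp <- max_project(gfp)
  pp <- max_project(pi)
  masks <- segment_spheroids(hp, threshold = threshold, min_area = min_area)
  recs <- measure_spheroids(masks, gp, pp, pi_threshold = pi_threshold)
  list(
    spheroids = recs, summary = summarize_spheroids(recs),
    masks = masks, hoechst_projection = hp,
    gfp_projection = gp, pi_projection = pp
  )
}
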