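#' Segment nuclei from a Hoechst image
#'
#' Watershed-based nuclear segmentation: (i) Gaussian smoothing, (ii)
#' locally adaptive foreground masking (pixel above its local-mean
#' neighbourhood by an offset proportional to the image dynamic range),
#' (iii) watershed on the Euclidean distance transform of the mask to split
#' touching nuclei, (iv) removal of objects below `min_area`, with
#' consecutive relabelling.
#'
#' @param hoechst a [channel_image] with channel `"hoechst"`.
#' @param min_area minimum object area in px; smaller objects are dropped.
#' @param smoothing_sigma Gaussian smoothing SD in px.
#' @param window half-width of the local-mean window in px.
#' @param offset_frac foreground offset as a fraction of the smoothed
#'   image's dynamic range; a pixel is foreground when it exceeds its local
#'   mean by `offset_frac * range`.
#' @param watershed_tolerance minimum depth separating two distance-map
#'   peaks for a split (px).
#' @param exclude_border drop objects touching the image border
#'   (default keeps them).
#' @return a [label_map] of kind `"nuclei"`. A blank (zero-contrast) image
#'   yields zero objects.
#' @export
segment_nuclei <- function(hoechst, min_area = 30, smoothing_sigma = 2,
                           window = 15, offset_frac = 0.05,
                           watershed_tolerance = 1, exclude_border = FALSE) {
  stopifnot(inherits(hoechst, "channel_image"))
  if (img_channel(hoechst) != "hoechst") {
    stop("`hoechst` must be the hoechst channel", call. = FALSE)
  }
  x <- unclass(hoechst)
  attributes(x) <- list(dim = dim(x))
  rng <- diff(range(x))
  if (rng == 0) {
    return(label_map(matrix(0L, nrow(x), ncol(x)), kind = "nuclei"))
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(x), sigma = smoothing_sigma))
  mask <- EBImage::thresh(EBImage::Image(sm),
    w = window, h = window,
    offset = offset_frac * diff(range(sm))
  )
  dmap <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dmap, tolerance = watershed_tolerance, ext = 1)
  lab <- as.matrix(EBImage::imageData(lab))
  storage.mode(lab) <- "integer"
  lab <- prune_labels(lab, min_area = min_area, exclude_border = exclude_border)
  label_map(lab, kind = "nuclei")
}

# drop small / border objects and relabel consecutively
prune_labels <- function(lab, min_area = 0, exclude_border = FALSE) {
  k <- max(lab)
  if (k == 0L) return(lab)
  drop <- rep(FALSE, k)
  if (min_area > 0) {
    areas <- tabulate(lab[lab > 0L], nbins = k)
    drop <- drop | areas < min_area
  }
  if (exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop[border[border > 0L]] <- TRUE
  }
  keep <- which(!drop & tabulate(lab[lab > 0L], nbins = k) > 0L)
  remap <- integer(k)
  remap[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Expand nuclei into cytoplasm rings ("Distance N" method)
#'
#' Each nuclear object is expanded by `expansion` pixels of exact Euclidean
#' distance; contested background pixels are assigned to the nucleus with
#' the nearest nuclear pixel, ties going to the lower label. Nuclear pixels
#' are then excluded, leaving a ring per cell carrying the same label as
#' its nucleus. The screen protocol used a 6-pixel expansion.
#'
#' @param nuclei a [label_map] of kind `"nuclei"`.
#' @param expansion expansion distance in px (>= 1), default 6.
#' @return a [label_map] of kind `"cytoplasm"` with the same label set
#'   (labels whose ring is empty simply have no pixels).
#' @export
segment_cytoplasm <- function(nuclei, expansion = 6) {
  stopifnot(inherits(nuclei, "label_map"))
  if (map_kind(nuclei) != "nuclei") stop("input must be a nuclei map", call. = FALSE)
  if (expansion < 1) stop("`expansion` must be >= 1", call. = FALSE)
  lab <- unclass(nuclei)
  attributes(lab) <- list(dim = dim(lab))
  nr <- nrow(lab); nc <- ncol(lab)

  # offsets within the expansion radius, scanned in order of distance so a
  # pixel keeps the first (nearest) nuclear label it sees; equal distances
  # resolve to the lower label
  r <- ceiling(expansion)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off$d2 <- off$dx^2 + off$dy^2
  off <- off[off$d2 > 0 & off$d2 <= expansion^2, ]
  off <- off[order(off$d2), ]

  best_d2 <- matrix(Inf, nr, nc)
  best_lab <- matrix(0L, nr, nc)
  bg <- lab == 0L

  for (i in seq_len(nrow(off))) {
    dx <- off$dx[i]; dy <- off$dy[i]; d2 <- off$d2[i]
    src_r <- max(1, 1 - dx):min(nr, nr - dx)
    src_c <- max(1, 1 - dy):min(nc, nc - dy)
    dst_r <- src_r + dx
    dst_c <- src_c + dy
    src <- lab[src_r, src_c, drop = FALSE]
    cur_d2 <- best_d2[dst_r, dst_c, drop = FALSE]
    cur_lab <- best_lab[dst_r, dst_c, drop = FALSE]
    upd <- src > 0L & bg[dst_r, dst_c, drop = FALSE] &
      (d2 < cur_d2 | (d2 == cur_d2 & src < cur_lab & cur_lab > 0L))
    if (any(upd)) {
      cur_d2[upd] <- d2
      cur_lab[upd] <- src[upd]
      best_d2[dst_r, dst_c] <- cur_d2
      best_lab[dst_r, dst_c] <- cur_lab
    }
  }
  label_map(best_lab, kind = "cytoplasm")
}

#' Threshold the PI channel into a binary death mask
#'
#' @param pi a [channel_image] with channel `"pi"`.
#' @param threshold intensity cutoff; pixels with intensity `>= threshold`
#'   are PI-positive. `NULL` (default) uses Otsu's threshold on the channel.
#' @return logical matrix the size of the image.
#' @export
pi_mask_from_image <- function(pi, threshold = NULL) {
  stopifnot(inherits(pi, "channel_image"))
  if (img_channel(pi) != "pi") stop("`pi` must be the pi channel", call. = FALSE)
  x <- unclass(pi)
  attributes(x) <- list(dim = dim(x))
  if (is.null(threshold)) threshold <- otsu_threshold(x)
  x >= threshold
}

# Otsu threshold on an arbitrary intensity range; a zero-range image gets a
# threshold above its maximum (empty foreground).
otsu_threshold <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(r[2] + 1)
  scaled <- EBImage::Image((x - r[1]) / diff(r))
  as.numeric(EBImage::otsu(scaled, range = c(0, 1), levels = 256)) * diff(r) + r[1]
}

#' Per-cell compartment measurements
#'
#' For every nucleus label: mean GFP over nuclear pixels, mean GFP over the
#' cytoplasm ring, the fraction of nuclear pixels overlapped by the PI
#' mask, and the PI classification. A cell is PI-positive when at least 10%
#' of its nuclear area overlaps the PI signal (inclusive boundary). For
#' nuclear reporters (p53, p21) the nuclear mean is the primary readout;
#' for the cytoplasmic BTG2 reporter, the cytoplasmic mean.
#'
#' @param nuclei nuclei [label_map].
#' @param cytoplasm cytoplasm [label_map] from [segment_cytoplasm()].
#' @param gfp GFP [channel_image].
#' @param pi_mask logical matrix from [pi_mask_from_image()].
#' @param overlap_threshold PI overlap fraction at/above which a cell is
#'   called positive (default 0.10).
#' @return data.frame with one row per label: `label`, `nucleus_area`,
#'   `nuclear_mean_gfp`, `cytoplasm_area`, `cytoplasmic_mean_gfp` (`NA` if
#'   the ring has no pixels), `pi_overlap_fraction`, `pi_positive`.
#' @export
measure_cells <- function(nuclei, cytoplasm, gfp, pi_mask,
                          overlap_threshold = 0.10) {
  dims <- list(dim(nuclei), dim(cytoplasm), dim(gfp), dim(pi_mask))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("nuclei, cytoplasm, gfp and pi_mask must share one shape", call. = FALSE)
  }
  nuc <- as.integer(nuclei)
  cyt <- as.integer(cytoplasm)
  g <- as.numeric(gfp)
  k <- max(nuc, 0L)
  if (k == 0L) {
    return(data.frame(
      label = integer(0), nucleus_area = integer(0),
      nuclear_mean_gfp = numeric(0), cytoplasm_area = integer(0),
      cytoplasmic_mean_gfp = numeric(0), pi_overlap_fraction = numeric(0),
      pi_positive = logical(0)
    ))
  }
  nuc_area <- tabulate(nuc[nuc > 0L], nbins = k)
  nuc_sum <- as.numeric(rowsum(g[nuc > 0L], nuc[nuc > 0L], reorder = TRUE))
  cyt_area <- tabulate(cyt[cyt > 0L], nbins = k)
  cyt_mean <- rep(NA_real_, k)
  if (any(cyt > 0L)) {
    sums <- rowsum(g[cyt > 0L], cyt[cyt > 0L], reorder = TRUE)
    present <- as.integer(rownames(sums))
    cyt_mean[present] <- as.numeric(sums) / cyt_area[present]
  }
  pi_count <- tabulate(nuc[nuc > 0L & as.logical(pi_mask)], nbins = k)
  frac <- pi_count / nuc_area
  data.frame(
    label = seq_len(k),
    nucleus_area = nuc_area,
    nuclear_mean_gfp = nuc_sum / nuc_area,
    cytoplasm_area = cyt_area,
    cytoplasmic_mean_gfp = cyt_mean,
    pi_overlap_fraction = frac,
    pi_positive = frac >= overlap_threshold
  )
}

#' Image-level summary of per-cell measurements
#'
#' @param records data.frame from [measure_cells()].
#' @param image_id optional image identifier carried into the output.
#' @param metadata optional named list (well metadata) appended as columns.
#' @return one-row data.frame with `mean_nuclear_gfp`,
#'   `mean_cytoplasmic_gfp`, `pi_positive_fraction`, `n_cells` and a
#'   `flagged` column that is `TRUE` when there were no cells (all summary
#'   values `NA`).
#' @export
summarize_image <- function(records, image_id = NA_character_, metadata = NULL) {
  n <- nrow(records)
  out <- data.frame(
    image_id = image_id,
    n_cells = n,
    mean_nuclear_gfp = if (n) mean(records$nuclear_mean_gfp) else NA_real_,
    mean_cytoplasmic_gfp = if (n && any(!is.na(records$cytoplasmic_mean_gfp))) {
      mean(records$cytoplasmic_mean_gfp, na.rm = TRUE)
    } else {
      NA_real_
    },
    pi_positive_fraction = if (n) mean(records$pi_positive) else NA_real_,
    flagged = n == 0L
  )
  if (!is.null(metadata)) out <- cbind(out, as.data.frame(metadata))
  out
}

#' Quantify one 2D field end to end
#'
#' Convenience wrapper: segments nuclei and cytoplasm, thresholds the PI
#' channel, measures every cell and summarises the image.
#'
#' @param hoechst,gfp,pi the three [channel_image]s of one field.
#' @param reporter `"p53"`, `"p21"` (nuclear readout) or `"BTG2"`
#'   (cytoplasmic readout); selects which compartment mean is reported as
#'   `reporter_gfp` in the summary.
#' @param pi_threshold PI threshold or `NULL` for Otsu.
#' @param expansion cytoplasm expansion in px.
#' @param ... further arguments passed to [segment_nuclei()].
#' @return list with `cells` (per-cell records), `summary` (one-row
#'   data.frame including `reporter_gfp`), `nuclei` and `cytoplasm` maps.
#' @export
quantify_monolayer <- function(hoechst, gfp, pi, reporter = c("p53", "p21", "BTG2"),
                               pi_threshold = NULL, expansion = 6, ...) {
  reporter <- match.arg(reporter)
  nuclei <- segment_nuclei(hoechst, ...)
  cyto <- segment_cytoplasm(nuclei, expansion = expansion)
  mask <- pi_mask_from_image(pi, threshold = pi_threshold)
  cells <- measure_cells(nuclei, cyto, gfp, mask)
  summ <- summarize_image(cells)
  summ$reporter <- reporter
  summ$reporter_gfp <- if (reporter == "BTG2") {
    summ$mean_cytoplasmic_gfp
  } else {
    summ$mean_nuclear_gfp
  }
  list(cells = cells, summary = summ, nuclei = nuclei, cytoplasm = cyto)
}
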