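#' Single-channel fluorescence image
#'
#' Lightweight container for one 2D plane of one fluorescence channel.
#' Pixels are stored as a numeric matrix of nonnegative intensities in
#' arbitrary units on a 16-bit scale (0--65535); coordinates are 0-based
#' row-major when exported, but R's native 1-based matrix indexing is used
#' internally.
#'
#' @param pixels numeric matrix of nonnegative intensities.
#' @param channel one of `"hoechst"` (nuclear stain), `"gfp"` (reporter) or
#'   `"pi"` (propidium iodide, cell-death stain).
#' @param pixel_size optional pixel size in micrometres per pixel.
#' @return a `channel_image`: the matrix with channel metadata attached.
#' @export
channel_image <- function(pixels, channel = c("hoechst", "gfp", "pi"),
                          pixel_size = NULL) {
  channel <- match.arg(channel)
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("`pixels` must be numeric", call. = FALSE)
  if (any(dim(pixels) < 1L)) stop("image must have both dimensions >= 1", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("intensities must be finite and nonnegative", call. = FALSE)
  }
  structure(pixels,
    class = c("channel_image", class(matrix())),
    channel = channel, pixel_size = pixel_size
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf(
    "<channel_image> %d x %d px, channel = %s, range [%g, %g]\n",
    nrow(x), ncol(x), attr(x, "channel"), min(x), max(x)
  ))
  invisible(x)
}

#' Channel tag of an image or stack
#' @param x a `channel_image` or `z_stack`.
#' @return the channel string.
#' @export
img_channel <- function(x) attr(x, "channel")

#' Ordered stack of image planes along z
#'
#' @param planes list of numeric matrices (identical dimensions), ordered
#'   bottom to top, or a 3D array sliced along the third dimension.
#' @param channel channel tag shared by all planes.
#' @param step distance between consecutive planes in micrometres
#'   (default 30).
#' @return a `z_stack` object.
#' @export
z_stack <- function(planes, channel = c("hoechst", "gfp", "pi"), step = 30) {
  channel <- match.arg(channel)
  if (is.array(planes) && length(dim(planes)) == 3L) {
    planes <- lapply(seq_len(dim(planes)[3]), function(k) planes[, , k])
  }
  if (!is.list(planes) || length(planes) < 1L) {
    stop("a z-stack needs at least one plane", call. = FALSE)
  }
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all planes must share the same dimensions", call. = FALSE)
  }
  if (!is.numeric(step) || step <= 0) stop("`step` must be positive", call. = FALSE)
  structure(list(planes = planes, channel = channel, step = step),
    class = "z_stack"
  )
}

#' @export
print.z_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf(
    "<z_stack> %d planes of %d x %d px, channel = %s, step = %g um\n",
    length(x$planes), d[1], d[2], x$channel, x$step
  ))
  invisible(x)
}

#' Number of planes in a z-stack
#' @param x a `z_stack`.
#' @export
n_planes <- function(x) length(x$planes)

#' Integer-labelled segmentation mask
#'
#' 0 marks background; objects carry positive integer labels. For nuclei
#' and spheroid maps the label set is `{1..K}` with no gaps; cytoplasm
#' maps inherit their labels from the nuclei map they were derived from,
#' so individual labels may be absent when a nucleus has no free
#' surrounding pixels.
#'
#' @param labels integer matrix of nonnegative labels.
#' @param kind one of `"nuclei"`, `"cytoplasm"`, `"spheroid"`.
#' @return a `label_map`.
#' @export
label_map <- function(labels, kind = c("nuclei", "cytoplasm", "spheroid")) {
  kind <- match.arg(kind)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L)) {
    stop("labels must be nonnegative integers", call. = FALSE)
  }
  ids <- sort(unique(labels[labels > 0L]))
  if (kind != "cytoplasm" && length(ids) &&
    !identical(ids, seq_len(max(ids)))) {
    stop("label set must be consecutive 1..K", call. = FALSE)
  }
  structure(labels,
    class = c("label_map", class(matrix())),
    kind = kind
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf(
    "<label_map> %d x %d px, kind = %s, %d object(s)\n",
    nrow(x), ncol(x), attr(x, "kind"), n_objects(x)
  ))
  invisible(x)
}

#' Kind of a label map
#' @param x a `label_map`.
#' @export
map_kind <- function(x) attr(x, "kind")

#' Number of labelled objects in a label map
#' @param x a `label_map`.
#' @return count of distinct positive labels.
#' @export
n_objects <- function(x) length(unique(x[x > 0L]))

#' Labels present in a label map
#' @param x a `label_map`.
#' @return sorted integer vector of positive labels.
#' @export
map_labels <- function(x) sort(unique(as.integer(x[x > 0L])))

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators leave no hidden global state behind.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# clamp intensities onto the 16-bit scale used throughout
clamp16 <- function(x) pmin(pmax(x, 0), 65535)
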