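#' Simulate a 2D monolayer field of reporter cells
#'
#' Renders the three channels acquired in a 2D reporter screen -- Hoechst
#' (nuclei), GFP (reporter) and propidium iodide (death stain) -- together
#' with the exact ground truth needed to score downstream segmentation and
#' measurement. Nuclei are anisotropic Gaussian blobs whose half-maximum
#' contour defines an elliptical ground-truth mask; centers are placed by
#' rejection sampling under a minimum spacing so that objects may touch but
#' never coincide.
#'
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param image_size side length of the square field in pixels.
#' @param gfp_level mean GFP intensity of each cell region; either a single
#'   value or one value per nucleus.
#' @param pi_fraction fraction of nuclei rendered PI-positive (0..1);
#'   `round(pi_fraction * n_nuclei)` nuclei are chosen at random.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param radius_range range (min, max) of nuclear semi-axis lengths in px.
#' @param min_spacing minimum center-to-center distance in px. Default
#'   `2 * max(radius_range)`: touching-but-separable objects that exercise
#'   watershed splitting.
#' @param pi_paint_fraction fraction of each PI-positive nucleus' mask that
#'   is actually painted bright (innermost pixels first). 1 paints the whole
#'   nucleus; smaller values build exact partial-overlap fixtures for the
#'   10%-overlap death rule.
#' @param hoechst_peak peak Hoechst intensity of a nucleus.
#' @param background additive background level of all channels.
#' @param noise_sd Gaussian pixel noise SD added to every channel (0 = none).
#' @param pi_level intensity painted into the PI channel over positive nuclei.
#' @param max_attempts rejection-sampling attempts per nucleus before a
#'   packing error is raised.
#' @return list with elements `hoechst`, `gfp`, `pi` (each a
#'   [channel_image]) and `ground_truth` (an `imaging_ground_truth` list:
#'   `nucleus_centers`, `nucleus_masks`, `pi_positive_ids`,
#'   `per_object_gfp_mean`, `radii`, `pi_paint_fraction`).
#' @export
generate_monolayer_images <- function(n_nuclei, image_size = 512,
                                      gfp_level = 5000, pi_fraction = 0,
                                      seed = 1L,
                                      radius_range = c(5, 9),
                                      min_spacing = NULL,
                                      pi_paint_fraction = 1,
                                      hoechst_peak = 30000,
                                      background = 500,
                                      noise_sd = 0,
                                      pi_level = 40000,
                                      max_attempts = 10000) {
  stopifnot(n_nuclei >= 0, image_size >= 16, pi_fraction >= 0, pi_fraction <= 1)
  if (!length(gfp_level) %in% c(1L, max(1L, n_nuclei))) {
    stop("`gfp_level` must have length 1 or n_nuclei", call. = FALSE)
  }
  if (is.null(min_spacing)) min_spacing <- 2 * max(radius_range)

  with_seed(seed, {
    centers <- place_centers(n_nuclei, image_size,
      margin = max(radius_range) + 2,
      min_spacing = min_spacing, max_attempts = max_attempts
    )
    rx <- stats::runif(n_nuclei, radius_range[1], radius_range[2])
    ry <- stats::runif(n_nuclei, radius_range[1], radius_range[2])
    theta <- stats::runif(n_nuclei, 0, pi)

    hoechst <- matrix(background, image_size, image_size)
    gfp <- matrix(background, image_size, image_size)
    pi_img <- matrix(background, image_size, image_size)
    labels <- matrix(0L, image_size, image_size)
    best_d2 <- matrix(Inf, image_size, image_size)

    gfp_levels <- rep_len(gfp_level, max(1L, n_nuclei))
    # half-maximum of a Gaussian falls at sqrt(2 log 2) * sigma
    hm <- sqrt(2 * log(2))

    for (i in seq_len(n_nuclei)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      w <- ceiling(3 * max(rx[i], ry[i]))
      xs <- max(1L, floor(cx - w)):min(image_size, ceiling(cx + w))
      ys <- max(1L, floor(cy - w)):min(image_size, ceiling(cy + w))
      dx <- outer(xs - cx, rep(1, length(ys)))
      dy <- outer(rep(1, length(xs)), ys - cy)
      u <- dx * cos(theta[i]) + dy * sin(theta[i])
      v <- -dx * sin(theta[i]) + dy * cos(theta[i])
      blob <- hoechst_peak * exp(-0.5 * ((u * hm / rx[i])^2 + (v * hm / ry[i])^2))
      hoechst[xs, ys] <- hoechst[xs, ys] + blob

      inside <- (u / rx[i])^2 + (v / ry[i])^2 <= 1
      d2 <- dx^2 + dy^2
      sub_lab <- labels[xs, ys]
      sub_d2 <- best_d2[xs, ys]
      take <- inside & d2 < sub_d2 # contested pixels go to the nearest center
      sub_lab[take] <- i
      sub_d2[take] <- d2[take]
      labels[xs, ys] <- sub_lab
      best_d2[xs, ys] <- sub_d2

      # cell region (nucleus + surrounding cytoplasm) carries the GFP signal
      cell <- (u / (rx[i] + 8))^2 + (v / (ry[i] + 8))^2 <= 1
      sub_g <- gfp[xs, ys]
      sub_g[cell] <- pmax(sub_g[cell], gfp_levels[i])
      gfp[xs, ys] <- sub_g
    }

    n_pos <- round(pi_fraction * n_nuclei)
    pi_ids <- if (n_pos > 0) sort(sample.int(n_nuclei, n_pos)) else integer(0)
    for (i in pi_ids) {
      px <- which(labels == i)
      ord <- order(best_d2[px]) # innermost pixels first: exact paint counts
      # ceiling: the painted fraction is never below the requested one
      k <- ceiling(pi_paint_fraction * length(px))
      if (k > 0) pi_img[px[ord[seq_len(k)]]] <- pi_level
    }

    if (noise_sd > 0) {
      n_px <- image_size^2
      hoechst <- hoechst + stats::rnorm(n_px, 0, noise_sd)
      gfp <- gfp + stats::rnorm(n_px, 0, noise_sd)
      pi_img <- pi_img + stats::rnorm(n_px, 0, noise_sd)
    }

    truth <- structure(list(
      nucleus_centers = centers,
      nucleus_masks = label_map(labels, kind = "nuclei"),
      pi_positive_ids = pi_ids,
      per_object_gfp_mean = if (n_nuclei) gfp_levels else numeric(0),
      radii = cbind(rx = rx, ry = ry, theta = theta),
      pi_paint_fraction = pi_paint_fraction
    ), class = "imaging_ground_truth")

    list(
      hoechst = channel_image(clamp16(hoechst), "hoechst"),
      gfp = channel_image(clamp16(gfp), "gfp"),
      pi = channel_image(clamp16(pi_img), "pi"),
      ground_truth = truth
    )
  })
}

# Rejection-sample `n` centers in [margin, size - margin]^2 with pairwise
# distance >= min_spacing. Failing to place a center within `max_attempts`
# draws is a packing error, never silent truncation.
place_centers <- function(n, size, margin, min_spacing, max_attempts) {
  centers <- matrix(numeric(0), 0, 2)
  lo <- margin + 1
  hi <- size - margin
  if (n > 0 && hi <= lo) stop("image too small for requested nuclei", call. = FALSE)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- stats::runif(2, lo, hi)
      if (nrow(centers) == 0L ||
        min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >= min_spacing^2) {
        centers <- rbind(centers, p)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "could not place nucleus %d of %d at spacing %.1f px after %d attempts",
        i, n, min_spacing, max_attempts
      ), call. = FALSE)
    }
  }
  dimnames(centers) <- list(NULL, c("x", "y"))
  centers
}
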