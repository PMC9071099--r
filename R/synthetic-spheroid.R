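#' Simulate a confocal z-stack of spheroids
#'
#' Emulates 3D spheroid cultures imaged as a z-stack (default 9 planes at a
#' 30 um step, matching a typical low-magnification confocal acquisition).
#' Each spheroid is a solid sphere: its cross-section in plane z is a disk
#' of radius `r * sqrt(1 - (dz/r)^2)`, so the maximum-intensity projection
#' of the Hoechst stack is the equatorial disk. PI positivity is painted as
#' a concentric inner core whose projected area is an exact, known fraction
#' of the projected spheroid area.
#'
#' @param n_spheroids number of spheroids (>= 0).
#' @param n_planes number of z planes (>= 1); the screen protocol used 9-11.
#' @param plane_step distance between planes in micrometres (default 30).
#' @param image_size side length of the square field in pixels.
#' @param seed integer seed; identical seeds give identical stacks.
#' @param radius_range range of equatorial radii in pixels.
#' @param pixel_size micrometres per pixel, converting the xy radius into a
#'   physical z extent.
#' @param gfp_level mean GFP intensity inside each spheroid (scalar or per
#'   spheroid).
#' @param pi_area_fraction fraction of each spheroid's projected area that
#'   is PI-positive (scalar or per spheroid, 0..1).
#' @param hoechst_level Hoechst intensity inside a spheroid cross-section.
#' @param background additive background of all channels.
#' @param noise_sd Gaussian pixel noise SD per plane (0 = none).
#' @param pi_level PI intensity painted over the positive core.
#' @param max_attempts rejection-sampling attempts per spheroid.
#' @return list with `hoechst`, `gfp`, `pi` ([z_stack]s) and `ground_truth`
#'   containing the projected `spheroid_masks` ([label_map]), per-object
#'   `true_pi_fraction` (pixel-exact painted fraction of the projection),
#'   `per_object_gfp_mean`, `centers` and `radius_px`.
#' @export
generate_spheroid_stack <- function(n_spheroids, n_planes = 9, plane_step = 30,
                                    image_size = 512, seed = 1L,
                                    radius_range = c(35, 60),
                                    pixel_size = 2.5,
                                    gfp_level = 5000,
                                    pi_area_fraction = 0,
                                    hoechst_level = 20000,
                                    background = 200,
                                    noise_sd = 0,
                                    pi_level = 40000,
                                    max_attempts = 10000) {
  if (n_planes < 1) stop("a z-stack needs at least one plane", call. = FALSE)
  stopifnot(
    n_spheroids >= 0, plane_step > 0, pixel_size > 0,
    all(pi_area_fraction >= 0), all(pi_area_fraction <= 1)
  )
  gfp_levels <- rep_len(gfp_level, max(1L, n_spheroids))
  pi_fracs <- rep_len(pi_area_fraction, max(1L, n_spheroids))

  with_seed(seed, {
    r_px <- stats::runif(n_spheroids, radius_range[1], radius_range[2])
    centers <- place_spheroid_centers(n_spheroids, image_size, r_px, max_attempts)
    # z center near the middle of the stack, jittered by up to half a step
    z_mid <- (n_planes + 1) / 2
    z_c_um <- (z_mid + stats::runif(max(1L, n_spheroids), -0.5, 0.5) - z_mid) * plane_step

    blank <- function() matrix(background, image_size, image_size)
    hoechst <- lapply(seq_len(n_planes), function(k) blank())
    gfp <- lapply(seq_len(n_planes), function(k) blank())
    pi_img <- lapply(seq_len(n_planes), function(k) blank())

    labels <- matrix(0L, image_size, image_size)
    pi_proj <- matrix(FALSE, image_size, image_size)

    for (i in seq_len(n_spheroids)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      r_um <- r_px[i] * pixel_size
      w <- ceiling(r_px[i]) + 1
      xs <- max(1L, floor(cx - w)):min(image_size, ceiling(cx + w))
      ys <- max(1L, floor(cy - w)):min(image_size, ceiling(cy + w))
      d2 <- outer((xs - cx)^2, rep(1, length(ys))) +
        outer(rep(1, length(xs)), (ys - cy)^2)

      eq_disk <- d2 <= r_px[i]^2
      sub <- labels[xs, ys]
      sub[eq_disk & sub == 0L] <- i
      labels[xs, ys] <- sub
      core <- d2 <= pi_fracs[i] * r_px[i]^2 # area ratio is exactly the fraction
      pi_proj[xs, ys] <- pi_proj[xs, ys] | core

      for (k in seq_len(n_planes)) {
        dz <- (k - z_mid) * plane_step - z_c_um[i]
        if (abs(dz) >= r_um) next
        cr <- r_px[i] * sqrt(1 - (dz / r_um)^2)
        disk <- d2 <= cr^2
        hoechst[[k]][xs, ys][disk] <- hoechst_level
        gfp[[k]][xs, ys][disk] <- gfp_levels[i]
        core_k <- d2 <= pi_fracs[i] * cr^2
        pi_img[[k]][xs, ys][core_k] <- pi_level
      }
    }

    if (noise_sd > 0) {
      addn <- function(m) clamp16(m + stats::rnorm(length(m), 0, noise_sd))
      hoechst <- lapply(hoechst, addn)
      gfp <- lapply(gfp, addn)
      pi_img <- lapply(pi_img, addn)
    }

    mask_map <- label_map(labels, kind = "spheroid")
    areas <- tabulate(labels[labels > 0L], nbins = n_spheroids)
    pi_counts <- if (n_spheroids) {
      tabulate(labels[pi_proj & labels > 0L], nbins = n_spheroids)
    } else {
      integer(0)
    }
    truth <- structure(list(
      spheroid_masks = mask_map,
      true_pi_fraction = if (n_spheroids) pi_counts / pmax(areas, 1L) else numeric(0),
      per_object_gfp_mean = if (n_spheroids) gfp_levels else numeric(0),
      centers = centers[seq_len(n_spheroids), , drop = FALSE],
      radius_px = r_px
    ), class = "imaging_ground_truth")

    list(
      hoechst = z_stack(hoechst, "hoechst", step = plane_step),
      gfp = z_stack(gfp, "gfp", step = plane_step),
      pi = z_stack(pi_img, "pi", step = plane_step),
      ground_truth = truth
    )
  })
}

place_spheroid_centers <- function(n, size, r_px, max_attempts) {
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    margin <- r_px[i] + 2
    if (size - margin <= margin + 1) {
      stop("image too small for requested spheroid radius", call. = FALSE)
    }
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- stats::runif(2, margin + 1, size - margin)
      ok <- TRUE
      if (nrow(centers) > 0L) {
        dist <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
        # clear separation: 1.3x the touching distance of each pair
        ok <- all(dist >= 1.3 * (r_px[seq_len(i - 1)] + r_px[i]))
      }
      if (ok) {
        centers <- rbind(centers, p)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not place spheroid %d of %d", i, n), call. = FALSE)
    }
  }
  if (n == 0L) centers <- matrix(numeric(0), 0, 2)
  dimnames(centers) <- list(NULL, c("x", "y"))
  centers
}
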