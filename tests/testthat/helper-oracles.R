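# Independent oracles and scoring helpers used across the suite.

# strip class/channel metadata down to a bare matrix
as_mat <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x
}

# centroids of a label map, one row per label
label_centroids <- function(map) {
  lab <- unclass(map)
  attributes(lab) <- list(dim = dim(lab))
  k <- max(lab)
  if (k == 0L) return(matrix(numeric(0), 0, 2))
  idx <- which(lab > 0L, arr.ind = TRUE)
  v <- lab[lab > 0L]
  cbind(
    tapply(idx[, 1], v, mean),
    tapply(idx[, 2], v, mean)
  )
}

# one-to-one greedy matching of ground-truth nuclei to detected objects:
# a truth nucleus matches the nearest unused detection within its own
# maximum radius. Returns the matched fraction and the spurious fraction.
segmentation_score <- function(truth, map) {
  centers <- truth$nucleus_centers
  det <- label_centroids(map)
  k <- nrow(det)
  if (nrow(centers) == 0L) {
    return(c(matched = NA_real_, spurious = if (k) 1 else 0))
  }
  if (k == 0L) return(c(matched = 0, spurious = 0))
  rmax <- apply(truth$radii[, c("rx", "ry"), drop = FALSE], 1, max)
  used <- rep(FALSE, k)
  matched <- 0L
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((det[, 1] - centers[i, 1])^2 + (det[, 2] - centers[i, 2])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= rmax[i]) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  c(matched = matched / nrow(centers), spurious = (k - matched) / k)
}

# brute-force nearest-nucleus ring assignment: for every background pixel,
# scan all nuclear pixels, keep the nearest within `expansion`, ties to the
# lower label. Quadratic; for small fixtures only.
brute_force_expand <- function(lab, expansion) {
  lab <- unclass(lab)
  attributes(lab) <- list(dim = dim(lab))
  nr <- nrow(lab); nc <- ncol(lab)
  nuc <- which(lab > 0L, arr.ind = TRUE)
  nuclab <- lab[lab > 0L]
  out <- matrix(0L, nr, nc)
  for (p in which(lab == 0L)) {
    i <- (p - 1L) %% nr + 1L
    j <- (p - 1L) %/% nr + 1L
    d2 <- (nuc[, 1] - i)^2 + (nuc[, 2] - j)^2
    md <- min(d2)
    if (md <= expansion^2) out[p] <- min(nuclab[d2 == md])
  }
  out
}

# naive agglomerative complete linkage: returns the sorted merge heights
naive_complete_heights <- function(d) {
  d <- as.matrix(d)
  members <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(members) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(members) - 1L)) {
      for (j in (i + 1L):length(members)) {
        h <- max(d[members[[i]], members[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    members[[best[2]]] <- c(members[[best[2]]], members[[best[3]]])
    members[[best[3]]] <- NULL
  }
  sort(heights)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}

# hand-rolled evaluation of a degree-1 full-span tricube local fit is just
# weighted least squares; for collinear data any weighting reproduces the
# line, so the least-squares line itself is the oracle there.

# well table -> single response_curve for one condition
curve_for <- function(tbl, model, reporter, compound, duration) {
  d <- tbl[tbl$model == model & tbl$reporter == reporter &
    tbl$compound == compound & tbl$duration == duration, ]
  tr <- d[d$well_type == "treated", ]
  response_curve(
    sort(unique(tr$concentration_uM)),
    data.frame(concentration = tr$concentration_uM, value = tr$value),
    d[d$well_type == "solvent", "value"]
  )
}

# planted two-group profile matrix: rows within a group are tight around
# the group template, between-group separation ~10x the within-group spread
planted_profiles <- function(n_per_group = 4, n_features = 16, seed = 42) {
  set.seed(seed)
  g1 <- runif(n_features)
  g2 <- g1 + 10
  m <- rbind(
    t(replicate(n_per_group, g1 + runif(n_features, -0.05, 0.05))),
    t(replicate(n_per_group, g2 + runif(n_features, -0.05, 0.05)))
  )
  rownames(m) <- paste0("row", seq_len(2 * n_per_group))
  list(matrix = m, labels = rep(1:2, each = n_per_group))
}
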