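# Map-level multiple-comparison control: BH-FDR, three-map conjunction,
# Monte-Carlo cluster-extent calibration, connected-component labelling.

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up BH procedure at level `q`; returns the rejection mask and the
#' adaptive threshold (the largest rejected raw p-value).
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param q FDR level, default 0.05.
#' @return List `mask` (logical), `threshold` (largest rejected p, or NA if
#'   nothing is rejected), `q`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  mask <- stats::p.adjust(p_values, method = "BH") <= q
  mask[is.na(mask)] <- FALSE
  thr <- if (any(mask)) max(p_values[mask]) else NA_real_
  list(mask = mask, threshold = thr, q = q)
}

#' Conjunction of the a, b, and a*b significance maps
#'
#' A voxel passes the conjunction iff its p-value is below `p_thresh` in all
#' three maps.
#'
#' @param p_map_a,p_map_b,p_map_ab Arrays (or vectors) of identical shape.
#' @param p_thresh Voxel-wise threshold, default 0.002.
#' @return Logical array of the common shape.
#' @export
conjunction_mask <- function(p_map_a, p_map_b, p_map_ab, p_thresh = 0.002) {
  if (!identical(dim(p_map_a), dim(p_map_b)) ||
      !identical(dim(p_map_a), dim(p_map_ab)) ||
      length(p_map_a) != length(p_map_b) ||
      length(p_map_a) != length(p_map_ab))
    stop("the three p-maps must have identical shape")
  m <- (p_map_a < p_thresh) & (p_map_b < p_thresh) & (p_map_ab < p_thresh)
  m[is.na(m)] <- FALSE
  m
}

# neighbour offsets for 6/18/26 connectivity
.neighbour_offsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  d <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d <= 2, "26" = d <= 3,
                 stop("connectivity must be 6, 18, or 26"))
  as.matrix(off[keep, ])
}

#' Label connected suprathreshold clusters
#'
#' Connected-component labelling of a binary 3D mask under 6-, 18-, or
#' 26-neighbour connectivity; clusters smaller than `extent_k` voxels are
#' dropped. When a statistic array is supplied, each cluster's peak voxel
#' and peak statistic are reported (otherwise the peak is the first voxel in
#' array order).
#'
#' @param mask Logical 3D array (a matrix or vector is treated as a
#'   degenerate volume).
#' @param connectivity 6, 18, or 26 (default).
#' @param extent_k Minimum cluster size retained, default 1.
#' @param stat Optional numeric array of the same shape for peak reporting.
#' @return List of class `cluster_set`: `labels` (integer array, 0 =
#'   background/dropped) and `clusters` (data frame `id`, `size`,
#'   `peak_x/y/z` 1-based array coordinates, `peak_stat`).
#' @export
label_clusters <- function(mask, connectivity = 26, extent_k = 1,
                           stat = NULL) {
  dm <- dim(mask)
  if (is.null(dm)) dm <- c(length(mask), 1L, 1L)
  if (length(dm) == 2) dm <- c(dm, 1L)
  mask <- array(as.logical(mask), dm)
  if (!is.null(stat)) stat <- array(as.numeric(stat), dm)
  off <- .neighbour_offsets(connectivity)
  lab <- array(0L, dm)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(structure(list(labels = lab,
                          clusters = data.frame(id = integer(0),
                                                size = integer(0),
                                                peak_x = integer(0),
                                                peak_y = integer(0),
                                                peak_z = integer(0),
                                                peak_stat = numeric(0))),
                     class = "cluster_set"))
  # label propagation: start from linear indices, iterate min over neighbours
  lin <- which(mask)
  lab[lin] <- lin
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(off))) {
      nb <- idx
      nb[, 1] <- nb[, 1] + off[k, 1]
      nb[, 2] <- nb[, 2] + off[k, 2]
      nb[, 3] <- nb[, 3] + off[k, 3]
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
            nb[, 2] >= 1 & nb[, 2] <= dm[2] &
            nb[, 3] >= 1 & nb[, 3] <= dm[3]
      if (!any(ok)) next
      here <- lin[ok]
      there <- nb[ok, 1] + (nb[ok, 2] - 1L) * dm[1] +
        (nb[ok, 3] - 1L) * dm[1] * dm[2]
      in_mask <- mask[there]
      if (!any(in_mask)) next
      here <- here[in_mask]; there <- there[in_mask]
      new_lab <- pmin(lab[here], lab[there])
      if (any(new_lab < lab[here])) { lab[here] <- pmin(lab[here], new_lab); changed <- TRUE }
      if (any(new_lab < lab[there])) { lab[there] <- pmin(lab[there], new_lab); changed <- TRUE }
    }
    if (!changed) break
  }
  roots <- sort(unique(lab[lin]))
  comp <- match(lab[lin], roots)
  sizes <- tabulate(comp, length(roots))
  keep <- which(sizes >= extent_k)
  out_lab <- array(0L, dm)
  clusters <- data.frame(id = integer(0), size = integer(0),
                         peak_x = integer(0), peak_y = integer(0),
                         peak_z = integer(0), peak_stat = numeric(0))
  for (j in seq_along(keep)) {
    members <- lin[comp == keep[j]]
    out_lab[members] <- j
    if (!is.null(stat)) {
      pk <- members[which.max(abs(stat[members]))]
      pstat <- stat[pk]
    } else {
      pk <- members[1]
      pstat <- NA_real_
    }
    pz <- (pk - 1L) %/% (dm[1] * dm[2])
    py <- ((pk - 1L) %% (dm[1] * dm[2])) %/% dm[1]
    px <- (pk - 1L) %% dm[1]
    clusters <- rbind(clusters,
                      data.frame(id = j, size = sizes[keep[j]],
                                 peak_x = px + 1L, peak_y = py + 1L,
                                 peak_z = pz + 1L, peak_stat = pstat))
  }
  structure(list(labels = out_lab, clusters = clusters),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Cluster set:", nrow(x$clusters), "cluster(s)\n")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

# separable Gaussian smoothing of a 3D array, kernel truncated at 3 sigma
.smooth_gaussian3d <- function(vol, fwhm) {
  if (fwhm <= 0) return(vol)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  dm <- dim(vol)
  smooth_axis <- function(v, axis) {
    n <- dm[axis]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok]
    }
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    a <- aperm(v, perm)
    da <- dim(a)
    a <- matrix(a, da[1], da[2] * da[3])
    a <- K %*% a
    a <- array(a, da)
    aperm(a, order(perm))
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}

#' Monte-Carlo cluster-extent threshold
#'
#' Calibrates the minimum cluster size controlling the family-wise cluster
#' error at `cluster_alpha` under a smooth Gaussian null: each iteration
#' draws a white Gaussian volume, smooths it to the requested FWHM (voxel
#' units), renormalises the masked values to unit variance, thresholds
#' |z| at the two-tailed `primary_p` quantile, and records the largest
#' cluster. The returned extent k is the ceiling of the
#' `1 - cluster_alpha` quantile of the maximum sizes.
#'
#' @param mask Logical 3D array defining the search volume, or an integer
#'   vector of dimensions (full-volume mask).
#' @param fwhm Smoothing kernel FWHM in voxel units (0 = no smoothing).
#' @param primary_p Two-tailed voxel-forming threshold, default 0.001.
#' @param cluster_alpha Cluster-level error rate, default 0.05.
#' @param n_iterations Monte-Carlo iterations (>= 100).
#' @param connectivity Cluster connectivity (6/18/26), default 26.
#' @param seed Integer seed.
#' @return List of class `extent_threshold`: `k`, `max_sizes`, and the
#'   calibration settings.
#' @export
monte_carlo_cluster_threshold <- function(mask, fwhm = 0, primary_p = 0.001,
                                          cluster_alpha = 0.05,
                                          n_iterations = 1000,
                                          connectivity = 26, seed = 1L) {
  if (n_iterations < 100) stop("n_iterations must be at least 100")
  if (is.numeric(mask) && is.null(dim(mask)) && length(mask) <= 3) {
    dm <- as.integer(c(mask, rep(1L, 3 - length(mask))))
    mask <- array(TRUE, dm)
  }
  dm <- dim(mask)
  if (length(dm) == 2) { dm <- c(dm, 1L); mask <- array(mask, dm) }
  mask <- array(as.logical(mask), dm)
  if (!any(mask)) stop("mask is empty")
  zthr <- stats::qnorm(1 - primary_p / 2)
  set.seed(as.integer(seed))
  max_sizes <- integer(n_iterations)
  for (it in seq_len(n_iterations)) {
    vol <- array(stats::rnorm(prod(dm)), dm)
    vol <- .smooth_gaussian3d(vol, fwhm)
    s <- stats::sd(vol[mask])
    if (s > 0) vol <- vol / s
    supra <- abs(vol) > zthr & mask
    if (!any(supra)) { max_sizes[it] <- 0L; next }
    cs <- label_clusters(supra, connectivity = connectivity, extent_k = 1)
    max_sizes[it] <- max(cs$clusters$size)
  }
  k <- as.integer(max(1, ceiling(stats::quantile(max_sizes, 1 - cluster_alpha,
                                                 names = FALSE, type = 7))))
  structure(list(k = k, max_sizes = max_sizes, fwhm = fwhm,
                 primary_p = primary_p, cluster_alpha = cluster_alpha,
                 n_iterations = n_iterations, connectivity = connectivity,
                 seed = seed),
            class = "extent_threshold")
}

#' @export
print.extent_threshold <- function(x, ...) {
  cat("Monte-Carlo cluster-extent threshold: k =", x$k, "voxels\n")
  cat("  primary p =", x$primary_p, " fwhm =", x$fwhm,
      " alpha =", x$cluster_alpha, " iterations =", x$n_iterations, "\n")
  invisible(x)
}
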