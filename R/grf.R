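#' Estimate field smoothness from model residuals
#'
#' Random-field smoothness (per-axis FWHM) from the spatial derivatives of
#' the per-voxel-standardized residual maps: each voxel's residual vector
#' across maps is scaled to unit norm, the variance of the first-difference
#' spatial derivative is pooled over in-mask neighbour pairs and maps, and
#' `fwhm = sqrt(4 ln 2 / var)` per axis (in voxels, reported also in mm).
#' The resel volume is the in-mask voxel count divided by the product of
#' the FWHMs in voxels.
#'
#' @param residuals n x V matrix of residual maps over in-mask voxels, or a
#'   list of 3D arrays.
#' @param mask Logical 3D mask.
#' @param voxel_size_mm Voxel sizes in mm.
#' @return Object of class `smoothness_estimate`: `fwhm_voxels`, `fwhm_mm`,
#'   `resels`, `n_voxels`.
#' @export
estimate_smoothness <- function(residuals, mask, voxel_size_mm = c(3, 3, 3)) {
  if (is.list(residuals))
    residuals <- t(vapply(residuals, function(a) a[as.logical(mask)],
                          numeric(sum(mask))))
  if (nrow(residuals) < 2) stop("need at least 2 residual maps")
  nrm <- sqrt(colSums(residuals^2))
  if (any(nrm <= 0)) stop("flat residuals: smoothness is undefined")
  E <- sweep(residuals, 2, nrm, "/")
  gd <- dim(mask)
  vox <- which(as.logical(mask))
  coord <- arrayInd(vox, gd)
  pos <- array(0L, gd); pos[vox] <- seq_along(vox)
  lam <- numeric(3)
  for (ax in 1:3) {
    shifted <- coord
    shifted[, ax] <- shifted[, ax] + 1L
    ok <- shifted[, ax] <= gd[ax]
    nb <- pos[shifted[ok, , drop = FALSE]]
    here <- which(ok)[nb > 0]
    nb <- nb[nb > 0]
    if (!length(nb)) stop("mask too thin along axis ", ax)
    d <- E[, nb, drop = FALSE] - E[, here, drop = FALSE]
    lam[ax] <- mean(colSums(d^2))
  }
  fwhm_vox <- sqrt(4 * log(2) / lam)
  if (any(!is.finite(fwhm_vox)))
    stop("flat residuals along some axis: infinite FWHM")
  fwhm_vox <- pmax(fwhm_vox, 1e-6)
  structure(list(fwhm_voxels = fwhm_vox,
                 fwhm_mm = fwhm_vox * voxel_size_mm,
                 resels = sum(mask) / prod(fwhm_vox),
                 n_voxels = sum(mask)),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness> FWHM %s voxels (%s mm), %.1f resels over %d voxels\n",
              paste(sprintf("%.2f", x$fwhm_voxels), collapse = " x "),
              paste(sprintf("%.2f", x$fwhm_mm), collapse = " x "),
              x$resels, x$n_voxels))
  invisible(x)
}

# Worsley lattice resel counts R_0..R_3 for an arbitrary mask.
# fwhm_vox: per-axis FWHM in voxels.
resel_counts <- function(mask, fwhm_vox) {
  m <- array(as.logical(mask), dim(mask))
  gd <- dim(m)
  shift <- function(a, ax) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[ax]] <- seq_len(gd[ax] - 1) + 1
    out <- array(FALSE, gd)
    src <- rep(list(quote(expr = )), 3)
    src[[ax]] <- seq_len(gd[ax] - 1)
    do.call(`[<-`, c(list(out), src, list(do.call(`[`, c(list(a), idx)))))
  }
  mx <- m & shift(m, 1); my <- m & shift(m, 2); mz <- m & shift(m, 3)
  P <- sum(m)
  Ex <- sum(mx); Ey <- sum(my); Ez <- sum(mz)
  Fxy <- sum(mx & shift(my, 1) & my)
  Fxz <- sum(mx & shift(mz, 1) & mz)
  Fyz <- sum(my & shift(mz, 2) & mz)
  C <- sum(mx & shift(my, 1) & my & shift(mz, 1) & shift(mz, 2) & mz &
             shift(shift(mz, 1), 2))
  f <- fwhm_vox
  r0 <- P - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - C
  r1 <- (Ex - Fxy - Fxz + C) / f[1] + (Ey - Fxy - Fyz + C) / f[2] +
    (Ez - Fxz - Fyz + C) / f[3]
  r2 <- (Fxy - C) / (f[1] * f[2]) + (Fxz - C) / (f[1] * f[3]) +
    (Fyz - C) / (f[2] * f[3])
  r3 <- C / prod(f)
  c(r0, r1, r2, r3)
}

# Euler characteristic densities of a unit Gaussian field, dimensions 0..3.
ec_density <- function(z) {
  c(stats::pnorm(z, lower.tail = FALSE),
    sqrt(4 * log(2)) / (2 * pi) * exp(-z^2 / 2),
    (4 * log(2)) / (2 * pi)^(3 / 2) * z * exp(-z^2 / 2),
    (4 * log(2))^(3 / 2) / (2 * pi)^2 * (z^2 - 1) * exp(-z^2 / 2))
}

# Expected number of clusters (expected Euler characteristic) and expected
# cluster size (voxels) for a Z field thresholded at z.
grf_expectations <- function(z_thresh, smoothness, mask) {
  R <- resel_counts(mask, smoothness$fwhm_voxels)
  Em <- max(sum(R * ec_density(z_thresh)), .Machine$double.xmin)
  En <- sum(mask) * stats::pnorm(z_thresh, lower.tail = FALSE) / Em
  list(Em = Em, En = En)
}

# P(cluster extent >= k voxels) under the stationary-Gaussian cluster-size
# approximation: exp(-beta k^(2/3)), beta = (Gamma(5/2) / E[n])^(2/3).
grf_cluster_tail <- function(k, En) {
  beta <- (gamma(5 / 2) / En)^(2 / 3)
  exp(-beta * k^(2 / 3))
}

#' Cluster-level corrected p-value under random-field theory
#'
#' Familywise probability of observing at least one cluster of `k` or more
#' voxels in a thresholded Gaussian Z field:
#' `1 - exp(-E[m] P(n >= k))`, with E[m] the expected Euler characteristic
#' over the mask's resel counts and P(n >= k) the cluster-size tail.
#'
#' @param k Cluster extent in voxels.
#' @param z_thresh Cluster-forming Z threshold.
#' @param smoothness A [estimate_smoothness()] result.
#' @param mask Logical 3D mask.
#' @return Corrected cluster p-value in (0, 1].
#' @export
grf_cluster_p <- function(k, z_thresh, smoothness, mask) {
  ex <- grf_expectations(z_thresh, smoothness, mask)
  pmin(pmax(1 - exp(-ex$Em * grf_cluster_tail(k, ex$En)),
            .Machine$double.xmin), 1)
}

#' Cluster-extent threshold under random-field theory
#'
#' Smallest extent k (in voxels) whose familywise cluster p-value falls at
#' or below `cluster_alpha` at the given cluster-forming Z threshold.
#'
#' @param z_thresh Cluster-forming Z threshold (e.g. 2.33 for p < 0.01).
#' @param smoothness A [estimate_smoothness()] result.
#' @param mask Logical 3D mask.
#' @param cluster_alpha Cluster-level familywise alpha (default 0.05).
#' @return Integer extent threshold (voxels).
#' @export
grf_extent_threshold <- function(z_thresh, smoothness, mask,
                                 cluster_alpha = 0.05) {
  if (z_thresh <= 0) stop("z_thresh must be positive")
  ex <- grf_expectations(z_thresh, smoothness, mask)
  if (!is.finite(ex$En) || ex$En <= 0) stop("degenerate smoothness estimate")
  for (k in seq_len(sum(mask))) {
    if (ex$Em * grf_cluster_tail(k, ex$En) <= cluster_alpha) return(k)
  }
  sum(mask)
}

#' Extract suprathreshold clusters from a Z map
#'
#' Connected components (face connectivity 6 by default, or 26 including
#' edges and corners) of the suprathreshold set `{Z > z_thresh}`, retaining
#' components of at least `k` voxels, with extent, peak Z, peak voxel
#' coordinate (1-based grid indices) and the random-field cluster p-value.
#'
#' @param z_map 3D Z array (or `stat_map`, whose Z is used).
#' @param z_thresh Cluster-forming threshold.
#' @param k Minimum extent in voxels (default 1).
#' @param connectivity 6 or 26 (default 6).
#' @param mask Optional logical mask restricting the search.
#' @param smoothness Optional [estimate_smoothness()] result; when supplied
#'   (with `mask`), cluster p-values are attached.
#' @return Object of class `cluster_set`: `table` (data.frame) and
#'   `voxels` (list of 1-based coordinate matrices per cluster).
#' @export
extract_clusters <- function(z_map, z_thresh, k = 1, connectivity = 6,
                             mask = NULL, smoothness = NULL) {
  if (inherits(z_map, "stat_map")) {
    if (is.null(mask)) mask <- z_map$mask
    z_map <- z_map$Z
  }
  gd <- dim(z_map)
  supra <- z_map > z_thresh
  if (!is.null(mask)) supra <- supra & as.logical(mask)
  labels <- label_components(supra, connectivity)
  n_cl <- max(labels)
  rows <- list(); voxels <- list()
  kept <- 0
  for (cl in seq_len(n_cl)) {
    vox <- which(labels == cl)
    if (length(vox) < k) next
    kept <- kept + 1
    coords <- arrayInd(vox, gd)
    zi <- z_map[vox]
    pk <- which.max(zi)
    p_cl <- if (!is.null(smoothness) && !is.null(mask))
      grf_cluster_p(length(vox), z_thresh, smoothness, mask) else NA_real_
    rows[[kept]] <- data.frame(cluster = kept, extent = length(vox),
                               peak_z = zi[pk],
                               peak_x = coords[pk, 1], peak_y = coords[pk, 2],
                               peak_z_coord = coords[pk, 3],
                               cluster_p = p_cl)
    voxels[[kept]] <- coords
  }
  tab <- if (kept) do.call(rbind, rows) else
    data.frame(cluster = integer(0), extent = integer(0), peak_z = numeric(0),
               peak_x = integer(0), peak_y = integer(0),
               peak_z_coord = integer(0), cluster_p = numeric(0))
  if (kept) {
    ord <- order(-tab$extent)
    tab <- tab[ord, , drop = FALSE]
    voxels <- voxels[ord]
    tab$cluster <- seq_len(kept)
    rownames(tab) <- NULL
  }
  structure(list(table = tab, voxels = voxels, z_threshold = z_thresh,
                 extent_threshold = k, connectivity = connectivity),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) at Z > %.3g, extent >= %d (connectivity %d)\n",
              nrow(x$table), x$z_threshold, x$extent_threshold,
              x$connectivity))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

# Label connected components of a logical 3D array by iterative flood fill.
label_components <- function(supra, connectivity = 6) {
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  gd <- dim(supra)
  offsets <- if (connectivity == 6) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else {
    o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    o[rowSums(o != 0) > 0, , drop = FALSE]
  }
  labels <- array(0L, gd)
  todo <- which(supra)
  lab <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, gd)
      nb <- sweep(offsets, 2, as.integer(cc), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= gd[1] & nb[, 2] >= 1 & nb[, 2] <= gd[2] &
        nb[, 3] >= 1 & nb[, 3] <= gd[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * gd[1] + (nb[, 3] - 1L) * gd[1] * gd[2]
      lin <- lin[supra[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- lab
        queue <- c(queue, lin)
      }
    }
  }
  labels
}

#' Dice overlap between a cluster and a planted voxel set
#'
#' @param coords Cluster coordinate matrix (rows of 1-based voxel indices).
#' @param target Logical 3D array (planted voxel set).
#' @return Dice coefficient `2|A & B| / (|A| + |B|)`.
#' @export
dice_overlap <- function(coords, target) {
  gd <- dim(target)
  lin <- coords[, 1] + (coords[, 2] - 1) * gd[1] + (coords[, 3] - 1) * gd[1] * gd[2]
  inter <- sum(target[lin])
  2 * inter / (nrow(coords) + sum(target))
}
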