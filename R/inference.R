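#' Fisher z-transform
#'
#' `arctanh(b)`, applied to correlation-like regression coefficients to make
#' them approximately normal before group testing.
#'
#' @param b numeric vector with `|b| < 1`.
#' @return `atanh(b)`.
#' @seealso [clip_beta()]
#' @export
fisher_z <- function(b) {
  if (any(abs(b) >= 1, na.rm = TRUE))
    stop("fisher_z requires |b| < 1; clip upstream with clip_beta()")
  atanh(b)
}

#' Clip coefficients away from +/-1 before the Fisher transform
#'
#' Coefficients with `|b| >= 1 - tol` (possible for noise-free synthetic
#' voxels) are clipped to `+/-(1 - tol)`; the number of clipped values is
#' reported via a warning and an attribute.
#'
#' @param b numeric vector/array.
#' @param tol clipping margin (default `1e-6`).
#' @return `b` with extreme values clipped; attribute `n_clipped`.
#' @export
clip_beta <- function(b, tol = 1e-6) {
  hit <- which(abs(b) >= 1 - tol)
  if (length(hit)) {
    warning(sprintf("%d coefficient(s) clipped to +/-(1 - %g) before arctanh",
                    length(hit), tol))
    b[hit] <- sign(b[hit]) * (1 - tol)
  }
  attr(b, "n_clipped") <- length(hit)
  b
}

#' Voxelwise one-sample group t-test, expressed as z-scores
#'
#' For each voxel inside the analysis mask, tests the subject values against
#' zero with a one-sample t-test and converts t to a z-score by matching
#' two-sided tail probabilities, preserving the sign. Voxels with zero
#' variance across subjects are set to z = 0 and flagged.
#'
#' @param maps list of subject 3D arrays (e.g. Fisher-z maps) on one grid.
#' @param mask 3D logical analysis mask (conventionally brain minus white
#'   matter and CSF).
#' @return An object of class `stat_map`: list with `z` (3D array, NA
#'   outside mask), `mask`, `n_subjects`, `df`, `flagged` (linear indices of
#'   degenerate voxels).
#' @export
group_ttest <- function(maps, mask) {
  n <- length(maps)
  if (n < 2L) stop("need at least 2 subjects")
  dims <- dim(maps[[1]])
  for (m in maps)
    if (!identical(dim(m), dims)) stop("subject maps must share one grid")
  if (!identical(dim(mask), dims)) stop("mask grid mismatch")
  idx <- which(mask)
  M <- vapply(maps, function(m) m[idx], numeric(length(idx)))
  mu <- rowMeans(M)
  sdv <- sqrt(pmax(rowSums((M - mu)^2), 0) / (n - 1))
  flagged <- idx[sdv == 0 | !is.finite(sdv)]
  tval <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), 0)
  z <- t_to_z(tval, df = n - 1)
  z[sdv == 0 | !is.finite(sdv)] <- 0
  zarr <- array(NA_real_, dims)
  zarr[idx] <- z
  structure(list(z = zarr, mask = mask, n_subjects = n, df = n - 1L,
                 flagged = flagged),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s grid, %d voxels in mask, %d subjects (df = %d), z range [%.2f, %.2f]\n",
              paste(dim(x$z), collapse = "x"), sum(x$mask), x$n_subjects,
              x$df, min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE)))
  invisible(x)
}

# t -> z by two-sided tail-probability matching, sign preserved; log-scale
# tail probabilities keep large statistics finite.
t_to_z <- function(tval, df) {
  lp <- pt(abs(tval), df = df, lower.tail = FALSE, log.p = TRUE)
  sign(tval) * qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

#' Critical cluster size from random field theory
#'
#' Smallest cluster extent (in voxels) whose occurrence above the
#' cluster-forming threshold `u` has family-wise probability at most `alpha`
#' in a stationary smooth Gaussian field over the analysis mask. Uses the
#' expected-Euler-characteristic cluster-level machinery for a 3-D Gaussian
#' field: with resel volume \eqn{R = S \prod s_a / \prod FWHM_a},
#' the expected suprathreshold cluster count is
#' \eqn{E[m] = R\,(4\ln 2)^{3/2}(2\pi)^{-2}(u^2-1)e^{-u^2/2}}, the expected
#' suprathreshold volume is \eqn{E[N] = S\,\Phi(-u)} voxels, cluster extents
#' follow \eqn{P(n \ge k) = \exp(-\beta k^{2/3})} with
#' \eqn{\beta = [\Gamma(5/2)\,E[m]/E[N]]^{2/3}}, and
#' \eqn{FWE(k) = 1 - \exp(-E[m]\,P(n \ge k))}.
#'
#' @param u cluster-forming z threshold; must exceed 1 (the 3-D EC density
#'   changes sign at u = 1, below which the approximation is meaningless).
#' @param alpha family-wise error level in (0, 1).
#' @param fwhm_mm smoothness FWHM, mm (scalar or triple). Must be at least
#'   one voxel.
#' @param mask 3D logical analysis mask (or a voxel count).
#' @param voxel_size_mm voxel size, mm (scalar or triple).
#' @param df unused placeholder for a future t-field refinement; the field
#'   is treated as Gaussian (maps are converted to z upstream).
#' @return Integer critical cluster size (voxels).
#' @export
rft_critical_cluster_size <- function(u, alpha, fwhm_mm, mask,
                                      voxel_size_mm = c(1, 1, 1), df = Inf) {
  if (u <= 1) stop("cluster-forming threshold u must exceed 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  vs <- rep(voxel_size_mm, length.out = 3L)
  fwhm <- rep(fwhm_mm, length.out = 3L)
  if (any(fwhm < vs)) stop("FWHM must be at least one voxel per axis")
  S <- if (is.array(mask)) sum(mask) else as.numeric(mask)
  resels <- S * prod(vs) / prod(fwhm)
  if (resels < 1) stop("mask smaller than one resel")

  Em <- resels * (4 * log(2))^1.5 * (2 * pi)^-2 * (u^2 - 1) * exp(-u^2 / 2)
  EN <- S * pnorm(u, lower.tail = FALSE)
  beta <- (gamma(5 / 2) * Em / EN)^(2 / 3)
  fwe <- function(k) 1 - exp(-Em * exp(-beta * k^(2 / 3)))
  if (fwe(1) <= alpha) return(1L)
  # solve beta * k^(2/3) >= log(Em / -log(1 - alpha)) for the smallest integer
  k <- (log(Em / -log(1 - alpha)) / beta)^(3 / 2)
  k <- max(1L, ceiling(k - 1e-9))
  while (fwe(k) > alpha) k <- k + 1L
  as.integer(k)
}

#' Extract sign-separated suprathreshold clusters
#'
#' Thresholds a z map at `z >= u` (positive clusters) and `-z >= u`
#' (negative clusters) separately, labels connected components within each
#' sign under the chosen neighbourhood, and discards components smaller than
#' `k_crit`. Mixed-sign blobs are therefore never merged.
#'
#' @param stat a `stat_map` from [group_ttest()] (or a plain 3D z array,
#'   taken with an all-`TRUE` mask).
#' @param u cluster-forming threshold (> 0).
#' @param k_crit critical cluster size in voxels.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List of `cluster` objects: each a list with `voxels` (n-by-3,
#'   0-based), `sign` (+1/-1), `extent`, `peak_z`, `peak` (0-based index
#'   triple at max |z|).
#' @export
extract_clusters <- function(stat, u, k_crit, connectivity = 26L) {
  if (!inherits(stat, "stat_map")) {
    z <- stat
    stat <- list(z = z, mask = array(TRUE, dim(z)))
  }
  if (u <= 0) stop("u must be positive")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  z <- stat$z
  z[is.na(z)] <- 0
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- (sgn * z) >= u
    if (!any(supra)) next
    lab <- .label_components_cpp(supra, dim(z), as.integer(connectivity))
    for (cid in seq_len(max(lab))) {
      idx <- which(lab == cid)
      if (length(idx) < k_crit) next
      vox <- which(lab == cid, arr.ind = TRUE)
      pk <- idx[which.max(sgn * z[idx])]
      pkv <- arrayInd(pk, dim(z))
      out[[length(out) + 1L]] <- structure(
        list(voxels = unname(vox) - 1L, sign = sgn,
             extent = length(idx), peak_z = z[pk],
             peak = as.integer(pkv) - 1L),
        class = "cluster")
    }
  }
  out[order(-vapply(out, function(cl) abs(cl$peak_z), 1))]
}

#' Atlas-labelled cluster report
#'
#' Compares cluster locations with atlas labels: one row per (cluster,
#' overlapped region), with the cluster's peak z, extent, peak coordinates
#' and hemisphere (of the peak, by x versus the grid midline). Clusters
#' entirely in background are reported as region `"unlabeled"`.
#'
#' @param clusters list of clusters from [extract_clusters()].
#' @param v a [label_volume()] on the same grid.
#' @return Data frame of class `cluster_report` with columns `cluster`,
#'   `sign`, `hemisphere`, `peak_z`, `extent`, `peak_i`, `peak_j`, `peak_k`,
#'   `region`, `n_voxels`.
#' @export
label_clusters <- function(clusters, v) {
  stopifnot(inherits(v, "label_volume"))
  mid <- dim(v$data)[1] / 2
  rows <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    labs <- label_at(v, cl$voxels)
    tab <- table(labs[labs != 0L])
    regions <- if (length(tab)) label_name(v, as.integer(names(tab)))
               else "unlabeled"
    counts <- if (length(tab)) as.integer(tab) else cl$extent
    hemi <- if (cl$peak[1] + 0.5 < mid) "left" else "right"
    rows[[ci]] <- data.frame(
      cluster = ci, sign = cl$sign, hemisphere = hemi,
      peak_z = cl$peak_z, extent = cl$extent,
      peak_i = cl$peak[1], peak_j = cl$peak[2], peak_k = cl$peak[3],
      region = regions, n_voxels = counts)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(cluster = integer(), sign = numeric(),
                         hemisphere = character(), peak_z = numeric(),
                         extent = integer(), peak_i = integer(),
                         peak_j = integer(), peak_k = integer(),
                         region = character(), n_voxels = integer())
  class(out) <- c("cluster_report", "data.frame")
  out
}

#' Full group cluster inference on subject coefficient maps
#'
#' Pipeline wrapper: Fisher-z transform of the subject coefficient maps
#' (clipped away from +/-1), voxelwise one-sample t-test converted to z,
#' RFT critical cluster size, and sign-separated cluster extraction. One
#' critical size is computed at level `alpha` and applied to the positive
#' and negative maps separately (the classical sign-separated procedure);
#' the worst-case overall family-wise error is therefore bounded by
#' 2`alpha`, and the extent approximation is conservative in practice at
#' customary thresholds. Set `sign_split = TRUE` for a Bonferroni split
#' (`alpha/2` per sign) that bounds the overall error by `alpha`.
#'
#' @param beta_maps list of subject 3D coefficient arrays (correlation-like).
#' @param mask 3D logical analysis mask (brain minus white matter/CSF).
#' @param u cluster-forming z threshold (default 2.3).
#' @param alpha overall family-wise level (default 0.05).
#' @param fwhm_mm assumed smoothness FWHM in mm.
#' @param voxel_size_mm voxel size in mm.
#' @param connectivity cluster neighbourhood (default 26).
#' @param sign_split Bonferroni-split alpha over the two signs (default
#'   `FALSE`: one shared critical size at `alpha`, as in the classical
#'   procedure).
#' @return List with `stat` (`stat_map`), `k_crit`, `clusters`, and `report`
#'   (unlabelled: run [label_clusters()] with an atlas for region names).
#' @export
cluster_inference <- function(beta_maps, mask, u = 2.3, alpha = 0.05,
                              fwhm_mm = 6, voxel_size_mm = c(1, 1, 1),
                              connectivity = 26L, sign_split = FALSE) {
  zmaps <- lapply(beta_maps, function(b) {
    zb <- suppressWarnings(clip_beta(b))
    atanh(zb)
  })
  stat <- group_ttest(zmaps, mask)
  a <- if (sign_split) alpha / 2 else alpha
  k_crit <- rft_critical_cluster_size(u, a, fwhm_mm, mask, voxel_size_mm,
                                      df = stat$df)
  clusters <- extract_clusters(stat, u, k_crit, connectivity)
  list(stat = stat, k_crit = k_crit, clusters = clusters)
}

#' Analysis mask: brain labels minus white matter and CSF
#'
#' @param v a [label_volume()] with groups `wm` and `csf` (either may be
#'   absent).
#' @return 3D logical array.
#' @export
analysis_mask <- function(v) {
  excl <- c(v$groups$wm, v$groups$csf)
  array(v$data > 0 & !(v$data %in% excl), dim(v$data))
}

#' Write a signed thresholded z map as NIfTI
#'
#' @param clusters clusters from [extract_clusters()].
#' @param stat the `stat_map` they came from.
#' @param v a [label_volume()] for grid/voxel size.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_thresholded_map <- function(clusters, stat, v, path) {
  arr <- array(0, dim(stat$z))
  for (cl in clusters) {
    idx <- cl$voxels + 1L
    arr[idx] <- stat$z[idx]
  }
  write_volume(arr, path, v$voxel_size_mm)
}
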