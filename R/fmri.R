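#' Standardize a time series
#'
#' Centers to mean 0 and scales to unit standard deviation,
#' \eqn{(x - \mu)/\sigma}. Constant series are an error because the
#' downstream regression coefficients are correlation-like only for
#' unit-variance signals.
#'
#' @param ts numeric vector.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
standardize <- function(ts) {
  sdev <- sd(ts)
  if (!is.finite(sdev) || sdev == 0)
    stop("cannot standardize a constant series")
  (ts - mean(ts)) / sdev
}

#' Preprocess a BOLD run: drop initial volumes, detrend, bandpass
#'
#' Removes the first `n_drop` volumes (magnetization-saturation frames; the
#' motion table is trimmed identically), removes a per-voxel linear trend,
#' and applies a zero-phase 4th-order Butterworth bandpass within the brain
#' mask. Voxels outside the mask are left untouched.
#'
#' @param run a [bold_run()].
#' @param n_drop number of leading volumes to discard (default 5).
#' @param band numeric length-2 passband in Hz; must lie strictly inside
#'   (0, Nyquist). Default `c(0.01, 0.08)`, the standard resting-state band.
#' @param order Butterworth order (default 4).
#' @return A [bold_run()] with T - `n_drop` timepoints.
#' @export
preprocess_bold <- function(run, n_drop = 5L, band = c(0.01, 0.08),
                            order = 4L) {
  stopifnot(inherits(run, "bold_run"))
  tt <- dim(run$data)[4]
  if (tt - n_drop < 20L)
    stop("too few timepoints after dropping initial volumes")
  nyq <- 1 / (2 * run$tr_s)
  if (length(band) != 2L || band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop(sprintf("band must lie strictly inside (0, %.4f) Hz", nyq))
  keep <- (n_drop + 1L):tt
  data <- run$data[, , , keep, drop = FALSE]
  motion <- run$motion[keep, , drop = FALSE]

  d <- dim(data)
  mat <- matrix(data, nrow = prod(d[1:3]), ncol = d[4])
  inmask <- which(run$brain_mask)
  X <- mat[inmask, , drop = FALSE]           # V x T, voxel-major
  X <- detrend_rows(X)
  nyq2 <- 1 / (2 * run$tr_s)
  bf <- signal::butter(order, band / nyq2, type = "pass")
  X <- .filtfilt_rows_cpp(bf$b, bf$a, X, 3L * (length(bf$a) - 1L) * 4L)
  mat[inmask, ] <- X
  bold_run(array(mat, d), tr_s = run$tr_s, motion = motion,
           brain_mask = run$brain_mask, subject_id = run$subject_id,
           voxel_size_mm = run$voxel_size_mm)
}

# Remove the per-row linear trend (intercept + slope) from a V x T matrix.
detrend_rows <- function(X) {
  tt <- ncol(X)
  D <- cbind(1, seq_len(tt) - (tt + 1) / 2)
  X - (X %*% D) %*% tcrossprod(solve(crossprod(D)), D)
}

# Zero-phase Butterworth bandpass applied column-wise to a T x V matrix.
# signal::butter supplies the coefficients; the filter is run forward and
# backward (with odd-symmetric edge padding, as filtfilt does) by a C++
# time-stepping loop, because signal::filtfilt accepts only vectors.
bandpass_matrix <- function(X, tr_s, band, order = 4L) {
  nyq <- 1 / (2 * tr_s)
  bf <- signal::butter(order, band / nyq, type = "pass")
  t(.filtfilt_rows_cpp(bf$b, bf$a, t(X), 3L * (length(bf$a) - 1L) * 4L))
}

#' Build the confound design for STN seed regressions
#'
#' Columns: intercept, the 6 motion parameters (centered and unit-scaled
#' where non-constant), and the standardized global mean signal over the
#' brain mask.
#'
#' @param run a preprocessed [bold_run()].
#' @param global include the global mean regressor (default `TRUE`).
#' @param motion include the motion regressors (default `TRUE`).
#' @return Numeric T-by-p matrix with named columns.
#' @export
confound_matrix <- function(run, global = TRUE, motion = TRUE) {
  tt <- dim(run$data)[4]
  out <- matrix(1, tt, 1L, dimnames = list(NULL, "offset"))
  if (motion) {
    keep <- apply(run$motion, 2L, sd) > 0
    if (any(keep)) {
      mot <- apply(run$motion[, keep, drop = FALSE], 2L, standardize)
      colnames(mot) <- paste0("motion", which(keep))
      out <- cbind(out, mot)
    }
  }
  if (global) {
    mat <- matrix(run$data, ncol = tt)
    g <- colMeans(mat[which(run$brain_mask), , drop = FALSE])
    out <- cbind(out, global = standardize(g))
  }
  out
}

# OLS of standardized targets on [principals | confounds]; returns the
# coefficient rows for the principal regressors. Y is T x V (already
# standardized per column); P is T x q.
ols_principal <- function(P, confounds, Y) {
  X <- cbind(P, confounds)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[length(sv)] / sv[1] < 1e-8) {
    # name the offending columns by leave-one-out rank probing
    qrX <- qr(X)
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[drop], collapse = ", "))
  }
  cf <- qr.coef(qr(X), Y)
  cf[seq_len(ncol(P)), , drop = FALSE]
}

#' Whole-brain seed regression on the mean STN signal
#'
#' Expresses the standardized signal of every brain voxel as a linear
#' combination of the standardized mean seed (STN) signal plus confounds
#' (offset, motion parameters, global mean), and returns the coefficient of
#' the seed regressor per voxel. Because both sides are standardized, the
#' coefficient is correlation-like, which keeps the downstream Fisher
#' z-transform well defined. Seed voxels are excluded from the output map;
#' constant voxels are flagged and excluded.
#'
#' @param run a preprocessed [bold_run()].
#' @param seed_mask 3D logical array (or n-by-3 matrix of 0-based voxel
#'   indices) selecting the seed voxels; must be non-empty.
#' @param confounds confound matrix from [confound_matrix()], or `NULL` to
#'   build the default one from `run`.
#' @return A `beta_map`: 3D array of coefficients (NA outside the brain
#'   mask, at seed voxels and at flagged constant voxels), with attributes
#'   `subject_id`, `regressor = "seed"`, `voxel_size_mm` and
#'   `n_flagged_constant`.
#' @export
seed_regression <- function(run, seed_mask, confounds = NULL) {
  stopifnot(inherits(run, "bold_run"))
  seed_idx <- mask_to_linear(seed_mask, dim(run$data)[1:3])
  if (!length(seed_idx)) stop("seed mask is empty")
  tt <- dim(run$data)[4]
  mat <- matrix(run$data, ncol = tt)
  seed <- standardize(colMeans(mat[seed_idx, , drop = FALSE]))
  if (is.null(confounds)) confounds <- confound_matrix(run)

  vox <- setdiff(which(run$brain_mask), seed_idx)
  Y <- t(mat[vox, , drop = FALSE])
  Yc <- sweep(Y, 2L, colMeans(Y))
  sds <- sqrt(colSums(Yc^2) / (nrow(Y) - 1L))
  ok <- sds > 0
  Y <- sweep(Yc[, ok, drop = FALSE], 2L, sds[ok], "/")
  beta <- ols_principal(matrix(seed, ncol = 1L,
                               dimnames = list(NULL, "seed")),
                        confounds, Y)
  out <- array(NA_real_, dim(run$data)[1:3])
  out[vox[ok]] <- beta[1L, ]
  structure(out, subject_id = run$subject_id, regressor = "seed",
            voxel_size_mm = run$voxel_size_mm,
            n_flagged_constant = sum(!ok), class = c("beta_map", "array"))
}

mask_to_linear <- function(mask, dims) {
  if (is.matrix(mask) && ncol(mask) == 3L) {
    idx <- mask + 1L
    return(as.integer(idx[, 1] + dims[1] * (idx[, 2] - 1L) +
                        dims[1] * dims[2] * (idx[, 3] - 1L)))
  }
  which(mask)
}

#' Reverse regression: motor and limbic coefficients per STN voxel
#'
#' Regresses each standardized STN voxel signal on two principal regressors
#' — the standardized mean signal of the motor ROI group and of the limbic
#' ROI group — plus confounds, and returns the two coefficient maps over the
#' STN. ROI groups must not overlap the STN mask. Maps from several subjects
#' can be summed with [accumulate_maps()] after conversion via
#' [map_from_beta()].
#'
#' @param run a preprocessed [bold_run()].
#' @param stn_mask 3D logical array or n-by-3 0-based index matrix for the
#'   STN voxels.
#' @param motor_rois,limbic_rois 3D logical arrays or index matrices for the
#'   two ROI groups (use the ipsilateral groups for each STN).
#' @param confounds confound matrix, or `NULL` for the default.
#' @return List with `beta_map` elements `motor` and `limbic` (3D arrays,
#'   NA outside the STN).
#' @export
reverse_regression <- function(run, stn_mask, motor_rois, limbic_rois,
                               confounds = NULL) {
  stopifnot(inherits(run, "bold_run"))
  dims <- dim(run$data)[1:3]
  stn_idx <- mask_to_linear(stn_mask, dims)
  mot_idx <- mask_to_linear(motor_rois, dims)
  lim_idx <- mask_to_linear(limbic_rois, dims)
  if (!length(mot_idx) || !length(lim_idx)) stop("ROI groups must be non-empty")
  if (length(intersect(stn_idx, c(mot_idx, lim_idx))))
    stop("motor/limbic ROIs overlap the STN mask")
  tt <- dim(run$data)[4]
  mat <- matrix(run$data, ncol = tt)
  P <- cbind(motor = standardize(colMeans(mat[mot_idx, , drop = FALSE])),
             limbic = standardize(colMeans(mat[lim_idx, , drop = FALSE])))
  if (is.null(confounds)) confounds <- confound_matrix(run)
  Y <- t(mat[stn_idx, , drop = FALSE])
  Y <- apply(Y, 2L, standardize)
  beta <- ols_principal(P, confounds, Y)
  mk <- function(row, nm) {
    out <- array(NA_real_, dims)
    out[stn_idx] <- beta[row, ]
    structure(out, subject_id = run$subject_id, regressor = nm,
              voxel_size_mm = run$voxel_size_mm,
              class = c("beta_map", "array"))
  }
  list(motor = mk(1L, "motor"), limbic = mk(2L, "limbic"))
}

#' Convert a `beta_map` array to a `voxel_map` data frame
#'
#' @param b a `beta_map` (3D array with NA outside its support).
#' @return A `voxel_map` with one row per defined voxel.
#' @export
map_from_beta <- function(b) {
  idx <- which(!is.na(b), arr.ind = TRUE)
  voxel_map(unname(idx) - 1L, b[!is.na(b)],
            attr(b, "voxel_size_mm"))
}

#' Rank-correlation gradient index of a per-voxel map
#'
#' Spearman correlation between the voxel coordinate along one spatial axis
#' and the map value; quantifies a spatial gradient such as the mediolateral
#' increase of STN motor connectivity. With `midline` given, the coordinate
#' is the absolute distance from that midline (in voxels), so that positive
#' values mean higher map values laterally on both sides.
#'
#' @param map a `voxel_map` data frame (or `beta_map`, converted
#'   internally).
#' @param axis spatial axis: 1/`"x"`, 2/`"y"`, 3/`"z"`.
#' @param midline optional midline coordinate (0-based voxel units) for
#'   two-sided lateral distance.
#' @return Spearman correlation in `[-1, 1]`; errors for maps with fewer
#'   than 3 voxels or constant values.
#' @export
gradient_index <- function(map, axis = 1L, midline = NULL) {
  if (inherits(map, "beta_map")) map <- map_from_beta(map)
  if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
  coord <- map[[c("i", "j", "k")[axis]]]
  if (length(coord) < 3L) stop("gradient_index needs at least 3 voxels")
  if (!is.null(midline)) coord <- abs(coord - midline)
  if (sd(map$value) == 0)
    stop("gradient index undefined for a constant map")
  cor(coord, map$value, method = "spearman")
}

#' Gaussian spatial smoothing of a 3D volume
#'
#' FFT-based (circular) convolution with an isotropic Gaussian kernel of the
#' given full width at half maximum; sigma = FWHM / sqrt(8 ln 2). Used to
#' emulate the spatial smoothing that acquisition pipelines apply upstream,
#' and to build smooth null fields for cluster-inference calibration.
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm full width at half maximum, mm (scalar or triple).
#' @param voxel_size_mm voxel size, mm (scalar or triple).
#' @return Smoothed array of the same dimension.
#' @export
smooth_volume <- function(arr, fwhm_mm, voxel_size_mm = c(1, 1, 1)) {
  d <- dim(arr)
  fwhm <- rep(fwhm_mm, length.out = 3L) / rep(voxel_size_mm, length.out = 3L)
  sigma <- fwhm / sqrt(8 * log(2))
  kern1 <- function(n, s) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1], sigma[1]), kern1(d[2], sigma[2])),
             kern1(d[3], sigma[3]))
  dim(K) <- d
  Re(fft(fft(arr) * fft(K), inverse = TRUE)) / prod(d)
}
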