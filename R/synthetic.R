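#' Simulation specifications
#'
#' `atlas_spec()`, `streamline_spec()` and `bold_spec()` bundle the tunables
#' of the three simulators. Defaults emulate the cohort the analysis is
#' designed for: STN seed regions of 16 (left) and 15 (right) voxels, 5,000
#' streamlines launched per seed voxel, BOLD runs of 200 timepoints at
#' TR 2.2 s of which the first 5 are discarded, and a mediolateral gradient
#' of motor connectivity across the STN.
#'
#' @param grid integer triple: atlas grid shape (default 32^3).
#' @param voxel_size_mm voxel edge lengths, mm (default 2 mm isotropic).
#' @return A list of class `atlas_spec`.
#' @rdname simulation_specs
#' @export
atlas_spec <- function(grid = c(32L, 32L, 32L), voxel_size_mm = c(2, 2, 2)) {
  structure(list(grid = as.integer(grid),
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "atlas_spec")
}

#' @param n_per_seed streamlines launched per seed voxel (default 5000).
#' @param p_motor motor-target hit probability: scalar, or
#'   `c(medial = , lateral = )` for a ramp linear in the mediolateral
#'   position of the seed voxel within its STN (default
#'   `c(medial = 0.2, lateral = 0.8)`, the planted gradient).
#' @param p_limbic limbic-target hit probability (scalar, default 0.05).
#' @param relay_fraction fraction of motor-target streamlines routed through
#'   a relay nucleus on their way to the cortex (default 0.3).
#' @param jitter_sd_mm Gaussian jitter applied to interior polyline points
#'   (default 0.3 mm).
#' @param step_mm resampling step of the simulated polylines (default 1 mm).
#' @rdname simulation_specs
#' @export
streamline_spec <- function(n_per_seed = 5000L,
                            p_motor = c(medial = 0.2, lateral = 0.8),
                            p_limbic = 0.05, relay_fraction = 0.3,
                            jitter_sd_mm = 0.3, step_mm = 1) {
  p_motor <- ramp2(p_motor)
  if (any(p_motor < 0) || any(p_motor > 1) || p_limbic < 0 ||
      max(p_motor) + p_limbic > 1)
    stop("hit probabilities must lie in [0,1] and sum to at most 1")
  if (relay_fraction < 0 || relay_fraction > 1)
    stop("relay_fraction must be in [0,1]")
  structure(list(n_per_seed = as.integer(n_per_seed), p_motor = p_motor,
                 p_limbic = p_limbic, relay_fraction = relay_fraction,
                 jitter_sd_mm = jitter_sd_mm, step_mm = step_mm),
            class = "streamline_spec")
}

#' @param n_subjects number of synthetic subjects (default 10, the
#'   functional cohort size).
#' @param n_timepoints timepoints per run (default 200).
#' @param tr_s repetition time, s (default 2.2).
#' @param band latent passband, Hz (default `c(0.01, 0.08)`).
#' @param stn_motor_loading STN voxel loading on the motor latent: scalar or
#'   `c(medial = , lateral = )` ramp (default `c(0.2, 0.8)`).
#' @param stn_limbic_loading STN loading on the limbic latent (default the
#'   reversed ramp `c(0.8, 0.2)`, highest at the medial tip).
#' @param roi_loading loading of motor/limbic cortical ROI voxels on their
#'   system latent (default 0.8).
#' @param global_loading loading of every brain voxel on the global latent
#'   (default 0.3).
#' @param ar_coef AR(1) coefficient of the voxel noise, in (-1, 1)
#'   (default 0.3).
#' @param noise_sd marginal noise standard deviation (default 0.8, giving
#'   signal-to-noise near 1 at strongly loaded voxels).
#' @param stn_noise_sd noise sd at STN voxels (default `noise_sd`).
#' @param drift_sd sd of the per-voxel linear drift slope, signal units per
#'   volume (default 0.005).
#' @param motion_coupling sd of per-voxel couplings to the 6 standardized
#'   motion parameters (default 0.1).
#' @param latent_corr correlation between the motor and limbic latents
#'   (default 0).
#' @param noise_band_limited if `TRUE` the noise is bandpassed to `band` as
#'   well, so planted correlations are exact in the analysis band
#'   (default `FALSE`: broadband AR(1) noise, as in raw data).
#' @rdname simulation_specs
#' @export
bold_spec <- function(n_subjects = 10L, n_timepoints = 200L, tr_s = 2.2,
                      band = c(0.01, 0.08),
                      stn_motor_loading = c(medial = 0.2, lateral = 0.8),
                      stn_limbic_loading = c(medial = 0.8, lateral = 0.2),
                      roi_loading = 0.8, global_loading = 0.3,
                      ar_coef = 0.3, noise_sd = 0.8, stn_noise_sd = noise_sd,
                      drift_sd = 0.005, motion_coupling = 0.1,
                      latent_corr = 0, noise_band_limited = FALSE) {
  if (abs(ar_coef) >= 1) stop("AR(1) coefficient must lie in (-1, 1)")
  if (n_timepoints <= 25L) stop("need more than 25 timepoints")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints), tr_s = tr_s,
                 band = band, stn_motor_loading = ramp2(stn_motor_loading),
                 stn_limbic_loading = ramp2(stn_limbic_loading),
                 roi_loading = roi_loading, global_loading = global_loading,
                 ar_coef = ar_coef, noise_sd = noise_sd,
                 stn_noise_sd = stn_noise_sd, drift_sd = drift_sd,
                 motion_coupling = motion_coupling, latent_corr = latent_corr,
                 noise_band_limited = noise_band_limited),
            class = "bold_spec")
}

ramp2 <- function(x) {
  x <- unname(as.numeric(x))
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L) stop("expected a scalar or c(medial, lateral) pair")
  names(x) <- c("medial", "lateral")
  x
}

# Block table of the toy atlas, in 0-based inclusive voxel ranges on the
# default 32^3 grid (scaled proportionally for other grids is NOT attempted:
# the geometry is fixed; grids smaller than 32^3 are rejected).
#
# Layout (x = mediolateral, midline at x = 16; y = anterior->posterior;
# z = inferior->superior):
#   - STN pair near the grid centre (left 16 voxels, right 15);
#   - motor cortical blocks above (z 26-29), centred over each STN in x so
#     path lengths are mediolaterally symmetric;
#   - relay nuclei (thalamus, caudate, putamen, GPe, GPi) in a posterior
#     band (y 22-26) that direct seed->cortex trajectories never touch;
#   - limbic blocks below (z 3-7); white matter and CSF slabs; a generic
#     gray-matter filler completes the brain box.
toy_atlas_blocks <- function() {
  B <- function(id, name, xr, yr, zr)
    list(id = id, name = name, xr = xr, yr = yr, zr = zr)
  list(
    B(1L,  "STN L",                      c(6, 9),   c(14, 15), c(16, 17)),
    B(2L,  "STN R",                      c(22, 26), c(14, 16), c(16, 16)),
    B(3L,  "Thalamus",                   c(12, 19), c(22, 26), c(18, 23)),
    B(4L,  "Caudate",                    c(8, 11),  c(22, 26), c(18, 23)),
    B(5L,  "Putamen",                    c(4, 7),   c(22, 26), c(18, 23)),
    B(6L,  "Lateral Globus Pallidus",    c(20, 23), c(22, 26), c(18, 23)),
    B(7L,  "Medial Globus Pallidus",     c(24, 27), c(22, 26), c(18, 23)),
    B(8L,  "Primary Motor Cortex (BA4) R",  c(20, 22), c(14, 19), c(26, 29)),
    B(9L,  "Premotor and Supplementary Motor Area (BA6) R",
                                         c(23, 25), c(14, 19), c(26, 29)),
    B(10L, "Precentral Gyrus R",         c(26, 28), c(14, 19), c(26, 29)),
    B(11L, "Primary Motor Cortex (BA4) L",  c(10, 12), c(14, 19), c(26, 29)),
    B(12L, "Premotor and Supplementary Motor Area (BA6) L",
                                         c(7, 9),   c(14, 19), c(26, 29)),
    B(13L, "Precentral Gyrus L",         c(4, 6),   c(14, 19), c(26, 29)),
    B(14L, "Hippocampus R",              c(20, 21), c(14, 19), c(3, 7)),
    B(15L, "Amygdala R",                 c(22, 23), c(14, 19), c(3, 7)),
    B(16L, "Parahippocampal Gyrus R",    c(24, 25), c(14, 19), c(3, 7)),
    B(17L, "Anterior Cingulate R",       c(26, 27), c(14, 19), c(3, 7)),
    B(18L, "Cingulate Gyrus R",          c(28, 29), c(14, 19), c(3, 7)),
    B(19L, "Hippocampus L",              c(10, 11), c(14, 19), c(3, 7)),
    B(20L, "Amygdala L",                 c(8, 9),   c(14, 19), c(3, 7)),
    B(21L, "Parahippocampal Gyrus L",    c(6, 7),   c(14, 19), c(3, 7)),
    B(22L, "Anterior Cingulate L",       c(4, 5),   c(14, 19), c(3, 7)),
    B(23L, "Cingulate Gyrus L",          c(2, 3),   c(14, 19), c(3, 7)),
    B(24L, "White Matter",               c(4, 27),  c(8, 12),  c(10, 13)),
    B(25L, "CSF",                        c(4, 27),  c(4, 6),   c(16, 20))
  )
}

toy_atlas_groups <- function() {
  list(stn_left = 1L, stn_right = 2L, relay = 3:7,
       motor_right = 8:10, motor_left = 11:13, motor = 8:13,
       limbic_right = 14:18, limbic_left = 19:23, limbic = 14:23,
       wm = 24L, csf = 25L)
}

#' Build the toy block atlas
#'
#' Generates a deterministic block-based label volume with left/right STN
#' (16 and 15 voxels), the five relay nuclei, three motor and five limbic
#' cortical labels per hemisphere, white matter, CSF and a gray-matter
#' filler, with all analysis groups prefilled. Blocks are axis-aligned
#' boxes; the geometry is validated for overlaps.
#'
#' @param spec an [atlas_spec()].
#' @param seed RNG seed (accepted for API uniformity; the atlas is fully
#'   deterministic).
#' @return A [label_volume()].
#' @export
make_toy_atlas <- function(spec = atlas_spec(), seed = 1L) {
  grid <- spec$grid
  if (any(grid < 32L))
    stop("the toy atlas geometry needs a grid of at least 32 voxels per axis")
  blocks <- toy_atlas_blocks()
  arr <- array(0L, grid)
  for (b in blocks) {
    xr <- b$xr + 1L; yr <- b$yr + 1L; zr <- b$zr + 1L
    sub <- arr[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]]
    if (any(sub != 0L))
      stop(sprintf("atlas blocks overlap at label %d (%s)", b$id, b$name))
    arr[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- b$id
  }
  # gray-matter filler completes the brain box
  gm_id <- 26L
  box <- array(FALSE, grid)
  box[3:min(30L, grid[1] - 2L), 3:min(30L, grid[2] - 2L),
      3:min(31L, grid[3] - 1L)] <- TRUE
  arr[box & arr == 0L] <- gm_id
  nm <- c(setNames(vapply(blocks, `[[`, "", "name"),
                   vapply(blocks, `[[`, 1L, "id")),
          setNames("Gray Matter", gm_id))
  label_volume(arr, spec$voxel_size_mm, names = nm,
               groups = toy_atlas_groups())
}

# mediolateral position of STN voxels: 0 at the medial tip, 1 laterally
stn_lateral_fraction <- function(vox_x, side) {
  rng <- range(vox_x)
  if (rng[1] == rng[2]) return(rep(0.5, length(vox_x)))
  lam <- (vox_x - rng[1]) / (rng[2] - rng[1])
  if (side == "left") 1 - lam else lam
}

block_point <- function(b, voxel_size, margin_mm = 1) {
  # uniform point inside the block, margin_mm away from its faces
  lo <- (b$xyz_lo) * voxel_size + margin_mm
  hi <- (b$xyz_hi + 1) * voxel_size - margin_mm
  runif(3, lo, hi)
}

block_geom <- function(v, id) {
  idx <- which(v$data == id, arr.ind = TRUE)
  list(xyz_lo = apply(idx, 2, min) - 1L, xyz_hi = apply(idx, 2, max) - 1L)
}

resample_polyline <- function(w, step) {
  seglen <- sqrt(rowSums(diff(w)^2))
  arc <- c(0, cumsum(seglen))
  total <- arc[length(arc)]
  n <- max(2L, ceiling(total / step) + 1L)
  s <- seq(0, total, length.out = n)
  cbind(approx(arc, w[, 1], xout = s)$y,
        approx(arc, w[, 2], xout = s)$y,
        approx(arc, w[, 3], xout = s)$y)
}

#' Simulate tractography streamlines from the STN
#'
#' For each seed voxel of the chosen STN, launches `n_per_seed` streamlines.
#' Each draws a target category from the voxel's hit probabilities (motor
#' ramped mediolaterally, limbic, or a white-matter non-hit); motor-bound
#' lines are routed either directly to a uniformly chosen ipsilateral motor
#' block — along a corridor that by construction avoids the posterior relay
#' band — or, with probability `relay_fraction`, through a waypoint inside
#' the thalamus. Polylines are resampled at `step_mm` and interior points
#' receive Gaussian jitter. Reproducible given (`spec`, `seed`).
#'
#' @param atlas a [label_volume()] from [make_toy_atlas()].
#' @param spec a [streamline_spec()].
#' @param seed integer RNG seed.
#' @param stn `"stn_right"` (default) or `"stn_left"`.
#' @param subject_id subject identifier.
#' @return A [streamline_set()].
#' @export
simulate_streamlines <- function(atlas, spec = streamline_spec(), seed = 1L,
                                 stn = "stn_right", subject_id = "s1") {
  stopifnot(inherits(atlas, "label_volume"), inherits(spec, "streamline_spec"))
  set.seed(seed)
  side <- if (stn == "stn_left") "left" else "right"
  vs <- atlas$voxel_size_mm
  seeds <- which(array(atlas$data %in% group_ids(atlas, stn),
                       dim(atlas$data)), arr.ind = TRUE) - 1L
  seeds <- unname(as.matrix(seeds))
  if (!nrow(seeds)) stop("atlas has no voxels for ", stn)
  lam <- stn_lateral_fraction(seeds[, 1], side)
  p_mot <- spec$p_motor[1] + lam * (spec$p_motor[2] - spec$p_motor[1])

  motor_ids <- group_ids(atlas, paste0("motor_", side))
  limbic_ids <- group_ids(atlas, paste0("limbic_", side))
  geom <- lapply(setNames(nm = c(motor_ids, limbic_ids, 3L, 24L)),
                 function(id) block_geom(atlas, id))

  nseed <- nrow(seeds)
  total <- nseed * spec$n_per_seed
  lines <- vector("list", total)
  seed_vox <- matrix(0L, total, 3L)
  q <- 0L
  for (sv in seq_len(nseed)) {
    cen <- (seeds[sv, ] + 0.5) * vs
    u <- runif(spec$n_per_seed)
    cat_motor <- u < p_mot[sv]
    cat_limbic <- !cat_motor & u < p_mot[sv] + spec$p_limbic
    via_relay <- cat_motor & (runif(spec$n_per_seed) < spec$relay_fraction)
    for (li in seq_len(spec$n_per_seed)) {
      if (cat_motor[li]) {
        tid <- sample(motor_ids, 1L)
        tp <- block_point(geom[[as.character(tid)]], vs)
        if (via_relay[li]) {
          rp <- block_point(geom[["3"]], vs)  # thalamus waypoint
          w <- rbind(cen, rp, c(tp[1], tp[2], 50), tp)
        } else {
          w <- rbind(cen, c(tp[1], tp[2], 44), tp)
        }
      } else if (cat_limbic[li]) {
        tid <- sample(limbic_ids, 1L)
        tp <- block_point(geom[[as.character(tid)]], vs)
        w <- rbind(cen, c(tp[1], tp[2], 18), tp)
      } else {
        tp <- block_point(geom[["24"]], vs)  # white-matter non-hit
        w <- rbind(cen, tp)
      }
      m <- resample_polyline(w, spec$step_mm)
      if (nrow(m) > 2L && spec$jitter_sd_mm > 0) {
        ni <- nrow(m) - 2L
        m[2:(nrow(m) - 1L), ] <- m[2:(nrow(m) - 1L), ] +
          matrix(rnorm(3L * ni, sd = spec$jitter_sd_mm), ni, 3L)
      }
      q <- q + 1L
      lines[[q]] <- m
      seed_vox[q, ] <- seeds[sv, ]
    }
  }
  streamline_set(lines, seed_vox, subject_id = subject_id,
                 n_per_seed = spec$n_per_seed)
}

#' Bounded random-walk motion parameters
#'
#' Reflected Gaussian random walk starting at zero: translations stay within
#' +/-1 mm, rotations within +/-0.01 rad.
#'
#' @param n_timepoints number of rows.
#' @param seed RNG seed.
#' @param trans_step,rot_step per-step innovation sd.
#' @return `n_timepoints` x 6 matrix (tx, ty, tz in mm; rx, ry, rz in rad).
#' @export
make_motion_params <- function(n_timepoints, seed = 1L,
                               trans_step = 0.05, rot_step = 5e-4) {
  set.seed(seed)
  bounds <- c(rep(1, 3), rep(0.01, 3))
  steps <- c(rep(trans_step, 3), rep(rot_step, 3))
  out <- matrix(0, n_timepoints, 6L)
  if (n_timepoints > 1L) {
    for (c6 in 1:6) {
      x <- cumsum(c(0, rnorm(n_timepoints - 1L, sd = steps[c6])))
      # reflect into [-b, b]
      b <- bounds[c6]
      x <- abs((x + b) %% (4 * b) - 2 * b) - b
      out[, c6] <- x
    }
  }
  colnames(out) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad")
  out
}

#' Simulate resting-state BOLD runs
#'
#' Generates one run per synthetic subject on the atlas grid. Three latent
#' components (motor, limbic, global) are band-limited unit-variance series;
#' every brain voxel is a loading-weighted sum of latents plus AR(1) noise,
#' a random linear drift and a motion-coupled nuisance term. Motor and
#' limbic cortical ROI voxels load on their system latent; STN voxels follow
#' the spec's mediolateral loading ramps. Reproducible given (`spec`,
#' `seed`).
#'
#' @param atlas a [label_volume()] from [make_toy_atlas()].
#' @param spec a [bold_spec()].
#' @param seed integer RNG seed.
#' @return List of [bold_run()] objects, one per subject.
#' @export
simulate_bold <- function(atlas, spec = bold_spec(), seed = 1L) {
  stopifnot(inherits(atlas, "label_volume"), inherits(spec, "bold_spec"))
  set.seed(seed)
  dims <- dim(atlas$data)
  tt <- spec$n_timepoints
  mask <- atlas$data > 0L
  vox <- which(mask)
  labs <- atlas$data[vox]
  V <- length(vox)

  # loading matrix: columns (motor, limbic, global)
  L <- matrix(0, V, 3L)
  L[, 3] <- spec$global_loading
  L[labs %in% atlas$groups$motor, 1] <- spec$roi_loading
  L[labs %in% atlas$groups$limbic, 2] <- spec$roi_loading
  nsd <- rep(spec$noise_sd, V)
  for (side in c("left", "right")) {
    stn_id <- group_ids(atlas, paste0("stn_", side))
    sel <- which(labs %in% stn_id)
    if (!length(sel)) next
    xcoord <- (arrayInd(vox[sel], dims)[, 1]) - 1L
    lamf <- stn_lateral_fraction(xcoord, side)
    L[sel, 1] <- spec$stn_motor_loading[1] +
      lamf * (spec$stn_motor_loading[2] - spec$stn_motor_loading[1])
    L[sel, 2] <- spec$stn_limbic_loading[1] +
      lamf * (spec$stn_limbic_loading[2] - spec$stn_limbic_loading[1])
    nsd[sel] <- spec$stn_noise_sd
  }

  runs <- vector("list", spec$n_subjects)
  for (subj in seq_len(spec$n_subjects)) {
    lat <- band_limited_series(tt, 3L, spec$tr_s, spec$band)
    if (spec$latent_corr != 0)
      lat[, 2] <- standardize(spec$latent_corr * lat[, 1] +
                                sqrt(1 - spec$latent_corr^2) * lat[, 2])
    noise <- matrix(rnorm(tt * V), tt, V)
    if (spec$ar_coef != 0) {
      phi <- spec$ar_coef
      noise <- noise * sqrt(1 - phi^2)
      noise[1, ] <- noise[1, ] / sqrt(1 - phi^2)
      for (t in 2:tt) noise[t, ] <- phi * noise[t - 1L, ] + noise[t, ]
    }
    if (spec$noise_band_limited) {
      noise <- bandpass_matrix(noise, spec$tr_s, spec$band)
      noise <- sweep(noise, 2L, apply(noise, 2L, sd), "/")
    }
    sig <- lat %*% t(L) + sweep(noise, 2L, nsd, "*")
    if (spec$drift_sd > 0) {
      slope <- rnorm(V, sd = spec$drift_sd)
      sig <- sig + outer(seq_len(tt) - (tt + 1) / 2, slope)
    }
    motion <- make_motion_params(tt, seed = seed * 1000L + subj)
    if (spec$motion_coupling > 0) {
      mstd <- apply(motion, 2L, function(x)
        if (sd(x) > 0) (x - mean(x)) / sd(x) else x)
      W <- matrix(rnorm(6L * V, sd = spec$motion_coupling), 6L, V)
      sig <- sig + mstd %*% W
    }
    arr <- array(0, c(dims, tt))
    flat <- matrix(arr, ncol = tt)
    flat[vox, ] <- t(sig)
    runs[[subj]] <- bold_run(array(flat, c(dims, tt)), tr_s = spec$tr_s,
                             motion = motion, brain_mask = mask,
                             subject_id = sprintf("sim%02d", subj),
                             voxel_size_mm = atlas$voxel_size_mm)
  }
  runs
}

# q unit-variance series bandpassed to `band`
band_limited_series <- function(tt, q, tr_s, band) {
  x <- bandpass_matrix(matrix(rnorm(tt * q), tt, q), tr_s, band)
  apply(x, 2L, standardize)
}

#' Write a complete synthetic multi-subject dataset to disk
#'
#' Emits the atlas (NIfTI + YAML sidecar), per-subject streamlines (VTK),
#' per-subject BOLD runs (NIfTI 4D + motion TSV + mask) and the simulation
#' parameters (YAML) into a directory.
#'
#' @param dir output directory (created if needed).
#' @param n_subjects_structural,n_subjects_functional cohort sizes
#'   (defaults 8 and 10).
#' @param seed RNG seed.
#' @param atlas_spec,streamline_spec,bold_spec simulation specifications.
#' @return `dir`, invisibly.
#' @export
simulate_dataset <- function(dir, n_subjects_structural = 8L,
                             n_subjects_functional = 10L, seed = 1L,
                             atlas_spec = stnconn::atlas_spec(),
                             streamline_spec = stnconn::streamline_spec(),
                             bold_spec = stnconn::bold_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- make_toy_atlas(atlas_spec, seed)
  save_label_volume(atlas, file.path(dir, "atlas.nii.gz"))
  for (i in seq_len(n_subjects_structural)) {
    for (side in c("stn_left", "stn_right")) {
      s <- simulate_streamlines(atlas, streamline_spec,
                                seed = seed + 97L * i + (side == "stn_left"),
                                stn = side, subject_id = sprintf("sub%02d", i))
      save_streamlines(s, file.path(dir, sprintf("sub%02d_%s.vtk", i, side)))
    }
  }
  bspec <- bold_spec
  bspec$n_subjects <- as.integer(n_subjects_functional)
  runs <- simulate_bold(atlas, bspec, seed)
  for (i in seq_along(runs))
    save_bold_run(runs[[i]], file.path(dir, sprintf("sub%02d_bold.nii.gz", i)))
  yaml::write_yaml(list(seed = seed,
                        atlas = unclass(atlas_spec),
                        streamlines = unclass(streamline_spec),
                        bold = unclass(bold_spec)),
                   file.path(dir, "simulation.yaml"))
  invisible(dir)
}
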