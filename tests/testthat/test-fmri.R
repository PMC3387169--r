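# compact BOLD run: V voxels on a tiny grid, supplied as a T x V signal
# matrix laid out over the first voxels of the grid
tiny_run <- function(sig, dims = NULL, tr_s = 2.2, motion = NULL) {
  tt <- nrow(sig); V <- ncol(sig)
  if (is.null(dims)) dims <- c(V, 1L, 1L)
  arr <- array(0, c(dims, tt))
  flat <- matrix(arr, ncol = tt)
  flat[seq_len(V), ] <- t(sig)
  mask <- array(FALSE, dims); mask[seq_len(V)] <- TRUE
  if (is.null(motion)) motion <- matrix(0, tt, 6)
  bold_run(array(flat, c(dims, tt)), tr_s = tr_s, motion = motion,
           brain_mask = mask)
}

test_that("standardize centers, scales, and is idempotent", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z)
  set.seed(1)
  x <- rnorm(50, 5, 3)
  expect_equal(standardize(x), (x - mean(x)) / sd(x))
  expect_error(standardize(rep(2, 10)), "constant")
})

test_that("preprocessing drops volumes, detrends, and bandpasses", {
  tt <- 120
  ramp <- outer(seq_len(tt), c(1, -2))  # pure linear trends
  run <- tiny_run(ramp, tr_s = 2.2,
                  motion = matrix(rnorm(tt * 6), tt, 6))
  out <- preprocess_bold(run, n_drop = 5)
  expect_equal(dim(out$data)[4], tt - 5L)
  expect_equal(nrow(out$motion), tt - 5L)
  expect_identical(out$motion, run$motion[6:tt, ])
  sig <- matrix(out$data, ncol = tt - 5L)[1:2, ]
  expect_lt(max(abs(sig)), 1e-8)      # ramps vanish entirely
  expect_error(preprocess_bold(run, n_drop = 5, band = c(0.01, 0.5)),
               "band")
  expect_error(preprocess_bold(run, n_drop = 101), "few timepoints")
})

test_that("the bandpass attenuates out-of-band sinusoids", {
  tr <- 2.2; tt <- 200
  tsec <- seq_len(tt) * tr
  run <- tiny_run(cbind(sin(2 * pi * 0.2 * tsec), sin(2 * pi * 0.04 * tsec)),
                  tr_s = tr)
  out <- preprocess_bold(run, n_drop = 0, band = c(0.01, 0.08))
  sig <- matrix(out$data, ncol = tt)[1:2, ]
  mid <- 50:150
  att_stop <- 20 * log10(sd(sig[1, mid]) / sd(sin(2 * pi * 0.2 * tsec)[mid]))
  att_pass <- 20 * log10(sd(sig[2, mid]) / sd(sin(2 * pi * 0.04 * tsec)[mid]))
  expect_lt(att_stop, -20)            # 0.2 Hz crushed by >= 20 dB
  expect_gt(att_pass, -1)             # 0.04 Hz essentially untouched
})

test_that("a noise-free target equal to the seed recovers beta = 1", {
  set.seed(2)
  tt <- 60
  u <- standardize(rnorm(tt))
  sig <- cbind(u, u, u, matrix(rnorm(tt * 5), tt, 5))  # seed 2x, echo, noise
  run <- tiny_run(sig, dims = c(8, 1, 1))
  seed_mask <- array(FALSE, c(8, 1, 1)); seed_mask[1:2] <- TRUE
  b <- seed_regression(run, seed_mask)
  expect_equal(b[3, 1, 1], 1, tolerance = 1e-10)
  expect_true(all(is.na(b[1:2, 1, 1])))   # seed voxels excluded from the map
})

test_that("beta is invariant to affine rescaling of raw signals", {
  set.seed(3)
  tt <- 80
  sig <- matrix(rnorm(tt * 6), tt, 6)
  run1 <- tiny_run(sig)
  run2 <- tiny_run(sweep(sig, 2, c(3, 10, 1, 1, 1, 1), "*") + 7)
  m <- array(FALSE, c(6, 1, 1)); m[1] <- TRUE
  conf <- confound_matrix(run1, global = FALSE, motion = FALSE)
  b1 <- seed_regression(run1, m, confounds = conf)
  b2 <- seed_regression(run2, m, confounds = conf)
  expect_equal(as.vector(b1), as.vector(b2), tolerance = 1e-10)
})

test_that("confounds orthogonal to seed and target leave beta unchanged", {
  set.seed(4)
  tt <- 100
  sig <- matrix(rnorm(tt * 4), tt, 4)
  run <- tiny_run(sig)
  m <- array(FALSE, c(4, 1, 1)); m[1] <- TRUE
  base <- confound_matrix(run, global = FALSE, motion = FALSE)
  conf <- rnorm(tt)
  conf <- resid(lm(conf ~ sig))        # orthogonal to everything
  b0 <- seed_regression(run, m, confounds = base)
  b1 <- seed_regression(run, m, confounds = cbind(base, orth = conf))
  expect_lt(max(abs(b0 - b1), na.rm = TRUE), 1e-8)
})

test_that("rank-deficient designs are reported with the offending column", {
  set.seed(5)
  tt <- 50
  run <- tiny_run(matrix(rnorm(tt * 3), tt, 3))
  m <- array(FALSE, c(3, 1, 1)); m[1] <- TRUE
  base <- confound_matrix(run, global = FALSE, motion = FALSE)
  dup <- cbind(base, bad = 2 * base[, "offset"])
  expect_error(seed_regression(run, m, confounds = dup),
               "collinear")
})

test_that("null regressions have beta near zero with variance ~ 1/T", {
  set.seed(6)
  tt <- 150; V <- 200
  run <- tiny_run(matrix(rnorm(tt * (V + 1)), tt, V + 1),
                  dims = c(V + 1, 1, 1))
  m <- array(FALSE, c(V + 1, 1, 1)); m[1] <- TRUE
  b <- seed_regression(run, m,
                       confounds = confound_matrix(run, global = FALSE,
                                                   motion = FALSE))
  bs <- b[!is.na(b)]
  expect_lt(abs(mean(bs)), 3 / sqrt(tt * V))  # mean of V betas, sd ~ T^-1/2
  expect_equal(var(bs), 1 / tt, tolerance = 0.3)
})

test_that("reverse regression separates orthogonal motor/limbic latents", {
  set.seed(7)
  tt <- 120
  q <- qr.Q(qr(matrix(rnorm(tt * 2), tt, 2)))
  um <- standardize(q[, 1]); ul <- standardize(q[, 2])
  # voxels: motor ROI (2), limbic ROI (2), STN copies motor latent (2), noise
  sig <- cbind(um, um, ul, ul, um, um, matrix(rnorm(tt * 4), tt, 4))
  dims <- c(10, 1, 1)
  run <- tiny_run(sig, dims = dims)
  msk <- function(idx) { a <- array(FALSE, dims); a[idx] <- TRUE; a }
  rr <- reverse_regression(run, msk(5:6), msk(1:2), msk(3:4),
                           confounds = confound_matrix(run, global = FALSE,
                                                       motion = FALSE))
  expect_equal(rr$motor[5, 1, 1], 1, tolerance = 1e-8)
  expect_equal(rr$limbic[5, 1, 1], 0, tolerance = 1e-8)
  expect_true(all(is.na(rr$motor[7:10])))
  expect_error(reverse_regression(run, msk(1), msk(1:2), msk(3:4)),
               "overlap")
})

test_that("gradient_index follows its sign and degeneracy contract", {
  vm <- stnconn:::voxel_map(cbind(0:9, 0, 0), seq(0.1, 1, 0.1), c(1, 1, 1))
  expect_equal(gradient_index(vm, axis = "x"), 1)
  vm2 <- stnconn:::voxel_map(cbind(0:9, 0, 0), -seq(0.1, 1, 0.1), c(1, 1, 1))
  expect_equal(gradient_index(vm2, axis = 1L), -1)
  # two-sided lateral distance via the midline argument
  vm3 <- stnconn:::voxel_map(cbind(c(0:4, 6:10), 0, 0),
                             c(5:1, 1:5) / 5, c(1, 1, 1))
  expect_equal(gradient_index(vm3, axis = "x", midline = 5), 1)
  expect_error(gradient_index(stnconn:::voxel_map(cbind(0:4, 0, 0),
                                                  rep(1, 5), c(1, 1, 1)),
                              "x"), "constant")
  expect_error(gradient_index(stnconn:::voxel_map(cbind(0:1, 0, 0),
                                                  1:2, c(1, 1, 1)), "x"),
               "3 voxels")
})

test_that("a map independent of the axis has a null-centered index", {
  set.seed(8)
  idx <- replicate(300, {
    vm <- stnconn:::voxel_map(cbind(0:19, 0, 0), rnorm(20), c(1, 1, 1))
    gradient_index(vm, "x")
  })
  expect_lt(abs(mean(idx)), 0.05)
  expect_equal(sd(idx), 1 / sqrt(19), tolerance = 0.25)
})
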