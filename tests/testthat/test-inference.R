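test_that("fisher_z is arctanh with a guarded domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_identical(fisher_z(0.5), atanh(0.5))
  b <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-b), -fisher_z(b))
  expect_error(fisher_z(1), "\\|b\\| < 1")
  expect_warning(bc <- clip_beta(c(0.3, 1, -1)), "clipped")
  expect_equal(attr(bc, "n_clipped"), 2L)
  expect_true(all(abs(bc) < 1))
})

test_that("group t-tests flag degenerate voxels and match closed form", {
  dims <- c(5, 5, 5)
  mask <- array(TRUE, dims)
  same <- array(0.4, dims)
  st <- group_ttest(list(same, same, same), mask)
  expect_length(st$flagged, prod(dims))   # all identical: zero variance
  expect_true(all(st$z[mask] == 0))
  expect_equal(st$df, 2L)
  # N(0.3, 0.1^2), n = 10: E[t] ~ 0.3 / (0.1/sqrt(10)) = 9.49
  set.seed(21)
  maps <- lapply(1:10, function(i) array(rnorm(prod(dims), 0.3, 0.1), dims))
  st2 <- group_ttest(maps, mask)
  M <- vapply(maps, function(m) m[mask], numeric(prod(dims)))
  tref <- apply(M, 1, function(x) t.test(x)$statistic)
  zexp <- sign(tref) * qnorm(pt(abs(tref), 9, lower.tail = FALSE),
                             lower.tail = FALSE)
  expect_equal(st2$z[mask], unname(zexp), tolerance = 1e-10)
  expect_equal(mean(tref), 0.3 / (0.1 / sqrt(10)), tolerance = 0.15)
  expect_error(group_ttest(maps[1], mask), "2 subjects")
})

test_that("the critical cluster size obeys its limits and monotonicities", {
  mask <- array(TRUE, c(32, 32, 32))
  expect_equal(rft_critical_cluster_size(3, 1 - 1e-9, 2, mask), 1L)
  k <- vapply(c(2.3, 2.6, 3.1, 3.5), function(u)
    rft_critical_cluster_size(u, 0.05, 2, mask), 1L)
  expect_true(all(diff(k) <= 0))           # non-increasing in u
  ka <- vapply(c(0.01, 0.05, 0.2), function(a)
    rft_critical_cluster_size(2.3, a, 2, mask), 1L)
  expect_true(all(diff(ka) <= 0))          # non-increasing in alpha
  kv <- vapply(c(16, 24, 32), function(n)
    rft_critical_cluster_size(2.3, 0.05, 2, array(TRUE, rep(n, 3))), 1L)
  expect_true(all(diff(kv) >= 0))          # non-decreasing in search volume
  expect_error(rft_critical_cluster_size(0.5, 0.05, 2, mask), "exceed 1")
  expect_error(rft_critical_cluster_size(2.3, 0.05, 8, array(TRUE, c(4, 4, 4))),
               "resel")
  expect_error(rft_critical_cluster_size(2.3, 0.05, 0.5, mask), "FWHM")
})

test_that("cluster extraction thresholds extent and separates signs", {
  z <- array(0, c(12, 12, 12))
  z[3:7, 3:6, 3] <- 5                     # 20-voxel positive blob
  cl <- extract_clusters(z, u = 2.3, k_crit = 14)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$extent, 20L)
  expect_equal(cl[[1]]$sign, 1)
  expect_equal(cl[[1]]$peak_z, 5)
  expect_length(extract_clusters(z, 2.3, k_crit = 25), 0L)
  # adjacent blobs of opposite sign are never merged
  z2 <- array(0, c(12, 12, 12))
  z2[3:6, 3:6, 3] <- 4
  z2[7:10, 3:6, 3] <- -4
  cl2 <- extract_clusters(z2, 2.3, 10)
  expect_length(cl2, 2L)
  expect_setequal(vapply(cl2, function(c) c$sign, 1), c(1, -1))
  expect_true(all(vapply(cl2, function(c) c$extent, 1L) == 16L))
})

test_that("negating the map swaps positive and negative clusters exactly", {
  set.seed(31)
  z <- smooth_volume(array(rnorm(16^3), c(16, 16, 16)), 2) * 30
  cp <- extract_clusters(z, 2.3, 3)
  cn <- extract_clusters(-z, 2.3, 3)
  expect_equal(length(cp), length(cn))
  keyof <- function(cl) paste(sort(apply(cl$voxels, 1, paste, collapse = ",")),
                              collapse = ";")
  expect_setequal(
    vapply(cp, function(c) paste(c$sign, keyof(c)), ""),
    vapply(cn, function(c) paste(-c$sign, keyof(c)), ""))
})

test_that("connected components match a brute-force flood fill", {
  set.seed(32)
  for (conn in c(6L, 26L)) {
    for (rep in 1:5) {
      mask <- array(runif(10^3) < 0.25, c(10, 10, 10))
      got <- stnconn:::.label_components_cpp(mask, dim(mask), conn)
      ref <- oracle_components(mask, conn)
      # same partition (label ids may differ)
      expect_equal(max(got), max(ref))
      key <- paste(got[mask], ref[mask])
      expect_equal(length(unique(key)), max(ref))
    }
  }
})

test_that("cluster reports carry atlas labels, peaks and hemispheres", {
  v <- make_toy_atlas()
  z <- array(0, dim(v$data))
  thal <- which(v$data == 3L, arr.ind = TRUE)
  z[thal] <- 6                             # blob exactly on the thalamus
  cl <- extract_clusters(z, 2.3, 5)
  rep1 <- label_clusters(cl, v)
  expect_s3_class(rep1, "cluster_report")
  expect_true("Thalamus" %in% rep1$region)
  expect_equal(sum(rep1$n_voxels[rep1$cluster == 1]), cl[[1]]$extent)
  # cluster straddling two labels reports both with counts summing to extent
  z2 <- array(0, dim(v$data))
  z2[21:24, 15:18, 27:28] <- 4             # spans BA4 R and BA6 R
  cl2 <- extract_clusters(z2, 2.3, 5)
  rep2 <- label_clusters(cl2, v)
  expect_setequal(rep2$region,
                  c("Primary Motor Cortex (BA4) R",
                    "Premotor and Supplementary Motor Area (BA6) R"))
  expect_equal(sum(rep2$n_voxels), cl2[[1]]$extent)
  expect_true(all(rep2$hemisphere == "right"))
  # background-only cluster
  z3 <- array(0, dim(v$data)); z3[1, 1:6, 1] <- 9
  rep3 <- label_clusters(extract_clusters(z3, 2.3, 3), v)
  expect_equal(rep3$region, "unlabeled")
  expect_equal(rep3$hemisphere, "left")
})

test_that("the analysis mask drops white matter and CSF", {
  v <- make_toy_atlas()
  m <- analysis_mask(v)
  expect_false(any(m[v$data == 24L]))
  expect_false(any(m[v$data == 25L]))
  expect_true(all(m[v$data == 3L]))
  expect_false(any(m[v$data == 0L]))
})

test_that("cluster_inference wires the full group pipeline together", {
  set.seed(33)
  dims <- c(16, 16, 16)
  mask <- array(TRUE, dims)
  effect <- array(0, dims); effect[6:11, 6:11, 6:11] <- 0.5
  maps <- lapply(1:8, function(i)
    effect + smooth_volume(array(rnorm(prod(dims), sd = 1), dims), 2) * 0.1)
  res <- cluster_inference(maps, mask, u = 2.3, alpha = 0.05, fwhm_mm = 2,
                           voxel_size_mm = c(1, 1, 1))
  expect_gt(length(res$clusters), 0L)
  expect_true(any(vapply(res$clusters, function(cl)
    cl$sign > 0 && cl$extent >= res$k_crit, TRUE)))
})
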