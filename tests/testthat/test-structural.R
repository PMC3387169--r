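# straight line along +x starting at x0 (mm), entering the target block
# (x in [10,14) mm) at arc 10-x0
xline <- function(x0, y = 3, z = 3) rbind(c(x0, y, z), c(15.9, y, z))

test_that("the worked connectivity example evaluates to C = 2", {
  v <- hand_target_volume()  # 4-voxel target, x in [10,14) mm
  # two hitting streamlines with l = 10 mm and 6 mm, n_stn = 2:
  # C = (10 + 6) / (2 * 4) = 2
  s <- streamline_set(list(xline(0), xline(4)), matrix(0L, 2, 3))
  rec <- connectivity_measure(s, v, 1L, n_stn = 2L)
  expect_equal(rec$n_t, 2L)
  expect_equal(sort(rec$lengths), c(6, 10))
  expect_equal(rec$C, 2)
})

test_that("C is zero iff no streamline reaches the target", {
  v <- hand_target_volume()
  miss <- streamline_set(list(rbind(c(0, 10, 10), c(4, 10, 10))),
                         matrix(0L, 1, 3))
  rec <- connectivity_measure(miss, v, 1L, n_stn = 1L)
  expect_equal(rec$n_t, 0L)
  expect_equal(rec$C, 0)
  expect_error(connectivity_measure(miss, v, 99L), "absent")
})

test_that("re-entering the target counts once, at the first entry", {
  v <- hand_target_volume()
  # enters the target, leaves through y, comes back
  inout <- rbind(c(0, 3, 3), c(11, 3, 3), c(11, 9, 3), c(13, 9, 3),
                 c(13, 3, 3))
  s <- streamline_set(list(inout), matrix(0L, 1, 3))
  rec <- connectivity_measure(s, v, 1L, n_stn = 1L)
  expect_equal(rec$n_t, 1L)
  expect_equal(rec$lengths, 10)
})

test_that("padding the target with unreachable voxels rescales C exactly", {
  v <- hand_target_volume()
  s <- streamline_set(list(xline(0), xline(4)), matrix(0L, 2, 3))
  C4 <- connectivity_measure(s, v, 1L, n_stn = 2L)$C
  v2 <- v
  v2$data[1:4, 8, 8] <- 1L  # 4 extra target voxels no streamline can reach
  C8 <- connectivity_measure(s, v2, 1L, n_stn = 2L)$C
  expect_equal(C8, C4 * 4 / 8)
})

test_that("C is invariant to streamline order and chunking", {
  set.seed(33)
  v <- rand_atlas()
  s <- rand_streamline_set(v, 24L)
  rec <- connectivity_measure(s, v, 1L, n_stn = 3L)
  perm <- sample(24L)
  s_perm <- subset_streamlines(s, perm)
  expect_equal(connectivity_measure(s_perm, v, 1L, n_stn = 3L)$C, rec$C)
  # split into chunks, sum the length sums
  parts <- split(seq_len(24L), rep(1:3, each = 8L))
  lens <- unlist(lapply(parts, function(idx)
    connectivity_measure(subset_streamlines(s, idx), v, 1L, n_stn = 3L)$lengths))
  expect_equal(sum(lens) / (3 * rec$n_roi), rec$C)
})

test_that("non-hitting streamlines are inert; hitting ones add to C", {
  v <- hand_target_volume()
  hit <- xline(0); miss <- rbind(c(0, 10, 10), c(4, 10, 10))
  s2 <- streamline_set(list(hit, miss), matrix(0L, 2, 3))
  s1 <- streamline_set(list(hit), matrix(0L, 1, 3))
  expect_equal(connectivity_measure(s2, v, 1L, n_stn = 1L)$C,
               connectivity_measure(s1, v, 1L, n_stn = 1L)$C)
  s3 <- streamline_set(list(hit, hit), matrix(0L, 2, 3))
  expect_gt(connectivity_measure(s3, v, 1L, n_stn = 1L)$C,
            connectivity_measure(s1, v, 1L, n_stn = 1L)$C)
})

test_that("count weighting and boundary-origin lengths are available", {
  v <- hand_target_volume()
  s <- streamline_set(list(xline(0), xline(4)), matrix(0L, 2, 3))
  rec <- connectivity_measure(s, v, 1L, n_stn = 2L, length_weight = "count")
  expect_equal(rec$C, 2 / (2 * 4))
  # with an STN label en route, l is measured from the STN exit
  v2 <- hand_target_volume()
  v2$data[2, 2, 2] <- 3L   # STN voxel: x in [2,4) mm
  v2$names <- c("1" = "target", "3" = "STN R")
  v2$groups <- list(stn_right = 3L)
  sE <- streamline_set(list(xline(0, y = 3, z = 3)), matrix(0L, 1, 3))
  recE <- connectivity_measure(sE, v2, 1L, n_stn = 1L,
                               length_origin = "stn_exit")
  expect_equal(recE$lengths, 10 - 4)  # target entry at 10, STN exit at 4
})

test_that("connectivity_measure matches the brute-force oracle", {
  set.seed(44)
  for (rep in 1:20) {
    v <- rand_atlas()
    s <- rand_streamline_set(v, sample(5:20, 1L))
    n_stn <- sample(1:5, 1L)
    got <- connectivity_measure(s, v, 1L, n_stn = n_stn)
    ref <- oracle_connectivity(s, v, 1L, n_stn)
    expect_equal(got$n_t, ref$n_t)
    if (ref$C > 0) expect_lt(abs(got$C - ref$C) / ref$C, 1e-9)
    else expect_equal(got$C, 0)
  }
})

test_that("group tables aggregate per-subject C with one-sided t-tests", {
  v <- hand_target_volume()
  mk <- function(x0s) list(
    streamlines = streamline_set(lapply(x0s, xline),
                                 matrix(0L, length(x0s), 3)),
    atlas = v, n_stn = 2L)
  subjects <- lapply(list(c(0, 4), c(1, 5), c(2, 3), c(0, 2)), mk)
  tab <- connectivity_table(subjects, targets = 1L)
  expect_s3_class(tab, "connectivity_table")
  expect_equal(nrow(tab), 1L)
  expect_lt(tab$p, 0.001)
  expect_false(tab$degenerate)
  expect_error(connectivity_table(subjects[1], 1L), "2 subjects")
})

test_that("degenerate group tables are handled explicitly", {
  v <- hand_target_volume()
  miss <- function() list(
    streamlines = streamline_set(list(rbind(c(0, 10, 10), c(4, 10, 10))),
                                 matrix(0L, 1, 3)),
    atlas = v, n_stn = 1L)
  subjects <- replicate(8, miss(), simplify = FALSE)
  tab <- connectivity_table(subjects, targets = 1L)
  expect_equal(tab$p, 1)           # all-zero C: no evidence
  hitter <- function() list(
    streamlines = streamline_set(list(xline(0)), matrix(0L, 1, 3)),
    atlas = v, n_stn = 1L)
  tab2 <- connectivity_table(replicate(4, hitter(), simplify = FALSE), 1L)
  expect_equal(tab2$p, 0)          # zero variance, positive mean
  expect_true(tab2$degenerate)
})

test_that("eight subjects with strong C give p below 0.001", {
  # closed-form check on the one-sided one-sample t machinery
  set.seed(55)
  stat <- stnconn:::one_sided_onesample_t(rnorm(8, mean = 1, sd = 0.1))
  expect_lt(stat[2], 0.001)
  expect_equal(stat[2], pt(stat[1], df = 7, lower.tail = FALSE))
})

test_that("per-voxel maps separate connected from unconnected seed voxels", {
  v <- hand_target_volume()
  v$data[2, 2, 2] <- 3L  # seed voxel A
  v$data[2, 6, 2] <- 3L  # seed voxel B
  v$names <- c("1" = "target", "3" = "STN R")
  v$groups <- list(stn_right = 3L)
  sA <- lapply(1:3, function(i) xline(0, y = 3, z = 3))      # hit from A
  sB <- lapply(1:3, function(i) rbind(c(0, 11, 3), c(6, 11, 3)))  # miss from B
  s <- streamline_set(c(sA, sB),
                      rbind(matrix(rep(c(1L, 1L, 1L), 3), 3, byrow = TRUE),
                            matrix(rep(c(1L, 5L, 1L), 3), 3, byrow = TRUE)),
                      n_per_seed = 3L)
  m <- per_voxel_connectivity(s, v, 1L)
  a <- m$value[m$i == 1 & m$j == 1]
  b <- m$value[m$i == 1 & m$j == 5]
  expect_gt(a, 0)
  expect_equal(b, 0)
  # map over a declared seed group fills silent voxels with zero
  v$data[2, 7, 2] <- 3L
  expect_message(m2 <- per_voxel_connectivity(s, v, 1L, seed_group = "stn_right"),
                 "no streamlines")
  expect_equal(nrow(m2), 3L)
  expect_equal(m2$value[m2$j == 6], 0)
})

test_that("accumulated maps are voxelwise sums, max-normalized", {
  vm <- function(vals) stnconn:::voxel_map(cbind(0:1, 0, 0), vals, c(1, 1, 1))
  acc <- accumulate_maps(list(vm(c(1, 3)), vm(c(2, 1))), normalize = TRUE)
  expect_equal(sort(acc$value), c(3 / 4, 1))
  acc2 <- accumulate_maps(list(vm(c(1, 3)), vm(c(2, 1))), normalize = FALSE)
  expect_equal(sort(acc2$value), c(3, 4))
})
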