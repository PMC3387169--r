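# Independent brute-force oracles and random fixture generators.
#
# The traversal oracles never share code with the package's analytic voxel
# walk: they rely only on dense sampling along the polyline plus bisection
# on point-membership tests, with voxel lookup done by plain floor division.

# ---- geometry helpers -------------------------------------------------------

# cumulative arc lengths at polyline vertices
vertex_arcs <- function(line) {
  c(0, cumsum(sqrt(rowSums(diff(line)^2))))
}

# points at arc positions s (vectorized)
point_at <- function(line, s) {
  arcs <- vertex_arcs(line)
  cbind(approx(arcs, line[, 1], xout = s)$y,
        approx(arcs, line[, 2], xout = s)$y,
        approx(arcs, line[, 3], xout = s)$y)
}

# voxel indices by plain floor division; NA outside grid
floor_voxel <- function(p, vs, dims) {
  p <- matrix(p, ncol = 3L)
  idx <- floor(sweep(p, 2L, vs, "/"))
  bad <- idx[, 1] < 0 | idx[, 1] >= dims[1] |
         idx[, 2] < 0 | idx[, 2] >= dims[2] |
         idx[, 3] < 0 | idx[, 3] >= dims[3]
  idx[bad, ] <- NA
  idx
}

oracle_label_at <- function(p, v) {
  idx <- floor_voxel(p, v$voxel_size_mm, dim(v$data))
  out <- integer(nrow(idx))
  ok <- !is.na(idx[, 1])
  out[ok] <- v$data[idx[ok, , drop = FALSE] + 1L]
  out
}

# dense sample arcs: fixed step plus the exact vertex arcs
dense_arcs <- function(line, step = 0.01) {
  arcs <- vertex_arcs(line)
  total <- arcs[length(arcs)]
  sort(unique(c(arcs, seq(0, total, by = step), total)))
}

# Arc of first entry into the region where `inside(point)` is TRUE,
# localized by dense sampling and refined by bisection; NA if never inside.
oracle_first_entry <- function(line, inside, step = 0.01, iters = 60L) {
  s <- dense_arcs(line, step)
  hit <- inside(point_at(line, s))
  first <- which(hit)[1]
  if (is.na(first)) return(NA_real_)
  if (first == 1L) return(0)
  lo <- s[first - 1L]; hi <- s[first]
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (inside(point_at(line, mid))) hi <- mid else lo <- mid
  }
  hi
}

# first-entry arc into the set of voxels carrying any of `ids`
oracle_region_entry <- function(line, v, ids, step = 0.01) {
  oracle_first_entry(line, function(p) oracle_label_at(p, v) %in% ids, step)
}

# Brute-force connectivity measure: per streamline, region-level first-entry
# arc (dense sampling + bisection), summed over hitting streamlines.
oracle_connectivity <- function(s, v, ids, n_stn, step = 0.01) {
  n_roi <- sum(v$data %in% ids)
  lens <- vapply(s$streamlines, function(m)
    oracle_region_entry(m, v, ids, step), 1)
  lens <- lens[!is.na(lens)]
  list(C = sum(lens) / (n_stn * n_roi), n_t = length(lens), lengths = lens)
}

# Ordered distinct labels with first-entry arcs, via per-label region entry.
oracle_label_sequence <- function(line, v, step = 0.01) {
  labs <- unique(oracle_label_at(point_at(line, dense_arcs(line, step)), v))
  labs <- labs[labs != 0L]
  if (!length(labs)) return(data.frame(label = integer(), arc = numeric()))
  arcs <- vapply(labs, function(id) oracle_region_entry(line, v, id, step), 1)
  o <- order(arcs)
  data.frame(label = labs[o], arc = arcs[o])
}

# Dense-sampled traversal: voxel visit runs (consecutive duplicates
# collapsed, out-of-grid dropped) with entry arcs refined by bisection.
oracle_traversal <- function(line, v, step = 0.01) {
  s <- dense_arcs(line, step)
  vox <- floor_voxel(point_at(line, s), v$voxel_size_mm, dim(v$data))
  key <- ifelse(is.na(vox[, 1]), NA, paste(vox[, 1], vox[, 2], vox[, 3]))
  r <- rle(ifelse(is.na(key), "<out>", key))
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  keep <- r$values != "<out>"
  # drop runs that repeat the previous kept voxel (out-of-grid interruptions
  # never happen inside the grid, so this is a no-op in practice)
  out <- NULL
  for (q in which(keep)) {
    first <- starts[q]
    trip <- as.integer(strsplit(r$values[q], " ")[[1]])
    if (first == 1L) {
      arc <- 0
    } else {
      lo <- s[first - 1L]; hi <- s[first]
      inside <- function(p) {
        fv <- floor_voxel(p, v$voxel_size_mm, dim(v$data))
        !is.na(fv[1, 1]) && all(fv[1, ] == trip)
      }
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (inside(point_at(line, mid))) hi <- mid else lo <- mid
      }
      arc <- hi
    }
    out <- rbind(out, c(trip, arc))
  }
  if (is.null(out)) out <- matrix(numeric(), ncol = 4L)
  colnames(out) <- c("i", "j", "k", "arc")
  out
}

# Brute-force hyperdirect filter: double loop over streamlines and labels.
oracle_hyperdirect <- function(s, v, motor, relay, step = 0.01) {
  ends <- vapply(s$streamlines, function(m) {
    p <- m[nrow(m), , drop = FALSE]
    oracle_label_at(p, v)
  }, 1L)
  ending <- which(ends %in% motor)
  direct <- ending[vapply(ending, function(q) {
    labs <- oracle_label_at(point_at(s$streamlines[[q]],
                                     dense_arcs(s$streamlines[[q]], step)), v)
    !any(labs %in% relay)
  }, TRUE)]
  list(kept = direct, n_ending_motor = length(ending),
       n_direct = length(direct),
       fraction_direct = length(direct) / length(ending))
}

# Brute-force 3D connected components (BFS over an adjacency stencil).
oracle_components <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nn <- rowSums(abs(offs))
  offs <- offs[nn > 0 & nn <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, dims)
  comp <- 0L
  todo <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(todo))) {
    start <- todo[r, ]
    if (lab[start[1], start[2], start[3]] != 0L) next
    comp <- comp + 1L
    queue <- matrix(start, ncol = 3L)
    lab[start[1], start[2], start[3]] <- comp
    while (nrow(queue)) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2L, cur, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      for (w in seq_len(nrow(nb))) {
        if (mask[nb[w, 1], nb[w, 2], nb[w, 3]] &&
            lab[nb[w, 1], nb[w, 2], nb[w, 3]] == 0L) {
          lab[nb[w, 1], nb[w, 2], nb[w, 3]] <- comp
          queue <- rbind(queue, nb[w, , drop = FALSE])
        }
      }
    }
  }
  lab
}

# ---- random fixtures --------------------------------------------------------

# random toy atlas: a grid up to 20^3 with a handful of random non-overlapping
# boxes; label 1 is the designated target, labels 2.. fill the rest
rand_atlas <- function(n_labels = 4L, max_dim = 20L) {
  dims <- sample(8:max_dim, 3L, replace = TRUE)
  vs <- round(runif(3, 0.8, 2.5), 2)
  arr <- array(0L, dims)
  placed <- 0L
  guard <- 0L
  while (placed < n_labels && guard < 200L) {
    guard <- guard + 1L
    sz <- sample(2:4, 3L, replace = TRUE)
    lo <- c(sample.int(dims[1] - sz[1], 1L), sample.int(dims[2] - sz[2], 1L),
            sample.int(dims[3] - sz[3], 1L))
    sub <- arr[lo[1]:(lo[1] + sz[1] - 1L), lo[2]:(lo[2] + sz[2] - 1L),
               lo[3]:(lo[3] + sz[3] - 1L)]
    if (any(sub != 0L)) next
    placed <- placed + 1L
    arr[lo[1]:(lo[1] + sz[1] - 1L), lo[2]:(lo[2] + sz[2] - 1L),
        lo[3]:(lo[3] + sz[3] - 1L)] <- placed
  }
  label_volume(arr, vs,
               names = setNames(paste0("region", seq_len(placed)),
                                seq_len(placed)))
}

# random polyline of a few segments inside (and occasionally outside) the grid
rand_polyline <- function(v, n_vertices = 4L, allow_outside = FALSE) {
  ext <- dim(v$data) * v$voxel_size_mm
  pad <- if (allow_outside) 0.2 * ext else rep(0, 3)
  m <- cbind(runif(n_vertices, -pad[1], ext[1] + pad[1]),
             runif(n_vertices, -pad[2], ext[2] + pad[2]),
             runif(n_vertices, -pad[3], ext[3] + pad[3]))
  m
}

rand_streamline_set <- function(v, n_lines = 20L, allow_outside = FALSE) {
  lines <- replicate(n_lines,
                     rand_polyline(v, sample(2:5, 1L), allow_outside),
                     simplify = FALSE)
  streamline_set(lines, matrix(0L, n_lines, 3L))
}

# small hand-built volume: one target block of 4 voxels in an 8^3 grid of
# 2 mm voxels (target spans x voxels 5-6, y 1-2, z 1)
hand_target_volume <- function() {
  arr <- array(0L, c(8, 8, 8))
  arr[6:7, 2:3, 2] <- 1L
  label_volume(arr, c(2, 2, 2), names = c("1" = "target"))
}
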