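#' Length-weighted streamline-count connectivity to one target region
#'
#' For a single subject, counts the streamlines that pass through or end in
#' the target region (each streamline at most once, at its first visit) and
#' sums the arc length from the streamline's seed end to its first entry
#' into the target. The connectivity measure is
#' \deqn{C = \frac{\sum_i l_i}{N_{STN} \cdot N_{ROI}}}{C = sum(l_i) / (N_STN * N_ROI)}
#' where \eqn{l_i} is that arc length in mm, \eqn{N_{STN}} the seed-region
#' size in voxels and \eqn{N_{ROI}} the target size in voxels. Length
#' weighting compensates the drop in streamline counts with distance from
#' the seed; with `length_weight = "count"` the raw normalized count
#' \eqn{N_t/(N_{STN} N_{ROI})} is returned instead.
#'
#' @param s a [streamline_set()].
#' @param v a [label_volume()].
#' @param target integer label id, or a vector of ids treated as one union
#'   region (first entry into any member counts, once per streamline).
#' @param n_stn seed-region size in voxels (\eqn{N_{STN}}); defaults to the
#'   number of voxels carrying an STN label in `v`.
#' @param length_weight `"linear"` (sum of arc lengths, the default) or
#'   `"count"` (plain streamline count).
#' @param length_origin where \eqn{l_i} starts: `"seed"` (streamline start,
#'   the default) or `"stn_exit"` (the exit from the last STN-labelled voxel
#'   visited before the target, falling back to the streamline start when the
#'   line never touches an STN voxel).
#' @return An object of class `connectivity_record`: list with `target`,
#'   `n_t` (hit count), `lengths` (per hitting streamline, mm), `C`,
#'   `n_stn`, `n_roi`.
#' @export
connectivity_measure <- function(s, v, target, n_stn = NULL,
                                 length_weight = c("linear", "count"),
                                 length_origin = c("seed", "stn_exit")) {
  stopifnot(inherits(s, "streamline_set"), inherits(v, "label_volume"))
  length_weight <- match.arg(length_weight)
  length_origin <- match.arg(length_origin)
  target <- as.integer(target)
  n_roi <- sum(v$data %in% target)
  if (n_roi == 0L)
    stop("target region absent from the label volume (N_ROI = 0)")
  if (is.null(n_stn))
    n_stn <- sum(v$data %in% c(v$groups$stn_left, v$groups$stn_right))
  if (n_stn < 1L) stop("`n_stn` must be >= 1")

  seqs <- label_sequences(s, v)
  lens <- hit_lengths(seqs, target,
                      stn_ids = c(v$groups$stn_left, v$groups$stn_right),
                      length_origin = length_origin,
                      s = s, v = v)
  n_t <- length(lens)
  C <- if (length_weight == "linear") sum(lens) / (n_stn * n_roi)
       else n_t / (n_stn * n_roi)
  lens <- as.numeric(lens)
  structure(list(target = target, n_t = n_t, lengths = lens, C = C,
                 n_stn = as.integer(n_stn), n_roi = as.integer(n_roi),
                 length_weight = length_weight),
            class = "connectivity_record")
}

#' @export
print.connectivity_record <- function(x, ...) {
  cat(sprintf("<connectivity_record> target %s: N_t = %d, C = %.6g (N_STN = %d, N_ROI = %d)\n",
              paste(x$target, collapse = "+"), x$n_t, x$C, x$n_stn, x$n_roi))
  invisible(x)
}

# First-entry arc lengths into the target union, one per hitting streamline.
hit_lengths <- function(seqs, target, stn_ids, length_origin, s, v) {
  out <- numeric(0)
  hit_idx <- integer(0)
  for (q in seq_along(seqs)) {
    m <- seqs[[q]]
    rows <- which(m[, 1] %in% target)
    if (!length(rows)) next
    arc <- min(m[rows, 2])
    if (length_origin == "stn_exit") {
      vt <- .walk_polyline_cpp(s$streamlines[[q]], v$voxel_size_mm, dim(v$data))
      labs <- label_at(v, vt[, 1:3, drop = FALSE])
      in_stn <- which(labs %in% stn_ids & vt[, 4] < arc)
      if (length(in_stn)) {
        last <- max(in_stn)
        # exit arc of that visit = entry arc of the following voxel
        arc <- arc - (if (last < nrow(vt)) vt[last + 1L, 4] else vt[last, 4])
      }
    }
    out <- c(out, unname(arc))
    hit_idx <- c(hit_idx, q)
  }
  attr(out, "hit_index") <- hit_idx
  out
}

#' Group connectivity table with one-sided t-tests
#'
#' Computes the connectivity measure per subject for each target region and
#' tests, per target, whether the mean of C over subjects exceeds zero with a
#' one-sided one-sample Student t-test (df = n - 1). No multiple-testing
#' correction is applied across targets. Degenerate cases: all-zero C gives
#' p = 1 (no evidence); zero variance with a positive mean gives p = 0 and is
#' flagged.
#'
#' @param subjects list of per-subject lists with elements `streamlines`
#'   (a [streamline_set()]), `atlas` (a [label_volume()]) and optionally
#'   `n_stn` (defaults to the subject's atlas STN size).
#' @param targets integer vector of target label ids.
#' @param ... passed to [connectivity_measure()] (`length_weight`,
#'   `length_origin`).
#' @return A data frame of class `connectivity_table`, sorted by p-value,
#'   with columns `target`, `region`, `mean_C`, `t`, `p`, `degenerate`, and
#'   per-subject columns `C_<id>` and `N_<id>`.
#' @export
connectivity_table <- function(subjects, targets, ...) {
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  n <- length(subjects)
  ids <- vapply(subjects, function(su) su$streamlines$subject_id, "")
  if (anyDuplicated(ids)) ids <- paste0(ids, "_", seq_len(n))
  Cmat <- matrix(0, nrow = length(targets), ncol = n)
  Nmat <- matrix(0L, nrow = length(targets), ncol = n)
  for (j in seq_len(n)) {
    su <- subjects[[j]]
    for (i in seq_along(targets)) {
      rec <- connectivity_measure(su$streamlines, su$atlas, targets[i],
                                  n_stn = su$n_stn, ...)
      Cmat[i, j] <- rec$C
      Nmat[i, j] <- rec$n_t
    }
  }
  stat <- t(apply(Cmat, 1L, one_sided_onesample_t))
  out <- data.frame(
    target = as.integer(targets),
    region = label_name(subjects[[1]]$atlas, targets),
    mean_C = rowMeans(Cmat),
    t = stat[, 1], p = stat[, 2], degenerate = stat[, 3] > 0)
  colnames(Cmat) <- paste0("C_", ids)
  colnames(Nmat) <- paste0("N_", ids)
  out <- cbind(out, Cmat, Nmat)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("connectivity_table", "data.frame")
  out
}

# returns c(t, p, degenerate) for H1: mean > 0
one_sided_onesample_t <- function(x) {
  n <- length(x)
  m <- mean(x)
  sdev <- sd(x)
  if (sdev == 0) {
    if (m == 0) return(c(NA_real_, 1, 0))
    return(c(Inf, 0, 1))
  }
  tval <- m / (sdev / sqrt(n))
  c(tval, pt(tval, df = n - 1, lower.tail = FALSE), 0)
}

#' Per-seed-voxel connectivity map
#'
#' Computes the connectivity measure separately for the streamlines launched
#' from each seed voxel (with \eqn{N_{STN} = 1}), against the union of a
#' group of target labels. This exposes the spatial topography of the seed
#' nucleus, e.g. the mediolateral gradient of STN motor connectivity. Maps
#' from multiple subjects can be summed and max-normalized with
#' [accumulate_maps()].
#'
#' @param s a [streamline_set()] with per-streamline seed-voxel attribution.
#' @param v a [label_volume()].
#' @param target_group integer label ids treated as one union target, or a
#'   group name in `v$groups`.
#' @param seed_group optional group name (e.g. `"stn_right"`) whose voxels
#'   define the map support; voxels without streamlines get value 0. By
#'   default the map covers the seed voxels present in `s`.
#' @param ... passed to [connectivity_measure()].
#' @return A `voxel_map`: data frame with columns `i`, `j`, `k` (0-based
#'   voxel indices) and `value`, with the voxel size as attribute
#'   `voxel_size_mm`.
#' @export
per_voxel_connectivity <- function(s, v, target_group, seed_group = NULL, ...) {
  stopifnot(inherits(s, "streamline_set"), inherits(v, "label_volume"))
  if (is.character(target_group)) target_group <- group_ids(v, target_group)
  key <- paste(s$seed_voxel[, 1], s$seed_voxel[, 2], s$seed_voxel[, 3])
  if (is.null(seed_group)) {
    vox <- unique(s$seed_voxel)
  } else {
    idx <- which(array(v$data %in% group_ids(v, seed_group), dim(v$data)),
                 arr.ind = TRUE)
    vox <- unname(as.matrix(idx)) - 1L
  }
  vkey <- paste(vox[, 1], vox[, 2], vox[, 3])
  val <- numeric(nrow(vox))
  missing <- 0L
  for (q in seq_len(nrow(vox))) {
    sel <- which(key == vkey[q])
    if (!length(sel)) { missing <- missing + 1L; next }
    sub <- streamline_set(s$streamlines[sel],
                          s$seed_voxel[sel, , drop = FALSE],
                          subject_id = s$subject_id,
                          n_per_seed = s$n_per_seed)
    val[q] <- connectivity_measure(sub, v, target_group, n_stn = 1L, ...)$C
  }
  if (missing > 0L)
    message(sprintf("per_voxel_connectivity: %d seed voxel(s) with no streamlines (value 0)",
                    missing))
  voxel_map(vox, val, v$voxel_size_mm)
}

voxel_map <- function(vox, value, voxel_size_mm) {
  out <- data.frame(i = as.integer(vox[, 1]), j = as.integer(vox[, 2]),
                    k = as.integer(vox[, 3]), value = as.numeric(value))
  attr(out, "voxel_size_mm") <- voxel_size_mm
  class(out) <- c("voxel_map", "data.frame")
  out
}

#' Sum per-voxel maps across subjects and max-normalize
#'
#' @param maps list of `voxel_map` data frames (from
#'   [per_voxel_connectivity()] or [reverse_regression()]).
#' @param normalize divide by the maximum absolute value so the cumulated
#'   map lies in `[-1, 1]` (default `TRUE`).
#' @return A `voxel_map` over the union of voxels.
#' @export
accumulate_maps <- function(maps, normalize = TRUE) {
  stopifnot(length(maps) >= 1L)
  all <- do.call(rbind, lapply(maps, function(m) as.data.frame(m)[c("i", "j", "k", "value")]))
  agg <- aggregate(value ~ i + j + k, data = all, FUN = sum)
  if (normalize && any(agg$value != 0))
    agg$value <- agg$value / max(abs(agg$value))
  voxel_map(as.matrix(agg[c("i", "j", "k")]), agg$value,
            attr(maps[[1]], "voxel_size_mm"))
}

#' Write a voxel map into the atlas grid as NIfTI
#'
#' @param map a `voxel_map`.
#' @param v the [label_volume()] defining the grid.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_voxel_map <- function(map, v, path) {
  arr <- array(0, dim(v$data))
  arr[as.matrix(map[c("i", "j", "k")]) + 1L] <- map$value
  write_volume(arr, path, v$voxel_size_mm)
}
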