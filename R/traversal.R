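#' Voxels traversed by a polyline
#'
#' Walks a polyline through the voxel grid of a label volume and returns
#' every traversed voxel in order, together with the cumulative arc length
#' (mm, measured along the polyline) at which the voxel is first entered.
#' Crossing arcs are computed analytically from the axis-plane intersections
#' of each segment, so no traversed voxel is skipped and entry arcs are exact
#' (no sampling step is involved). Consecutive duplicate voxels are
#' collapsed; points outside the grid are dropped while the arc length keeps
#' accumulating, so the traversal continues when the polyline re-enters.
#'
#' @param line n-by-3 numeric matrix of polyline points (mm), n >= 2.
#' @param v a [label_volume()] defining the grid.
#' @return Data frame with columns `i`, `j`, `k` (0-based voxel indices) and
#'   `arc` (mm at first entry of that visit; 0 for the voxel containing the
#'   start point).
#' @export
voxels_traversed <- function(line, v) {
  stopifnot(inherits(v, "label_volume"))
  line <- as.matrix(line)
  if (nrow(line) < 2L) stop("polyline must have at least 2 points")
  m <- .walk_polyline_cpp(line, v$voxel_size_mm, dim(v$data))
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
             k = as.integer(m[, 3]), arc = m[, 4])
}

#' First-visit label sequence of a polyline
#'
#' Looks up the atlas label of every voxel traversed by the streamline and
#' reduces the result to the ordered list of distinct non-background labels,
#' each with the arc length at its first entry. A region that is re-entered
#' later therefore counts only once, at its first visit.
#'
#' @inheritParams voxels_traversed
#' @return Data frame with columns `label` (integer id) and `arc` (mm at
#'   first entry).
#' @export
label_sequence <- function(line, v) {
  stopifnot(inherits(v, "label_volume"))
  line <- as.matrix(line)
  if (nrow(line) < 2L) stop("polyline must have at least 2 points")
  m <- .label_walk_cpp(list(line), v$voxel_size_mm, dim(v$data), v$data)[[1]]
  data.frame(label = as.integer(m[, 1]), arc = m[, 2])
}

# Batched label sequences for a whole streamline set (internal fast path).
# Returns a list of matrices with columns (label, arc).
label_sequences <- function(s, v) {
  .label_walk_cpp(s$streamlines, v$voxel_size_mm, dim(v$data), v$data)
}

#' Total length of a polyline in mm
#' @param line n-by-3 matrix of points.
#' @return Numeric scalar.
#' @export
polyline_length <- function(line) {
  line <- as.matrix(line)
  if (nrow(line) < 2L) return(0)
  sum(sqrt(rowSums(diff(line)^2)))
}
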