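#' Atlas label at a streamline's endpoint
#'
#' Returns the label of the voxel containing the final point of the
#' polyline; background (0) when the endpoint is unlabelled or outside the
#' grid. "Ending in" a region is deliberately distinct from merely passing
#' through it.
#'
#' @param line n-by-3 numeric matrix (mm), n >= 2.
#' @param v a [label_volume()].
#' @return Integer label id.
#' @export
endpoint_label <- function(line, v) {
  line <- as.matrix(line)
  if (nrow(line) < 2L) stop("polyline must have at least 2 points")
  label_at(v, point_to_voxel(line[nrow(line), ], v))
}

#' Filter candidate monosynaptic (hyperdirect) streamlines
#'
#' The hyperdirect pathway is the hypothesized monosynaptic projection
#' between motor cortex and STN that bypasses the striato-pallido-thalamic
#' relays. A streamline is kept iff its endpoint lies in a motor label and
#' its full first-visit label sequence contains no relay label (thalamus,
#' caudate, putamen, external and internal globus pallidus by default).
#'
#' @param s a [streamline_set()].
#' @param v a [label_volume()].
#' @param motor integer label ids of the motor cortical areas, or a group
#'   name in `v$groups` (default `"motor"`).
#' @param relay integer label ids to be bypassed, or a group name (default
#'   `"relay"`). Must be disjoint from `motor`.
#' @param min_direct threshold on `n_direct` for `has_direct` (default 1).
#' @return An object of class `hyperdirect_result`: list with `kept`
#'   (indices of kept streamlines), `n_ending_motor`, `n_direct`,
#'   `fraction_direct` (`NaN` when no streamline ends in motor cortex) and
#'   `has_direct`.
#' @export
filter_hyperdirect <- function(s, v, motor = "motor", relay = "relay",
                               min_direct = 1L) {
  stopifnot(inherits(s, "streamline_set"), inherits(v, "label_volume"))
  if (is.character(motor)) motor <- group_ids(v, motor)
  if (is.character(relay)) relay <- group_ids(v, relay)
  if (length(intersect(motor, relay)))
    stop("motor and relay label sets must be disjoint")
  ends <- vapply(s$streamlines, function(m)
    endpoint_label(m, v), 1L)
  ending_motor <- which(ends %in% motor)
  kept <- integer(0)
  if (length(ending_motor)) {
    seqs <- label_sequences(
      streamline_set(s$streamlines[ending_motor],
                     s$seed_voxel[ending_motor, , drop = FALSE],
                     subject_id = s$subject_id, n_per_seed = s$n_per_seed), v)
    direct <- !vapply(seqs, function(m) any(m[, 1] %in% relay), TRUE)
    kept <- ending_motor[direct]
  }
  structure(list(
    kept = kept,
    n_ending_motor = length(ending_motor),
    n_direct = length(kept),
    fraction_direct = length(kept) / length(ending_motor),
    has_direct = length(kept) >= min_direct),
    class = "hyperdirect_result")
}

#' @export
print.hyperdirect_result <- function(x, ...) {
  cat(sprintf(
    "<hyperdirect_result> %d/%d motor-ending streamlines bypass all relay nuclei (%.1f%%); direct connection: %s\n",
    x$n_direct, x$n_ending_motor, 100 * x$fraction_direct,
    if (x$has_direct) "yes" else "no"))
  invisible(x)
}

#' Subset a streamline set
#'
#' @param s a [streamline_set()].
#' @param idx integer indices of streamlines to keep.
#' @return A [streamline_set()] with the selected streamlines.
#' @export
subset_streamlines <- function(s, idx) {
  streamline_set(s$streamlines[idx], s$seed_voxel[idx, , drop = FALSE],
                 subject_id = s$subject_id, n_per_seed = s$n_per_seed)
}
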