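#' Label volumes
#'
#' A `label_volume` is a 3D integer array of atlas label ids together with the
#' physical voxel size (mm), a label-id to region-name dictionary and named
#' groups of label ids (for example `"motor"`, `"limbic"`, `"relay"`,
#' `"stn_left"`, `"stn_right"`). Label 0 is reserved for background.
#'
#' @param data 3D integer array of label ids (0 = background).
#' @param voxel_size_mm numeric triple of positive voxel edge lengths in mm.
#' @param names named character vector or list mapping label id (as name) to
#'   region name, e.g. `c("1" = "STN R")`.
#' @param groups named list of integer label-id vectors. Every id must exist
#'   in `names`.
#' @return An object of class `label_volume`.
#' @seealso [load_label_volume()], [save_label_volume()], [make_toy_atlas()]
#' @export
label_volume <- function(data, voxel_size_mm, names = character(), groups = list()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(data != round(data)))
    stop("label volume must be integer-valued")
  data <- array(as.integer(data), dim(data))  # strip foreign attributes
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three positive numbers")
  names <- unlist(names)
  if (length(names)) {
    ids <- suppressWarnings(as.integer(base::names(names)))
    if (any(is.na(ids))) stop("label ids in `names` must be integers")
    if (any(ids == 0L)) stop("label id 0 is reserved for background")
  }
  v <- structure(
    list(data = data, voxel_size_mm = voxel_size_mm,
         names = as.character(names), groups = lapply(groups, as.integer)),
    class = "label_volume")
  base::names(v$names) <- if (length(names)) base::names(names) else NULL
  known <- as.integer(base::names(v$names))
  for (g in base::names(v$groups)) {
    bad <- setdiff(v$groups[[g]], known)
    if (length(bad))
      stop(sprintf("group '%s' references unknown label id(s): %s",
                   g, paste(bad, collapse = ", ")))
  }
  v
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels @ %s mm; %d labels, %d groups\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"),
              length(x$names), length(x$groups)))
  invisible(x)
}

#' Label ids of a named group
#'
#' @param v a [label_volume()].
#' @param group group name present in `v$groups`.
#' @return Integer vector of label ids.
#' @export
group_ids <- function(v, group) {
  stopifnot(inherits(v, "label_volume"))
  if (!group %in% names(v$groups))
    stop(sprintf("unknown group '%s'", group))
  v$groups[[group]]
}

#' Region name of a label id
#' @param v a [label_volume()].
#' @param id integer label id(s).
#' @return Character vector; `"unlabeled"` for background/unknown ids.
#' @export
label_name <- function(v, id) {
  out <- unname(v$names[as.character(id)])
  out[is.na(out)] <- "unlabeled"
  out
}

#' Map a point in mm to its voxel index
#'
#' Implements the shared coordinate contract: `index_k = floor(p_k / s_k)`
#' with half-open voxel intervals, so a point exactly on a boundary belongs
#' to the higher-index voxel. Returns `NA` for points outside the grid.
#'
#' @param p numeric length-3 point in mm, or an n-by-3 matrix of points.
#' @param v a [label_volume()] supplying voxel size and grid extent.
#' @return Integer 0-based voxel index triple (or n-by-3 matrix); all-`NA`
#'   rows mark out-of-grid points.
#' @export
point_to_voxel <- function(p, v) {
  stopifnot(inherits(v, "label_volume"))
  one <- is.null(dim(p))
  p <- matrix(as.numeric(p), ncol = 3L)
  idx <- floor(sweep(p, 2L, v$voxel_size_mm, "/"))
  d <- dim(v$data)
  bad <- idx[, 1] < 0 | idx[, 1] >= d[1] |
         idx[, 2] < 0 | idx[, 2] >= d[2] |
         idx[, 3] < 0 | idx[, 3] >= d[3]
  idx[bad, ] <- NA_real_
  storage.mode(idx) <- "integer"
  if (one) idx[1L, ] else idx
}

#' Label at a set of 0-based voxel indices
#' @param v a [label_volume()].
#' @param idx integer length-3 voxel index, or n-by-3 matrix (0-based).
#'   `NA` rows give label 0.
#' @return Integer label id(s).
#' @export
label_at <- function(v, idx) {
  idx <- matrix(as.integer(idx), ncol = 3L)
  out <- integer(nrow(idx))
  ok <- !is.na(idx[, 1])
  if (any(ok))
    out[ok] <- v$data[idx[ok, , drop = FALSE] + 1L]
  out
}

#' Read a label volume from NIfTI plus a YAML sidecar
#'
#' The NIfTI file must hold 3D integer data; voxel size is taken from the
#' header. The sidecar (by default the same path with extension `.yaml`)
#' supplies the label dictionary and groups:
#'
#' ```yaml
#' labels:
#'   1: STN R
#'   2: Thalamus
#' groups:
#'   relay: [Thalamus]
#'   stn_right: [1]
#' ```
#'
#' Group entries may be label ids or region names.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param config path to the YAML sidecar; defaults to `path` with the NIfTI
#'   extension replaced by `.yaml`.
#' @return A [label_volume()].
#' @export
load_label_volume <- function(path, config = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume")
  if (any(arr != round(arr)))
    stop("label volume must contain integer data")
  vs <- RNifti::pixdim(img)[1:3]
  if (is.null(config))
    config <- sidecar_path(path)
  names <- character(); groups <- list()
  if (file.exists(config)) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$labels)) {
      names <- vapply(cfg$labels, as.character, "")
    }
    if (!is.null(cfg$groups)) {
      id_of <- function(x) {
        if (is.numeric(x) || grepl("^[0-9]+$", x)) return(as.integer(x))
        hit <- names(names)[names == as.character(x)]
        if (!length(hit))
          stop(sprintf("group entry '%s' matches no label name or id", x))
        as.integer(hit[1L])
      }
      groups <- lapply(cfg$groups, function(g) vapply(g, id_of, 1L))
    }
  }
  label_volume(arr, vs, names = names, groups = groups)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".yaml", path)
}

#' Write a label volume to NIfTI plus a YAML sidecar
#'
#' @param v a [label_volume()].
#' @param path output `.nii`/`.nii.gz` path; the sidecar is written next to
#'   it with extension `.yaml`.
#' @return `path`, invisibly.
#' @export
save_label_volume <- function(v, path) {
  stopifnot(inherits(v, "label_volume"))
  write_volume(v$data, path, v$voxel_size_mm, datatype = "int32")
  cfg <- list(
    labels = as.list(setNames(as.list(v$names), names(v$names))),
    groups = lapply(v$groups, as.integer))
  yaml::write_yaml(cfg, sidecar_path(path))
  invisible(path)
}

# Shared NIfTI writer honouring the corner-origin coordinate contract.
write_volume <- function(arr, path, voxel_size_mm, datatype = "auto") {
  img <- RNifti::asNifti(unclass(arr), internal = FALSE)
  pd <- RNifti::pixdim(img)
  n <- min(length(pd), length(voxel_size_mm))
  pd[seq_len(n)] <- voxel_size_mm[seq_len(n)]
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
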