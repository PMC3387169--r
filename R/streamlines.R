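#' Streamline sets
#'
#' A `streamline_set` holds tractography polylines in mm coordinates, the
#' 0-based seed-voxel index triple each streamline was launched from, the
#' subject id, and the number of streamlines launched per seed voxel. The
#' first point of each polyline is its seed end.
#'
#' @param streamlines list of n-by-3 numeric matrices (n >= 2), mm.
#' @param seed_voxel integer matrix with one row per streamline, columns
#'   (i, j, k), 0-based.
#' @param subject_id character scalar.
#' @param n_per_seed streamlines launched per seed voxel (>= 1).
#' @return An object of class `streamline_set`.
#' @seealso [load_streamlines()], [save_streamlines()],
#'   [simulate_streamlines()]
#' @export
streamline_set <- function(streamlines, seed_voxel, subject_id = "s1",
                           n_per_seed = 1L) {
  streamlines <- lapply(streamlines, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each streamline must be an n-by-3 matrix")
    if (nrow(m) < 2L) stop("each streamline needs at least 2 points")
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  seed_voxel <- matrix(as.integer(seed_voxel), ncol = 3L)
  if (nrow(seed_voxel) != length(streamlines))
    stop("`seed_voxel` must have one row per streamline")
  if (n_per_seed < 1L) stop("`n_per_seed` must be >= 1")
  structure(
    list(streamlines = streamlines, seed_voxel = seed_voxel,
         subject_id = as.character(subject_id),
         n_per_seed = as.integer(n_per_seed)),
    class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, 1L)
  cat(sprintf(
    "<streamline_set> subject %s: %d streamlines (%s points each), %d per seed voxel\n",
    x$subject_id, length(x$streamlines),
    if (length(npts)) paste0(min(npts), "-", max(npts)) else "0",
    x$n_per_seed))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Check that every streamline is seeded inside an STN voxel
#'
#' @param s a [streamline_set()].
#' @param v a [label_volume()] whose groups include `stn_left`/`stn_right`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_streamlines <- function(s, v) {
  stn <- c(v$groups$stn_left, v$groups$stn_right)
  if (!length(stn)) stop("atlas has no STN groups")
  labs <- label_at(v, s$seed_voxel)
  if (!all(labs %in% stn))
    stop("some seed voxels do not carry an STN label")
  invisible(TRUE)
}

#' Write streamlines as VTK legacy polydata
#'
#' Writes an ASCII VTK legacy file with `POINTS`, `LINES` and per-line
#' `CELL_DATA` (the 0-based seed-voxel triple as a 3-component integer
#' scalar). The title line carries the subject id and `n_per_seed` so a
#' round trip preserves them. An empty set produces a valid file with
#' `LINES 0 0`.
#'
#' @param s a [streamline_set()].
#' @param path output file path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
save_streamlines <- function(s, path) {
  stopifnot(inherits(s, "streamline_set"))
  con <- file(path, "w")
  on.exit(close(con))
  nl <- length(s$streamlines)
  npts <- vapply(s$streamlines, nrow, 1L)
  total <- sum(npts)
  writeLines(c(
    "# vtk DataFile Version 3.0",
    sprintf("stnconn streamlines subject=%s n_per_seed=%d",
            s$subject_id, s$n_per_seed),
    "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d float", total)), con)
  if (total > 0) {
    pts <- do.call(rbind, s$streamlines)
    writeLines(paste(format(pts[, 1], trim = TRUE, digits = 17),
                     format(pts[, 2], trim = TRUE, digits = 17),
                     format(pts[, 3], trim = TRUE, digits = 17)), con)
  }
  writeLines(sprintf("LINES %d %d", nl, nl + total), con)
  if (nl > 0) {
    offs <- cumsum(c(0L, npts[-nl]))
    conn <- vapply(seq_len(nl), function(i)
      paste(c(npts[i], seq.int(offs[i], length.out = npts[i])),
            collapse = " "), "")
    writeLines(conn, con)
    writeLines(c(
      sprintf("CELL_DATA %d", nl),
      "SCALARS seed_voxel int 3",
      "LOOKUP_TABLE default"), con)
    writeLines(paste(s$seed_voxel[, 1], s$seed_voxel[, 2], s$seed_voxel[, 3]),
               con)
  }
  invisible(path)
}

#' Read streamlines from VTK legacy polydata
#'
#' Accepts ASCII or binary legacy VTK polydata with `POINTS` and `LINES`
#' sections; per-line seed-voxel attribution is read from `CELL_DATA`
#' (3-component integer scalar named `seed_voxel`) when present, else set to
#' zeros. Point order is preserved (first point = seed end).
#'
#' @param path path to a `.vtk` file.
#' @return A [streamline_set()].
#' @export
load_streamlines <- function(path) {
  hdr <- readLines(path, n = 3L, warn = FALSE)
  if (length(hdr) < 3L || !grepl("^# vtk DataFile", hdr[1]))
    stop("not a VTK legacy file: ", path)
  fmt <- toupper(trimws(hdr[3]))
  if (fmt == "ASCII") load_vtk_ascii(path, hdr[2])
  else if (fmt == "BINARY") load_vtk_binary(path, hdr[2])
  else stop("unknown VTK data format: ", fmt)
}

parse_vtk_title <- function(title) {
  subj <- sub(".*subject=(\\S+).*", "\\1", title)
  nps <- sub(".*n_per_seed=([0-9]+).*", "\\1", title)
  list(subject_id = if (subj == title) "s1" else subj,
       n_per_seed = if (nps == title) 1L else as.integer(nps))
}

assemble_streamlines <- function(pts, conn_tokens, nl, seed, meta) {
  lines <- vector("list", nl)
  pos <- 1L
  for (i in seq_len(nl)) {
    np <- conn_tokens[pos]
    idx <- conn_tokens[(pos + 1L):(pos + np)]
    if (any(idx < 0L) || any(idx >= nrow(pts)))
      stop("LINES section references an out-of-range point index")
    lines[[i]] <- pts[idx + 1L, , drop = FALSE]
    pos <- pos + np + 1L
  }
  if (is.null(seed)) seed <- matrix(0L, nrow = nl, ncol = 3L)
  streamline_set(lines, seed, subject_id = meta$subject_id,
                 n_per_seed = meta$n_per_seed)
}

load_vtk_ascii <- function(path, title) {
  txt <- readLines(path, warn = FALSE)
  meta <- parse_vtk_title(title)
  ip <- grep("^POINTS\\s", txt)
  if (!length(ip)) stop("VTK file has no POINTS section")
  npts <- as.integer(strsplit(trimws(txt[ip[1]]), "\\s+")[[1]][2])
  il <- grep("^LINES\\s", txt)
  if (!length(il)) stop("VTK file has no LINES section")
  lhead <- as.integer(strsplit(trimws(txt[il[1]]), "\\s+")[[1]][2:3])
  nl <- lhead[1]

  read_nums <- function(start, n) {
    # scan n whitespace-separated numbers beginning at line `start`
    if (n == 0) return(numeric(0))
    vals <- scan(path, what = double(), skip = start - 1L, n = n,
                 quiet = TRUE)
    if (length(vals) < n) stop("truncated VTK section")
    vals
  }
  pts <- matrix(read_nums(ip[1] + 1L, npts * 3L), ncol = 3L, byrow = TRUE)
  conn <- as.integer(read_nums(il[1] + 1L, lhead[2]))

  seed <- NULL
  ic <- grep("^CELL_DATA\\s", txt)
  if (length(ic)) {
    isv <- grep("^SCALARS\\s+seed_voxel\\s", txt)
    if (length(isv)) {
      skip <- if (grepl("^LOOKUP_TABLE", txt[isv[1] + 1L])) 2L else 1L
      seed <- matrix(as.integer(read_nums(isv[1] + skip, nl * 3L)),
                     ncol = 3L, byrow = TRUE)
    }
  }
  assemble_streamlines(pts, conn, nl, seed, meta)
}

load_vtk_binary <- function(path, title) {
  meta <- parse_vtk_title(title)
  raw <- readBin(path, "raw", file.size(path))
  nlpos <- which(raw == as.raw(10L))
  line_at <- function(i) {
    # text of the i-th newline-terminated line
    from <- if (i == 1L) 1L else nlpos[i - 1L] + 1L
    rawToChar(raw[from:(nlpos[i] - 1L)])
  }
  # scan line-structured header pieces interleaved with binary payloads
  find_line <- function(pattern, after = 0L) {
    for (i in seq_along(nlpos)) {
      if (nlpos[i] <= after) next
      txt <- tryCatch(line_at(i), error = function(e) "")
      if (grepl(pattern, txt)) return(i)
    }
    NA_integer_
  }
  ip <- find_line("^POINTS\\s")
  if (is.na(ip)) stop("VTK file has no POINTS section")
  npts <- as.integer(strsplit(trimws(line_at(ip)), "\\s+")[[1]][2])
  ptype <- strsplit(trimws(line_at(ip)), "\\s+")[[1]][3]
  psize <- if (ptype %in% c("double")) 8L else 4L
  pstart <- nlpos[ip] + 1L
  pts <- readBin(raw[pstart:(pstart + 3L * npts * psize - 1L)],
                 "double", n = 3L * npts, size = psize, endian = "big")
  pts <- matrix(pts, ncol = 3L, byrow = TRUE)
  il <- find_line("^LINES\\s", after = pstart + 3L * npts * psize - 1L)
  if (is.na(il)) stop("VTK file has no LINES section")
  lhead <- as.integer(strsplit(trimws(line_at(il)), "\\s+")[[1]][2:3])
  nl <- lhead[1]
  lstart <- nlpos[il] + 1L
  conn <- readBin(raw[lstart:(lstart + 4L * lhead[2] - 1L)],
                  "integer", n = lhead[2], size = 4L, endian = "big")
  seed <- NULL
  isv <- find_line("^SCALARS\\s+seed_voxel\\s",
                   after = lstart + 4L * lhead[2] - 1L)
  if (!is.na(isv)) {
    ilt <- find_line("^LOOKUP_TABLE", after = nlpos[isv] - 1L)
    sstart <- nlpos[if (is.na(ilt)) isv else ilt] + 1L
    seed <- matrix(readBin(raw[sstart:(sstart + 4L * nl * 3L - 1L)],
                           "integer", n = nl * 3L, size = 4L, endian = "big"),
                   ncol = 3L, byrow = TRUE)
  }
  assemble_streamlines(pts, conn, nl, seed, meta)
}
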