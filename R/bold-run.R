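#' BOLD runs
#'
#' A `bold_run` couples a 4D BOLD array (x, y, z, t) with its repetition time
#' (s), the per-timepoint motion-parameter table (T rows, 6 columns: 3
#' translations in mm, 3 rotations in rad) and a 3D brain mask.
#'
#' @param data 4D numeric array.
#' @param tr_s repetition time in seconds.
#' @param motion T-by-6 numeric matrix/data frame; row count must equal the
#'   number of timepoints.
#' @param brain_mask 3D logical array matching the spatial dimensions.
#' @param subject_id character scalar.
#' @param voxel_size_mm numeric triple, mm.
#' @return An object of class `bold_run`.
#' @seealso [preprocess_bold()], [simulate_bold()]
#' @export
bold_run <- function(data, tr_s, motion, brain_mask, subject_id = "s1",
                     voxel_size_mm = c(1, 1, 1)) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4D array")
  tt <- dim(data)[4]
  motion <- as.matrix(motion)
  if (nrow(motion) != tt)
    stop("motion table must have one row per timepoint")
  if (ncol(motion) != 6L)
    stop("motion table must have 6 columns")
  if (!identical(dim(brain_mask), dim(data)[1:3]))
    stop("brain mask shape must equal the spatial shape")
  structure(
    list(data = data, tr_s = as.numeric(tr_s),
         motion = unname(motion),
         brain_mask = array(as.logical(brain_mask), dim(brain_mask)),
         subject_id = as.character(subject_id),
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bold_run> subject %s: %dx%dx%d voxels, %d timepoints, TR %.3f s, %d in mask\n",
    x$subject_id, d[1], d[2], d[3], d[4], x$tr_s, sum(x$brain_mask)))
  invisible(x)
}

#' Write a BOLD run (NIfTI 4D + motion TSV + mask NIfTI)
#'
#' @param run a [bold_run()].
#' @param path output `.nii`/`.nii.gz` path; the motion table goes to the
#'   same stem with suffix `_motion.tsv` and the mask to `_mask.nii.gz`.
#' @return `path`, invisibly.
#' @export
save_bold_run <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  write_volume(run$data, path, c(run$voxel_size_mm, run$tr_s))
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  mot <- as.data.frame(run$motion)
  names(mot) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad")
  write.table(mot, paste0(stem, "_motion.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_volume(run$brain_mask + 0L, paste0(stem, "_mask.nii.gz"),
               run$voxel_size_mm, datatype = "int32")
  invisible(path)
}

#' Read a BOLD run written by [save_bold_run()]
#'
#' @param path the 4D `.nii`/`.nii.gz` path.
#' @param subject_id subject identifier to attach.
#' @return A [bold_run()].
#' @export
load_bold_run <- function(path, subject_id = "s1") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("expected a 4D NIfTI volume")
  pd <- RNifti::pixdim(img)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  mot <- as.matrix(read.table(paste0(stem, "_motion.tsv"), header = TRUE,
                              sep = "\t"))
  mask <- as.array(RNifti::readNifti(paste0(stem, "_mask.nii.gz"))) > 0
  bold_run(arr, tr_s = pd[4], motion = mot, brain_mask = mask,
           subject_id = subject_id, voxel_size_mm = pd[1:3])
}
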