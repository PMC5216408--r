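#' Read a NIfTI-1 volume
#'
#' Reads a 3D or 4D NIfTI-1 file into a [volume4d()]. A 3D image (e.g. a mask)
#' is promoted to a single-frame 4D volume; use [read_mask()] for a logical 3D
#' mask. The TR is taken from the 4th pixdim slot when present.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `volume4d`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  a <- array(as.double(a), dim(a))   # drop image-header attributes
  pd <- RNifti::pixdim(img)
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 4L)
    stop("malformed NIfTI: field 'dim' is not 3D or 4D in ", path)
  if (any(pd[1:3] <= 0))
    stop("malformed NIfTI: field 'pixdim' has non-positive spacing in ", path)
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  volume4d(a, voxel_size = pd[1:3], tr = tr,
           affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Write a volume as NIfTI-1
#'
#' @param vol A `volume4d`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$voxel_size, vol$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D mask as a logical array
#'
#' @param path Path to a 3D NIfTI-1 file; nonzero voxels are in-mask.
#' @return Logical 3D array.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  array(v$data[, , , 1] != 0, grid_dims(v))
}

#' Write a logical 3D mask as NIfTI-1
#' @param mask Logical 3D array.
#' @param path Output path.
#' @param voxel_size Voxel sizes in mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, voxel_size = c(3, 3, 3)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a rigid-body motion trace
#'
#' Motion files are whitespace-delimited text with 6 columns (3 translations
#' in mm, 3 rotations in radians), one row per volume.
#'
#' @param path File path.
#' @return `read_motion`: a [motion_trace()].
#' @export
read_motion <- function(path, tr = 2) {
  m <- as.matrix(utils::read.table(path))
  motion_trace(m, tr = tr)
}

#' @rdname read_motion
#' @param motion A [motion_trace()].
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(motion$params, digits = 10), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a UTF-8 TSV with columns `subject_id`, `diagnosis` (ASD/TC),
#' `age_years`, `gender` (0/1), `fiq`, `ados_comm`, `ados_social`,
#' `ados_stereo` (ADOS cells empty for TC) and optionally `cohort` and
#' `mean_fd`. If `cohort` is absent it is derived from age with the
#' child (<11), adolescent (11 to <18), adult (>=18 years) cut-points.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame`, one row per subject.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("subject_id", "diagnosis", "age_years", "gender", "fiq")
  missing <- setdiff(required, names(ph))
  if (length(missing))
    stop("phenotype table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(ph$subject_id))
    stop("duplicated subject_id in phenotype table")
  if (!is.numeric(ph$age_years) || anyNA(ph$age_years))
    stop("unparseable age_years in phenotype table")
  if (is.null(ph$cohort)) ph$cohort <- age_to_cohort(ph$age_years)
  ph$diagnosis <- factor(ph$diagnosis, levels = c("ASD", "TC"))
  ph$cohort <- factor(ph$cohort, levels = c("child", "adolescent", "adult"))
  if (anyNA(ph$diagnosis)) stop("diagnosis must be ASD or TC")
  for (col in c("ados_comm", "ados_social", "ados_stereo"))
    if (is.null(ph[[col]])) ph[[col]] <- NA_real_
  ph
}

#' @rdname read_phenotypes
#' @param phenotypes A phenotype `data.frame`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Age-cohort assignment
#'
#' Child below 11 years, adolescent from 11 to below 18, adult from 18 years.
#' @param age Numeric ages in years.
#' @return Factor with levels child, adolescent, adult.
#' @export
age_to_cohort <- function(age) {
  cut(age, breaks = c(-Inf, 11, 18, Inf), right = FALSE,
      labels = c("child", "adolescent", "adult"))
}
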