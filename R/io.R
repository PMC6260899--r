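# File-level I/O: DWI volumes with FSL-style bval/bvec tables, label maps,
# and tabular output.

#' Read FSL-style bval/bvec files
#'
#' The FSL dialect stores b-values as one whitespace-separated row and
#' gradient directions as three rows (x, y, z), one column per volume.
#' `dialect = "column"` accepts the transposed layout (one volume per row).
#'
#' @param path_bval,path_bvec paths to the text files.
#' @param dialect `"fsl"` (default) or `"column"`.
#' @return an [acq_scheme()].
#' @export
read_bval_bvec <- function(path_bval, path_bvec, dialect = c("fsl", "column")) {
  dialect <- match.arg(dialect)
  bvalues <- scan(path_bval, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(path_bvec))
  if (dialect == "fsl") {
    if (nrow(bvec) != 3L) {
      stop("FSL bvec must have 3 rows, got ", nrow(bvec),
           " (use dialect = \"column\" for one-volume-per-row files)")
    }
    bvec <- t(bvec)
  } else if (ncol(bvec) != 3L) {
    stop("column-dialect bvec must have 3 columns, got ", ncol(bvec))
  }
  if (length(bvalues) != nrow(bvec)) {
    stop("bval/bvec length mismatch: ", length(bvalues), " b-values vs ",
         nrow(bvec), " directions")
  }
  acq_scheme(bvalues, bvec)
}

#' Write FSL-style bval/bvec files
#'
#' @param scheme an [acq_scheme()].
#' @param path_bval,path_bvec output paths.
#' @return invisibly, the two paths.
#' @export
write_bval_bvec <- function(scheme, path_bval, path_bvec) {
  writeLines(paste(format(scheme$bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), path_bval)
  rows <- apply(t(scheme$directions), 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(rows, path_bvec)
  invisible(c(path_bval, path_bvec))
}

#' Read a 4D DWI dataset
#'
#' @param path_nifti 4D NIfTI volume.
#' @param path_bval,path_bvec FSL-style b-value/direction tables.
#' @param dialect bvec dialect, see [read_bval_bvec()].
#' @return list with `volume` (4D array), `scheme` ([acq_scheme()]),
#'   `pixdim` and `affine`.
#' @export
read_dwi <- function(path_nifti, path_bval, path_bvec, dialect = "fsl") {
  nii <- read_nifti(path_nifti)
  if (length(dim(nii$data)) != 4L) {
    stop("DWI volume must be 4D, got ", length(dim(nii$data)), "D: ", path_nifti)
  }
  scheme <- read_bval_bvec(path_bval, path_bvec, dialect)
  nvol <- dim(nii$data)[4]
  if (length(scheme) != nvol) {
    stop("dimension mismatch: NIfTI has ", nvol, " volumes but scheme has ",
         length(scheme), " entries")
  }
  list(volume = nii$data, scheme = scheme,
       pixdim = nii$pixdim, affine = nii$affine)
}

#' Write a 4D DWI dataset
#'
#' Writes the volume as NIfTI-1 (float64, so that [read_dwi()] inverts it
#' bit-exactly) plus FSL bval/bvec files derived from the base path:
#' `<base>.nii[.gz]`, `<base>.bval`, `<base>.bvec`.
#'
#' @param volume 4D numeric array.
#' @param scheme matching [acq_scheme()].
#' @param base_path output path; `.nii` appended when no NIfTI suffix given.
#' @param pixdim voxel size in mm.
#' @return list of the three written paths.
#' @export
write_dwi <- function(volume, scheme, base_path, pixdim = c(3, 3, 3)) {
  if (length(dim(volume)) != 4L) stop("volume must be 4D")
  if (dim(volume)[4] != length(scheme)) {
    stop("dimension mismatch: volume has ", dim(volume)[4],
         " volumes but scheme has ", length(scheme), " entries")
  }
  if (grepl("\\.nii(\\.gz)?$", base_path)) {
    nii_path <- base_path
    stem <- sub("\\.nii(\\.gz)?$", "", base_path)
  } else {
    nii_path <- paste0(base_path, ".nii")
    stem <- base_path
  }
  write_nifti(volume, nii_path, pixdim = pixdim, datatype = "float64")
  write_bval_bvec(scheme, paste0(stem, ".bval"), paste0(stem, ".bvec"))
  list(nifti = nii_path, bval = paste0(stem, ".bval"),
       bvec = paste0(stem, ".bvec"))
}

#' Labeled volume (ROI / segmentation map)
#'
#' @param voxels 3D integer array; 0 is background.
#' @param labels named list or vector mapping label id (as character) to
#'   tissue name; every nonzero label present in `voxels` must appear.
#' @param pixdim voxel size in mm.
#' @return list of class `labeled_volume`.
#' @export
labeled_volume <- function(voxels, labels, pixdim = c(3, 3, 3)) {
  if (length(dim(voxels)) != 3L) stop("label map must be 3D")
  if (max(abs(voxels - round(voxels))) > 0) stop("labels must be integers")
  present <- setdiff(sort(unique(as.vector(voxels))), 0)
  labels <- unlist(labels)
  missing <- setdiff(as.character(present), names(labels))
  if (length(missing)) {
    stop("labels present in map but absent from dictionary: ",
         paste(missing, collapse = ", "))
  }
  structure(list(voxels = voxels, labels = labels, pixdim = pixdim),
            class = "labeled_volume")
}

#' Write an ROI summary or statistics table
#'
#' Writes a delimited text table. For `roi_summary` objects a wide layout is
#' used: one row per region, and per parameter both the human-readable
#' `"mean (sd)"` string and machine-readable `<param>_mean`, `<param>_sd`,
#' `<param>_n` columns at full precision.
#'
#' @param x an `roi_summary` data frame (from [roi_summary()]) or any data
#'   frame (written as-is).
#' @param path output path; `.csv` selects comma separation, anything else
#'   tab separation.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (is.data.frame(x) && nrow(x) == 0L) stop("refusing to write an empty table")
  if (inherits(x, "roi_summary")) x <- roi_summary_wide(x)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(format_table_precise(x), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_table_precise <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- formatC(df[[j]], format = "g", digits = 17)
    }
  }
  df
}

#' Read a table written by [write_table()]
#'
#' @param path path to the `.csv`/`.tsv` file.
#' @return data frame with numeric columns restored.
#' @export
read_table_file <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

# Wide Table-2-shaped layout of a long roi_summary.
roi_summary_wide <- function(s) {
  regions <- unique(s$region)
  params <- unique(s$parameter)
  out <- data.frame(region = regions, stringsAsFactors = FALSE)
  for (p in params) {
    sub <- s[s$parameter == p, ]
    idx <- match(regions, sub$region)
    out[[paste0(p, "_mean_sd")]] <-
      sprintf("%.3g (%.3g)", sub$mean[idx], sub$sd[idx])
    out[[paste0(p, "_mean")]] <- sub$mean[idx]
    out[[paste0(p, "_sd")]] <- sub$sd[idx]
    out[[paste0(p, "_n")]] <- sub$n[idx]
  }
  out
}
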