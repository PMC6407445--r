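# File export/import: NIfTI label and field volumes (via RNifti), a
# label -> conductivity sidecar table, and legacy-ASCII VTK structured
# points for the potential field (written directly; the format is a short
# documented header plus point data).

#' Write / read a tissue model as NIfTI + conductivity sidecar
#'
#' The label grid is written as an integer NIfTI volume with the voxel size
#' in `pixdim`; the conductivity table goes to `<path>.cond.tsv` with
#' columns `label`, `code`, `sigma_S_per_m`.
#'
#' @param tissue an `sns_tissue`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_tissue_nifti()` returns `path` invisibly;
#'   `read_tissue_nifti()` returns an `sns_tissue`.
#' @export
write_tissue_nifti <- function(tissue, path) {
  img <- RNifti::asNifti(tissue$labels + 0L)
  RNifti::pixdim(img) <- tissue$voxel_mm
  RNifti::writeNifti(img, path)
  codes <- tissue_labels()
  nm <- names(tissue$conductivity)
  side <- data.frame(label = nm,
                     code = as.integer(codes[nm]),
                     sigma_S_per_m = as.numeric(tissue$conductivity))
  write.table(side, paste0(path, ".cond.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tissue_nifti
#' @export
read_tissue_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  side <- read.delim(paste0(path, ".cond.tsv"))
  cond <- setNames(side$sigma_S_per_m, side$label)
  arr <- array(as.integer(img), dim = dim(img))
  tissue_model(arr, vox, conductivity = cond)
}

#' Write a potential field as NIfTI
#'
#' @param field an `sns_field` from [solve_potential()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field_nifti <- function(field, path) {
  vals <- field$values
  vals[is.na(vals)] <- 0
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- field$voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a potential field as a legacy VTK structured-points file
#'
#' ASCII legacy VTK (`DATASET STRUCTURED_POINTS`) with the potential as a
#' single scalar point field, readable by ParaView and pyvista.
#'
#' @param field an `sns_field`.
#' @param path output `.vtk` path.
#' @param name scalar field name in the file.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, path, name = "potential_V") {
  d <- dim(field$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "snsvta potential field",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g",
                       field$origin_mm[1] + field$voxel_mm[1] / 2,
                       field$origin_mm[2] + field$voxel_mm[2] / 2,
                       field$origin_mm[3] + field$voxel_mm[3] / 2),
               sprintf("SPACING %g %g %g", field$voxel_mm[1],
                       field$voxel_mm[2], field$voxel_mm[3]),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  vals <- as.numeric(field$values)
  vals[is.na(vals)] <- 0
  writeLines(formatC(vals, format = "g", digits = 9), con)
  invisible(path)
}
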