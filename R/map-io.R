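#' Read a per-vertex scalar map
#'
#' Formats: `text` (one value per line; `NaN`/`NA` mark missing data),
#' `curv` (FreeSurfer new-format binary curvature), `gifti` (first scalar
#' data array of a functional/shape GIFTI) and `nifti` (a NIfTI volume
#' sampled at vertex locations through an explicit voxel-to-vertex index
#' table). Non-finite values become masked-out vertices.
#'
#' @param path file path.
#' @param format one of `"text"`, `"curv"`, `"gifti"`, `"nifti"`; guessed
#'   from the extension when missing.
#' @param n_vertices optional expected vertex count; a mismatch raises a
#'   dimension error stating both counts.
#' @param voxel_index for `nifti`: integer vector of 1-based linear voxel
#'   indices, one per vertex.
#' @return a [surface_map()].
#' @export
read_map <- function(path, format = NULL, n_vertices = NULL, voxel_index = NULL) {
  if (!file.exists(path)) stop_es("no such file: ", path, class = "format_error")
  format <- format %||% guess_map_format(path)
  map <- switch(format,
    "text" = {
      vals <- suppressWarnings(as.numeric(readLines(path, warn = FALSE)))
      surface_map(vals)
    },
    "curv" = read_fs_curv(path),
    "gifti" = read_gifti_map(path),
    "nifti" = {
      if (is.null(voxel_index)) {
        stop_es("nifti maps need a voxel_index table mapping voxels to vertices",
                class = "validation_error")
      }
      vol <- RNifti::readNifti(path)
      surface_map(as.numeric(vol[voxel_index]))
    },
    stop_es("unknown map format: ", format, class = "format_error"))
  if (!is.null(n_vertices) && length(map$values) != n_vertices) {
    stop_es("map has ", length(map$values), " values but mesh expects ",
            n_vertices, class = "dimension_error")
  }
  map
}

#' Write a per-vertex scalar map
#'
#' Inverse of [read_map()]. Text output keeps full double precision (exact
#' round trip); GIFTI and FreeSurfer curv store 32-bit floats; `nifti`
#' scatters values into a volume through the same voxel-to-vertex table
#' used by [read_map()].
#'
#' @param map a [surface_map()] (or plain numeric vector).
#' @param path output path.
#' @param format as in [read_map()].
#' @param dim for `nifti`: the volume dimensions.
#' @param voxel_index for `nifti`: 1-based linear voxel index per vertex.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, format = NULL, dim = NULL, voxel_index = NULL) {
  map <- as_surface_map(map)
  format <- format %||% guess_map_format(path)
  switch(format,
    "text" = {
      vals <- map$values
      out <- ifelse(map$mask, sprintf("%.17g", vals), "NaN")
      writeLines(out, path)
    },
    "curv" = write_fs_curv(map, path),
    "gifti" = write_gifti_map(map, path),
    "nifti" = {
      if (is.null(dim) || is.null(voxel_index)) {
        stop_es("nifti maps need dim and voxel_index", class = "validation_error")
      }
      vol <- array(NaN, dim = dim)
      vals <- map$values
      vals[!map$mask] <- NaN
      vol[voxel_index] <- vals
      RNifti::writeNifti(RNifti::asNifti(vol), path)
    },
    stop_es("unknown map format: ", format, class = "format_error"))
  invisible(path)
}

guess_map_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.gii$", low)) return("gifti")
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.curv$", low)) return("curv")
  "text"
}

## FreeSurfer "new format" curv: magic 0xFFFFFF, big-endian
read_fs_curv <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "integer", 3L, size = 1L, signed = FALSE)
  if (!(magic[1] == 255 && magic[2] == 255 && magic[3] == 255)) {
    stop_es(path, ": byte 0: not a new-format curv file", class = "format_error")
  }
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  readBin(con, "integer", 1L, size = 4L, endian = "big")  # face count, unused
  vpv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (vpv != 1L) stop_es(path, ": values per vertex must be 1", class = "format_error")
  surface_map(readBin(con, "numeric", nv, size = 4L, endian = "big"))
}

write_fs_curv <- function(map, path) {
  con <- file(path, "wb"); on.exit(close(con))
  vals <- map$values
  vals[!map$mask] <- NaN
  writeBin(as.raw(c(255, 255, 255)), con)
  writeBin(as.integer(length(vals)), con, size = 4L, endian = "big")
  writeBin(0L, con, size = 4L, endian = "big")
  writeBin(1L, con, size = 4L, endian = "big")
  writeBin(as.numeric(vals), con, size = 4L, endian = "big")
}
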