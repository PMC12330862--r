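#' Read a mesh from disk
#'
#' Supported dialects: `off` (Object File Format), `ply` (ASCII PLY),
#' `freesurfer-surface` (big-endian binary triangle surface), `gifti`
#' (surface GIFTI with POINTSET + TRIANGLE arrays), `node-ele`
#' (TetGen-style ASCII pair; pass the `.node` path, the sibling `.ele`
#' is read automatically) and `vtk` (legacy ASCII unstructured grid of
#' tetrahedra). Vertex order is preserved from the file; all connectivity
#' is 0-based internally (node/ele files are converted at the boundary).
#'
#' @param path file path.
#' @param format one of `"freesurfer-surface"`, `"gifti"`, `"off"`,
#'   `"ply"`, `"node-ele"`, `"vtk"`. Guessed from the extension when
#'   missing.
#' @return a [triangle_mesh()] or [tet_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop_es("no such file: ", path, class = "format_error")
  format <- format %||% guess_mesh_format(path)
  switch(format,
    "off" = read_off(path),
    "ply" = read_ply(path),
    "freesurfer-surface" = read_fs_surface(path),
    "gifti" = read_gifti_surface(path),
    "node-ele" = read_node_ele(path),
    "vtk" = read_vtk_tets(path),
    stop_es("unknown mesh format: ", format, class = "format_error"))
}

#' Write a mesh to disk
#'
#' Inverse of [read_mesh()]; see that function for the dialects.
#'
#' @param mesh a [triangle_mesh()] or [tet_mesh()].
#' @param path output path (for `node-ele`, the `.node` path).
#' @param format as in [read_mesh()].
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- format %||% guess_mesh_format(path)
  switch(format,
    "off" = write_off(mesh, path),
    "ply" = write_ply(mesh, path),
    "freesurfer-surface" = write_fs_surface(mesh, path),
    "gifti" = write_gifti_surface(mesh, path),
    "node-ele" = write_node_ele(mesh, path),
    "vtk" = write_vtk_tets(mesh, path),
    stop_es("unknown mesh format: ", format, class = "format_error"))
  invisible(path)
}

guess_mesh_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.off$", low)) return("off")
  if (grepl("\\.ply$", low)) return("ply")
  if (grepl("\\.gii$", low)) return("gifti")
  if (grepl("\\.node$", low)) return("node-ele")
  if (grepl("\\.vtk$", low)) return("vtk")
  "freesurfer-surface"
}

fmt_err <- function(path, line, msg) {
  stop_es(path, ": line ", line, ": ", msg, class = "format_error")
}

read_off <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (!length(ln) || toupper(trimws(ln[1])) != "OFF") {
    fmt_err(path, 1, "missing OFF header")
  }
  counts <- scan(text = ln[2], quiet = TRUE)
  if (length(counts) < 2) fmt_err(path, 2, "expected vertex/face counts")
  nv <- counts[1]; nf <- counts[2]
  body <- scan(text = ln[-(1:2)], quiet = TRUE)
  v <- matrix(body[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  rest <- body[-seq_len(3 * nv)]
  f <- matrix(rest[seq_len(4 * nf)], ncol = 4, byrow = TRUE)
  if (any(f[, 1] != 3)) fmt_err(path, 3 + nv, "only triangular faces supported")
  triangle_mesh(v, f[, 2:4, drop = FALSE])
}

write_off <- function(mesh, path) {
  stopifnot(!is_tet_mesh(mesh))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
}

read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!length(ln) || trimws(ln[1]) != "ply") fmt_err(path, 1, "missing ply magic")
  hdr_end <- which(trimws(ln) == "end_header")[1]
  if (is.na(hdr_end)) fmt_err(path, length(ln), "no end_header")
  hdr <- ln[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", hdr))) fmt_err(path, 2, "only ASCII PLY supported")
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", grep("^element\\s+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "", grep("^element\\s+face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) fmt_err(path, 1, "missing element counts")
  vl <- ln[hdr_end + seq_len(nv)]
  v <- matrix(scan(text = vl, quiet = TRUE), nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fl <- ln[hdr_end + nv + seq_len(nf)]
  f <- matrix(scan(text = fl, quiet = TRUE), nrow = nf, byrow = TRUE)
  if (any(f[, 1] != 3)) fmt_err(path, hdr_end + nv + 1, "only triangular faces supported")
  triangle_mesh(v, f[, 2:4, drop = FALSE])
}

write_ply <- function(mesh, path) {
  stopifnot(!is_tet_mesh(mesh))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
}

## FreeSurfer binary triangle surface (big-endian)
FS_TRIANGLE_MAGIC <- 16777214L

read_fs_surface <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "integer", 3L, size = 1L, signed = FALSE)
  val <- magic[1] * 65536 + magic[2] * 256 + magic[3]
  if (val != FS_TRIANGLE_MAGIC) {
    stop_es(path, ": byte 0: not a FreeSurfer triangle surface (magic ", val, ")",
            class = "format_error")
  }
  ## comment terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (!length(b)) stop_es(path, ": truncated header", class = "format_error")
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  v <- readBin(con, "numeric", 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", 3L * nf, size = 4L, endian = "big")
  triangle_mesh(matrix(v, ncol = 3, byrow = TRUE),
                matrix(f, ncol = 3, byrow = TRUE))
}

write_fs_surface <- function(mesh, path) {
  stopifnot(!is_tet_mesh(mesh))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(255, 255, 254)), con)
  writeBin(charToRaw("created by eigenstrapr\n\n"), con)
  writeBin(as.integer(nrow(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces)), con, size = 4L, endian = "big")
}

read_node_ele <- function(path) {
  node_path <- path
  ele_path <- sub("\\.node$", ".ele", path)
  if (identical(ele_path, node_path)) ele_path <- paste0(path, ".ele")
  if (!file.exists(ele_path)) stop_es("missing .ele companion for ", path,
                                      class = "format_error")
  strip <- function(p) {
    ln <- readLines(p, warn = FALSE)
    ln <- sub("#.*$", "", ln)
    ln[nzchar(trimws(ln))]
  }
  nl <- strip(node_path)
  nhd <- scan(text = nl[1], quiet = TRUE)
  nv <- nhd[1]
  vt <- matrix(scan(text = nl[1 + seq_len(nv)], quiet = TRUE),
               nrow = nv, byrow = TRUE)
  first_id <- vt[1, 1]
  v <- vt[order(vt[, 1]), 2:4, drop = FALSE]
  el <- strip(ele_path)
  ehd <- scan(text = el[1], quiet = TRUE)
  nt <- ehd[1]
  tt <- matrix(scan(text = el[1 + seq_len(nt)], quiet = TRUE),
               nrow = nt, byrow = TRUE)
  tets <- tt[, 2:5, drop = FALSE] - first_id   # convert to 0-based
  tet_mesh(v, tets)
}

write_node_ele <- function(mesh, path) {
  stopifnot(is_tet_mesh(mesh))
  node_path <- if (grepl("\\.node$", path)) path else paste0(path, ".node")
  ele_path <- sub("\\.node$", ".ele", node_path)
  nv <- nrow(mesh$vertices)
  con <- file(node_path, "w")
  writeLines(sprintf("%d 3 0 0", nv), con)
  writeLines(sprintf("%d %s", seq_len(nv),
                     apply(mesh$vertices, 1, function(r)
                       paste(format(r, digits = 17), collapse = " "))), con)
  close(con)
  con <- file(ele_path, "w")
  writeLines(sprintf("%d 4 0", nrow(mesh$tets)), con)
  writeLines(sprintf("%d %s", seq_len(nrow(mesh$tets)),
                     apply(mesh$tets + 1L, 1, paste, collapse = " ")), con)
  close(con)
}

read_vtk_tets <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk DataFile", ln[1])) fmt_err(path, 1, "not a legacy VTK file")
  if (!any(toupper(trimws(ln)) == "ASCII")) fmt_err(path, 3, "only ASCII VTK supported")
  ip <- grep("^POINTS", ln)[1]
  if (is.na(ip)) fmt_err(path, length(ln), "no POINTS section")
  np <- as.integer(strsplit(trimws(ln[ip]), "\\s+")[[1]][2])
  ic <- grep("^CELLS", ln)[1]
  pts <- scan(text = ln[(ip + 1):(ic - 1)], quiet = TRUE)
  v <- matrix(pts[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  nc <- as.integer(strsplit(trimws(ln[ic]), "\\s+")[[1]][2])
  it <- grep("^CELL_TYPES", ln)[1]
  cells <- scan(text = ln[(ic + 1):(it - 1)], quiet = TRUE)
  cm <- matrix(cells, nrow = nc, byrow = TRUE)
  if (any(cm[, 1] != 4)) fmt_err(path, ic, "only tetrahedral cells supported")
  types <- scan(text = ln[(it + 1):length(ln)], quiet = TRUE)
  if (any(types != 10)) fmt_err(path, it, "only VTK_TETRA (10) cells supported")
  tet_mesh(v, cm[, 2:5, drop = FALSE])
}

write_vtk_tets <- function(mesh, path) {
  stopifnot(is_tet_mesh(mesh))
  con <- file(path, "w"); on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 2.0", "eigenstrapr tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", nt, 5L * nt), con)
  writeLines(apply(mesh$tets, 1, function(r)
    paste(c(4L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("10", nt), con)
}
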