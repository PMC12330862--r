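## Minimal GIFTI (.gii) support: surface files (POINTSET + TRIANGLE data
## arrays) and per-vertex scalar files (one or more float32 arrays), with
## Base64Binary or GZipBase64Binary encoding, little/big endian. This
## covers the .surf.gii / .func.gii / .shape.gii dialects the package
## exchanges; data are stored as the format's native 32-bit types, so map
## round trips are exact only to float32 precision (~1e-7 relative).

gii_type <- function(dt) {
  switch(dt,
    "NIFTI_TYPE_FLOAT32" = list(what = "numeric", size = 4L),
    "NIFTI_TYPE_FLOAT64" = list(what = "numeric", size = 8L),
    "NIFTI_TYPE_INT32" = list(what = "integer", size = 4L),
    stop_es("unsupported GIFTI data type: ", dt, class = "format_error"))
}

gii_read_array <- function(da) {
  at <- xml2::xml_attrs(da)
  ty <- gii_type(at[["DataType"]])
  enc <- at[["Encoding"]]
  endian <- if (identical(at[["Endian"]], "BigEndian")) "big" else "little"
  dims <- as.integer(at[grep("^Dim[0-9]+$", names(at))])
  nelem <- prod(dims)
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
  if (identical(enc, "GZipBase64Binary")) raw <- memDecompress(raw, type = "gzip")
  else if (!identical(enc, "Base64Binary")) {
    stop_es("unsupported GIFTI encoding: ", enc, class = "format_error")
  }
  vals <- readBin(raw, ty$what, n = nelem, size = ty$size, endian = endian)
  order <- at[["ArrayIndexingOrder"]] %||% "RowMajorOrder"
  if (length(dims) == 2L) {
    if (identical(order, "RowMajorOrder")) {
      matrix(vals, nrow = dims[1], byrow = TRUE)
    } else matrix(vals, nrow = dims[1])
  } else vals
}

gii_ns_strip <- function(doc) {
  ## GIFTI files may or may not carry a default namespace; strip for xpath
  xml2::xml_ns_strip(doc)
  doc
}

read_gifti_arrays <- function(path) {
  doc <- gii_ns_strip(xml2::read_xml(path))
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(das)) stop_es(path, ": no DataArray elements", class = "format_error")
  intents <- xml2::xml_attr(das, "Intent")
  arrays <- lapply(das, gii_read_array)
  names(arrays) <- intents
  arrays
}

read_gifti_surface <- function(path) {
  arrays <- read_gifti_arrays(path)
  vi <- which(names(arrays) == "NIFTI_INTENT_POINTSET")[1]
  fi <- which(names(arrays) == "NIFTI_INTENT_TRIANGLE")[1]
  if (is.na(vi) || is.na(fi)) {
    stop_es(path, ": needs POINTSET and TRIANGLE arrays", class = "format_error")
  }
  triangle_mesh(arrays[[vi]], arrays[[fi]])
}

gii_write_array <- function(values, intent, dtype) {
  ty <- gii_type(dtype)
  if (is.matrix(values)) {
    dims <- dim(values)
    flat <- as.vector(t(values))
    dim_attr <- sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"', dims[1], dims[2])
  } else {
    dim_attr <- sprintf('Dimensionality="1" Dim0="%d"', length(values))
    flat <- values
  }
  raw <- writeBin(if (ty$what == "integer") as.integer(flat) else as.numeric(flat),
                  raw(), size = ty$size, endian = "little")
  b64 <- jsonlite::base64_enc(memCompress(raw, type = "gzip"))
  paste0('<DataArray Intent="', intent, '" DataType="', dtype,
         '" ArrayIndexingOrder="RowMajorOrder" ', dim_attr,
         ' Encoding="GZipBase64Binary" Endian="LittleEndian"',
         ' ExternalFileName="" ExternalFileOffset="">\n<Data>',
         gsub("[[:space:]]", "", b64), "</Data>\n</DataArray>")
}

gii_write_doc <- function(arrays_xml, path) {
  txt <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="',
                length(arrays_xml), '">\n',
                paste(arrays_xml, collapse = "\n"), "\n</GIFTI>\n")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

write_gifti_surface <- function(mesh, path) {
  stopifnot(!is_tet_mesh(mesh))
  gii_write_doc(list(
    gii_write_array(mesh$vertices, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32"),
    gii_write_array(mesh$faces, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32")), path)
}

read_gifti_map <- function(path) {
  arrays <- read_gifti_arrays(path)
  scalars <- arrays[!(names(arrays) %in%
                        c("NIFTI_INTENT_POINTSET", "NIFTI_INTENT_TRIANGLE"))]
  if (!length(scalars)) stop_es(path, ": no scalar data array", class = "format_error")
  surface_map(as.numeric(scalars[[1]]))
}

write_gifti_map <- function(map, path) {
  vals <- map$values
  vals[!map$mask] <- NaN
  gii_write_doc(list(
    gii_write_array(vals, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32")), path)
}
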