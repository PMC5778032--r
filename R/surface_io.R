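#' Read a triangulated surface
#'
#' Supported dialects:
#' \describe{
#'   \item{`freesurfer`}{FreeSurfer binary triangle surface (magic bytes
#'     `0xFF 0xFF 0xFE`), the native format of `lh.white` / `rh.pial` etc.}
#'   \item{`gifti`}{GIFTI geometry (`.surf.gii`): XML with a
#'     `NIFTI_INTENT_POINTSET` and a `NIFTI_INTENT_TRIANGLE` data array,
#'     ASCII / Base64 / gzipped-Base64 encodings, little-endian.}
#'   \item{`plaintext`}{One header line `"V F"`, then V lines `x y z`, then F
#'     lines `i j k` with 0-based vertex indices.}
#' }
#' `format = "auto"` picks by magic bytes / extension.
#'
#' @param path path to the surface file.
#' @param format one of `"auto"`, `"freesurfer"`, `"gifti"`, `"plaintext"`.
#' @param mask optional path to a cortex mask (see [read_cortex_mask()]) or a
#'   logical vector of length V.
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path, format = c("auto", "freesurfer", "gifti",
                                          "plaintext"),
                         mask = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("surface file not found: ", path)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 3L)
    format <- if (length(magic) == 3L && all(magic == as.raw(c(0xff, 0xff, 0xfe))))
      "freesurfer"
    else if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti"
    else "plaintext"
  }
  mesh <- switch(format,
    freesurfer = read_surface_freesurfer(path),
    gifti = read_surface_gifti(path),
    plaintext = read_surface_plaintext(path))
  if (!is.null(mask)) {
    m <- if (is.character(mask)) read_cortex_mask(mask, n_vertices(mesh)) else mask
    mesh <- surface_mesh(mesh$vertices, mesh$faces, mask = m,
                         hemisphere = mesh$hemisphere)
  }
  mesh
}

read_surface_plaintext <- function(path) {
  header <- scan(path, what = integer(), n = 2L, quiet = TRUE)
  if (length(header) != 2L || any(header < 0L))
    stop("plaintext surface ", path, ": line 1 must be 'V F'")
  v <- header[1L]; f <- header[2L]
  dat <- scan(path, what = double(), skip = 1L, quiet = TRUE)
  if (length(dat) != 3L * (v + f))
    stop("plaintext surface ", path, ": expected ", 3 * (v + f),
         " numbers after the header, found ", length(dat))
  verts <- matrix(dat[seq_len(3L * v)], ncol = 3L, byrow = TRUE)
  faces <- matrix(as.integer(dat[3L * v + seq_len(3L * f)]),
                  ncol = 3L, byrow = TRUE) + 1L
  surface_mesh(verts, faces)
}

#' Write a surface in the plaintext dialect
#'
#' @param mesh a [surface_mesh()].
#' @param path output path. Faces are written 0-based.
#' @return `path`, invisibly.
#' @export
write_surface_plaintext <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(n_vertices(mesh), nrow(mesh$faces)), con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(mesh$faces - 1L, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

# FreeSurfer 3-byte big-endian integer
read_int3 <- function(con) {
  b <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  b[1L] * 65536L + b[2L] * 256L + b[3L]
}

read_surface_freesurfer <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (magic != 16777214L)  # 0xFFFFFE, triangle-file magic
    stop("not a FreeSurfer binary triangle surface (magic ", magic,
         " at byte offset 0): ", path)
  # created-by string: terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    ch <- readBin(con, "raw", n = 1L)
    if (length(ch) == 0L) stop("truncated FreeSurfer surface header: ", path)
    if (ch == as.raw(10) && prev == as.raw(10)) break
    prev <- ch
  }
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  v <- counts[1L]; f <- counts[2L]
  verts <- readBin(con, "double", n = 3L * v, size = 4L, endian = "big")
  faces <- readBin(con, "integer", n = 3L * f, size = 4L, endian = "big")
  surface_mesh(matrix(verts, ncol = 3L, byrow = TRUE),
               matrix(faces, ncol = 3L, byrow = TRUE) + 1L)
}

#' Write a FreeSurfer binary triangle surface
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_freesurfer <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xff, 0xff, 0xfe)), con)
  writeBin(charToRaw("created by vifc\n\n"), con)
  writeBin(c(n_vertices(mesh), nrow(mesh$faces)), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces - 1L)), con, size = 4L, endian = "big")
  invisible(path)
}

# ---- GIFTI ------------------------------------------------------------------

gifti_decode_darray <- function(node) {
  att <- xml2::xml_attrs(node)
  dtype <- att[["DataType"]]
  n <- prod(as.integer(att[grep("^Dim[0-9]+$", names(att))]))
  txt <- xml2::xml_text(xml2::xml_find_first(node, ".//Data"))
  enc <- att[["Encoding"]]
  if (enc == "ASCII") {
    vals <- scan(text = txt, what = double(), quiet = TRUE)
  } else {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
    else if (enc != "Base64Binary") stop("unsupported GIFTI encoding: ", enc)
    endian <- if (identical(att[["Endian"]], "BigEndian")) "big" else "little"
    vals <- switch(dtype,
      NIFTI_TYPE_FLOAT32 = readBin(raw, "double", n = n, size = 4L,
                                   endian = endian),
      NIFTI_TYPE_FLOAT64 = readBin(raw, "double", n = n, size = 8L,
                                   endian = endian),
      NIFTI_TYPE_INT32 = readBin(raw, "integer", n = n, size = 4L,
                                 endian = endian),
      NIFTI_TYPE_UINT8 = readBin(raw, "integer", n = n, size = 1L,
                                 signed = FALSE, endian = endian),
      stop("unsupported GIFTI DataType: ", dtype))
  }
  dims <- as.integer(att[grep("^Dim[0-9]+$", names(att))])
  if (length(dims) == 2L) {
    byrow <- !identical(att[["ArrayIndexingOrder"]], "ColumnMajorOrder")
    vals <- matrix(vals, nrow = dims[1L], ncol = dims[2L], byrow = byrow)
  }
  list(intent = att[["Intent"]], values = vals)
}

gifti_darrays <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, "//DataArray")
  if (length(nodes) == 0L) stop("no DataArray elements in GIFTI file: ", path)
  lapply(nodes, gifti_decode_darray)
}

read_surface_gifti <- function(path) {
  da <- gifti_darrays(path)
  intents <- vapply(da, `[[`, character(1), "intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) != 1L || length(it) != 1L)
    stop("GIFTI geometry needs one POINTSET and one TRIANGLE array: ", path)
  surface_mesh(da[[ip]]$values, da[[it]]$values + 1L)
}

gifti_xml_darray <- function(values, intent, dtype) {
  dims <- if (is.matrix(values))
    sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"', nrow(values), ncol(values))
  else sprintf('Dimensionality="1" Dim0="%d"', length(values))
  flat <- if (is.matrix(values)) as.vector(t(values)) else values
  raw <- if (dtype == "NIFTI_TYPE_INT32")
    writeBin(as.integer(flat), raw(), size = 4L, endian = "little")
  else writeBin(as.numeric(flat), raw(), size = 4L, endian = "little")
  b64 <- jsonlite::base64_enc(memCompress(raw, type = "gzip"))
  paste0('<DataArray Intent="', intent, '" DataType="', dtype,
         '" ArrayIndexingOrder="RowMajorOrder" ', dims,
         ' Encoding="GZipBase64Binary" Endian="LittleEndian"',
         ' ExternalFileName="" ExternalFileOffset="">\n<Data>',
         b64, '</Data>\n</DataArray>')
}

gifti_write <- function(darrays, path) {
  txt <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="',
                length(darrays), '">\n',
                paste(darrays, collapse = "\n"), "\n</GIFTI>\n")
  writeLines(txt, path)
  invisible(path)
}

#' Write a GIFTI geometry file
#'
#' Minimal `.surf.gii` writer (POINTSET float32 + TRIANGLE int32, gzipped
#' Base64, little-endian), readable by standard neuroimaging toolchains.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path (conventionally `*.surf.gii`).
#' @return `path`, invisibly.
#' @export
write_surface_gifti <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  gifti_write(c(
    gifti_xml_darray(mesh$vertices, "NIFTI_INTENT_POINTSET",
                     "NIFTI_TYPE_FLOAT32"),
    gifti_xml_darray(mesh$faces - 1L, "NIFTI_INTENT_TRIANGLE",
                     "NIFTI_TYPE_INT32")), path)
}

#' Read a cortex mask
#'
#' Accepts either a FreeSurfer label file (header line, count line, then one
#' row per labelled vertex whose first column is the 0-based vertex index) or
#' a one-column 0/1 text file of length V.
#'
#' @param path mask file path.
#' @param n_vertices number of vertices of the target mesh.
#' @return logical vector of length `n_vertices`.
#' @export
read_cortex_mask <- function(path, n_vertices) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^#", lines[1L])) {
    # FreeSurfer label: comment, count, then "vtx x y z stat" rows
    cnt <- as.integer(trimws(lines[2L]))
    rows <- lines[3L:(2L + cnt)]
    idx <- as.integer(vapply(strsplit(trimws(rows), "\\s+"), `[[`, "", 1L)) + 1L
    if (any(idx < 1L | idx > n_vertices))
      stop("label file references vertices outside [0, ", n_vertices - 1L, "]")
    m <- rep(FALSE, n_vertices)
    m[idx] <- TRUE
    return(m)
  }
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals) || length(vals) != n_vertices ||
      !all(vals %in% c(0, 1)))
    stop("mask file must be a FreeSurfer label or ", n_vertices,
         " lines of 0/1: ", path)
  vals == 1
}
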