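#' Read / write per-vertex scalar maps
#'
#' Format is selected by extension:
#' `*.txt` one value per line (`NA` for undefined vertices), `*.csv` a
#' single-column CSV with header, `*.curv` FreeSurfer curvature binary
#' (new-format magic `0xFFFFFF`; undefined stored as NaN), `*.gii` GIFTI
#' functional/shape with one float32 data array.
#'
#' @param path file path; the extension picks the dialect.
#' @return `read_map()`: a numeric vector. `write_map()`: `path`, invisibly.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  switch(tolower(tools::file_ext(path)),
    txt = scan(path, what = double(), na.strings = "NA", quiet = TRUE),
    csv = utils::read.csv(path)[[1L]],
    curv = read_curv(path),
    gii = read_map_gifti(path),
    stop("unsupported map extension: ", path))
}

#' @rdname read_map
#' @param x numeric vector (NA = undefined vertex).
#' @export
write_map <- function(x, path) {
  switch(tolower(tools::file_ext(path)),
    txt = writeLines(format(x, digits = 17, trim = TRUE), path),
    csv = utils::write.csv(data.frame(value = x), path, row.names = FALSE),
    curv = write_curv(x, path),
    gii = gifti_write(gifti_xml_darray(ifelse(is.na(x), NaN, x),
                                       "NIFTI_INTENT_NONE",
                                       "NIFTI_TYPE_FLOAT32"), path),
    stop("unsupported map extension: ", path))
  invisible(path)
}

read_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (magic != 16777215L)  # 0xFFFFFF: new-format curv
    stop("not a new-format FreeSurfer curv file (magic ", magic, "): ", path)
  hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
  vals <- readBin(con, "double", n = hdr[1L], size = 4L, endian = "big")
  vals[is.nan(vals)] <- NA_real_
  vals
}

write_curv <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xff, 0xff, 0xff)), con)
  writeBin(c(length(x), 0L, 1L), con, size = 4L, endian = "big")
  writeBin(as.numeric(ifelse(is.na(x), NaN, x)), con, size = 4L,
           endian = "big")
  invisible(path)
}

read_map_gifti <- function(path) {
  da <- gifti_darrays(path)
  scalars <- Filter(function(d) !is.matrix(d$values) ||
                      min(dim(d$values)) == 1L, da)
  if (length(scalars) != 1L)
    stop("expected one per-vertex scalar array in ", path)
  v <- as.numeric(scalars[[1L]]$values)
  v[is.nan(v)] <- NA_real_
  v
}

#' Read a dense vertices x timepoints BOLD series
#'
#' `*.csv` / `*.tsv`: numeric matrix, one row per vertex, no header.
#' `*.func.gii` / `*.gii`: one GIFTI data array per timepoint (each length V),
#' or a single V x N array.
#'
#' @param path series file.
#' @return numeric V x N matrix.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv")) {
    sep <- if (ext == "csv") "," else "\t"
    return(as.matrix(utils::read.table(path, sep = sep, header = FALSE)))
  }
  if (ext == "gii") {
    da <- gifti_darrays(path)
    if (length(da) == 1L && is.matrix(da[[1L]]$values))
      return(da[[1L]]$values)
    return(do.call(cbind, lapply(da, function(d) as.numeric(d$values))))
  }
  stop("unsupported series extension: ", path)
}

#' @rdname read_series
#' @param x numeric V x N matrix.
#' @export
write_series <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv")) {
    utils::write.table(x, path, sep = if (ext == "csv") "," else "\t",
                       row.names = FALSE, col.names = FALSE)
  } else if (ext == "gii") {
    gifti_write(gifti_xml_darray(x, "NIFTI_INTENT_TIME_SERIES",
                                 "NIFTI_TYPE_FLOAT32"), path)
  } else stop("unsupported series extension: ", path)
  invisible(path)
}
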