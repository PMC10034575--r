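# Minimal NRRD volume I/O (NRRD0004, raw or gzip encoding, little endian).
# Covers exactly the field set this package writes: doses and displacement
# components as double, masks as uint8 0/1; spacings + axis mins carry the
# grid geometry. Fastest axis first, matching the in-memory [x, y, z] order.

nrrd_type_map <- c(double = "double", uint8 = "unsigned char")

#' Write a 3D or 4D array as an NRRD volume
#'
#' @param x numeric or logical array (3D; or 4D with trailing component axis
#'   for displacement fields).
#' @param path output file path.
#' @param spacing,origin grid geometry in mm (spatial axes only).
#' @param type `"double"` for dose/displacement data, `"uint8"` for masks.
#' @param encoding `"gzip"` (default) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, spacing, origin = c(0, 0, 0),
                       type = c("double", "uint8"), encoding = c("gzip", "raw")) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  x <- as.array(x)
  nd <- length(dim(x))
  if (!nd %in% c(3L, 4L)) stop("only 3D or 4D arrays are supported")
  spac <- c(spacing, if (nd == 4L) NA)   # component axis has no spacing
  mins <- c(origin, if (nd == 4L) NA)
  hdr <- c(
    "NRRD0004",
    "# adaptidose volume",
    sprintf("type: %s", nrrd_type_map[[type]]),
    sprintf("dimension: %d", nd),
    sprintf("sizes: %s", paste(dim(x), collapse = " ")),
    sprintf("spacings: %s", paste(ifelse(is.na(spac), "nan",
                                         sprintf("%.17g", spac)), collapse = " ")),
    sprintf("axis mins: %s", paste(ifelse(is.na(mins), "nan",
                                          sprintf("%.17g", mins)), collapse = " ")),
    sprintf("encoding: %s", encoding),
    "endian: little",
    ""
  )
  payload <- if (type == "uint8") {
    as.raw(as.integer(x != 0))
  } else {
    writeBin(as.numeric(x), raw(), size = 8, endian = "little")
  }
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(payload, con)
  invisible(path)
}

#' Read an NRRD volume written by [write_nrrd()]
#'
#' @param path NRRD file path.
#' @return list with `values` (array), `spacing`, `origin`.
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) stop(sprintf("NRRD file not found: %s", path))
  bytes <- readBin(path, raw(), n = file.size(path))
  nl <- which(bytes == as.raw(10L))
  # header ends at the first blank line (two consecutive newlines)
  blank <- nl[which(diff(nl) == 1L)[1]]
  if (is.na(blank)) stop(sprintf("truncated NRRD header: %s", path))
  hdr <- strsplit(rawToChar(bytes[seq_len(blank)]), "\n", fixed = TRUE)[[1]]
  if (!startsWith(hdr[1], "NRRD"))
    stop(sprintf("not an NRRD file: %s", path))
  hdr <- hdr[-1]
  hdr <- hdr[nzchar(hdr) & !startsWith(hdr, "#")]
  kv <- regmatches(hdr, regexpr(": ", hdr), invert = TRUE)
  fields <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  sizes <- as.integer(strsplit(fields[["sizes"]], " ")[[1]])
  typ <- fields[["type"]]
  enc <- fields[["encoding"]]
  spac <- suppressWarnings(as.numeric(strsplit(fields[["spacings"]], " ")[[1]]))
  mins <- suppressWarnings(as.numeric(strsplit(fields[["axis mins"]], " ")[[1]]))
  n <- prod(sizes)
  nbytes <- n * if (typ == "unsigned char") 1L else 8L
  payload <- bytes[(blank + 2L):length(bytes)]
  if (identical(enc, "gzip")) payload <- memDecompress(payload, type = "gzip")
  if (length(payload) < nbytes)
    stop(sprintf("NRRD payload shorter than expected in %s", path))
  values <- if (typ == "unsigned char") {
    as.integer(payload[seq_len(nbytes)]) != 0L
  } else {
    readBin(payload, numeric(), n = n, size = 8, endian = "little")
  }
  dim(values) <- sizes
  nspat <- sum(!is.na(spac))
  list(values = values,
       spacing = spac[seq_len(min(3L, nspat))],
       origin = mins[seq_len(min(3L, nspat))])
}
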