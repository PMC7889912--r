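# Portable containers for hyperspectral maps.
#
# Two dialects: a plain-text TSV with header comment lines (wavenumber axis
# and metadata) and one row per pixel, and an R-native serialized container
# (a single file holding the named datasets `wavenumber`, `coords`,
# `spectra`, `meta`) that round-trips bit-exactly.

#' Write a hyperspectral map container
#'
#' @param map a [HyperspectralMap-class].
#' @param path output file path.
#' @param format `"rds"` (binary, bit-exact round trip) or `"tsv"` (text
#'   dialect, full double precision).
#' @return `path`, invisibly.
#' @export
writeMapContainer <- function(map, path, format = c("rds", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(map, "HyperspectralMap"))
  if (format == "rds") {
    saveRDS(list(wavenumber = map@wavenumber, coords = map@coords,
                 spectra = map@spectra, dims = map@dims, meta = map@meta),
            path, version = 2)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    num <- function(x) sprintf("%.17g", x)
    meta <- map@meta
    writeLines(c(
      "# digitalSERS hyperspectral map v1",
      paste0("# chip\t", meta$chip %||% "NA"),
      paste0("# image\t", meta$image %||% "NA"),
      paste0("# origin\t", paste(num(meta$origin %||% c(NA, NA)),
                                 collapse = "\t")),
      paste0("# dims\t", paste(map@dims, collapse = "\t")),
      paste0("# wavenumber\t", paste(num(map@wavenumber), collapse = "\t")),
      paste(c("x", "y", paste0("w", seq_along(map@wavenumber))),
            collapse = "\t")), con)
    body <- cbind(map@coords, map@spectra)
    write.table(matrix(num(body), nrow = nrow(body)), con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a hyperspectral map container
#'
#' @param path file written by [writeMapContainer()]; the dialect is
#'   detected from the content.
#' @return a [HyperspectralMap-class].
#' @export
readMapContainer <- function(path) {
  if (!file.exists(path)) stop("no such map container: ", path)
  head4 <- readBin(path, "raw", 4)
  isText <- identical(rawToChar(head4[1:2]), "# ")
  if (!isText) {
    obj <- tryCatch(readRDS(path), error = function(e)
      stop("corrupted map container (not a valid serialized map): ", path))
    need <- c("wavenumber", "coords", "spectra", "dims", "meta")
    if (!is.list(obj) || !all(need %in% names(obj)))
      stop("corrupted map container (missing datasets): ", path)
    return(new("HyperspectralMap", wavenumber = obj$wavenumber,
               coords = obj$coords, spectra = obj$spectra,
               dims = obj$dims, meta = obj$meta))
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) {
    ln <- grep(paste0("^# ", key, "\t"), hdr, value = TRUE)
    if (!length(ln)) stop("corrupted map container (missing ", key, "): ",
                          path)
    strsplit(sub(paste0("^# ", key, "\t"), "", ln[1]), "\t")[[1]]
  }
  wn <- as.numeric(field("wavenumber"))
  dims <- as.integer(field("dims"))
  body <- read.delim(path, comment.char = "#", header = TRUE,
                     check.names = FALSE)
  if (ncol(body) != length(wn) + 2)
    stop("corrupted map container (row width mismatch): ", path)
  meta <- list(chip = field("chip"), image = as.integer(field("image")),
               origin = suppressWarnings(as.numeric(field("origin"))))
  new("HyperspectralMap", wavenumber = wn,
      coords = as.matrix(body[, 1:2]),
      spectra = unname(as.matrix(body[, -(1:2)])),
      dims = dims, meta = meta)
}

#' Write call tables and chip results as TSV
#'
#' Call tables use the fixed column order `chip`, `image`, `pillar_row`,
#' `pillar_col`, `channel`, `intensity`, `active`.  Chip results write the
#' per-channel summary; the per-image breakdown goes to a sibling file with
#' suffix `_images`.
#'
#' @param x a call table data.frame or a [ChipResult-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeResultTSV <- function(x, path) {
  if (is(x, "ChipResult")) {
    write.table(cbind(chip = x@chip, x@perChannel), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cbind(chip = x@chip, x@perImage),
                sub("(\\.[^.]*)?$", "_images\\1", path), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    cols <- c("chip", "image", "pillar_row", "pillar_col", "channel",
              "intensity", "active")
    write.table(x[, cols], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
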