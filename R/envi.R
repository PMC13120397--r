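#' Read an ENVI-format hyperspectral cube
#'
#' Parses the ASCII `.hdr` header (keys: samples, lines, bands, data type,
#' interleave, byte order, wavelength) and reads the flat binary cube it
#' describes into a rows x cols x bands array.
#'
#' @param hdr_path path to the `.hdr` file. The binary file is taken from the
#'   header's `data file` key when present, else the header path with `.hdr`
#'   stripped, else with `.dat` substituted.
#' @param kind cube kind flag, `"raw"` (default) or `"reflectance"`.
#' @return A [hypercube()].
#' @details Supported data types: 2 (int16), 3 (int32), 4 (float32),
#'   5 (float64), 12 (uint16). Interleaves: bsq, bil, bip.
#' @export
read_envi <- function(hdr_path, kind = "raw") {
  hdr <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ENVI header missing keys: ", paste(miss, collapse = ", "))
  ns <- as.integer(hdr$samples)   # cols
  nl <- as.integer(hdr$lines)    # rows
  nb <- as.integer(hdr$bands)
  dtype <- as.integer(hdr[["data type"]])
  interleave <- tolower(hdr$interleave)
  byte_order <- if (!is.null(hdr[["byte order"]])) as.integer(hdr[["byte order"]]) else 0L
  endian <- if (byte_order == 0L) "little" else "big"
  wl <- if (!is.null(hdr$wavelength)) as.numeric(hdr$wavelength) else seq_len(nb)

  bin_path <- hdr[["data file"]]
  if (is.null(bin_path)) {
    cand <- c(sub("\\.hdr$", "", hdr_path), sub("\\.hdr$", ".dat", hdr_path),
              sub("\\.hdr$", ".img", hdr_path))
    bin_path <- cand[file.exists(cand)][1]
    if (is.na(bin_path)) stop("cannot locate binary file for ", hdr_path)
  } else if (!file.exists(bin_path)) {
    bin_path <- file.path(dirname(hdr_path), basename(bin_path))
  }

  spec <- switch(as.character(dtype),
    "2" = list(what = integer(), size = 4L, rsize = 2L, signed = TRUE),
    "3" = list(what = integer(), size = 4L, rsize = 4L, signed = TRUE),
    "4" = list(what = numeric(), size = 8L, rsize = 4L, signed = TRUE),
    "5" = list(what = numeric(), size = 8L, rsize = 8L, signed = TRUE),
    "12" = list(what = integer(), size = 4L, rsize = 2L, signed = FALSE),
    stop("unsupported ENVI data type: ", dtype))
  n_elem <- ns * nl * nb
  con <- file(bin_path, "rb")
  on.exit(close(con))
  raw_v <- readBin(con, what = spec$what, n = n_elem, size = spec$rsize,
                   signed = spec$signed, endian = endian)
  if (length(raw_v) != n_elem) {
    stop("binary file holds ", length(raw_v), " elements; header promises ", n_elem)
  }
  vals <- switch(interleave,
    # bsq: col fastest, then row, then band
    bsq = aperm(array(raw_v, dim = c(ns, nl, nb)), c(2, 1, 3)),
    # bil: col fastest, then band, then row
    bil = aperm(array(raw_v, dim = c(ns, nb, nl)), c(3, 1, 2)),
    # bip: band fastest, then col, then row
    bip = aperm(array(raw_v, dim = c(nb, ns, nl)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave))
  hypercube(vals, wl, kind = kind)
}

#' Write a hypercube to ENVI format
#'
#' Writes `<base>.hdr` (ASCII) and `<base>.dat` (flat binary, little-endian).
#'
#' @param cube a [hypercube()].
#' @param base_path output path without extension.
#' @param interleave `"bsq"`, `"bil"` or `"bip"` (default `"bsq"`).
#' @param data_type ENVI data type code: 4 (float32, default) or 5 (float64).
#' @return The `.hdr` path, invisibly.
#' @export
write_envi <- function(cube, base_path, interleave = c("bsq", "bil", "bip"),
                       data_type = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4L, 5L)) stop("write supports data types 4 and 5")
  d <- dim(cube$values)
  v <- switch(interleave,
    bsq = aperm(cube$values, c(2, 1, 3)),
    bil = aperm(cube$values, c(2, 3, 1)),
    bip = aperm(cube$values, c(3, 2, 1)))
  dat_path <- paste0(base_path, ".dat")
  hdr_path <- paste0(base_path, ".hdr")
  con <- file(dat_path, "wb")
  writeBin(as.numeric(v), con, size = if (data_type == 4L) 4L else 8L,
           endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = { specpoly export }",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("data file = ", basename(dat_path)),
    paste0("wavelength = {\n ",
           paste(sprintf("%.6g", cube$wavelengths), collapse = ", "), " }")
  )
  writeLines(hdr, hdr_path)
  invisible(hdr_path)
}

# Parse an ENVI ASCII header into a named list; multi-line { } blocks are
# concatenated, list values split on commas.
parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^ENVI", lines[1])) {
    stop(path, " is not an ENVI header (missing ENVI magic line)")
  }
  txt <- paste(lines[-1], collapse = "\n")
  out <- list()
  pos <- 1L
  # match "key = value" where value is either a { ... } block or a line
  pat <- "(?s)([A-Za-z][A-Za-z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- tolower(trimws(substr(piece, 1L, eq - 1L)))
    val <- trimws(substr(piece, eq + 1L, nchar(piece)))
    if (startsWith(val, "{")) {
      val <- gsub("[{}]", "", val)
      val <- trimws(strsplit(val, ",")[[1]])
      val <- val[nzchar(val)]
      if (key %in% c("wavelength", "fwhm")) val <- as.numeric(val)
      if (length(val) == 1L) val <- val[[1]]
    }
    out[[key]] <- val
  }
  out
}
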