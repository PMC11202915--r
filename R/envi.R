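# ENVI header/binary hypercube input-output. The header is a plain-text
# key = value file (with {...} lists spanning lines); the binary holds the
# cube in BSQ, BIL or BIP interleave. Data types 4 (float32) and 5 (float64)
# are supported; cubes are written as float64 so round-trips are bit-exact.

.enviPerm <- list(bsq = c(2L, 1L, 3L),   # sample, line, band
                  bil = c(2L, 3L, 1L),   # sample, band, line
                  bip = c(3L, 2L, 1L))   # band, sample, line

#' Write a hypercube as an ENVI header/binary pair
#'
#' @param cube A \linkS4class{Hypercube}.
#' @param path Output stem or header path; the header is written to
#'   \code{<stem>.hdr} and the binary to \code{<stem>.dat}.
#' @param interleave One of \code{"bsq"}, \code{"bil"}, \code{"bip"}.
#' @return The header path, invisibly.
#' @export
#' @examples
#' cube <- Hypercube(array(runif(4 * 4 * 8), c(4, 4, 8)), seq(400, 470, 10))
#' hdr <- writeENVI(cube, file.path(tempdir(), "toy"))
writeENVI <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(is(cube, "Hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube@data)
  if (any(d == 0L)) stop("refusing to write an empty cube")
  stem <- sub("\\.hdr$", "", path)
  hdrPath <- paste0(stem, ".hdr")
  datPath <- paste0(stem, ".dat")
  wl <- paste(format(cube@wavelengths, trim = TRUE, digits = 15),
              collapse = ", ")
  lines <- c(
    "ENVI",
    "description = {synthetic reflectance cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }", wl))
  writeLines(lines, hdrPath)
  con <- file(datPath, "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(cube@data, .enviPerm[[interleave]])), con,
           size = 8L, endian = "little")
  invisible(hdrPath)
}

# Parse an ENVI header into a named list; {...} values become numeric vectors.
.parseEnviHeader <- function(hdrPath) {
  txt <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  out <- list()
  # key = { multi-line list }
  listPat <- "([a-zA-Z ]+?)\\s*=\\s*\\{([^}]*)\\}"
  m <- gregexpr(listPat, txt)[[1]]
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      frag <- substring(txt, m[i], m[i] + attr(m, "match.length")[i] - 1L)
      key <- trimws(sub(listPat, "\\1", frag))
      val <- trimws(sub(listPat, "\\2", frag))
      out[[tolower(key)]] <- val
    }
    txt <- gsub(listPat, "", txt)
  }
  for (line in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", line, fixed = TRUE)) next
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    out[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}

#' Read an ENVI hypercube
#'
#' @param header_path Path to the \code{.hdr} file; the binary is looked up as
#'   \code{<stem>.dat}, \code{<stem>.img}, \code{<stem>.bin} or \code{<stem>}.
#' @return A \linkS4class{Hypercube}; header fields are kept in
#'   \code{metadata}.
#' @export
readENVI <- function(header_path) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  hdr <- .parseEnviHeader(header_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ENVI header, missing field(s): ",
         paste(miss, collapse = ", "))
  if (is.null(hdr[["wavelength"]]))
    stop("malformed ENVI header: no wavelength list")
  ns <- as.integer(hdr[["samples"]]); nl <- as.integer(hdr[["lines"]])
  nb <- as.integer(hdr[["bands"]])
  interleave <- tolower(hdr[["interleave"]])
  if (!interleave %in% names(.enviPerm))
    stop("unsupported interleave: ", interleave)
  dtype <- as.integer(hdr[["data type"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  endian <- if (identical(hdr[["byte order"]], "1")) "big" else "little"
  wl <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1]])
  if (length(wl) != nb)
    stop(sprintf("header declares %d bands but lists %d wavelengths", nb,
                 length(wl)))

  stem <- sub("\\.hdr$", "", header_path)
  cand <- c(paste0(stem, c(".dat", ".img", ".bin")), stem)
  datPath <- cand[file.exists(cand)][1]
  if (is.na(datPath)) stop("binary file not found for ", header_path)
  nExpect <- as.double(ns) * nl * nb
  nAvail <- file.size(datPath) / size
  if (nAvail != nExpect)
    stop(sprintf(
      "binary size mismatch: header implies %.0f values, file holds %.0f",
      nExpect, nAvail))
  con <- file(datPath, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = nExpect, size = size, endian = endian)

  perm <- .enviPerm[[interleave]]
  dims <- c(nl, ns, nb)[perm]
  arr <- aperm(array(raw, dims), order(perm))
  Hypercube(arr, wl, metadata = hdr)
}

#' Crop a hypercube to a wavelength window
#'
#' Retains bands with \code{wl_min <= lambda <= wl_max} (the default window is
#' the 400-1100 nm visible/short-NIR analysis range), preserving band order.
#'
#' @param cube A \linkS4class{Hypercube}.
#' @param wl_min,wl_max Window end points in nm.
#' @return A \linkS4class{Hypercube} with the retained bands.
#' @export
#' @examples
#' cube <- Hypercube(array(runif(4 * 4 * 8), c(4, 4, 8)), seq(400, 470, 10))
#' dim(cropBands(cube, 400, 430))
cropBands <- function(cube, wl_min = 400, wl_max = 1100) {
  stopifnot(is(cube, "Hypercube"))
  keep <- cube@wavelengths >= wl_min & cube@wavelengths <= wl_max
  if (!any(keep))
    stop(sprintf("no bands in [%g, %g] nm", wl_min, wl_max))
  Hypercube(cube@data[, , keep, drop = FALSE], cube@wavelengths[keep],
            cube@metadata)
}
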