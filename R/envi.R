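# ENVI header + flat-binary raster I/O.
#
# The de-facto exchange format in hyperspectral imaging: a text header
# (<path>.hdr) describing a raw binary image (<path>.dat here). All three
# interleave dialects are understood; in memory the package always uses the
# (x, y, lambda) axis order, mapped onto ENVI's (lines, samples, bands).

.envi_types <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = TRUE),
  `3` = list(what = "integer", size = 4L, signed = TRUE),
  `4` = list(what = "numeric", size = 4L, signed = TRUE),
  `5` = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.envi_paths <- function(path) {
  # accept either the bare stem, the .hdr or the .dat path
  stem <- sub("\\.(hdr|dat|img)$", "", path)
  list(hdr = paste0(stem, ".hdr"), dat = paste0(stem, ".dat"))
}

.parse_envi_header <- function(hdr_path) {
  if (!file.exists(hdr_path)) {
    stop(sprintf("ENVI header not found: %s", hdr_path))
  }
  txt <- readLines(hdr_path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^\\s*ENVI\\s*$", txt[1L])) {
    stop(sprintf("not an ENVI header (missing ENVI magic line): %s", hdr_path))
  }
  body <- paste(txt[-1L], collapse = "\n")
  fields <- list()
  # key = { multi-line list }  or  key = scalar
  pat <- "(?ms)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\\n]*)$"
  m <- gregexpr(pat, body, perl = TRUE)[[1L]]
  if (m[1L] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(body, starts[i], starts[i] + lens[i] - 1L)
      key <- tolower(trimws(sub("(?ms)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=.*$",
                                "\\1", piece, perl = TRUE)))
      val <- trimws(sub("(?ms)^[^=]*=\\s*", "", piece, perl = TRUE))
      fields[[key]] <- val
    }
  }
  fields
}

.envi_num_list <- function(raw) {
  inner <- gsub("[{}]", "", raw)
  as.numeric(trimws(strsplit(inner, ",")[[1L]]))
}

.require_field <- function(fields, name) {
  if (is.null(fields[[name]])) {
    stop(sprintf("ENVI header is missing required field '%s'", name))
  }
  fields[[name]]
}

#' Read a hypercube from an ENVI header/binary pair
#'
#' @param path path to the `.hdr` file, the binary file, or their common stem.
#' @return a [hypercube()] in `(x, y, lambda)` order, independent of the
#'   on-disk interleave (BSQ, BIL or BIP).
#' @export
read_hypercube <- function(path) {
  p <- .envi_paths(path)
  f <- .parse_envi_header(p$hdr)
  samples <- as.integer(.require_field(f, "samples"))
  lines <- as.integer(.require_field(f, "lines"))
  bands <- as.integer(.require_field(f, "bands"))
  dtype <- as.character(as.integer(.require_field(f, "data type")))
  interleave <- tolower(trimws(.require_field(f, "interleave")))
  if (is.null(f[["wavelength"]])) {
    stop("ENVI header is missing required field 'wavelength'")
  }
  wl <- .envi_num_list(f[["wavelength"]])
  if (length(wl) != bands) {
    stop(sprintf("header lists %d wavelengths but declares %d bands",
                 length(wl), bands))
  }
  spec <- .envi_types[[dtype]]
  if (is.null(spec)) stop(sprintf("unsupported ENVI data type %s", dtype))
  n <- as.double(samples) * lines * bands
  fsize <- file.size(p$dat)
  if (is.na(fsize)) stop(sprintf("ENVI binary not found: %s", p$dat))
  if (fsize != n * spec$size) {
    stop(sprintf(
      "ENVI binary size mismatch: header declares %d x %d x %d (%s bytes), file has %s bytes",
      lines, samples, bands, format(n * spec$size, scientific = FALSE),
      format(fsize, scientific = FALSE)
    ))
  }
  con <- file(p$dat, "rb")
  on.exit(close(con))
  raw <- readBin(con, what = spec$what, n = n, size = spec$size,
                 signed = spec$signed, endian = "little")
  # file order -> array dims (fastest-varying first), then permute to (x,y,l)
  arr <- switch(interleave,
    bsq = aperm(array(raw, dim = c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(raw, dim = c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(raw, dim = c(bands, samples, lines)), c(3L, 2L, 1L)),
    stop(sprintf("unsupported interleave '%s'", interleave))
  )
  meta <- list()
  if (!is.null(f[["description"]])) {
    meta$description <- gsub("[{}]", "", f[["description"]])
  }
  hypercube(arr, wl, meta)
}

.format_envi_num <- function(x) {
  formatC(x, format = "g", digits = 12)
}

#' Write a hypercube as an ENVI header/binary pair
#'
#' Values are stored as little-endian 32-bit floats by default (the package's
#' convention for normalized reflectance); raw simulated camera counts can be
#' stored as 16-bit unsigned integers with `data_type = 12`.
#'
#' @param cube a [hypercube()].
#' @param path output stem (`.hdr` and `.dat` are appended).
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI numeric type code: 4 (float32, default), 5 (float64)
#'   or 12 (uint16).
#' @return the output stem, invisibly.
#' @export
write_hypercube <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                            data_type = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  spec <- .envi_types[[as.character(data_type)]]
  if (is.null(spec) || !data_type %in% c(4L, 5L, 12L)) {
    stop("data_type must be 4 (float32), 5 (float64) or 12 (uint16)")
  }
  p <- .envi_paths(path)
  d <- dim(cube$data)
  perm <- switch(interleave,
    bsq = c(2L, 1L, 3L), bil = c(2L, 3L, 1L), bip = c(3L, 2L, 1L))
  vec <- as.vector(aperm(cube$data, perm))
  hdr <- c(
    "ENVI",
    "description = { hyseclass hypercube }",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(.format_envi_num(cube$wavelengths), collapse = ", "), " }")
  )
  writeLines(hdr, p$hdr)
  con <- file(p$dat, "wb")
  on.exit(close(con))
  if (spec$what == "integer") {
    iv <- as.integer(round(vec))
    if (data_type == 12L) {
      if (any(iv < 0L) || any(iv > 65535L)) {
        stop("values outside [0, 65535] cannot be stored as uint16")
      }
      # writeBin has no unsigned 16-bit mode: wrap to the signed two's
      # complement bit pattern, which reads back correctly with signed=FALSE
      iv <- ifelse(iv > 32767L, iv - 65536L, iv)
    }
    writeBin(iv, con, size = spec$size, endian = "little")
  } else {
    writeBin(as.numeric(vec), con, size = spec$size, endian = "little")
  }
  invisible(sub("\\.dat$", "", p$dat))
}

#' Read a label map (single-band integer ENVI raster + JSON legend)
#'
#' @param path stem or `.hdr`/`.dat` path; a legend sidecar
#'   `<stem>.legend.json` must exist.
#' @return a [label_map()].
#' @export
read_label_map <- function(path) {
  p <- .envi_paths(path)
  f <- .parse_envi_header(p$hdr)
  samples <- as.integer(.require_field(f, "samples"))
  lines <- as.integer(.require_field(f, "lines"))
  bands <- as.integer(.require_field(f, "bands"))
  if (bands != 1L) stop("label maps must be single-band rasters")
  dtype <- as.character(as.integer(.require_field(f, "data type")))
  spec <- .envi_types[[dtype]]
  if (is.null(spec)) stop(sprintf("unsupported ENVI data type %s", dtype))
  legend_path <- paste0(sub("\\.dat$", "", p$dat), ".legend.json")
  if (!file.exists(legend_path)) {
    stop(sprintf("legend sidecar not found: %s", legend_path))
  }
  leg <- jsonlite::fromJSON(legend_path)
  legend <- stats::setNames(as.character(leg$name), as.character(leg$label))
  con <- file(p$dat, "rb")
  on.exit(close(con))
  raw <- readBin(con, what = spec$what, n = samples * lines, size = spec$size,
                 signed = spec$signed, endian = "little")
  labels <- t(array(raw, dim = c(samples, lines)))
  label_map(labels, legend)
}

#' Write a label map as a single-band int32 ENVI raster plus JSON legend
#'
#' @param map a [label_map()].
#' @param path output stem.
#' @return the output stem, invisibly.
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  p <- .envi_paths(path)
  d <- dim(map$labels)
  hdr <- c(
    "ENVI",
    "description = { hyseclass label map }",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    "bands = 1",
    "header offset = 0",
    "file type = ENVI Classification",
    "data type = 3",
    "interleave = bsq",
    "byte order = 0"
  )
  writeLines(hdr, p$hdr)
  con <- file(p$dat, "wb")
  writeBin(as.integer(t(map$labels)), con, size = 4L, endian = "little")
  close(con)
  stem <- sub("\\.dat$", "", p$dat)
  legend_df <- data.frame(
    label = as.integer(names(map$legend)),
    name = unname(map$legend),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(legend_df, paste0(stem, ".legend.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(stem)
}

#' Write a reference library to JSON
#' @param library a [reference_library()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_reference_library <- function(library, path) {
  stopifnot(inherits(library, "reference_library"))
  obj <- list(
    wavelengths = library$wavelengths,
    background_label = library$background_label,
    classes = lapply(seq_along(library$names), function(i) {
      list(
        name = library$names[i],
        rgb = as.numeric(library$rgb[i, ]),
        spectrum = as.numeric(library$spectra[i, ])
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reference library from JSON
#' @param path `.json` path written by [write_reference_library()].
#' @return a [reference_library()].
#' @export
read_reference_library <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  nm <- vapply(obj$classes, `[[`, character(1L), "name")
  sp <- do.call(rbind, lapply(obj$classes, function(cl) as.numeric(cl$spectrum)))
  rgb <- do.call(rbind, lapply(obj$classes, function(cl) as.numeric(cl$rgb)))
  reference_library(nm, sp, rgb, as.numeric(obj$wavelengths))
}
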