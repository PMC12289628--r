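## Minimal uncompressed grayscale TIFF stack I/O (little-endian, 8- or
## 16-bit, one page per slice along the vertical axis). No R TIFF package is
## assumed; the subset written here is what CT workstations export for
## reconstructed stacks.

tiff_types <- c(BYTE = 1L, SHORT = 3L, LONG = 4L)

#' Write a volume or mask as a multi-page TIFF stack with a voxel-size sidecar
#'
#' Slices along axis 1 (vertical) become pages; intensities are rounded and
#' clipped to the chosen bit depth (masks are written as 0/255). A JSON
#' sidecar `<path>.json` declares the voxel size in micrometers.
#'
#' @param x a [voxel_grid()] or [phase_mask()].
#' @param path output file path (`.tif`).
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(x, path, bits = 8) {
  if (!bits %in% c(8, 16)) stop("'bits' must be 8 or 16")
  a <- x$data
  if (inherits(x, "phase_mask")) a <- a * 255L
  d <- dim(a)
  maxv <- 2^bits - 1
  a <- round(pmin(pmax(a, 0), maxv))
  width <- d[3]; height <- d[2]
  bytes_px <- bits / 8
  strip_size <- width * height * bytes_px
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(42L), con, size = 2, endian = "little")
  data_start <- 8L
  first_ifd <- data_start + d[1] * strip_size
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  for (s in seq_len(d[1])) {
    page <- t(a[s, , ])   # row-major: rows = axis 2
    writeBin(as.integer(page), con, size = bytes_px, endian = "little")
  }
  n_entries <- 8L
  ifd_size <- 2 + n_entries * 12 + 4
  entry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(tiff_types[[type]], con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == "SHORT") {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  for (s in seq_len(d[1])) {
    entry_offset <- first_ifd + (s - 1) * ifd_size
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256, "LONG", width)
    entry(257, "LONG", height)
    entry(258, "SHORT", bits)
    entry(259, "SHORT", 1)               # no compression
    entry(262, "SHORT", 1)               # BlackIsZero
    entry(273, "LONG", data_start + (s - 1) * strip_size)
    entry(278, "LONG", height)
    entry(279, "LONG", strip_size)
    nxt <- if (s < d[1]) entry_offset + ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  jsonlite::write_json(list(voxel_size_um = x$voxel_size,
                            vertical_axis = 1,
                            phase = if (inherits(x, "phase_mask")) x$phase
                                    else NULL),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

read_u <- function(con, size) readBin(con, "integer", 1, size = size,
                                      signed = size >= 4, endian = "little")

#' Read a multi-page grayscale TIFF stack
#'
#' Supports the uncompressed little-endian subset written by
#' [write_tiff_stack()] (and by typical CT reconstruction exports): 8- or
#' 16-bit grayscale, strip layout. Voxel size is taken from the `.json`
#' sidecar when present, else from `voxel_size`.
#'
#' @param path TIFF file path.
#' @param voxel_size fallback voxel size in micrometers.
#' @return A [voxel_grid()].
#' @export
read_tiff_stack <- function(path, voxel_size = NULL) {
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    voxel_size <- meta$voxel_size_um
  }
  if (is.null(voxel_size)) stop("no voxel size: provide 'voxel_size' or a sidecar")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (magic != "II") stop("only little-endian ('II') TIFF is supported")
  if (read_u(con, 2) != 42L) stop("not a TIFF file")
  ifd_off <- read_u(con, 4)
  pages <- list()
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n <- read_u(con, 2)
    tags <- list()
    for (e in seq_len(n)) {
      tag <- read_u(con, 2); type <- read_u(con, 2)
      count <- read_u(con, 4)
      raw4 <- readBin(con, "raw", 4)
      val <- if (count == 1 && type %in% c(1L, 3L, 4L)) {
        sz <- c(1L, 0L, 2L, 4L)[type]
        sum(as.integer(raw4[seq_len(sz)]) * 256^(seq_len(sz) - 1))
      } else {
        off <- sum(as.integer(raw4) * 256^(0:3))
        list(offset = off, count = count, type = type)
      }
      tags[[as.character(tag)]] <- val
    }
    nxt <- read_u(con, 4)
    width <- tags[["256"]]; height <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 8L else tags[["258"]]
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
      stop("compressed TIFF is not supported")
    get_vec <- function(v) {
      if (!is.list(v)) return(v)
      here <- seek(con)
      seek(con, v$offset)
      sz <- c(1L, 0L, 2L, 4L)[v$type]
      out <- readBin(con, "integer", v$count, size = sz,
                     signed = sz >= 4, endian = "little")
      seek(con, here)
      out
    }
    offs <- get_vec(tags[["273"]])
    cnts <- get_vec(tags[["279"]])
    px <- integer(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      nv <- cnts[s] / (bits / 8)
      px <- c(px, readBin(con, "integer", nv, size = bits / 8,
                          signed = FALSE, endian = "little"))
    }
    pages[[length(pages) + 1L]] <- t(matrix(px, nrow = width, ncol = height))
    ifd_off <- nxt
  }
  d1 <- length(pages)
  d2 <- nrow(pages[[1]]); d3 <- ncol(pages[[1]])
  a <- array(0, c(d1, d2, d3))
  for (s in seq_len(d1)) a[s, , ] <- pages[[s]]
  voxel_grid(a, voxel_size)
}

#' Read a phantom specification from a JSON config file
#'
#' The JSON mirrors the fields of [phantom_spec()]; primitive coordinate
#' fields are numeric arrays.
#'
#' @param path JSON file path.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pdf <- j$primitives
  prims <- lapply(seq_len(nrow(pdf)), function(i) {
    p <- lapply(pdf, function(col) if (is.list(col)) col[[i]] else col[i])
    p[!vapply(p, function(v) is.null(v) || all(is.na(v)), logical(1))]
  })
  lev <- lapply(j$phase_levels, as.numeric)
  phantom_spec(grid_shape = j$grid_shape, voxel_size = j$voxel_size,
               primitives = prims, phase_levels = lev,
               saturation = j$saturation %||% 0,
               embolism_rate = j$embolism_rate %||% 0,
               rng_seed = j$rng_seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ground truth as CSV plus a global JSON summary
#'
#' @param truth ground-truth bundle from a phantom constructor.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_ground_truth <- function(truth, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, "_primitives.csv"))
  js <- file.path(dir, paste0(prefix, "_global.json"))
  write.csv(truth$primitives, csv, row.names = FALSE)
  g <- truth$global
  g$class_counts <- as.list(g$class_counts)
  jsonlite::write_json(g, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
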