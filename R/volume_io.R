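# Volume containers and lossless TIFF / CSV / JSON I/O.
#
# Storage convention (load-bearing for every metric in the package):
# arrays are indexed (z, y, x); z = 0-based depth index with z = 0 the top,
# air-facing surface; depth in micrometres of the top face of voxel z is
# z * voxel_um. TIFF pages are written z-ascending from the top surface and
# this is recorded in the ImageDescription metadata and asserted on read.

#' OCT intensity volume
#'
#' A 3-D grid of 16-bit intensities (0--65535) with isotropic voxel size.
#' Axis order is fixed to (z, y, x); page/plane `z = 1` is the top,
#' air-facing surface of the model.
#'
#' @param data integer array, dim (nz, ny, nx), values in \[0, 65535\].
#' @param voxel_um isotropic voxel edge length in micrometres.
#' @param provenance free-text metadata string.
#' @return an `oct_volume` object.
#' @export
oct_volume <- function(data, voxel_um = 1, provenance = "") {
  d <- assert_dims3(data, "intensity data")
  if (any(d < 8L)) stop_("each volume dimension must be >= 8 voxels")
  if (!is.numeric(voxel_um) || length(voxel_um) != 1L || voxel_um <= 0)
    stop_("voxel_um must be a positive scalar")
  voxel_um <- as.numeric(voxel_um)
  if (anyNA(data)) stop_("intensity data contains NA")
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 65535)
    stop_("intensities must lie within [0, 65535]")
  if (!is.integer(data)) {
    if (any(data != round(data))) stop_("intensities must be integers")
    storage.mode(data) <- "integer"
  }
  structure(list(data = data, voxel_um = voxel_um, provenance = provenance),
            class = "oct_volume")
}

#' Semantic label volume
#'
#' Per-voxel class codes: 0 medium/background, 1 cancer, 2 stromal cell,
#' 3 collagen matrix. Same axis and depth conventions as [oct_volume()].
#'
#' @param data integer array with codes in \{0, 1, 2, 3\}.
#' @param voxel_um isotropic voxel size in micrometres.
#' @return a `label_volume` object.
#' @export
label_volume <- function(data, voxel_um = 1) {
  assert_dims3(data, "label data")
  if (anyNA(data)) stop_("label data contains NA")
  voxel_um <- as.numeric(voxel_um)
  if (!all(data %in% 0:3))
    stop_("label codes must be within {0 medium, 1 cancer, 2 stromal cell, 3 matrix}")
  if (!is.integer(data)) storage.mode(data) <- "integer"
  structure(list(data = data, voxel_um = voxel_um), class = "label_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oct_volume> %d x %d x %d voxels (z,y,x) @ %g um, range [%d, %d]\n",
              d[1], d[2], d[3], x$voxel_um, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  tab <- tabulate(as.integer(x$data) + 1L, 4L)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %g um | medium %d, cancer %d, stromal %d, matrix %d\n",
              d[1], d[2], d[3], x$voxel_um, tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

## ---- minimal baseline TIFF codec (uncompressed, little-endian, grayscale) ----
## No TIFF-capable R package is available in this stack, so the subset of
## baseline TIFF needed here (multi-page, 8/16-bit unsigned, strip-based,
## uncompressed) is implemented directly. Interoperability is tested against
## an independent TIFF implementation in the test-suite.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               samples = 277L, rows_per_strip = 278L, strip_bytes = 279L,
               sample_format = 339L)

uint_to_raw <- function(v, size) {
  v <- as.numeric(v)
  if (size == 1L) return(as.raw(v))
  if (size == 2L) {
    r <- raw(2L * length(v))
    r[c(TRUE, FALSE)] <- as.raw(v %% 256)
    r[c(FALSE, TRUE)] <- as.raw(v %/% 256)
  } else {
    r <- raw(4L * length(v))
    r[seq(1L, length(r), 4L)] <- as.raw(v %% 256)
    r[seq(2L, length(r), 4L)] <- as.raw((v %/% 256) %% 256)
    r[seq(3L, length(r), 4L)] <- as.raw((v %/% 65536) %% 256)
    r[seq(4L, length(r), 4L)] <- as.raw(v %/% 16777216)
  }
  r
}

raw_to_uint <- function(r, size) {
  if (size == 1L) return(as.integer(r))
  m <- matrix(as.integer(r), nrow = size)
  if (size == 2L) m[1, ] + 256 * m[2, ]
  else m[1, ] + 256 * m[2, ] + 65536 * m[3, ] + 16777216 * m[4, ]
}

tiff_entry <- function(tag, type, count, value_raw) {
  # value_raw must already be <= 4 bytes (inline) here
  stopifnot(length(value_raw) <= 4L)
  c(uint_to_raw(tag, 2L), uint_to_raw(type, 2L), uint_to_raw(count, 4L),
    value_raw, raw(4L - length(value_raw)))
}

# Write pages (list of integer matrices, row = y, col = x) as a multi-page
# grayscale TIFF. bits is 8 or 16; description (JSON string) goes on page 1.
tiff_write_pages <- function(pages, path, bits, description) {
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  bytes_pp <- bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(uint_to_raw(42L, 2L), con)
  # layout per page: [pixel data][description bytes (page 1)][IFD]
  # first IFD offset computed from page-1 data size
  desc_raw <- c(charToRaw(description), as.raw(0L))
  npix <- ny * nx
  offset <- 8L  # running file offset after header
  page_plan <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    data_off <- offset
    dlen <- npix * bytes_pp
    desc_off <- data_off + dlen
    dl <- if (i == 1L) length(desc_raw) else 0L
    ifd_off <- desc_off + dl
    has_desc <- i == 1L
    n_entries <- if (has_desc) 11L else 10L
    ifd_len <- 2L + 12L * n_entries + 4L
    page_plan[[i]] <- list(data_off = data_off, desc_off = desc_off,
                           ifd_off = ifd_off, has_desc = has_desc)
    offset <- ifd_off + ifd_len
  }
  writeBin(uint_to_raw(page_plan[[1]]$ifd_off, 4L), con)
  for (i in seq_along(pages)) {
    pl <- page_plan[[i]]
    pg <- pages[[i]]
    # row-major pixel order: transpose so x varies fastest
    writeBin(uint_to_raw(as.vector(t(pg)), bytes_pp), con)
    if (pl$has_desc) writeBin(desc_raw, con)
    entries <- list(
      tiff_entry(TIFF_TAGS["width"], 4L, 1L, uint_to_raw(nx, 4L)),
      tiff_entry(TIFF_TAGS["length"], 4L, 1L, uint_to_raw(ny, 4L)),
      tiff_entry(TIFF_TAGS["bits"], 3L, 1L, uint_to_raw(bits, 2L)),
      tiff_entry(TIFF_TAGS["compression"], 3L, 1L, uint_to_raw(1L, 2L)),
      tiff_entry(TIFF_TAGS["photometric"], 3L, 1L, uint_to_raw(1L, 2L))
    )
    if (pl$has_desc)
      entries <- c(entries, list(tiff_entry(TIFF_TAGS["description"], 2L,
                                            length(desc_raw),
                                            uint_to_raw(pl$desc_off, 4L))))
    entries <- c(entries, list(
      tiff_entry(TIFF_TAGS["strip_offsets"], 4L, 1L, uint_to_raw(pl$data_off, 4L)),
      tiff_entry(TIFF_TAGS["samples"], 3L, 1L, uint_to_raw(1L, 2L)),
      tiff_entry(TIFF_TAGS["rows_per_strip"], 4L, 1L, uint_to_raw(ny, 4L)),
      tiff_entry(TIFF_TAGS["strip_bytes"], 4L, 1L,
                 uint_to_raw(npix * bytes_pp, 4L)),
      tiff_entry(TIFF_TAGS["sample_format"], 3L, 1L, uint_to_raw(1L, 2L))
    ))
    writeBin(uint_to_raw(length(entries), 2L), con)
    for (e in entries) writeBin(e, con)
    next_off <- if (i < length(pages)) page_plan[[i + 1L]]$ifd_off else 0L
    writeBin(uint_to_raw(next_off, 4L), con)
  }
  invisible(path)
}

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

# Read all pages of a little-endian baseline TIFF. Returns list(pages = list
# of integer matrices, bits, description).
tiff_read_pages <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  sz <- file.info(path)$size
  raw_all <- readBin(path, "raw", n = sz)
  if (length(raw_all) < 8L) stop_("not a TIFF file (too short): %s", path)
  byte_order <- rawToChar(raw_all[1:2])
  if (byte_order == "MM")
    stop_("big-endian TIFF is not supported by this reader")
  if (byte_order != "II" || raw_to_uint(raw_all[3:4], 2L) != 42)
    stop_("not a TIFF file: %s", path)
  u <- function(from, size) raw_to_uint(raw_all[from:(from + size - 1L)], size)
  ifd_off <- u(5L, 4L)
  pages <- list()
  description <- NULL
  page_no <- 0L
  shape0 <- NULL
  bits0 <- NULL
  while (ifd_off != 0L) {
    page_no <- page_no + 1L
    if (ifd_off + 1L > sz) stop_("IFD offset beyond end of file (page %d)", page_no)
    n_entries <- u(ifd_off + 1L, 2L)
    tags <- list()
    for (e in seq_len(n_entries)) {
      at <- ifd_off + 1L + 2L + (e - 1L) * 12L
      tag <- u(at, 2L); type <- u(at + 2L, 2L); count <- u(at + 4L, 4L)
      tsize <- unname(tiff_type_size[as.character(type)])
      if (is.na(tsize)) next  # skip RATIONAL and friends
      total <- tsize * count
      voff <- if (total <= 4L) at + 8L else u(at + 8L, 4L) + 1L
      if (voff + total - 1L > sz)
        stop_("tag %d data beyond end of file (page %d)", tag, page_no)
      vals <- if (type == 2L) {
        rawToChar(raw_all[voff:(voff + count - 2L)])
      } else {
        raw_to_uint(raw_all[voff:(voff + total - 1L)], tsize)
      }
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop_("missing TIFF tag %d (page %d)", tag, page_no)
        default
      } else v
    }
    nx <- need(256L); ny <- need(257L)
    samples <- unique(need(277L, 1L))
    if (length(samples) != 1L || samples != 1)
      stop_("multi-sample TIFF (SamplesPerPixel=%s) is not supported", samples[1])
    bits <- unique(need(258L, 1L))
    if (length(bits) != 1L) stop_("mixed per-sample bit depths (page %d)", page_no)
    comp <- need(259L, 1L)
    if (comp != 1L) stop_("compressed TIFF (compression=%d) is not supported", comp)
    fmt <- unique(need(339L, 1L))
    if (length(fmt) != 1L || fmt != 1L)
      stop_("non-integer sample format (SampleFormat=%d, page %d)", fmt[1], page_no)
    if (!bits %in% c(8L, 16L))
      stop_("unsupported bit depth %d (page %d)", bits, page_no)
    if (page_no == 1L) {
      shape0 <- c(ny, nx); bits0 <- bits
      description <- tags[["270"]]
    } else {
      if (!identical(c(ny, nx), shape0))
        stop_("mixed page shapes: page %d is %dx%d, page 1 is %dx%d",
              page_no, ny, nx, shape0[1], shape0[2])
      if (bits != bits0) stop_("mixed bit depths across pages")
    }
    offs <- need(273L); cnts <- need(279L, ny * nx * bits / 8L)
    if (length(cnts) != length(offs)) stop_("strip bookkeeping mismatch (page %d)", page_no)
    bytes_pp <- bits / 8L
    buf <- raw(ny * nx * bytes_pp)
    pos <- 1L
    for (s in seq_along(offs)) {
      from <- offs[s] + 1L
      if (from + cnts[s] - 1L > sz)
        stop_("truncated pixel data on page %d (strip %d)", page_no, s)
      buf[pos:(pos + cnts[s] - 1L)] <- raw_all[from:(from + cnts[s] - 1L)]
      pos <- pos + cnts[s]
    }
    vals <- raw_to_uint(buf, bytes_pp)
    pages[[page_no]] <- matrix(as.integer(vals), nrow = ny, ncol = nx,
                               byrow = TRUE)
    ifd_off <- {
      at <- ifd_off + 1L + 2L + n_entries * 12L
      u(at, 4L)
    }
  }
  list(pages = pages, bits = bits0, description = description)
}

volume_metadata_json <- function(voxel_um, kind) {
  jsonlite::toJSON(list(software = "octinvasion", kind = kind,
                        voxel_um = voxel_um, axis_order = "zyx",
                        z_direction = "top-down"),
                   auto_unbox = TRUE)
}

pages_to_array <- function(pages) {
  d <- c(length(pages), nrow(pages[[1]]), ncol(pages[[1]]))
  arr <- array(0L, d)
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

#' Write / read an OCT intensity volume as multi-page 16-bit TIFF
#'
#' Pages are written z-ascending from the top surface; voxel size and the
#' depth convention are stored in the ImageDescription metadata of the first
#' page and asserted on read. I/O is lossless: `read_volume(write_volume(v))`
#' reproduces the intensity grid exactly.
#'
#' @param volume an [oct_volume()].
#' @param path file path.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   [oct_volume()].
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "oct_volume")) stop_("expected an oct_volume")
  d <- dim(volume$data)
  pages <- lapply(seq_len(d[1]), function(z) volume$data[z, , ])
  tiff_write_pages(pages, path, 16L,
                   volume_metadata_json(volume$voxel_um, "intensity"))
  invisible(path)
}

#' @param voxel_um fallback voxel size if the file carries no metadata.
#' @rdname write_volume
#' @export
read_volume <- function(path, voxel_um = NULL) {
  tf <- tiff_read_pages(path)
  if (tf$bits != 16L)
    stop_("format mismatch: %d-bit TIFF is not an intensity volume (16-bit); use read_labels() for label stacks",
          tf$bits)
  meta <- parse_volume_metadata(tf$description)
  vx <- meta$voxel_um %||% voxel_um
  if (is.null(vx))
    stop_("voxel size unknown: file has no metadata and voxel_um not given")
  oct_volume(pages_to_array(tf$pages), voxel_um = vx,
             provenance = sprintf("read from %s", path))
}

parse_volume_metadata <- function(description) {
  if (is.null(description)) return(list())
  meta <- tryCatch(jsonlite::fromJSON(description), error = function(e) NULL)
  if (is.null(meta) || !is.list(meta)) return(list())
  if (!is.null(meta$z_direction) && !identical(meta$z_direction, "top-down"))
    stop_("TIFF metadata declares z_direction '%s'; this package requires pages z-ascending from the top surface",
          meta$z_direction)
  meta
}

#' Write / read a label volume as multi-page 8-bit TIFF with JSON sidecar
#'
#' The sidecar (`<path>.json`) records the class-code mapping
#' \{0 medium, 1 cancer, 2 stromal cell, 3 matrix\} and the voxel size.
#'
#' @param labels a [label_volume()].
#' @param path file path (sidecar written at `paste0(path, ".json")`).
#' @return `write_labels` returns `path` invisibly; `read_labels` a
#'   [label_volume()].
#' @export
write_labels <- function(labels, path) {
  if (!inherits(labels, "label_volume")) stop_("expected a label_volume")
  d <- dim(labels$data)
  pages <- lapply(seq_len(d[1]), function(z) labels$data[z, , ])
  tiff_write_pages(pages, path, 8L,
                   volume_metadata_json(labels$voxel_um, "labels"))
  jsonlite::write_json(
    list(classes = list(`0` = "medium", `1` = "cancer",
                        `2` = "stromal cell", `3` = "matrix"),
         voxel_um = labels$voxel_um, axis_order = "zyx",
         z_direction = "top-down"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, voxel_um = NULL) {
  tf <- tiff_read_pages(path)
  if (tf$bits != 8L)
    stop_("format mismatch: %d-bit TIFF is not a label stack (8-bit); use read_volume() for intensity volumes",
          tf$bits)
  meta <- parse_volume_metadata(tf$description)
  sidecar <- paste0(path, ".json")
  if (is.null(meta$voxel_um) && file.exists(sidecar)) {
    sc <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
    meta$voxel_um <- sc$voxel_um
  }
  vx <- meta$voxel_um %||% voxel_um
  if (is.null(vx))
    stop_("voxel size unknown: file has no metadata and voxel_um not given")
  label_volume(pages_to_array(tf$pages), voxel_um = vx)
}

METRIC_COLUMNS <- c("model_id", "cell_line", "stroma", "day", "replicate",
                    "v_total_um3", "v_original_um3", "v_iccr_um3",
                    "hif_area_um2", "mass_invasion_index",
                    "depth_of_invasion_um")

#' Write / read the per-model invasion metrics table
#'
#' CSV with one row per model replicate and the fixed column set
#' `model_id, cell_line, stroma, day, replicate, v_total_um3, v_original_um3,
#' v_iccr_um3, hif_area_um2, mass_invasion_index, depth_of_invasion_um`.
#' Floats are written with 17 significant digits so the round trip is
#' loss-free.
#'
#' @param table data.frame with the columns above (extra columns are kept).
#' @param path file path.
#' @return `write_metrics` returns `path` invisibly; `read_metrics` the table.
#' @export
write_metrics <- function(table, path) {
  missing_cols <- setdiff(METRIC_COLUMNS, names(table))
  if (length(missing_cols))
    stop_("metrics table is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  num_cols <- vapply(table, is.numeric, logical(1))
  bad <- vapply(table[num_cols], function(col) any(!is.finite(col)), logical(1))
  if (any(bad))
    stop_("non-finite values in metric columns: %s",
          paste(names(bad)[bad], collapse = ", "))
  out <- table
  for (nm in names(out)[num_cols])
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(METRIC_COLUMNS, names(tab))
  if (length(missing_cols))
    stop_("metrics file is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  for (nm in METRIC_COLUMNS[6:11]) tab[[nm]] <- as.double(tab[[nm]])
  tab
}
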