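# Volume file I/O: MetaImage (.mhd + .raw) and multi-page uncompressed TIFF.
# Both codecs are self-contained: the pre-installed stack has no R package
# for either format. MetaImage is little-endian raw with a text header;
# TIFF output is baseline classic TIFF, 32-bit IEEE float, one strip per
# page, spacing recorded in the first page's ImageDescription.

#' Write / read a voxel or label volume
#'
#' Format is chosen by extension: `.mhd` writes a MetaImage header plus a
#' sibling `.raw` file; `.tif` / `.tiff` writes a multi-page uncompressed
#' TIFF (one page per z slice). `read_volume(write_volume(v, path))`
#' reproduces grayvalues exactly for integer-valued and float32-representable
#' data and the spacing to at least 6 decimals.
#'
#' @param vol A `voxel_volume` or `label_volume`.
#' @param path Output path (`.mhd`, `.tif` or `.tiff`).
#' @param element_type MetaImage element type: `MET_FLOAT` (default for
#'   grayscale), `MET_DOUBLE`, or `MET_UCHAR` (default for labels).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   `label_volume` (MET_UCHAR with valid class codes) or `voxel_volume`.
#' @export
write_volume <- function(vol, path, element_type = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mhd = write_mhd(vol, path, element_type),
    tif = ,
    tiff = write_tiff(vol, path),
    stop(sprintf("unknown volume extension '.%s' (use .mhd, .tif or .tiff)",
                 ext), call. = FALSE))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mhd = read_mhd(path),
    tif = ,
    tiff = read_tiff(path),
    stop(sprintf("unknown volume extension '.%s' (use .mhd, .tif or .tiff)",
                 ext), call. = FALSE))
}

write_mhd <- function(vol, path, element_type = NULL) {
  is_label <- inherits(vol, "label_volume")
  if (is.null(element_type)) {
    element_type <- if (is_label) "MET_UCHAR" else "MET_FLOAT"
  }
  stopifnot(element_type %in% c("MET_UCHAR", "MET_FLOAT", "MET_DOUBLE"))
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  dm <- dim(vol$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", dm[1], dm[2], dm[3]),
    sprintf("ElementSpacing = %.9f %.9f %.9f",
            vol$spacing, vol$spacing, vol$spacing),
    sprintf("Offset = %.9f %.9f %.9f",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  v <- as.vector(vol$data)
  if (element_type == "MET_UCHAR") {
    writeBin(as.integer(v), con, size = 1L, endian = "little")
  } else if (element_type == "MET_FLOAT") {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 8L, endian = "little")
  }
  invisible(path)
}

read_mhd <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_,
                 character(1))
  h <- stats::setNames(trimws(vals), keys)
  need <- c("DimSize", "ElementType", "ElementDataFile")
  if (!all(need %in% names(h))) {
    stop("corrupt MetaImage header: missing ",
         paste(setdiff(need, names(h)), collapse = ", "), call. = FALSE)
  }
  dm <- as.integer(strsplit(h[["DimSize"]], "\\s+")[[1]])
  if (length(dm) != 3 || any(is.na(dm)) || any(dm <= 0)) {
    stop("corrupt MetaImage header: bad DimSize", call. = FALSE)
  }
  spacing <- if ("ElementSpacing" %in% names(h)) {
    as.numeric(strsplit(h[["ElementSpacing"]], "\\s+")[[1]])[1]
  } else 1.0
  origin <- if ("Offset" %in% names(h)) {
    as.numeric(strsplit(h[["Offset"]], "\\s+")[[1]])
  } else c(0, 0, 0)
  et <- h[["ElementType"]]
  n <- prod(dm)
  con <- file(file.path(dirname(path), h[["ElementDataFile"]]), "rb")
  on.exit(close(con))
  v <- switch(et,
    MET_UCHAR = readBin(con, "integer", n, size = 1L, signed = FALSE,
                        endian = "little"),
    MET_FLOAT = readBin(con, "numeric", n, size = 4L, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop("unsupported ElementType: ", et, call. = FALSE))
  if (length(v) != n) {
    stop("corrupt MetaImage data: expected ", n, " elements, got ",
         length(v), call. = FALSE)
  }
  arr <- array(v, dim = dm)
  if (et == "MET_UCHAR" && all(v %in% MATERIAL_CLASSES)) {
    label_volume(arr, spacing, origin)
  } else {
    voxel_volume(arr, spacing, origin)
  }
}

# --- minimal classic TIFF (little-endian, uncompressed, float32) ----------

tiff_entry <- function(con, tag, type, count, value_raw) {
  writeBin(as.integer(tag), con, size = 2L, endian = "little")
  writeBin(as.integer(type), con, size = 2L, endian = "little")
  writeBin(as.integer(count), con, size = 4L, endian = "little")
  stopifnot(length(value_raw) == 4L)
  writeBin(value_raw, con)
}

raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                endian = "little")
raw_u16pad <- function(x) c(writeBin(as.integer(x), raw(), size = 2L,
                                     endian = "little"), as.raw(c(0, 0)))

write_tiff <- function(vol, path) {
  dm <- dim(vol$data)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  desc <- sprintf("mgscaffold spacing_mm=%.9f origin_mm=%.9f,%.9f,%.9f",
                  vol$spacing, vol$origin[1], vol$origin[2], vol$origin[3])
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  strip_bytes <- nx * ny * 4L
  desc_off <- 8L + 4L  # after header + first-IFD pointer placeholder? no:
  # layout: [8-byte header][description][pages: strip data + IFD]...
  # first IFD offset = 8 + len(description)+... compute below
  pos <- 8L
  first_ifd_at <- NA_integer_
  # header written; IFD offset patched at the end via seek
  writeBin(0L, con, size = 4L, endian = "little")  # placeholder
  pos <- 8L
  writeBin(desc_raw, con)
  desc_pos <- pos
  pos <- pos + length(desc_raw)
  n_entries_first <- 11L
  n_entries_rest <- 10L
  ifd_size <- function(ne) 2L + ne * 12L + 4L
  ifd_offsets <- integer(nz)
  v <- as.vector(vol$data)
  for (z in seq_len(nz)) {
    strip_off <- pos
    slice <- v[((z - 1L) * nx * ny + 1L):(z * nx * ny)]
    writeBin(as.numeric(slice), con, size = 4L, endian = "little")
    pos <- pos + strip_bytes
    ifd_offsets[z] <- pos
    ne <- if (z == 1L) n_entries_first else n_entries_rest
    writeBin(as.integer(ne), con, size = 2L, endian = "little")
    tiff_entry(con, 256L, 4L, 1L, raw_u32(nx))            # ImageWidth
    tiff_entry(con, 257L, 4L, 1L, raw_u32(ny))            # ImageLength
    tiff_entry(con, 258L, 3L, 1L, raw_u16pad(32L))        # BitsPerSample
    tiff_entry(con, 259L, 3L, 1L, raw_u16pad(1L))         # Compression
    tiff_entry(con, 262L, 3L, 1L, raw_u16pad(1L))         # Photometric
    if (z == 1L) {
      tiff_entry(con, 270L, 2L, length(desc_raw), raw_u32(desc_pos))
    }
    tiff_entry(con, 273L, 4L, 1L, raw_u32(strip_off))     # StripOffsets
    tiff_entry(con, 277L, 3L, 1L, raw_u16pad(1L))         # SamplesPerPixel
    tiff_entry(con, 278L, 4L, 1L, raw_u32(ny))            # RowsPerStrip
    tiff_entry(con, 279L, 4L, 1L, raw_u32(strip_bytes))   # StripByteCounts
    tiff_entry(con, 339L, 3L, 1L, raw_u16pad(3L))         # SampleFormat
    next_ifd <- if (z == nz) 0L else pos + ifd_size(ne) + strip_bytes
    writeBin(as.integer(next_ifd), con, size = 4L, endian = "little")
    pos <- pos + ifd_size(ne)
  }
  seek(con, 4L, "start", rw = "write")
  writeBin(ifd_offsets[1], con, size = 4L, endian = "little")
  invisible(path)
}

read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || u16(2L) != 42L) {
    stop("corrupt TIFF: bad header (only little-endian classic TIFF supported)",
         call. = FALSE)
  }
  ifd <- u32(4L)
  slices <- list()
  spacing <- 1.0
  origin <- c(0, 0, 0)
  while (ifd != 0L) {
    ne <- u16(ifd)
    tags <- list()
    for (e in seq_len(ne)) {
      base <- ifd + 2L + (e - 1L) * 12L
      tag <- u16(base)
      type <- u16(base + 2L)
      count <- u32(base + 4L)
      val <- if (type == 3L && count == 1L) u16(base + 8L) else u32(base + 8L)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val, voff = base + 8L)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) {
      stop("corrupt TIFF: IFD missing required tags", call. = FALSE)
    }
    nx <- tags[["256"]]$value; ny <- tags[["257"]]$value
    comp <- if ("259" %in% names(tags)) tags[["259"]]$value else 1L
    if (comp != 1L) stop("unsupported TIFF: compressed data", call. = FALSE)
    bits <- if ("258" %in% names(tags)) tags[["258"]]$value else 1L
    sfmt <- if ("339" %in% names(tags)) tags[["339"]]$value else 1L
    nstrip <- tags[["273"]]$count
    offs <- if (nstrip == 1L) tags[["273"]]$value else {
      vapply(seq_len(nstrip) - 1L,
             function(i) u32(tags[["273"]]$value + 4L * i), numeric(1))
    }
    cnts <- if (nstrip == 1L) tags[["279"]]$value else {
      vapply(seq_len(nstrip) - 1L,
             function(i) u32(tags[["279"]]$value + 4L * i), numeric(1))
    }
    buf <- unlist(lapply(seq_along(offs), function(i) {
      raw[(offs[i] + 1L):(offs[i] + cnts[i])]
    }))
    px <- if (bits == 32L && sfmt == 3L) {
      readBin(buf, "numeric", nx * ny, size = 4L, endian = "little")
    } else if (bits == 8L) {
      readBin(buf, "integer", nx * ny, size = 1L, signed = FALSE)
    } else {
      stop(sprintf("unsupported TIFF sample: %d-bit format %d", bits, sfmt),
           call. = FALSE)
    }
    if ("270" %in% names(tags)) {
      d <- tags[["270"]]
      doff <- if (d$count > 4L) d$value else d$voff
      txt <- rawToChar(raw[(doff + 1L):(doff + d$count)])
      txt <- sub("\\x00.*$", "", txt)
      m <- regmatches(txt, regexec("spacing_mm=([0-9.eE+-]+)", txt))[[1]]
      if (length(m) == 2) spacing <- as.numeric(m[2])
      m <- regmatches(txt, regexec(
        "origin_mm=([0-9.eE+-]+),([0-9.eE+-]+),([0-9.eE+-]+)", txt))[[1]]
      if (length(m) == 4) origin <- as.numeric(m[2:4])
    }
    slices[[length(slices) + 1L]] <- matrix(px, nrow = nx, ncol = ny)
    ifd <- u32(ifd + 2L + ne * 12L)
  }
  arr <- array(unlist(slices),
               dim = c(dim(slices[[1]]), length(slices)))
  voxel_volume(arr, spacing, origin)
}
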