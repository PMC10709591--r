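#' Read and write CT volumes
#'
#' Supports MetaImage (`.mha` single-file, `.mhd` + `.raw`) and NIfTI-1
#' (`.nii`, `.nii.gz`). Spacing and origin are preserved; HU values are
#' stored as written (64-bit float by default, so a write/read round trip is
#' bitwise exact). Only 3D volumes are accepted.
#'
#' @param path file path; the extension selects the format.
#' @param volume a `volume_grid` (for `write_volume`).
#' @param dtype storage type: "double", "float" or "short".
#' @return `read_volume`: a `volume_grid`. `write_volume`: `path`, invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lp <- tolower(path)
  if (grepl("\\.(mha|mhd)$", lp)) read_metaimage(path)
  else if (grepl("\\.nii(\\.gz)?$", lp)) read_nifti(path)
  else stop("unsupported volume format (use .mha, .mhd, .nii or .nii.gz): ", path)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path, dtype = c("double", "float", "short")) {
  stopifnot(inherits(volume, "volume_grid"))
  dtype <- match.arg(dtype)
  lp <- tolower(path)
  if (grepl("\\.(mha|mhd)$", lp)) write_metaimage(volume, path, dtype)
  else if (grepl("\\.nii(\\.gz)?$", lp)) write_nifti(volume, path, dtype)
  else stop("unsupported volume format (use .mha, .mhd, .nii or .nii.gz): ", path)
  invisible(path)
}

# ---- MetaImage -------------------------------------------------------------

met_types <- list(MET_SHORT = list(size = 2L, what = "integer"),
                  MET_USHORT = list(size = 2L, what = "integer"),
                  MET_INT = list(size = 4L, what = "integer"),
                  MET_FLOAT = list(size = 4L, what = "numeric"),
                  MET_DOUBLE = list(size = 8L, what = "numeric"),
                  MET_UCHAR = list(size = 1L, what = "integer"))

read_metaimage <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- list(); data_file <- NULL
  repeat {
    raw_line <- raw(0)
    repeat {
      ch <- readBin(con, "raw", 1L)
      if (length(ch) == 0L) stop("malformed MetaImage header: missing ElementDataFile")
      if (ch == as.raw(10L)) break
      raw_line <- c(raw_line, ch)
    }
    line <- trimws(rawToChar(raw_line))
    kv <- regmatches(line, regexec("^([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") { data_file <- kv[3]; break }
  }
  need <- function(field) {
    if (is.null(hdr[[field]])) stop("MetaImage header missing field: ", field)
    hdr[[field]]
  }
  ndims <- as.integer(need("NDims"))
  if (ndims != 3L) stop("only 3D volumes are supported (NDims = ", ndims, ")")
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  ty <- met_types[[need("ElementType")]]
  if (is.null(ty)) stop("unsupported ElementType: ", hdr$ElementType)
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True")
  n <- prod(dims)
  if (identical(data_file, "LOCAL")) {
    vals <- readBin(con, ty$what, n = n, size = ty$size,
                    endian = if (msb) "big" else "little",
                    signed = !hdr$ElementType %in% c("MET_UCHAR", "MET_USHORT"))
  } else {
    raw_path <- file.path(dirname(path), data_file)
    if (!file.exists(raw_path)) stop("MetaImage data file not found: ", raw_path)
    rc <- file(raw_path, "rb"); on.exit(close(rc), add = TRUE)
    vals <- readBin(rc, ty$what, n = n, size = ty$size,
                    endian = if (msb) "big" else "little",
                    signed = !hdr$ElementType %in% c("MET_UCHAR", "MET_USHORT"))
  }
  if (length(vals) != n) stop("MetaImage voxel data truncated")
  volume_grid(array(as.numeric(vals), dim = dims), spacing, origin)
}

write_metaimage <- function(volume, path, dtype) {
  ty <- switch(dtype, double = "MET_DOUBLE", float = "MET_FLOAT", short = "MET_SHORT")
  size <- switch(dtype, double = 8L, float = 4L, short = 2L)
  local_data <- grepl("\\.mha$", tolower(path))
  data_file <- if (local_data) "LOCAL" else paste0(
    sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  d <- dim(volume$voxels)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(volume$origin_mm, digits = 17), collapse = " ")),
           "CenterOfRotation = 0 0 0",
           paste("ElementSpacing =", paste(format(volume$spacing_mm, digits = 17), collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementType =", ty),
           paste("ElementDataFile =", data_file))
  vals <- as.vector(volume$voxels)
  if (dtype == "short") vals <- as.integer(round(pmin(pmax(vals, -32768), 32767)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (local_data) {
    writeBin(vals, con, size = size, endian = "little")
  } else {
    rc <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(rc), add = TRUE)
    writeBin(vals, rc, size = size, endian = "little")
  }
}

# ---- NIfTI-1 ---------------------------------------------------------------

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("malformed NIfTI header: file shorter than 348 bytes")
  rd <- function(off, what, n, size) readBin(hdr[(off + 1L):length(hdr)], what,
                                             n = n, size = size, endian = "little")
  if (rd(0, "integer", 1, 4) != 348L)
    stop("malformed NIfTI header: sizeof_hdr != 348 (field sizeof_hdr)")
  dim0 <- rd(40, "integer", 8, 2)
  if (dim0[1] != 3L) stop("only 3D volumes are supported (field dim[0] = ", dim0[1], ")")
  dims <- dim0[2:4]
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "numeric", 8, 4)
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4); scl_inter <- rd(116, "numeric", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- matrix(rd(280, "numeric", 12, 4), nrow = 3, byrow = TRUE)
  qoffset <- rd(268, "numeric", 3, 4)
  origin <- if (sform_code > 0) srow[, 4] else qoffset
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(dims)
  vals <- switch(as.character(datatype),
    "4" = readBin(con, "integer", n, size = 2L, endian = "little"),
    "8" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype code (field datatype): ", datatype))
  if (length(vals) != n) stop("NIfTI voxel data truncated")
  if (is.na(scl_slope) || scl_slope == 0) scl_slope <- 1
  vals <- as.numeric(vals) * scl_slope + ifelse(is.finite(scl_inter), scl_inter, 0)
  volume_grid(array(vals, dim = dims), pixdim[2:4], origin)
}

write_nifti <- function(volume, path, dtype) {
  d <- dim(volume$voxels)
  datatype <- switch(dtype, double = 64L, float = 16L, short = 4L)
  bitpix <- switch(dtype, double = 64L, float = 32L, short = 16L)
  hdr <- raw(348L)
  put <- function(hdr, off, vals, size) {
    b <- writeBin(vals, raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0, 348L, 4)
  hdr <- put(hdr, 40, as.integer(c(3, d, 1, 1, 1, 1)), 2)
  hdr <- put(hdr, 70, datatype, 2)
  hdr <- put(hdr, 72, bitpix, 2)
  hdr <- put(hdr, 76, c(1, volume$spacing_mm, 0, 0, 0, 0), 4)
  hdr <- put(hdr, 108, 352, 4)                      # vox_offset
  hdr <- put(hdr, 112, c(1, 0), 4)                  # scl_slope, scl_inter
  hdr <- put(hdr, 123, 10L, 1)                      # xyzt_units: mm
  hdr <- put(hdr, 252, 0L, 2)                       # qform_code
  hdr <- put(hdr, 254, 1L, 2)                       # sform_code
  hdr <- put(hdr, 268, volume$origin_mm, 4)         # qoffset (mirror)
  srow <- rbind(c(volume$spacing_mm[1], 0, 0, volume$origin_mm[1]),
                c(0, volume$spacing_mm[2], 0, volume$origin_mm[2]),
                c(0, 0, volume$spacing_mm[3], volume$origin_mm[3]))
  hdr <- put(hdr, 280, as.numeric(t(srow)), 4)
  hdr[(344 + 1L):(344 + 4L)] <- c(charToRaw("n+1"), as.raw(0L))
  vals <- as.vector(volume$voxels)
  size <- switch(dtype, double = 8L, float = 4L, short = 2L)
  if (dtype == "short") vals <- as.integer(round(pmin(pmax(vals, -32768), 32767)))
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                            # extension flag
  writeBin(vals, con, size = size, endian = "little")
}

# ---- condition sidecars, manifests -----------------------------------------

#' Write / read a slice-condition JSON sidecar
#'
#' @param cond a [slice_condition()].
#' @param path sidecar path (conventionally `<volume>.json`).
#' @return The path / the restored condition.
#' @export
write_condition <- function(cond, path) {
  stopifnot(inherits(cond, "slice_condition"))
  jsonlite::write_json(unclass(cond), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_condition
#' @export
read_condition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  slice_condition(as.numeric(x$thickness_mm), as.numeric(x$interval_mm),
                  as.numeric(x$source_thin_mm))
}

#' Write a run manifest
#'
#' Records tool version, the md5 of the run config, the seeds used, and an
#' md5-checksummed file list, so any pipeline result is reproducible from
#' its manifest alone.
#'
#' @param dir run directory (one manifest per run directory).
#' @param config_path path of the JSON config that produced the run.
#' @param seeds named list/vector of seeds.
#' @param files character vector of produced files.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config_path, seeds, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    tool = "vtsct",
    version = as.character(utils::packageVersion("vtsct")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = basename(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    seeds = as.list(seeds),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  out <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, out, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
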