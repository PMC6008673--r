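#' Native compressed volume file format
#'
#' A simple container for up to three-dimensional image data, optimized for
#' fast loading and simplicity, with the payload losslessly compressed by
#' the ZStandard algorithm. Byte layout (all integers little-endian):
#'
#' \preformatted{
#'   offset size  field
#'   0      4     magic "VXVF"
#'   4      2     format version (currently 1)
#'   6      1     number of axes (1-3)
#'   7      1     channels (1-4)
#'   8      1     dtype code (1 = u8, 2 = u16, 3 = f32)
#'   9      1     reserved (0)
#'   10     2     extra header bytes that follow (0 in version 1; readers
#'                skip them, keeping the format forward-compatible)
#'   12     4*n   extent per axis
#'   ...    8     uncompressed payload length (u64)
#'   ...    8     compressed payload length (u64)
#'   ...    *     ZStandard-compressed payload
#' }
#'
#' The payload is the element array x-fastest, one channel plane after
#' another; u16 elements are little-endian, f32 elements are IEEE 754
#' single precision. \code{readVolume(writeVolume(v))} is bit-exact for
#' every dtype.
#'
#' @param v a \linkS4class{Volume}.
#' @param path file path.
#' @param level ZStandard compression level.
#' @return \code{writeVolume}: the path, invisibly. \code{readVolume}: a
#'   \linkS4class{Volume}.
#' @examples
#' f <- tempfile(fileext = ".vxvf")
#' v <- makeVolume(c(8, 8, 8), dtype = "u16", fill = 7L)
#' writeVolume(v, f)
#' identical(asArray(readVolume(f)), asArray(v))
#' @name vio
NULL

VXVF_MAGIC <- charToRaw("VXVF")
.dtype_code <- c(u8 = 1L, u16 = 2L, f32 = 3L)

.encode_payload <- function(v) {
  x <- as.vector(v@data)
  switch(v@dtype,
         u8 = as.raw(x),
         u16 = as.raw(rbind(x %% 256L, x %/% 256L)),
         f32 = writeBin(as.double(x), raw(), size = 4L, endian = "little"))
}

.decode_payload <- function(bytes, dtype, n) {
  switch(dtype,
         u8 = as.integer(bytes),
         u16 = readBin(bytes, "integer", n = n, size = 2L, signed = FALSE,
                       endian = "little"),
         f32 = readBin(bytes, "double", n = n, size = 4L, endian = "little"))
}

.write_u64 <- function(con, x) {
  writeBin(as.integer(x %% 2^31), con, size = 4L, endian = "little")
  writeBin(as.integer(x %/% 2^31 %% 2^31), con, size = 4L, endian = "little")
}

.read_u64 <- function(bytes, off) {
  lo <- readBin(bytes[off + 1:4], "integer", size = 4L, endian = "little")
  hi <- readBin(bytes[off + 5:8], "integer", size = 4L, endian = "little")
  lo + hi * 2^31
}

#' @rdname vio
#' @export
writeVolume <- function(v, path, level = 6L) {
  stopifnot(is(v, "Volume"))
  raw_payload <- .encode_payload(v)
  comp <- .zstd_compress(raw_payload, as.integer(level))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(VXVF_MAGIC, con)
  writeBin(1L, con, size = 2L, endian = "little")            # version
  writeBin(as.integer(length(voxelDims(v))), con, size = 1L)  # naxes
  writeBin(nChannels(v), con, size = 1L)
  writeBin(.dtype_code[[v@dtype]], con, size = 1L)
  writeBin(0L, con, size = 1L)                                # reserved
  writeBin(0L, con, size = 2L, endian = "little")             # extra bytes
  writeBin(as.integer(voxelDims(v)), con, size = 4L, endian = "little")
  .write_u64(con, length(raw_payload))
  .write_u64(con, length(comp))
  writeBin(comp, con)
  invisible(path)
}

#' @rdname vio
#' @export
readVolume <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 12L)
    stop("truncated file: shorter than the fixed header", call. = FALSE)
  if (!identical(bytes[1:4], VXVF_MAGIC))
    stop("unrecognized format: bad magic bytes", call. = FALSE)
  version <- readBin(bytes[5:6], "integer", size = 2L, signed = FALSE,
                     endian = "little")
  if (version > 1L)
    stop("unsupported format version ", version, " (reader supports <= 1)",
         call. = FALSE)
  naxes <- as.integer(bytes[7])
  channels <- as.integer(bytes[8])
  dcode <- as.integer(bytes[9])
  dtype <- names(.dtype_code)[match(dcode, .dtype_code)]
  if (is.na(dtype))
    stop("unrecognized format: unknown dtype code ", dcode, call. = FALSE)
  if (!naxes %in% 1:3 || !channels %in% 1:4)
    stop("unrecognized format: implausible axis/channel counts",
         call. = FALSE)
  extra <- readBin(bytes[11:12], "integer", size = 2L, signed = FALSE,
                   endian = "little")
  off <- 12L + extra  # skip any extra header fields from newer writers
  need <- off + 4L * naxes + 16L
  if (length(bytes) < need)
    stop("truncated file: header needs ", need, " bytes, got ",
         length(bytes), call. = FALSE)
  dims <- readBin(bytes[(off + 1L):(off + 4L * naxes)], "integer",
                  n = naxes, size = 4L, endian = "little")
  off <- off + 4L * naxes
  usize <- .read_u64(bytes, off)
  csize <- .read_u64(bytes, off + 8L)
  off <- off + 16L
  if (length(bytes) - off < csize)
    stop("truncated file: expected ", csize, " payload bytes, got ",
         length(bytes) - off, call. = FALSE)
  nelem <- prod(dims) * channels
  bpe <- .type_bytes[[dtype]]
  if (usize != nelem * bpe)
    stop("corrupt header: payload length ", usize,
         " does not match dims x channels x element size (", nelem * bpe,
         ")", call. = FALSE)
  payload <- .zstd_decompress(bytes[(off + 1L):(off + csize)], usize)
  vals <- .decode_payload(payload, dtype, nelem)
  .volume(array(vals, dim = c(dims, channels)), dtype)
}

setClassUnion("functionOrNULL", c("function", "NULL"))

#' FormatPlugin: a file-format handler
#'
#' Plugins extend \code{\link{detectAndRead}} with support for third-party
#' file formats. A plugin's \code{probe} inspects the first bytes of a file
#' (side-effect free); its reader returns a \linkS4class{Volume}; a writer
#' is optional.
#'
#' @slot name unique plugin name.
#' @slot extensions lowercase file extensions handled (fallback when no
#'   content probe claims a file).
#' @slot probe \code{function(raw_bytes) -> logical}.
#' @slot reader \code{function(path) -> Volume}.
#' @slot writer \code{function(volume, path)} or \code{NULL}.
#' @name FormatPlugin-class
#' @aliases FormatPlugin
#' @exportClass FormatPlugin
setClass("FormatPlugin",
         representation(name = "character", extensions = "character",
                        probe = "function", reader = "function",
                        writer = "functionOrNULL"))

#' @rdname FormatPlugin-class
#' @param name,extensions,probe,reader,writer see slots.
#' @export
formatPlugin <- function(name, extensions, probe, reader, writer = NULL) {
  new("FormatPlugin", name = name, extensions = tolower(extensions),
      probe = probe, reader = reader, writer = writer)
}

#' Register, deregister and list format plugins
#'
#' Registered plugins participate in \code{\link{detectAndRead}}'s
#' auto-detection, in registration order (the native format is always
#' probed first).
#'
#' @param plugin a \linkS4class{FormatPlugin}.
#' @return \code{registerPlugin}/\code{deregisterPlugin}: invisibly, the
#'   plugin name; \code{listPlugins}: the registered names in probe order.
#' @export
registerPlugin <- function(plugin) {
  stopifnot(is(plugin, "FormatPlugin"))
  if (plugin@name %in% names(.vx$plugins))
    stop("a plugin named '", plugin@name, "' is already registered",
         call. = FALSE)
  .vx$plugins[[plugin@name]] <- plugin
  invisible(plugin@name)
}

#' @rdname registerPlugin
#' @param name plugin name.
#' @export
deregisterPlugin <- function(name) {
  if (!name %in% names(.vx$plugins))
    stop("no plugin named '", name, "' is registered", call. = FALSE)
  .vx$plugins[[name]] <- NULL
  invisible(name)
}

#' @rdname registerPlugin
#' @export
listPlugins <- function() c("native", names(.vx$plugins))

#' Read any supported file with format auto-detection
#'
#' Probes the native format first, then every registered plugin's content
#' probe in registration order, then falls back to matching the file
#' extension. The file's extension therefore never overrides a positive
#' content probe.
#'
#' @param path file path.
#' @return a \linkS4class{Volume}.
#' @export
detectAndRead <- function(path) {
  head_bytes <- readBin(path, "raw", n = 512L)
  if (length(head_bytes) >= 4L && identical(head_bytes[1:4], VXVF_MAGIC))
    return(readVolume(path))
  for (p in .vx$plugins) {
    claimed <- tryCatch(isTRUE(p@probe(head_bytes)), error = function(e) FALSE)
    if (claimed) return(p@reader(path))
  }
  ext <- tolower(file_ext(sub("\\.gz$", "", path)))
  extgz <- tolower(paste0(ext, ".gz"))
  for (p in .vx$plugins) {
    if (ext %in% p@extensions || extgz %in% p@extensions)
      return(p@reader(path))
  }
  stop("no plugin claims '", basename(path), "'; registered plugins: ",
       paste(listPlugins(), collapse = ", "), call. = FALSE)
}

#' Write a volume, choosing the format from the extension
#'
#' \code{.vxvf} (or unknown extensions) use the native writer; otherwise
#' the first registered plugin handling the extension and providing a
#' writer is used.
#'
#' @param v a \linkS4class{Volume}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAuto <- function(v, path) {
  ext <- tolower(file_ext(path))
  if (ext %in% c("", "vxvf")) return(writeVolume(v, path))
  for (p in .vx$plugins) {
    if (ext %in% p@extensions && !is.null(p@writer)) {
      p@writer(v, path)
      return(invisible(path))
    }
  }
  writeVolume(v, path)
}

# ---- bundled plugins -------------------------------------------------------

# minimal common-image plugin (PNG), intended as the template for user
# plugins
.make_png_plugin <- function() {
  formatPlugin(
    name = "stdimage",
    extensions = "png",
    probe = function(bytes) {
      length(bytes) >= 8L &&
        identical(bytes[1:8],
                  as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
    },
    reader = function(path) {
      a <- png::readPNG(path)
      if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
      .volume(aperm(a, c(2, 1, 3)), "f32")  # to x-fastest
    },
    writer = function(v, path) {
      if (length(voxelDims(v)) != 2L)
        stop("PNG writer needs a 2-axis volume", call. = FALSE)
      a <- pmin(pmax(normalizedArray(v), 0), 1)
      a <- aperm(a, c(2, 1, 3))
      if (dim(a)[3] == 1L) a <- a[, , 1]
      png::writePNG(a, path)
    })
}

# medical-imaging plugin wrapping established readers (NIfTI, TIFF)
.make_medimage_plugin <- function() {
  is_tiff <- function(bytes) {
    length(bytes) >= 4L &&
      (identical(bytes[1:4], as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
       identical(bytes[1:4], as.raw(c(0x4d, 0x4d, 0x00, 0x2a))))
  }
  is_nifti1 <- function(bytes) {
    length(bytes) >= 348L &&
      (identical(rawToChar(bytes[345:347]), "n+1") ||
       identical(rawToChar(bytes[345:347]), "ni1"))
  }
  formatPlugin(
    name = "medimage",
    extensions = c("nii", "nii.gz", "tif", "tiff"),
    probe = function(bytes) is_tiff(bytes) || is_nifti1(bytes),
    reader = function(path) {
      bytes <- readBin(path, "raw", n = 512L)
      if (is_tiff(bytes)) {
        a <- tiff::readTIFF(path)
        if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
        return(.volume(aperm(a, c(2, 1, 3)), "f32"))
      }
      a <- unclass(RNifti::readNifti(path))
      a <- array(as.double(a), dim = dim(a))
      volumeFromArray(a, dtype = "f32")
    },
    writer = function(v, path) {
      ext <- tolower(file_ext(sub("\\.gz$", "", path)))
      if (ext == "nii") {
        RNifti::writeNifti(RNifti::asNifti(asArray(v, drop = TRUE)), path)
      } else if (ext %in% c("tif", "tiff")) {
        if (length(voxelDims(v)) != 2L)
          stop("TIFF writer needs a 2-axis volume", call. = FALSE)
        a <- pmin(pmax(normalizedArray(v), 0), 1)
        a <- aperm(a, c(2, 1, 3))
        if (dim(a)[3] == 1L) a <- a[, , 1]
        tiff::writeTIFF(a, path)
      } else stop("medimage writer handles .nii and .tif/.tiff",
                  call. = FALSE)
    })
}
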