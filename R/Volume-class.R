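#' Volume: the universal image/volume payload
#'
#' A \code{Volume} is a dense 1- to 3-axis raster with 1-4 channels and one
#' of three element formats: \code{"u8"} (8-bit, space-saving), \code{"u16"}
#' (16-bit, high detail) or \code{"f32"} (floating point, HDR). Integer
#' formats are interpreted as normalized intensities in \code{[0, 1]} when
#' converted to float. Data are stored x-fastest with a trailing channel
#' plane, i.e. the internal array has dim \code{c(dims, channels)}.
#'
#' \code{"f32"} volumes are held in single precision: values are snapped to
#' the nearest 32-bit float on construction so that file round-trips are
#' bit-exact.
#'
#' @slot data array of dim \code{c(dims, channels)}; integer storage for
#'   \code{u8}/\code{u16}, double (single-precision-valued) for \code{f32}.
#' @slot dtype one of \code{"u8"}, \code{"u16"}, \code{"f32"}.
#'
#' @param x a \code{Volume}.
#' @param ... ignored.
#'
#' @return \code{voxelDims} returns the spatial extents; \code{nChannels}
#'   the channel count; \code{voxelType} the element format; \code{asArray}
#'   the raw storage array (channel axis dropped for single-channel volumes
#'   when \code{drop = TRUE}); \code{normalizedArray} a double array in
#'   normalized intensity space.
#'
#' @examples
#' v <- makeVolume(c(4, 4, 4), dtype = "u8", fill = 128L)
#' voxelDims(v)
#' range(normalizedArray(v))
#'
#' @aliases Volume
#' @name Volume-class
#' @exportClass Volume
setClass("Volume", representation(data = "array", dtype = "character"))

VOXEL_TYPES <- c("u8", "u16", "f32")
.type_max <- c(u8 = 255, u16 = 65535, f32 = 1)
.type_bytes <- c(u8 = 1L, u16 = 2L, f32 = 4L)

setValidity("Volume", function(object) {
  d <- dim(object@data)
  if (is.null(d) || length(d) < 2L || length(d) > 4L)
    return("data must have 2-4 dims (spatial axes plus channel axis)")
  nax <- length(d) - 1L
  ch <- d[length(d)]
  if (nax < 1L || nax > 3L) return("number of axes must be 1-3")
  if (!ch %in% 1:4) return("channels must be in 1..4")
  if (any(d[seq_len(nax)] < 1L)) return("invalid extent: all dims must be >= 1")
  if (length(object@dtype) != 1L || !object@dtype %in% VOXEL_TYPES)
    return(sprintf("invalid dtype: must be one of %s",
                   paste(VOXEL_TYPES, collapse = ", ")))
  if (object@dtype != "f32") {
    x <- object@data
    if (any(x < 0 | x > .type_max[[object@dtype]], na.rm = TRUE))
      return(sprintf("%s values must lie in [0, %d]", object@dtype,
                     as.integer(.type_max[[object@dtype]])))
  }
  TRUE
})

# snap doubles to the nearest 32-bit float (round trip through 4 bytes)
.f32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.double(x), raw(), size = 4L, endian = "little"),
               what = "double", n = length(x), size = 4L, endian = "little")
  dim(y) <- d
  y
}

# internal constructor from a full storage array (dims + channel axis)
.volume <- function(a, dtype) {
  if (dtype == "f32") {
    a <- .f32(a)
  } else {
    storage.mode(a) <- "integer"
  }
  new("Volume", data = a, dtype = dtype)
}

.check_dims <- function(dims) {
  if (!is.numeric(dims) || length(dims) < 1L || length(dims) > 3L ||
      anyNA(dims) || any(dims < 1) || any(dims != floor(dims)))
    stop("invalid extent: dims must be 1-3 positive integers, got (",
         paste(dims, collapse = ", "), ")", call. = FALSE)
  as.integer(dims)
}

#' Create a Volume
#'
#' @param dims spatial extents, 1-3 positive integers.
#' @param channels number of channels, 1-4.
#' @param dtype element format: \code{"u8"}, \code{"u16"} or \code{"f32"}.
#' @param fill value every element is initialized with (raw storage scale:
#'   0-255 for \code{u8}, 0-65535 for \code{u16}).
#' @return a \linkS4class{Volume}.
#' @examples
#' makeVolume(c(2, 2, 2), dtype = "f32", fill = 0)
#' @export
makeVolume <- function(dims, channels = 1L, dtype = "f32", fill = 0) {
  dims <- .check_dims(dims)
  if (!is.numeric(channels) || length(channels) != 1L || !channels %in% 1:4)
    stop("invalid channels: must be a single integer in 1..4", call. = FALSE)
  if (length(dtype) != 1L || !dtype %in% VOXEL_TYPES)
    stop("invalid dtype: must be one of ", paste(VOXEL_TYPES, collapse = ", "),
         call. = FALSE)
  a <- array(fill, dim = c(dims, as.integer(channels)))
  .volume(a, dtype)
}

#' Create a Volume from an array
#'
#' @param a a vector or array. For \code{channels = 1} its dim is taken as
#'   the spatial extents; otherwise the last dim must equal \code{channels}.
#' @param dtype element format.
#' @param channels number of channels.
#' @return a \linkS4class{Volume}.
#' @export
volumeFromArray <- function(a, dtype = "f32", channels = 1L) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  channels <- as.integer(channels)
  if (channels == 1L) {
    dims <- .check_dims(d)
    a <- array(a, dim = c(dims, 1L))
  } else {
    if (d[length(d)] != channels)
      stop("last array dim (", d[length(d)], ") must equal channels (",
           channels, ")", call. = FALSE)
    dims <- .check_dims(d[-length(d)])
    a <- array(a, dim = c(dims, channels))
  }
  .volume(a, dtype)
}

#' @rdname Volume-class
#' @export
setMethod("voxelDims", "Volume", function(x) {
  d <- dim(x@data)
  d[-length(d)]
})

#' @rdname Volume-class
#' @export
setMethod("nChannels", "Volume", function(x) {
  d <- dim(x@data)
  d[length(d)]
})

#' @rdname Volume-class
#' @export
setMethod("voxelType", "Volume", function(x) x@dtype)

#' @rdname Volume-class
#' @param drop drop the channel axis for single-channel volumes.
#' @export
setMethod("asArray", "Volume", function(x, drop = TRUE) {
  a <- x@data
  if (drop && nChannels(x) == 1L) {
    d <- dim(a)
    a <- array(a, dim = d[-length(d)])
  }
  a
})

#' @rdname Volume-class
#' @export
setMethod("normalizedArray", "Volume", function(x) {
  a <- x@data
  if (x@dtype == "f32") return(a + 0)  # already normalized-scale doubles
  a / .type_max[[x@dtype]]
})

setMethod("show", "Volume", function(object) {
  d <- voxelDims(object)
  rng <- suppressWarnings(range(object@data, finite = TRUE))
  cat(sprintf("Volume %s, %d channel%s, %s, range [%g, %g]\n",
              paste(d, collapse = "x"), nChannels(object),
              if (nChannels(object) > 1L) "s" else "", object@dtype,
              rng[1], rng[2]))
})

# single-channel spatial array (doubles in normalized space)
.spatial <- function(v) {
  a <- normalizedArray(v)
  array(a, dim = voxelDims(v))
}

.require_1ch <- function(v, what) {
  if (nChannels(v) != 1L)
    stop(what, " requires a single-channel volume; convert or split ",
         "channels first", call. = FALSE)
  invisible(v)
}

# wrap a spatial double array (dims only) as an f32 Volume
.f32_volume <- function(a, dims = dim(a)) {
  .volume(array(a, dim = c(dims, 1L)), "f32")
}

#' Sample a volume at integer coordinates
#'
#' Coordinates are 1-based. Out-of-range coordinates clamp to the nearest
#' edge element (clamp-to-edge addressing, the package-wide border policy).
#' The optional swizzle mask remaps output channels: each symbol of the mask
#' selects a source channel (\code{r}, \code{g}, \code{b}, \code{a}) or a
#' constant (\code{0} for zero, \code{1} for the maximum normalized value).
#' Values are returned in normalized intensity space.
#'
#' @param x a \linkS4class{Volume}.
#' @param coord integer coordinates, one per axis.
#' @param swizzle optional mask such as \code{"bgr"} or \code{"rrr1"}.
#' @return a numeric vector, one value per output channel.
#' @examples
#' v <- volumeFromArray(c(10, 20, 30))
#' sampleVoxel(v, -5)           # clamps to the first element
#' sampleVoxel(v, 2, "rrr1")
#' @rdname sampleVoxel
#' @export
setMethod("sampleVoxel", "Volume", function(x, coord, swizzle = NULL) {
  dims <- voxelDims(x)
  nax <- length(dims)
  if (length(coord) != nax)
    stop("coord must have ", nax, " components", call. = FALSE)
  c1 <- pmin(pmax(as.integer(round(coord)), 1L), dims)
  stride <- cumprod(c(1L, dims))[seq_len(nax)]
  lin <- 1L + sum((c1 - 1L) * stride)
  npx <- prod(dims)
  vals <- normalizedArray(x)[lin + (seq_len(nChannels(x)) - 1L) * npx]
  if (is.null(swizzle)) return(vals)
  syms <- strsplit(swizzle, "")[[1]]
  legal <- c("r", "g", "b", "a", "0", "1")
  bad <- setdiff(syms, legal)
  if (length(syms) == 0L || length(bad) > 0L)
    stop("invalid swizzle mask '", swizzle, "': legal symbols are ",
         paste(legal, collapse = ", "), call. = FALSE)
  out <- vapply(syms, function(s) {
    if (s == "0") return(0)
    if (s == "1") return(1)
    ci <- match(s, c("r", "g", "b", "a"))
    if (ci > nChannels(x))
      stop("swizzle component '", s, "' exceeds channel count (",
           nChannels(x), ")", call. = FALSE)
    vals[ci]
  }, numeric(1))
  unname(out)
})

#' Convert a volume's element format
#'
#' Conversions pass through normalized intensity space: a \code{u8} value
#' \code{x} maps to \code{x/255} in float, and a float value \code{y} maps
#' back to \code{round(y*255)} (round half up), clamped to the valid range.
#' \code{u8 <-> u16} rescales through the same normalized space, so
#' converting to \code{f32} and back is the identity for integer volumes.
#'
#' @param x a \linkS4class{Volume}.
#' @param dtype target element format.
#' @return a \linkS4class{Volume} of the requested format.
#' @examples
#' v <- makeVolume(3, dtype = "u8", fill = 255L)
#' voxelType(convertType(v, "f32"))
#' @rdname convertType
#' @export
setMethod("convertType", "Volume", function(x, dtype) {
  if (length(dtype) != 1L || !dtype %in% VOXEL_TYPES)
    stop("invalid dtype: must be one of ", paste(VOXEL_TYPES, collapse = ", "),
         call. = FALSE)
  if (dtype == x@dtype) return(x)
  norm <- normalizedArray(x)
  if (dtype == "f32") return(.volume(norm, "f32"))
  mx <- .type_max[[dtype]]
  enc <- pmin(pmax(floor(norm * mx + 0.5), 0), mx)  # round half up + clamp
  .volume(array(enc, dim = dim(x@data)), dtype)
})
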