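#' DistanceField: a Euclidean distance transform result
#'
#' A single-channel \code{f32} \linkS4class{Volume} whose element at voxel
#' \code{p} holds the Euclidean distance (in voxel units) from \code{p} to
#' the nearest solid voxel, together with the solidity threshold that
#' defined "solid".
#'
#' @slot threshold normalized intensity at or above which a voxel counted
#'   as solid.
#' @name DistanceField-class
#' @aliases DistanceField
#' @exportClass DistanceField
setClass("DistanceField", contains = "Volume",
         representation(threshold = "numeric"))

.dims3 <- function(v) {
  d <- voxelDims(v)
  as.integer(c(d, rep(1L, 3L - length(d))))
}

#' Separable 3D Euclidean distance transform
#'
#' Computes, for every voxel, the Euclidean distance to the nearest solid
#' voxel, where a voxel is solid iff its normalized intensity is
#' \code{>= threshold}. The algorithm is the classic separable
#' squared-distance transform: an initial preparation pass writes squared
#' distance 0 at solid voxels and a large finite sentinel elsewhere, then
#' one 1D lower-envelope-of-parabolas pass per axis, then a square root --
#' four passes in total. The result is exact (not an approximation) and
#' independent of the axis order.
#'
#' An input with no solid voxel at all yields the sentinel distance
#' (\code{sqrt(sum(dims^2) + 1)}, beyond the volume diagonal) everywhere.
#'
#' @param v single-channel \linkS4class{Volume} with normalized intensities
#'   in \code{[0, 1]} (integer formats are normalized automatically).
#' @param threshold solidity threshold, default 0.5.
#' @param axisOrder order in which the per-axis passes run; the result does
#'   not depend on it (exposed for verification).
#' @return a \linkS4class{DistanceField}.
#' @examples
#' v <- volumeFromArray(array(c(1, 0, 0), c(3, 1, 1)))
#' asArray(distanceTransform3D(v))   # 0, 1, 2
#' @export
distanceTransform3D <- function(v, threshold = 0.5, axisOrder = seq_len(3)) {
  .require_1ch(v, "distanceTransform3D")
  d3 <- .dims3(v)
  a <- array(normalizedArray(v), dim = d3)
  sentinel <- sum(as.double(d3)^2) + 1
  f <- ifelse(a >= threshold, 0, sentinel)
  sq <- .edt_squared(as.double(f), d3, as.integer(axisOrder) - 1L)
  out <- array(sqrt(pmin(sq, sentinel)), dim = voxelDims(v))
  new("DistanceField", .f32_volume(out), threshold = threshold)
}

#' 27-voxel median filter
#'
#' Each output voxel is the median (the 14th order statistic) of the 27
#' values in its 3x3x3 neighborhood, with clamp-to-edge addressing at the
#' borders. The element format is preserved: outputs are always elements of
#' the input.
#'
#' @param v single-channel \linkS4class{Volume}.
#' @return a \linkS4class{Volume} of the same dims and format.
#' @export
medianFilter3D <- function(v) {
  .require_1ch(v, "medianFilter3D")
  d3 <- .dims3(v)
  out <- .median27(as.double(v@data), d3)
  .volume(array(out, dim = c(voxelDims(v), 1L)), v@dtype)
}

#' Rescale intensities to [0, 1]
#'
#' Two steps: the global minimum and maximum over all elements (and
#' channels) are determined, then every value is mapped affinely so the
#' output spans \code{[0, 1]} exactly. A constant input maps to all zeros.
#'
#' @param v a \linkS4class{Volume}.
#' @return an \code{f32} \linkS4class{Volume}.
#' @export
rescaleIntensity <- function(v) {
  a <- normalizedArray(v)
  lo <- min(a)
  hi <- max(a)
  out <- if (hi > lo) (a - lo) / (hi - lo) else array(0, dim = dim(a))
  .volume(array(out, dim = dim(v@data)), "f32")
}

#' Binary threshold
#'
#' Output is 1 where the normalized intensity is \code{>= t}, else 0 -- the
#' same solidity convention the distance transform uses.
#'
#' @param v a \linkS4class{Volume}.
#' @param t threshold in normalized intensity space.
#' @return an \code{f32} \linkS4class{Volume} with values in \{0, 1\}.
#' @export
thresholdVolume <- function(v, t = 0.5) {
  a <- normalizedArray(v)
  .volume(array(as.double(a >= t), dim = dim(v@data)), "f32")
}

.check_kernel1d <- function(k) {
  if (!is.numeric(k) || length(k) %% 2L == 0L)
    stop("1D kernels must have odd length, got length ", length(k),
         call. = FALSE)
  as.double(k)
}

#' Separable convolution
#'
#' Correlates the volume with one odd-length 1D kernel per axis (pass
#' \code{NULL} for an axis to skip it), clamp-to-edge at the borders.
#' Channels are filtered independently.
#'
#' @param v a \linkS4class{Volume}.
#' @param kernels a numeric vector (applied along every axis) or a list
#'   with one entry per axis.
#' @return an \code{f32} \linkS4class{Volume}.
#' @export
convolveSeparable <- function(v, kernels) {
  nax <- length(voxelDims(v))
  if (!is.list(kernels)) kernels <- rep(list(kernels), nax)
  if (length(kernels) != nax)
    stop("need one kernel per axis (", nax, "), got ", length(kernels),
         call. = FALSE)
  fulld <- as.integer(dim(v@data))
  a <- as.double(normalizedArray(v))
  for (ax in seq_len(nax)) {
    if (is.null(kernels[[ax]])) next
    k <- .check_kernel1d(kernels[[ax]])
    a <- .conv_axis(a, fulld, ax - 1L, k)
  }
  .volume(array(a, dim = fulld), "f32")
}

#' Gaussian kernel / Gaussian blur
#'
#' The 1D kernel samples a Gaussian of standard deviation \code{sigma} at
#' integer offsets out to radius \code{ceiling(3*sigma)} and renormalizes
#' to sum 1; \code{gaussianBlur} applies it separably along every axis.
#'
#' @param sigma standard deviation in voxel units.
#' @return \code{gaussianKernel1D}: a numeric vector summing to 1.
#' @export
gaussianKernel1D <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' @rdname gaussianKernel1D
#' @param v a \linkS4class{Volume}.
#' @export
gaussianBlur <- function(v, sigma = 1) {
  convolveSeparable(v, gaussianKernel1D(sigma))
}

# per-axis central-difference gradients of the normalized field
.gradients <- function(v) {
  d3 <- .dims3(v)
  a <- as.double(array(normalizedArray(v), dim = d3))
  lapply(seq_len(3), function(ax) {
    if (d3[ax] == 1L) return(array(0, dim = d3))
    array(.conv_axis(a, d3, ax - 1L, c(-0.5, 0, 0.5)), dim = d3)
  })
}

#' Derivative (gradient magnitude) and surface normals
#'
#' Both use central differences per axis (clamp-to-edge at the borders).
#' \code{derivativeMagnitude} returns the Euclidean norm of the gradient;
#' \code{surfaceNormals} returns the negated normalized gradient as a
#' 3-channel volume (pointing from brighter towards darker material, i.e.
#' out of a bright object), with the zero vector wherever the gradient
#' magnitude vanishes.
#'
#' @param v single-channel \linkS4class{Volume}.
#' @return an \code{f32} \linkS4class{Volume} (3 channels for normals).
#' @export
derivativeMagnitude <- function(v) {
  .require_1ch(v, "derivativeMagnitude")
  g <- .gradients(v)
  mag <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  .f32_volume(array(mag, dim = voxelDims(v)))
}

#' @rdname derivativeMagnitude
#' @export
surfaceNormals <- function(v) {
  .require_1ch(v, "surfaceNormals")
  if (length(voxelDims(v)) != 3L)
    stop("surfaceNormals requires a 3-axis volume", call. = FALSE)
  g <- .gradients(v)
  mag <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  safe <- ifelse(mag > 0, mag, 1)
  n <- array(0, dim = c(voxelDims(v), 3L))
  for (i in seq_len(3)) n[, , , i] <- -g[[i]] / safe
  .volume(n, "f32")
}

#' Mean curvature of the implicit isosurfaces
#'
#' Treats the volume as an implicit function and computes the mean
#' curvature of its level sets, \code{H = div(grad v / |grad v|) / 2}, via
#' central differences on the gradient field. For a spherical level set of
#' radius r this is 1/r (positive for a level set curving away from the
#' gradient direction). Voxels where the gradient magnitude falls below
#' \code{tol} get curvature 0.
#'
#' @param v single-channel 3-axis \linkS4class{Volume}.
#' @param tol gradient-magnitude tolerance below which curvature is
#'   undefined and reported as 0.
#' @return an \code{f32} \linkS4class{Volume}.
#' @export
meanCurvature <- function(v, tol = 1e-6) {
  .require_1ch(v, "meanCurvature")
  d3 <- .dims3(v)
  g <- .gradients(v)
  mag <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  ok <- mag > tol
  div <- array(0, dim = d3)
  for (i in seq_len(3)) {
    ni <- ifelse(ok, g[[i]] / mag, 0)
    if (d3[i] == 1L) next
    div <- div + array(.conv_axis(as.double(ni), d3, i - 1L, c(-0.5, 0, 0.5)),
                       dim = d3)
  }
  out <- ifelse(ok, div / 2, 0)
  .f32_volume(array(out, dim = voxelDims(v)))
}

#' Min/max/average region filter
#'
#' Reduces the clamped \code{(2*radius+1)^3} box around every voxel with
#' the chosen operator.
#'
#' @param v single-channel \linkS4class{Volume}.
#' @param op \code{"min"}, \code{"max"} or \code{"avg"}.
#' @param radius box radius in voxels, \code{>= 1}.
#' @return an \code{f32} \linkS4class{Volume}.
#' @export
regionFilter <- function(v, op = c("min", "max", "avg"), radius = 1L) {
  op <- match.arg(op)
  .require_1ch(v, "regionFilter")
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  d3 <- .dims3(v)
  a <- as.double(array(normalizedArray(v), dim = d3))
  out <- .region_filter(a, d3, match(op, c("min", "max", "avg")) - 1L,
                        as.integer(radius))
  .f32_volume(array(out, dim = voxelDims(v)))
}

#' Element-wise arithmetic
#'
#' Applies \code{add}, \code{sub}, \code{mul}, \code{div} or \code{pow}
#' element by element between two volumes (which must agree in dims and
#' channels) or between a volume and a scalar. Arithmetic follows IEEE 754:
#' division by zero yields infinities, 0/0 yields NaN; nothing traps.
#'
#' @param a a \linkS4class{Volume}.
#' @param b a \linkS4class{Volume} of identical shape, or a scalar.
#' @param op operation name.
#' @return an \code{f32} \linkS4class{Volume}.
#' @export
elementwiseOp <- function(a, b, op = c("add", "sub", "mul", "div", "pow")) {
  op <- match.arg(op)
  xa <- normalizedArray(a)
  if (is(b, "Volume")) {
    if (!identical(voxelDims(a), voxelDims(b)) ||
        nChannels(a) != nChannels(b))
      stop(sprintf("shape mismatch: (%s)x%d vs (%s)x%d",
                   paste(voxelDims(a), collapse = ", "), nChannels(a),
                   paste(voxelDims(b), collapse = ", "), nChannels(b)),
           call. = FALSE)
    xb <- normalizedArray(b)
  } else {
    if (!is.numeric(b) || length(b) != 1L)
      stop("b must be a Volume or a single numeric scalar", call. = FALSE)
    xb <- b
  }
  out <- switch(op,
                add = xa + xb, sub = xa - xb, mul = xa * xb,
                div = xa / xb, pow = xa^xb)
  .volume(array(out, dim = dim(a@data)), "f32")
}

#' Extract a 2D slice from a 3D volume
#'
#' @param v 3-axis \linkS4class{Volume}.
#' @param axis axis perpendicular to the slice: 1-3 or \code{"x"},
#'   \code{"y"}, \code{"z"}.
#' @param index 1-based position along that axis.
#' @return a 2-axis \linkS4class{Volume} (an image), channels and element
#'   format preserved.
#' @export
extractSlice <- function(v, axis, index) {
  if (length(voxelDims(v)) != 3L)
    stop("extractSlice requires a 3-axis volume", call. = FALSE)
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  if (is.na(axis) || !axis %in% 1:3) stop("axis must be 1..3 or x/y/z",
                                          call. = FALSE)
  d <- voxelDims(v)
  if (index < 1L || index > d[axis])
    stop("index out of range: valid range is 1..", d[axis], call. = FALSE)
  a <- v@data
  s <- switch(axis,
              a[index, , , , drop = FALSE],
              a[, index, , , drop = FALSE],
              a[, , index, , drop = FALSE])
  .volume(array(s, dim = c(d[-axis], nChannels(v))), v@dtype)
}
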