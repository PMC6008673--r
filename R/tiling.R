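#' Plan a tiled decomposition of a volume
#'
#' Splits the spatial extents into axis-aligned core blocks that partition
#' the volume exactly (disjoint and covering, raster order, x fastest),
#' each surrounded by a halo of the requested width, such that every tile's
#' core-plus-halo stays within the voxel budget. Core extents are chosen
#' greedily axis by axis (x first), which makes the plan deterministic.
#'
#' @param dims spatial extents (1-3 positive integers).
#' @param maxVoxels voxel budget per tile (core plus halo).
#' @param halo halo width per axis (scalar recycled), in voxels.
#' @return a \code{TilePlan}: a list with \code{dims}, \code{halo},
#'   \code{core} (the nominal core extents) and \code{tiles}, a data.frame
#'   with 1-based \code{origin.*} and \code{core.*} columns per axis.
#' @examples
#' planTiles(10, maxVoxels = 4)$tiles
#' @export
planTiles <- function(dims, maxVoxels, halo = 0L) {
  dims <- .check_dims(dims)
  nax <- length(dims)
  halo <- as.integer(rep(halo, length.out = nax))
  if (any(halo < 0L)) stop("halo must be >= 0", call. = FALSE)
  minimum <- prod(1 + 2 * halo)
  if (maxVoxels < minimum)
    stop("budget too small for any legal tile: minimum is ", minimum,
         " voxels (one core voxel plus halo)", call. = FALSE)
  core <- integer(nax)
  used <- 1
  for (ax in seq_len(nax)) {
    rest <- if (ax < nax) prod(1 + 2 * halo[(ax + 1):nax]) else 1
    cmax <- floor(maxVoxels / (used * rest)) - 2 * halo[ax]
    core[ax] <- max(1L, min(dims[ax], as.integer(cmax)))
    used <- used * (core[ax] + 2 * halo[ax])
  }
  starts <- lapply(seq_len(nax), function(ax)
    seq.int(1L, dims[ax], by = core[ax]))
  grid <- do.call(expand.grid, starts)  # x fastest: raster order
  tiles <- data.frame(matrix(0L, nrow(grid), 0L))
  for (ax in seq_len(nax)) {
    o <- as.integer(grid[[ax]])
    tiles[[paste0("origin.", ax)]] <- o
    tiles[[paste0("core.", ax)]] <- pmin(core[ax], dims[ax] - o + 1L)
  }
  structure(list(dims = dims, halo = halo, core = core, tiles = tiles),
            class = "TilePlan")
}

#' @export
print.TilePlan <- function(x, ...) {
  cat(sprintf("TilePlan: %s volume, %d tile(s) of nominal core %s, halo %s\n",
              paste(x$dims, collapse = "x"), nrow(x$tiles),
              paste(x$core, collapse = "x"),
              paste(x$halo, collapse = "x")))
  invisible(x)
}

# crop the storage array to [lo, hi] along spatial axes (all channels)
.crop <- function(v, lo, hi) {
  idx <- c(lapply(seq_along(lo), function(ax) lo[ax]:hi[ax]),
           list(seq_len(nChannels(v))))
  a <- do.call(`[`, c(list(v@data), idx, list(drop = FALSE)))
  .volume(a, v@dtype)
}

#' Run a kernel tile by tile
#'
#' Decomposes the volume with \code{\link{planTiles}}, runs the kernel on
#' each tile's core-plus-halo region, and reassembles the cores. The halo
#' is filled from neighboring data; where a tile touches the volume border
#' the kernel's own clamp-to-edge policy takes over, so the assembled
#' result is identical to the untiled run whenever the declared halo covers
#' the kernel's true neighborhood radius. Non-local kernels (e.g. the
#' distance transform, whose 1D passes span whole lines) declare no radius
#' and are rejected.
#'
#' @param v a \linkS4class{Volume}.
#' @param kernel a function \code{Volume -> Volume} (dims-preserving), or
#'   the name of a registered node kind.
#' @param radius the kernel's neighborhood radius in voxels. Defaults to
#'   the registered kind's declared radius when \code{kernel} is a kind
#'   name.
#' @param maxVoxels voxel budget per tile (core plus halo).
#' @param halo halo width; defaults to \code{radius}. Must be
#'   \code{>= radius} or correctness cannot be guaranteed.
#' @param params parameters passed to a registered kind.
#' @return a \linkS4class{Volume}, elementwise identical to the untiled
#'   \code{kernel(v)}.
#' @examples
#' v <- makeVolume(c(12, 12, 12), fill = 0.5)
#' out <- runTiled(v, medianFilter3D, radius = 1, maxVoxels = 6^3)
#' @export
runTiled <- function(v, kernel, radius = NULL, maxVoxels = 2^18,
                     halo = NULL, params = list()) {
  if (is.character(kernel)) {
    kd <- nodeKind(kernel)
    prm <- modifyList(kd$params, params)
    if (is.null(radius)) radius <- .kind_radius(kd, prm)
    vports <- Filter(function(p) p$type == "volume" && p$required,
                     kd$inPorts)
    if (length(vports) == 0L)
      stop("kind '", kernel, "' has no required volume input", call. = FALSE)
    inport <- vports[[1]]$name
    fn <- function(x) {
      ins <- stats::setNames(list(x), inport)
      kd$fn(ins, prm, list())[[1]]
    }
  } else {
    fn <- kernel
  }
  if (is.null(radius) || anyNA(radius))
    stop("kernel declares no neighborhood radius and cannot be tiled",
         call. = FALSE)
  dims <- voxelDims(v)
  nax <- length(dims)
  radius <- as.integer(rep(radius, length.out = nax))
  if (is.null(halo)) halo <- radius
  halo <- as.integer(rep(halo, length.out = nax))
  if (any(halo < radius))
    stop("halo (", paste(halo, collapse = ","),
         ") is smaller than the kernel radius (",
         paste(radius, collapse = ","),
         "); correctness cannot be guaranteed", call. = FALSE)
  plan <- planTiles(dims, maxVoxels, halo)
  out <- NULL
  for (i in seq_len(nrow(plan$tiles))) {
    o <- vapply(seq_len(nax), function(ax) plan$tiles[[paste0("origin.", ax)]][i],
                integer(1))
    ce <- vapply(seq_len(nax), function(ax) plan$tiles[[paste0("core.", ax)]][i],
                 integer(1))
    lo <- pmax(o - halo, 1L)
    hi <- pmin(o + ce - 1L + halo, dims)
    sub <- .crop(v, lo, hi)
    res <- fn(sub)
    if (!is(res, "Volume") || !identical(voxelDims(res), voxelDims(sub)))
      stop("tiled kernels must preserve dims", call. = FALSE)
    if (is.null(out)) {
      out <- array(if (res@dtype == "f32") 0 else 0L,
                   dim = c(dims, nChannels(res)))
      out_dtype <- res@dtype
    }
    off <- o - lo  # core offset inside the padded tile
    src_idx <- c(lapply(seq_len(nax), function(ax)
      (off[ax] + 1L):(off[ax] + ce[ax])), list(seq_len(nChannels(res))))
    dst_idx <- c(lapply(seq_len(nax), function(ax)
      o[ax]:(o[ax] + ce[ax] - 1L)), list(seq_len(nChannels(res))))
    piece <- do.call(`[`, c(list(res@data), src_idx, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), dst_idx, list(piece)))
  }
  .volume(out, out_dtype)
}
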