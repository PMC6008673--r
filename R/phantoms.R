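#' Synthetic phantom volumes
#'
#' Reproducible test objects standing in for non-distributable scan data.
#' \code{makeSpherePhantom} is a two-level ball; \code{makeHeadPhantom}
#' emulates the tissue structure of a head MRI: an outer high-intensity
#' shell (skull/skin), a thin darker intermediate layer (cerebrospinal
#' fluid) and a textured inner core (brain), as three nested ellipsoidal
#' intensity classes over a dark background, together with the
#' ground-truth label volume.
#'
#' Both phantoms are fully reproducible from their parameters and seed.
#'
#' @param dims spatial extents.
#' @param center sphere centre (1-based voxel coordinates); defaults to the
#'   volume centre.
#' @param radius sphere radius in voxels; a voxel belongs to the sphere iff
#'   its distance to the centre is \code{<= radius} (radius 0 gives a
#'   single voxel).
#' @param inside,outside intensities of the two levels.
#' @param noiseSd standard deviation of added Gaussian noise (intensities
#'   are clamped back to [0, 1]).
#' @param seed optional seed; when given, the surrounding RNG state is left
#'   untouched.
#' @return \code{makeSpherePhantom}: an \code{f32} \linkS4class{Volume}.
#' @examples
#' v <- makeSpherePhantom(c(16, 16, 16), radius = 5)
#' sum(asArray(v) == 1)   # discrete ball volume
#' @export
makeSpherePhantom <- function(dims, center = NULL, radius = 8,
                              inside = 1, outside = 0, noiseSd = 0,
                              seed = NULL) {
  dims <- .check_dims(dims)
  dims3 <- c(dims, rep(1L, 3L - length(dims)))
  if (is.null(center)) center <- (dims3 + 1) / 2
  center <- rep(as.numeric(center), length.out = 3L)
  sq <- lapply(1:3, function(i) (seq_len(dims3[i]) - center[i])^2)
  r2 <- outer(outer(sq[[1]], sq[[2]], "+"), sq[[3]], "+")
  a <- ifelse(r2 <= radius^2, inside, outside)
  a <- .add_noise(a, noiseSd, seed)
  .f32_volume(array(a, dim = dims))
}

.add_noise <- function(a, noiseSd, seed) {
  if (noiseSd <= 0) return(a)
  .with_seed(seed, {
    a <- a + rnorm(length(a), sd = noiseSd)
  })
  pmin(pmax(a, 0), 1)
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# nominal intensity per tissue class (normalized)
.head_levels <- c(background = 0.05, skull = 0.95, csf = 0.35, brain = 0.65)

#' @rdname makeSpherePhantom
#' @return \code{makeHeadPhantom}: a list with \code{volume} (\code{f32}
#'   \linkS4class{Volume}) and \code{labels} (a \code{u8}
#'   \linkS4class{Volume}: 0 background, 1 CSF, 2 brain, 3 skull/skin --
#'   ordered by increasing nominal intensity).
#' @export
makeHeadPhantom <- function(dims = c(64, 64, 64), noiseSd = 0, seed = NULL) {
  dims <- .check_dims(dims)
  if (length(dims) != 3L) stop("head phantom is 3D", call. = FALSE)
  center <- (dims + 1) / 2
  semi <- 0.42 * dims  # outer ellipsoid semi-axes
  nsq <- lapply(1:3, function(i) ((seq_len(dims[i]) - center[i]) / semi[i])^2)
  rho <- sqrt(outer(outer(nsq[[1]], nsq[[2]], "+"), nsq[[3]], "+"))
  # labels ordered by increasing nominal intensity: 0 background, 1 CSF,
  # 2 brain, 3 skull/skin -- so a monotone intensity banding recovers them
  lab <- array(0L, dim = dims)
  lab[rho <= 1] <- 3L      # skull/skin shell
  lab[rho <= 0.88] <- 1L   # CSF layer
  lab[rho <= 0.80] <- 2L   # brain core
  a <- array(.head_levels[["background"]], dim = dims)
  a[lab == 3L] <- .head_levels[["skull"]]
  a[lab == 1L] <- .head_levels[["csf"]]
  # textured brain: low-amplitude deterministic modulation, kept well
  # inside the brain intensity band
  gx <- sin(2 * pi * seq_len(dims[1]) / 9)
  gy <- sin(2 * pi * seq_len(dims[2]) / 11)
  gz <- sin(2 * pi * seq_len(dims[3]) / 13)
  tex <- outer(outer(gx, gy), gz)
  a[lab == 2L] <- .head_levels[["brain"]] + 0.05 * tex[lab == 2L]
  a <- .add_noise(a, noiseSd, seed)
  list(volume = .f32_volume(array(a, dim = dims)),
       labels = .volume(array(lab, dim = c(dims, 1L)), "u8"))
}
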