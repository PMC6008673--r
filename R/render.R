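#' Camera and render settings for the volume ray-caster
#'
#' The camera is right-handed with a perspective projection; rays pass
#' through pixel centres. Eye, target and the stereo eye separation are in
#' voxel units (the volume occupies \code{[0, dims]}).
#'
#' @slot eye camera position.
#' @slot target look-at point.
#' @slot up up vector (need not be unit length or orthogonal).
#' @slot fov vertical field of view in degrees, in (0, 180).
#' @slot width,height output size in pixels.
#' @slot eyeSep stereo eye separation in voxel units.
#' @name Camera-class
#' @aliases Camera
#' @exportClass Camera
setClass("Camera",
         representation(eye = "numeric", target = "numeric", up = "numeric",
                        fov = "numeric", width = "integer",
                        height = "integer", eyeSep = "numeric"))

setValidity("Camera", function(object) {
  if (length(object@eye) != 3 || length(object@target) != 3 ||
      length(object@up) != 3)
    return("eye, target and up must be length-3 numerics")
  if (all(object@eye == object@target)) return("eye must differ from target")
  if (object@fov <= 0 || object@fov >= 180)
    return("fov must be in (0, 180) degrees")
  if (object@width < 1L || object@height < 1L)
    return("width and height must be >= 1")
  TRUE
})

#' @rdname Camera-class
#' @param eye,target,up,fov,width,height,eyeSep see slots.
#' @export
camera <- function(eye, target, up = c(0, 0, 1), fov = 45,
                   width = 64L, height = 64L, eyeSep = 0) {
  new("Camera", eye = as.numeric(eye), target = as.numeric(target),
      up = as.numeric(up), fov = fov, width = as.integer(width),
      height = as.integer(height), eyeSep = eyeSep)
}

RENDER_MODES <- c("translucent", "solid", "solid_curvature", "edge_step",
                  "solid_rescaled")

#' RenderSettings
#'
#' @slot mode one of \code{"translucent"} (front-to-back alpha
#'   compositing), \code{"solid"} (first-crossing isosurface with Lambert
#'   shading), \code{"solid_curvature"} (solid, coloured by mean curvature
#'   on a blue-white-red diverging ramp), \code{"edge_step"} (binary
#'   occupancy at the threshold), \code{"solid_rescaled"} (solid on the
#'   intensity-rescaled volume).
#' @slot threshold iso/step threshold in normalized intensity, in [0, 1].
#' @slot opacityScale opacity transfer scale for translucent mode: a
#'   sample's opacity is \code{clamp(value * opacityScale * step, 0, 1)}.
#' @slot step ray-march step in voxel units, > 0.
#' @slot background background RGB in [0, 1].
#' @name RenderSettings-class
#' @aliases RenderSettings
#' @exportClass RenderSettings
setClass("RenderSettings",
         representation(mode = "character", threshold = "numeric",
                        opacityScale = "numeric", step = "numeric",
                        background = "numeric"))

setValidity("RenderSettings", function(object) {
  if (!object@mode %in% RENDER_MODES)
    return(paste("mode must be one of", paste(RENDER_MODES, collapse = ", ")))
  if (object@step <= 0) return("step must be > 0")
  if (object@threshold < 0 || object@threshold > 1)
    return("threshold must be in [0, 1]")
  if (length(object@background) != 3) return("background must be RGB")
  TRUE
})

#' @rdname RenderSettings-class
#' @param mode,threshold,opacityScale,step,background see slots.
#' @export
renderSettings <- function(mode = "translucent", threshold = 0.5,
                           opacityScale = 1, step = 0.5,
                           background = c(0, 0, 0)) {
  new("RenderSettings", mode = mode, threshold = threshold,
      opacityScale = opacityScale, step = step,
      background = as.numeric(background))
}

# orthonormal camera basis (right-handed: right = forward x up)
.cam_basis <- function(cam) {
  fwd <- cam@target - cam@eye
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- c(fwd[2] * cam@up[3] - fwd[3] * cam@up[2],
             fwd[3] * cam@up[1] - fwd[1] * cam@up[3],
             fwd[1] * cam@up[2] - fwd[2] * cam@up[1])
  rn <- sqrt(sum(right^2))
  if (rn < 1e-12) stop("up vector is parallel to the view direction",
                       call. = FALSE)
  right <- right / rn
  upv <- c(right[2] * fwd[3] - right[3] * fwd[2],
           right[3] * fwd[1] - right[1] * fwd[3],
           right[1] * fwd[2] - right[2] * fwd[1])
  list(fwd = fwd, right = right, up = upv)
}

.render_one <- function(v, eye, basis, cam, s) {
  d3 <- .dims3(v)
  a <- as.double(array(normalizedArray(v), dim = d3))
  mode_id <- match(s@mode, RENDER_MODES) - 1L  # 0 translucent, 1 solid, ...
  aux <- numeric(0)
  aux_scale <- 0
  if (s@mode == "solid_rescaled") {
    v2 <- rescaleIntensity(v)
    a <- as.double(array(normalizedArray(v2), dim = d3))
    mode_id <- 1L
  } else if (s@mode == "solid_curvature") {
    cv <- meanCurvature(v)
    aux <- as.double(array(asArray(cv), dim = d3))
    aux_scale <- max(abs(aux), 1e-12)
    mode_id <- 2L
  } else if (s@mode == "edge_step") {
    mode_id <- 3L
  } else if (s@mode == "solid") {
    mode_id <- 1L
  } else {
    mode_id <- 0L
  }
  px <- .render_core(a, d3, aux, length(aux) > 0L, aux_scale, mode_id,
                     s@threshold, s@opacityScale, s@step, s@background,
                     as.double(eye), basis$right, basis$up, basis$fwd,
                     tan(cam@fov / 2 * pi / 180), cam@width, cam@height)
  .volume(array(px, dim = c(cam@width, cam@height, 4L)), "f32")
}

#' Render a volume to a 2D RGBA image
#'
#' Casts one perspective ray per pixel through the volume and shades it
#' according to the render mode (see \linkS4class{RenderSettings}).
#' Sampling along rays is trilinear with clamp-to-edge addressing.
#' Translucent mode composites front-to-back,
#' \code{C <- C + (1-A) * a_i * c_i}, \code{A <- A + (1-A) * a_i}, with
#' early exit once opacity saturates; solid modes stop at the first sample
#' at or above the threshold and shade with a headlight Lambert term
#' derived from the local gradient. Rays that miss the volume return the
#' background.
#'
#' @param v single-channel 3-axis \linkS4class{Volume}.
#' @param cam a \linkS4class{Camera}.
#' @param settings a \linkS4class{RenderSettings}.
#' @return a 2-axis, 4-channel \code{f32} \linkS4class{Volume} (RGBA).
#' @export
renderVolume <- function(v, cam, settings = renderSettings()) {
  .require_1ch(v, "renderVolume")
  if (length(voxelDims(v)) != 3L)
    stop("renderVolume requires a 3-axis volume", call. = FALSE)
  basis <- .cam_basis(cam)
  .render_one(v, cam@eye, basis, cam, settings)
}

.luminance <- function(img) {
  a <- asArray(img, drop = FALSE)
  0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
}

#' Render a red/cyan anaglyph stereo image
#'
#' Renders the scene twice with the eye displaced by plus/minus half the
#' camera's eye separation along the camera's right axis (both eyes keep
#' looking at the target), then encodes the left eye's luminance in the
#' red channel and the right eye's in green and blue -- the common red/cyan
#' convention. With zero eye separation both renders coincide and the
#' anaglyph equals the mono render's luminance in all channels.
#'
#' @inheritParams renderVolume
#' @return a 2-axis, 3-channel \code{f32} \linkS4class{Volume} (RGB).
#' @export
renderAnaglyph <- function(v, cam, settings = renderSettings()) {
  .require_1ch(v, "renderAnaglyph")
  if (length(voxelDims(v)) != 3L)
    stop("renderAnaglyph requires a 3-axis volume", call. = FALSE)
  basis <- .cam_basis(cam)
  off <- basis$right * cam@eyeSep / 2
  left <- .render_one(v, cam@eye - off, basis, cam, settings)
  right <- .render_one(v, cam@eye + off, basis, cam, settings)
  ll <- .luminance(left)
  lr <- .luminance(right)
  out <- array(0, dim = c(cam@width, cam@height, 3L))
  out[, , 1] <- ll
  out[, , 2] <- lr
  out[, , 3] <- lr
  .volume(out, "f32")
}

#' Front-to-back alpha compositing of a sample sequence
#'
#' The reference compositing operator used by the translucent render mode,
#' exposed for direct use: samples are given front first, and the
#' accumulated colour/opacity follow
#' \code{C <- C + (1-A) * alpha_i * color_i},
#' \code{A <- A + (1-A) * alpha_i}. Equivalent to the back-to-front
#' closed form \code{sum_i c_i a_i prod_{j<i} (1 - a_j)}.
#'
#' @param alpha per-sample opacities in [0, 1], front first.
#' @param color per-sample scalar colours.
#' @return list with accumulated \code{color} and \code{alpha}.
#' @export
compositeFrontToBack <- function(alpha, color) {
  stopifnot(length(alpha) == length(color))
  C <- 0
  A <- 0
  for (i in seq_along(alpha)) {
    C <- C + (1 - A) * alpha[i] * color[i]
    A <- A + (1 - A) * alpha[i]
  }
  list(color = C, alpha = A)
}
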