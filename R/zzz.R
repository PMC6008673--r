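# Built-in node kinds and bundled file-format plugins, registered at load.

.sink_path <- function(params, context) {
  p <- params$path
  if (is.null(p) || !nzchar(p)) stop("sink node needs a 'path' parameter",
                                     call. = FALSE)
  out <- context$outdir
  if (!is.null(out) && !grepl("^(/|[A-Za-z]:)", p)) file.path(out, p) else p
}

.register_builtin_kinds <- function() {
  inV <- function(required = TRUE) list(port("input", "volume", required))
  outV <- list(port("output", "volume"))

  registerNodeKind("read_volume", list(), outV, params = list(path = ""),
    fn = function(inputs, params, context)
      list(output = detectAndRead(params$path)),
    description = "load a volume/image with format auto-detection")

  registerNodeKind("sphere_phantom", list(), list(port("volume", "volume")),
    params = list(dims = c(64, 64, 64), center = NULL, radius = 20,
                  inside = 1, outside = 0, noiseSd = 0, seed = NULL),
    fn = function(inputs, params, context)
      list(volume = makeSpherePhantom(params$dims, params$center,
                                      params$radius, params$inside,
                                      params$outside, params$noiseSd,
                                      params$seed)),
    description = "synthetic two-level ball volume")

  registerNodeKind("head_phantom",
    list(), list(port("volume", "volume"), port("labels", "volume")),
    params = list(dims = c(64, 64, 64), noiseSd = 0, seed = NULL),
    fn = function(inputs, params, context) {
      ph <- makeHeadPhantom(params$dims, params$noiseSd, params$seed)
      list(volume = ph$volume, labels = ph$labels)
    },
    description = "synthetic head MRI phantom with ground-truth labels")

  registerNodeKind("distance_transform", inV(), outV,
    params = list(threshold = 0.5),
    fn = function(inputs, params, context)
      list(output = distanceTransform3D(inputs$input, params$threshold)),
    radius = NA,  # non-local separable passes: not tileable
    description = "Euclidean distance to the nearest solid voxel")

  registerNodeKind("median_filter", inV(), outV, params = list(),
    fn = function(inputs, params, context)
      list(output = medianFilter3D(inputs$input)),
    radius = 1,
    description = "27-voxel box median")

  registerNodeKind("rescale_intensity", inV(), outV, params = list(),
    fn = function(inputs, params, context)
      list(output = rescaleIntensity(inputs$input)),
    radius = NA,  # global min/max: not tileable
    description = "affine rescale to [0, 1]")

  registerNodeKind("threshold", inV(), outV, params = list(t = 0.5),
    fn = function(inputs, params, context)
      list(output = thresholdVolume(inputs$input, params$t)),
    radius = 0,
    description = "binary threshold (solid iff >= t)")

  registerNodeKind("gaussian_blur", inV(), outV, params = list(sigma = 1),
    fn = function(inputs, params, context)
      list(output = gaussianBlur(inputs$input, params$sigma)),
    radius = function(params) ceiling(3 * params$sigma),
    description = "separable Gaussian convolution")

  registerNodeKind("convolve", inV(), outV, params = list(kernel = 1),
    fn = function(inputs, params, context)
      list(output = convolveSeparable(inputs$input, params$kernel)),
    radius = function(params) (length(params$kernel) - 1) / 2,
    description = "separable convolution with a user kernel")

  registerNodeKind("derivative", inV(), outV, params = list(),
    fn = function(inputs, params, context)
      list(output = derivativeMagnitude(inputs$input)),
    radius = 1,
    description = "gradient magnitude (edge detection)")

  registerNodeKind("surface_normals", inV(), outV, params = list(),
    fn = function(inputs, params, context)
      list(output = surfaceNormals(inputs$input)),
    radius = 1,
    description = "negated normalized gradient, 3 channels")

  registerNodeKind("curvature", inV(), outV, params = list(),
    fn = function(inputs, params, context)
      list(output = meanCurvature(inputs$input)),
    radius = 2,
    description = "mean curvature of the implicit isosurfaces")

  registerNodeKind("region_filter", inV(), outV,
    params = list(op = "min", radius = 1),
    fn = function(inputs, params, context)
      list(output = regionFilter(inputs$input, params$op, params$radius)),
    radius = function(params) params$radius,
    description = "min/max/average box filter")

  registerNodeKind("convert_type", inV(), outV, params = list(dtype = "f32"),
    fn = function(inputs, params, context)
      list(output = convertType(inputs$input, params$dtype)),
    radius = 0,
    description = "element format conversion through normalized space")

  registerNodeKind("elementwise",
    list(port("a", "volume", required = TRUE),
         port("b", "volume", required = FALSE)),
    outV,
    params = list(op = "add", operand = 0),
    fn = function(inputs, params, context) {
      b <- if (is.null(inputs$b)) params$operand else inputs$b
      list(output = elementwiseOp(inputs$a, b, params$op))
    },
    radius = 0,
    description = "element-wise add/sub/mul/div/pow with a volume or scalar")

  registerNodeKind("compute_snippet", inV(), outV,
    params = list(source = "v", args = list()),
    fn = function(inputs, params, context) {
      k <- compileSnippet(params$source, type = "volume")
      list(output = do.call(applyPointwise,
                            c(list(k, inputs$input), params$args)))
    },
    radius = 0,
    description = "live-coded per-voxel expression kernel")

  registerNodeKind("image_snippet", list(), list(port("image", "image2d")),
    params = list(source = "0", width = 64, height = 64, args = list()),
    fn = function(inputs, params, context) {
      k <- compileSnippet(params$source, type = "image")
      list(image = do.call(renderImageSnippet,
                           c(list(k, params$width, params$height),
                             params$args)))
    },
    description = "live-coded 2D image generator")

  registerNodeKind("extract_slice", inV(),
    list(port("image", "image2d")),
    params = list(axis = 3, index = 1),
    fn = function(inputs, params, context)
      list(image = extractSlice(inputs$input, params$axis, params$index)),
    description = "3D to 2D cross-section")

  registerNodeKind("volume_renderer", inV(),
    list(port("image", "image2d")),
    params = list(width = 64, height = 64,
                  eye = NULL, target = NULL, up = c(0, 0, 1), fov = 45,
                  mode = "translucent", threshold = 0.5, opacityScale = 1,
                  step = 0.5, background = c(0, 0, 0), stereo = FALSE,
                  eyeSep = 0),
    fn = function(inputs, params, context) {
      v <- inputs$input
      d <- voxelDims(v)
      eye <- if (is.null(params$eye)) c(d[1] / 2, -1.5 * d[2], d[3] / 2)
             else params$eye
      target <- if (is.null(params$target)) d / 2 else params$target
      cam <- camera(eye, target, params$up, params$fov, params$width,
                    params$height, params$eyeSep)
      s <- renderSettings(params$mode, params$threshold, params$opacityScale,
                          params$step, params$background)
      img <- if (isTRUE(params$stereo)) renderAnaglyph(v, cam, s)
             else renderVolume(v, cam, s)
      list(image = img)
    },
    description = "ray-cast a 3D volume into a 2D image")

  registerNodeKind("write_volume", inV(), list(),
    params = list(path = ""),
    fn = function(inputs, params, context) {
      writeAuto(inputs$input, .sink_path(params, context))
      list()
    },
    description = "sink: write a volume (format from the extension)")

  registerNodeKind("write_image",
    list(port("input", "image2d", required = TRUE)), list(),
    params = list(path = ""),
    fn = function(inputs, params, context) {
      writeAuto(inputs$input, .sink_path(params, context))
      list()
    },
    description = "sink: write a 2D image (format from the extension)")
}

.onLoad <- function(libname, pkgname) {
  .vx$kinds <- list()
  .vx$plugins <- list()
  .register_builtin_kinds()
  registerPlugin(.make_medimage_plugin())
  registerPlugin(.make_png_plugin())
  invisible()
}
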