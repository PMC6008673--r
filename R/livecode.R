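#' KernelSnippet: a runtime-compiled per-voxel kernel
#'
#' Holds user source text, the introspected parameter specifications
#' (name and default), and the compiled per-element function. Created by
#' \code{\link{compileSnippet}}.
#'
#' @slot source the snippet source text.
#' @slot params named list of parameter defaults, in declaration order.
#' @slot fun the compiled function \code{(values, params) -> values}.
#' @slot type \code{"volume"} (per-voxel over \code{v}) or \code{"image"}
#'   (2D generator over \code{x}, \code{y}, \code{width}, \code{height}).
#' @name KernelSnippet-class
#' @aliases KernelSnippet
#' @exportClass KernelSnippet
setClass("KernelSnippet",
         representation(source = "character", params = "list",
                        fun = "function", type = "character"))

setMethod("show", "KernelSnippet", function(object) {
  ps <- if (length(object@params) == 0L) "none" else
    paste(sprintf("%s=%g", names(object@params),
                  unlist(object@params)), collapse = ", ")
  cat(sprintf("KernelSnippet (%s): params %s\n", object@type, ps))
})

# elementwise math vocabulary available inside snippets
.snippet_funs <- function() {
  list(`+` = `+`, `-` = `-`, `*` = `*`, `/` = `/`, `^` = `^`, `(` = `(`,
       min = function(...) do.call(pmin, list(...)),
       max = function(...) do.call(pmax, list(...)),
       abs = abs, exp = exp, log = log, sqrt = sqrt,
       pow = function(x, y) x^y,
       clamp = function(x, lo, hi) pmin(pmax(x, lo), hi))
}

# AST walk: collect free symbols, reject anything outside the whitelist
.walk_expr <- function(e, allowed_funs, syms = character()) {
  if (is.numeric(e) || is.logical(e)) return(syms)
  if (is.symbol(e)) return(union(syms, as.character(e)))
  if (is.call(e)) {
    fname <- e[[1]]
    if (!is.symbol(fname))
      stop("sandbox violation: only plain calls to the snippet math ",
           "functions are permitted", call. = FALSE)
    fname <- as.character(fname)
    if (!fname %in% allowed_funs)
      stop("sandbox violation: function '", fname, "' is not permitted; ",
           "allowed: ", paste(setdiff(allowed_funs, "("), collapse = ", "),
           call. = FALSE)
    for (i in seq_along(e)[-1]) syms <- .walk_expr(e[[i]], allowed_funs, syms)
    return(syms)
  }
  stop("sandbox violation: unsupported construct in snippet", call. = FALSE)
}

#' Compile a per-voxel kernel snippet
#'
#' Snippets are written in a restricted arithmetic expression dialect:
#' optional \code{param <name> = <default>} declaration lines followed by a
#' single expression over \code{v} (the element value) for volume kernels,
#' or over \code{x}, \code{y}, \code{width}, \code{height} (pixel
#' coordinates, 0-based) for image generators. Available functions:
#' arithmetic operators, \code{pow}, \code{min}, \code{max}, \code{abs},
#' \code{clamp}, \code{exp}, \code{log}, \code{sqrt}. Free variables that
#' are not declared are induced as parameters with default 0, mirroring the
#' automatic interface induction of the UI.
#'
#' Compilation is pure: on any failure (syntax error, a construct outside
#' the whitelist such as I/O or function definitions) an error is thrown
#' and no partial kernel is produced.
#'
#' @param source snippet source text.
#' @param type \code{"volume"} or \code{"image"}.
#' @return a \linkS4class{KernelSnippet}.
#' @examples
#' k <- compileSnippet("param add = 0
#' param exp = 1
#' (v + add)^exp")
#' snippetParams(k)
#' @export
compileSnippet <- function(source, type = c("volume", "image")) {
  type <- match.arg(type)
  lines <- strsplit(source, "\n", fixed = TRUE)[[1]]
  decl_re <- "^\\s*param\\s+([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*([-+0-9.eE]+)\\s*$"
  is_decl <- grepl(decl_re, lines)
  params <- list()
  for (ln in lines[is_decl]) {
    nm <- sub(decl_re, "\\1", ln)
    val <- suppressWarnings(as.numeric(sub(decl_re, "\\2", ln)))
    if (is.na(val))
      stop("compilation error: bad default in parameter declaration: ", ln,
           call. = FALSE)
    params[[nm]] <- val
  }
  body_txt <- paste(lines[!is_decl], collapse = "\n")
  exprs <- tryCatch(parse(text = body_txt, keep.source = FALSE),
                    error = function(e)
                      stop("compilation error: ", conditionMessage(e),
                           call. = FALSE))
  if (length(exprs) != 1L)
    stop("compilation error: snippet body must be exactly one expression, ",
         "got ", length(exprs), call. = FALSE)
  ex <- exprs[[1]]
  funs <- .snippet_funs()
  syms <- .walk_expr(ex, names(funs))
  builtin <- if (type == "volume") "v" else c("x", "y", "width", "height")
  induced <- setdiff(syms, c(builtin, names(params)))
  for (nm in induced) params[[nm]] <- 0
  env0 <- list2env(funs, parent = emptyenv())
  fun <- function(values, pvals) {
    e <- new.env(parent = env0)
    for (nm in names(pvals)) assign(nm, pvals[[nm]], envir = e)
    if (type == "volume") {
      assign("v", values, envir = e)
    } else {
      for (nm in names(values)) assign(nm, values[[nm]], envir = e)
    }
    eval(ex, envir = e)
  }
  new("KernelSnippet", source = source, params = params, fun = fun,
      type = type)
}

#' @rdname compileSnippet
#' @param kernel a \linkS4class{KernelSnippet}.
#' @export
snippetParams <- function(kernel) kernel@params

.merge_snippet_params <- function(kernel, supplied) {
  unknown <- setdiff(names(supplied), names(kernel@params))
  if (length(unknown) > 0L)
    stop("unknown snippet parameter(s) ",
         paste0("'", unknown, "'", collapse = ", "), "; valid: ",
         if (length(kernel@params) > 0L)
           paste(names(kernel@params), collapse = ", ") else "(none)",
         call. = FALSE)
  modifyList(kernel@params, as.list(supplied))
}

#' Apply a compiled kernel to every element of a volume
#'
#' \code{output[p, c] = k(input[p, c], params)} for every voxel and
#' channel; the shape is preserved. Values are presented to the kernel in
#' normalized intensity space and the result is an \code{f32} volume.
#'
#' @param kernel a \linkS4class{KernelSnippet} of type \code{"volume"}.
#' @param x a \linkS4class{Volume}.
#' @param ... parameter values overriding the introspected defaults.
#' @return an \code{f32} \linkS4class{Volume}.
#' @examples
#' k <- compileSnippet("param add = 0
#' param exp = 1
#' (v + add)^exp")
#' v <- makeVolume(c(2, 2), fill = 0.25)
#' asArray(applyPointwise(k, v, add = 0.25, exp = 2))[1, 1]  # 0.25
#' @rdname applyPointwise
#' @export
setMethod("applyPointwise", signature("KernelSnippet", "Volume"),
          function(kernel, x, ...) {
  if (kernel@type != "volume")
    stop("this snippet is an image generator; use renderImageSnippet()",
         call. = FALSE)
  pvals <- .merge_snippet_params(kernel, list(...))
  a <- normalizedArray(x)
  out <- kernel@fun(a, pvals)
  out <- array(out, dim = dim(x@data))  # constant expressions broadcast
  .volume(out, "f32")
})

#' Evaluate an image-generator snippet
#'
#' Runs a \code{type = "image"} snippet over the pixel grid: \code{x} and
#' \code{y} are 0-based pixel coordinates and \code{width}/\code{height}
#' the output size, in the spirit of fragment-shader playgrounds.
#'
#' @param kernel a \linkS4class{KernelSnippet} of type \code{"image"}.
#' @param width,height output size in pixels.
#' @param ... parameter values overriding the defaults.
#' @return a 2-axis single-channel \code{f32} \linkS4class{Volume}.
#' @examples
#' k <- compileSnippet("x / (width - 1)", type = "image")
#' asArray(renderImageSnippet(k, 4, 2))
#' @export
renderImageSnippet <- function(kernel, width, height, ...) {
  if (kernel@type != "image")
    stop("this snippet is a volume kernel; use applyPointwise()",
         call. = FALSE)
  pvals <- .merge_snippet_params(kernel, list(...))
  xs <- matrix(rep(seq_len(width) - 1, height), nrow = width)
  ys <- matrix(rep(seq_len(height) - 1, each = width), nrow = width)
  out <- kernel@fun(list(x = xs, y = ys, width = width, height = height),
                    pvals)
  out <- array(out, dim = c(width, height))
  .f32_volume(out)
}
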