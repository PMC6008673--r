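#' Node-kind registry
#'
#' Every processing operation is also available as a graph node kind. A
#' kind declares its ports (name + datatype, the "connector colour"), its
#' parameters with defaults, its neighborhood radius (used by
#' \code{\link{runTiled}}; \code{NA} marks non-local kinds that cannot be
#' tiled), and the function that evaluates it.
#'
#' The evaluation function receives \code{(inputs, params, context)}:
#' \code{inputs} is a named list keyed by in-port name (missing optional
#' inputs are \code{NULL}), \code{params} the merged parameter list, and
#' \code{context} run-scoped state such as the output directory.
#'
#' @param kind node-kind name.
#' @param inPorts,outPorts lists of ports created with \code{\link{port}}.
#' @param params named list of parameter defaults.
#' @param fn evaluation function \code{(inputs, params, context)} returning
#'   a named list keyed by out-port name.
#' @param radius neighborhood radius in voxels; a function of the params
#'   list for kinds whose footprint depends on a parameter; \code{NA} for
#'   non-local kinds.
#' @param description one-line description.
#' @return \code{registerNodeKind} returns the kind name invisibly;
#'   \code{nodeKinds} the registered names; \code{nodeKind} one definition.
#' @examples
#' "median_filter" %in% nodeKinds()
#' @export
registerNodeKind <- function(kind, inPorts = list(), outPorts = list(),
                             params = list(), fn, radius = NA,
                             description = "") {
  stopifnot(is.character(kind), length(kind) == 1L, is.function(fn))
  for (p in c(inPorts, outPorts)) {
    if (!is.list(p) || is.null(p$name) || is.null(p$type))
      stop("ports must be created with port()", call. = FALSE)
  }
  .vx$kinds[[kind]] <- list(kind = kind, inPorts = inPorts,
                            outPorts = outPorts, params = params, fn = fn,
                            radius = radius, description = description)
  invisible(kind)
}

#' @rdname registerNodeKind
#' @param name port name.
#' @param type port datatype: \code{"volume"}, \code{"image2d"},
#'   \code{"scalar"} or \code{"buffer"}.
#' @param required must this in-port be connected for the node to run?
#' @export
port <- function(name, type = c("volume", "image2d", "scalar", "buffer"),
                 required = TRUE) {
  type <- match.arg(type)
  list(name = name, type = type, required = required)
}

#' @rdname registerNodeKind
#' @export
nodeKinds <- function() sort(names(.vx$kinds))

#' @rdname registerNodeKind
#' @export
nodeKind <- function(kind) {
  k <- .vx$kinds[[kind]]
  if (is.null(k)) stop("unknown node kind '", kind, "'", call. = FALSE)
  k
}

.port_of <- function(kinddef, dir, name) {
  ports <- if (dir == "in") kinddef$inPorts else kinddef$outPorts
  for (p in ports) if (p$name == name) return(p)
  NULL
}

# declared tiling radius of a kind given its params (NA = not tileable)
.kind_radius <- function(kinddef, params) {
  r <- kinddef$radius
  if (is.function(r)) r <- r(params)
  r
}
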