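#' FlowGraph: a typed dataflow DAG
#'
#' Nodes (instances of registered kinds) are linked by edges from out-ports
#' to in-ports. Connections are validated at mutation time: the two port
#' datatypes must match, an in-port accepts at most one edge, and an edge
#' that would close a cycle is rejected -- the graph is acyclic at all
#' times. Nodes carry dirty flags; parameter changes and new connections
#' mark the downstream cone dirty, and \code{\link{executeGraph}} evaluates
#' exactly the dirty nodes in topological order, timing each one.
#'
#' A \code{FlowGraph} has reference semantics (its state lives in an
#' environment): \code{addNode}, \code{connect} and \code{setParam} modify
#' the graph in place.
#'
#' @param graph a \code{FlowGraph}.
#' @param id node identifier, unique within the graph.
#' @param kind a registered node kind (see \code{\link{nodeKinds}}).
#' @param params named list of parameter overrides for the node.
#'
#' @return \code{flowGraph} a new empty graph; \code{addNode} the graph,
#'   invisibly; \code{nodeIds} the node identifiers in insertion order;
#'   \code{graphEdges} a data.frame of edges.
#'
#' @examples
#' g <- flowGraph()
#' addNode(g, "src", "sphere_phantom", list(dims = c(8, 8, 8)))
#' addNode(g, "blur", "gaussian_blur", list(sigma = 1))
#' connect(g, "src.volume", "blur.input")
#' executeGraph(g)
#'
#' @aliases FlowGraph
#' @name FlowGraph-class
#' @exportClass FlowGraph
setClass("FlowGraph", representation(state = "environment"))

#' @rdname FlowGraph-class
#' @export
flowGraph <- function() {
  st <- new.env(parent = emptyenv())
  st$nodes <- list()
  st$edges <- data.frame(src_node = character(), src_port = character(),
                         dst_node = character(), dst_port = character(),
                         stringsAsFactors = FALSE)
  st$context <- list()
  new("FlowGraph", state = st)
}

#' @rdname FlowGraph-class
#' @export
setMethod("addNode", "FlowGraph", function(graph, id, kind, params = list()) {
  st <- graph@state
  if (id %in% names(st$nodes))
    stop("node id '", id, "' already exists", call. = FALSE)
  kd <- nodeKind(kind)
  unknown <- setdiff(names(params), names(kd$params))
  if (length(unknown) > 0L)
    stop("unknown parameter(s) ", paste0("'", unknown, "'", collapse = ", "),
         " for kind '", kind, "'; valid: ",
         paste(names(kd$params), collapse = ", "), call. = FALSE)
  st$nodes[[id]] <- list(id = id, kind = kind,
                         params = modifyList(kd$params, params),
                         dirty = TRUE, last_ms = NA_real_, outputs = NULL,
                         failed = FALSE)
  invisible(graph)
})

#' @rdname FlowGraph-class
#' @export
nodeIds <- function(graph) names(graph@state$nodes)

#' @rdname FlowGraph-class
#' @export
graphEdges <- function(graph) graph@state$edges

#' @rdname FlowGraph-class
#' @export
nodeInfo <- function(graph, id) {
  n <- graph@state$nodes[[id]]
  if (is.null(n)) stop("unknown node '", id, "'", call. = FALSE)
  n[c("id", "kind", "params", "dirty", "last_ms")]
}

# parse "node.port" references
.parse_ref <- function(ref) {
  if (is.character(ref) && length(ref) == 1L) {
    parts <- strsplit(ref, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("port reference must look like 'node.port', got '", ref, "'",
           call. = FALSE)
    return(parts)
  }
  if (length(ref) == 2L) return(as.character(ref))
  stop("invalid port reference", call. = FALSE)
}

# all nodes reachable from `ids` by following edges downstream (excl. ids)
.downstream <- function(st, ids) {
  seen <- character()
  frontier <- ids
  while (length(frontier) > 0L) {
    nxt <- unique(st$edges$dst_node[st$edges$src_node %in% frontier])
    nxt <- setdiff(nxt, c(seen, ids))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

.mark_dirty <- function(st, ids) {
  all_ids <- unique(c(ids, .downstream(st, ids)))
  for (i in all_ids) st$nodes[[i]]$dirty <- TRUE
  all_ids
}

# a path src ~> dst through edges, or NULL (used for cycle diagnostics)
.find_path <- function(st, from, to) {
  parent <- stats::setNames(list(NULL), from)
  frontier <- from
  while (length(frontier) > 0L) {
    nf <- character()
    for (f in frontier) {
      outs <- st$edges$dst_node[st$edges$src_node == f]
      for (o in outs) {
        if (!o %in% names(parent)) {
          parent[[o]] <- f
          nf <- c(nf, o)
        }
      }
    }
    if (to %in% names(parent)) break
    frontier <- nf
  }
  if (!to %in% names(parent)) return(NULL)
  path <- to
  while (!is.null(parent[[path[1]]])) path <- c(parent[[path[1]]], path)
  path
}

#' Connect two node ports
#'
#' Adds an edge from an out-port to an in-port, after validating that both
#' ports exist, that their datatypes match, that the in-port is free, and
#' that the edge would not close a cycle. On success the destination node
#' and everything downstream of it are marked dirty.
#'
#' @param graph a \linkS4class{FlowGraph}.
#' @param src source as \code{"node.port"} (an out-port).
#' @param dst destination as \code{"node.port"} (an in-port).
#' @return the edge, invisibly, as a named character vector.
#' @rdname connect
#' @export
setMethod("connect", "FlowGraph", function(graph, src, dst) {
  st <- graph@state
  s <- .parse_ref(src)
  d <- .parse_ref(dst)
  for (nid in c(s[1], d[1]))
    if (!nid %in% names(st$nodes))
      stop("unknown node '", nid, "'", call. = FALSE)
  skind <- nodeKind(st$nodes[[s[1]]]$kind)
  dkind <- nodeKind(st$nodes[[d[1]]]$kind)
  sp <- .port_of(skind, "out", s[2])
  if (is.null(sp))
    stop("node '", s[1], "' (", skind$kind, ") has no out-port '", s[2], "'",
         call. = FALSE)
  dp <- .port_of(dkind, "in", d[2])
  if (is.null(dp))
    stop("node '", d[1], "' (", dkind$kind, ") has no in-port '", d[2], "'",
         call. = FALSE)
  if (sp$type != dp$type)
    stop("incompatible connector types: ", sp$type, " vs ", dp$type,
         call. = FALSE)
  occupied <- st$edges$dst_node == d[1] & st$edges$dst_port == d[2]
  if (any(occupied))
    stop("input already connected: ", d[1], ".", d[2], call. = FALSE)
  if (s[1] == d[1] || !is.null(path <- .find_path(st, d[1], s[1]))) {
    path <- if (s[1] == d[1]) c(s[1], s[1]) else c(path, d[1])
    stop("cycle rejected: ", paste(path, collapse = " -> "), call. = FALSE)
  }
  st$edges <- rbind(st$edges,
                    data.frame(src_node = s[1], src_port = s[2],
                               dst_node = d[1], dst_port = d[2],
                               stringsAsFactors = FALSE))
  .mark_dirty(st, d[1])
  invisible(c(src = paste(s, collapse = "."), dst = paste(d, collapse = ".")))
})

#' Set a node parameter
#'
#' Changes one parameter and marks the node plus its entire downstream
#' reachable closure dirty, so the next \code{\link{executeGraph}}
#' recomputes exactly the affected cone.
#'
#' @param graph a \linkS4class{FlowGraph}.
#' @param id node identifier.
#' @param name parameter name (must exist for the node's kind).
#' @param value new value.
#' @return the character vector of node ids marked dirty.
#' @rdname setParam
#' @export
setMethod("setParam", "FlowGraph", function(graph, id, name, value) {
  st <- graph@state
  if (!id %in% names(st$nodes))
    stop("unknown node '", id, "'", call. = FALSE)
  node <- st$nodes[[id]]
  kd <- nodeKind(node$kind)
  if (!name %in% names(kd$params))
    stop("unknown parameter '", name, "' for kind '", node$kind,
         "'; valid: ", paste(names(kd$params), collapse = ", "),
         call. = FALSE)
  st$nodes[[id]]$params[[name]] <- value
  .mark_dirty(st, id)
})

# deterministic topological order: Kahn's algorithm, ties broken by node
# insertion order
.topo_order <- function(st) {
  ids <- names(st$nodes)
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (d in st$edges$dst_node) indeg[[d]] <- indeg[[d]] + 1L
  order <- character()
  ready <- ids[indeg[ids] == 0L]
  while (length(ready) > 0L) {
    n <- ready[1]
    ready <- ready[-1]
    order <- c(order, n)
    outs <- unique(st$edges$dst_node[st$edges$src_node == n])
    for (o in outs) {
      k <- sum(st$edges$src_node == n & st$edges$dst_node == o)
      indeg[[o]] <- indeg[[o]] - k
      if (indeg[[o]] == 0L) ready <- c(ready, o)
    }
    ready <- ids[ids %in% ready]  # keep insertion order
  }
  order
}

#' Execute a graph
#'
#' Evaluates every dirty node exactly once, in a deterministic topological
#' order (ties broken by node insertion order), clearing dirty flags and
#' recording per-node wall-clock compute time. Node-level failures (an
#' error from the node function, or a required input that is not
#' connected) are contained: the failing node is reported, its downstream
#' cone is skipped and left dirty, and unrelated subgraphs still run.
#'
#' @param graph a \linkS4class{FlowGraph}.
#' @param ... ignored.
#' @return a data.frame report with one row per visited node: \code{id},
#'   \code{kind}, \code{status} (\code{"ok"}, \code{"error"} or
#'   \code{"skipped"}), \code{ms}, \code{message}. A fully clean graph
#'   yields a zero-row report.
#' @rdname executeGraph
#' @export
setMethod("executeGraph", "FlowGraph", function(graph, ...) {
  st <- graph@state
  order <- .topo_order(st)
  report <- list()
  blocked <- character()  # failed or skipped this round
  for (id in order) {
    node <- st$nodes[[id]]
    if (!node$dirty) next
    kd <- nodeKind(node$kind)
    up_edges <- st$edges[st$edges$dst_node == id, , drop = FALSE]
    if (any(up_edges$src_node %in% blocked)) {
      blocked <- c(blocked, id)
      report[[length(report) + 1L]] <-
        data.frame(id = id, kind = node$kind, status = "skipped",
                   ms = NA_real_, message = "upstream node failed",
                   stringsAsFactors = FALSE)
      next
    }
    inputs <- list()
    missing_req <- character()
    for (p in kd$inPorts) {
      e <- up_edges[up_edges$dst_port == p$name, , drop = FALSE]
      if (nrow(e) == 1L) {
        inputs[[p$name]] <- st$nodes[[e$src_node]]$outputs[[e$src_port]]
      } else if (p$required) {
        missing_req <- c(missing_req, p$name)
      }
    }
    if (length(missing_req) > 0L) {
      blocked <- c(blocked, id)
      report[[length(report) + 1L]] <-
        data.frame(id = id, kind = node$kind, status = "error",
                   ms = NA_real_,
                   message = paste0("required input not connected: ",
                                    paste(missing_req, collapse = ", ")),
                   stringsAsFactors = FALSE)
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(ok = TRUE,
                         value = kd$fn(inputs, node$params, st$context)),
                    error = function(e) list(ok = FALSE,
                                             msg = conditionMessage(e)))
    ms <- (proc.time()[["elapsed"]] - t0) * 1000
    if (res$ok) {
      st$nodes[[id]]$outputs <- res$value
      st$nodes[[id]]$dirty <- FALSE
      st$nodes[[id]]$last_ms <- ms
      st$nodes[[id]]$failed <- FALSE
      report[[length(report) + 1L]] <-
        data.frame(id = id, kind = node$kind, status = "ok", ms = ms,
                   message = "", stringsAsFactors = FALSE)
    } else {
      blocked <- c(blocked, id)
      st$nodes[[id]]$failed <- TRUE
      report[[length(report) + 1L]] <-
        data.frame(id = id, kind = node$kind, status = "error", ms = ms,
                   message = res$msg, stringsAsFactors = FALSE)
    }
  }
  if (length(report) == 0L)
    return(data.frame(id = character(), kind = character(),
                      status = character(), ms = numeric(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, report)
})

#' Fetch a node's cached output
#'
#' @param graph a \linkS4class{FlowGraph}.
#' @param ref \code{"node.port"} reference to an out-port.
#' @return the cached value (\code{NULL} if the node has not run).
#' @export
nodeOutput <- function(graph, ref) {
  r <- .parse_ref(ref)
  n <- graph@state$nodes[[r[1]]]
  if (is.null(n)) stop("unknown node '", r[1], "'", call. = FALSE)
  n$outputs[[r[2]]]
}

#' Which nodes are dirty?
#'
#' @param graph a \linkS4class{FlowGraph}.
#' @return character vector of dirty node ids.
#' @export
dirtyNodes <- function(graph) {
  st <- graph@state
  names(st$nodes)[vapply(st$nodes, function(n) n$dirty, logical(1))]
}

setMethod("show", "FlowGraph", function(object) {
  st <- object@state
  cat(sprintf("FlowGraph: %d node(s), %d edge(s), %d dirty\n",
              length(st$nodes), nrow(st$edges), length(dirtyNodes(object))))
  for (n in st$nodes)
    cat(sprintf("  %s [%s]%s\n", n$id, n$kind,
                if (n$dirty) " *dirty*" else
                  sprintf(" (%.1f ms)", n$last_ms)))
})
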