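chain3 <- function() {
  g <- flowGraph()
  addNode(g, "a", "sphere_phantom", list(dims = c(4, 4, 4)))
  addNode(g, "b", "gaussian_blur", list(sigma = 0.5))
  addNode(g, "c", "threshold")
  connect(g, "a.volume", "b.input")
  connect(g, "b.output", "c.input")
  g
}

test_that("connections are validated at mutation time", {
  g <- flowGraph()
  addNode(g, "a", "sphere_phantom")
  addNode(g, "b", "gaussian_blur")
  addNode(g, "r", "volume_renderer")
  expect_error(connect(g, "a.volume", "r.nosuch"), "no in-port")
  expect_error(connect(g, "a.nosuch", "b.input"), "no out-port")
  # image2d out-port into a volume in-port: the connector "colours" differ
  expect_error(connect(g, "r.image", "b.input"),
               "incompatible connector types.*image2d.*volume")
  connect(g, "a.volume", "b.input")
  expect_error(connect(g, "a.volume", "b.input"), "input already connected")
  expect_equal(nrow(graphEdges(g)), 1)
})

test_that("cycles are rejected and leave the graph unchanged", {
  g <- flowGraph()
  addNode(g, "a", "gaussian_blur")
  addNode(g, "b", "median_filter")
  connect(g, "a.output", "b.input")
  before <- graphEdges(g)
  expect_error(connect(g, "b.output", "a.input"), "cycle rejected")
  expect_identical(graphEdges(g), before)
  expect_error(connect(g, "a.output", "a.input"), "cycle rejected")
})

test_that("setParam marks exactly the downstream reachable closure dirty", {
  g <- chain3()
  executeGraph(g)
  expect_identical(dirtyNodes(g), character(0))
  expect_setequal(setParam(g, "a", "radius", 1), c("a", "b", "c"))
  executeGraph(g)
  expect_setequal(setParam(g, "c", "t", 0.4), "c")

  # diamond a -> {b, c} -> d: touching b dirties only {b, d}
  g2 <- flowGraph()
  addNode(g2, "a", "sphere_phantom", list(dims = c(4, 4, 4)))
  addNode(g2, "b", "gaussian_blur")
  addNode(g2, "c", "median_filter")
  addNode(g2, "d", "elementwise", list(op = "add"))
  connect(g2, "a.volume", "b.input")
  connect(g2, "a.volume", "c.input")
  connect(g2, "b.output", "d.a")
  connect(g2, "c.output", "d.b")
  executeGraph(g2)
  expect_setequal(setParam(g2, "b", "sigma", 2), c("b", "d"))
  rep2 <- executeGraph(g2)
  expect_setequal(rep2$id, c("b", "d"))
  expect_true(all(rep2$status == "ok"))
})

test_that("execution is topological, idempotent, and times nodes", {
  g <- chain3()
  rep1 <- executeGraph(g)
  expect_identical(rep1$id, c("a", "b", "c"))
  expect_true(all(rep1$status == "ok"))
  expect_true(all(is.finite(rep1$ms)))
  expect_false(is.na(nodeInfo(g, "b")$last_ms))
  # idempotent: nothing is dirty, nothing runs
  expect_identical(nrow(executeGraph(g)), 0L)
})

test_that("executing equals composing the node functions directly", {
  g <- chain3()
  executeGraph(g)
  direct <- thresholdVolume(gaussianBlur(makeSpherePhantom(c(4, 4, 4)),
                                         sigma = 0.5))
  expect_equal(asArray(nodeOutput(g, "c.output")), asArray(direct))
})

test_that("node failure is contained to its downstream cone", {
  g <- flowGraph()
  addNode(g, "a", "sphere_phantom", list(dims = c(4, 4, 4)))
  addNode(g, "bad", "compute_snippet", list(source = "v"))
  addNode(g, "after", "gaussian_blur")
  addNode(g, "other", "median_filter")
  connect(g, "a.volume", "bad.input")
  connect(g, "bad.output", "after.input")
  connect(g, "a.volume", "other.input")
  setParam(g, "bad", "args", list(nosuch = 1))  # will error at evaluation
  rep <- executeGraph(g)
  expect_identical(rep$status[rep$id == "bad"], "error")
  expect_match(rep$message[rep$id == "bad"], "unknown snippet parameter")
  expect_identical(rep$status[rep$id == "after"], "skipped")
  expect_identical(rep$status[rep$id == "other"], "ok")
  # the failed cone stays dirty; the healthy branch is clean
  expect_setequal(dirtyNodes(g), c("bad", "after"))
})

test_that("unconnected required inputs error without aborting the rest", {
  g <- flowGraph()
  addNode(g, "lonely", "gaussian_blur")
  addNode(g, "src", "sphere_phantom", list(dims = c(4, 4, 4)))
  rep <- executeGraph(g)
  expect_identical(rep$status[rep$id == "lonely"], "error")
  expect_match(rep$message[rep$id == "lonely"], "required input not connected")
  expect_identical(rep$status[rep$id == "src"], "ok")
})

test_that("unknown nodes, params and kinds are named in errors", {
  g <- flowGraph()
  expect_error(addNode(g, "x", "no_such_kind"), "unknown node kind")
  addNode(g, "x", "gaussian_blur")
  expect_error(setParam(g, "y", "sigma", 1), "unknown node 'y'")
  expect_error(setParam(g, "x", "nope", 1), "unknown parameter 'nope'")
  expect_error(addNode(g, "x", "gaussian_blur"), "already exists")
})

test_that("dirty closure matches graph-search reachability on random DAGs", {
  for (seed in 1:20) {
    g <- rand_dag(seed)
    executeGraph(g)
    ids <- nodeIds(g)
    start <- ids[1 + seed %% length(ids)]
    got <- setParam(g, start,
                    if (startsWith(start, "s")) "radius" else "op",
                    if (startsWith(start, "s")) 2 else "add")
    expect_setequal(got, reach_oracle(graphEdges(g), start))
    # evaluation count equals the dirty closure size
    rep <- executeGraph(g)
    expect_setequal(rep$id, got)
  }
})
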