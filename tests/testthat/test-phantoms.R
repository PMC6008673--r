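test_that("sphere phantom matches the discrete ball count and is reproducible", {
  dims <- c(16, 16, 16)
  r <- 5
  v <- makeSpherePhantom(dims, radius = r)
  a <- asArray(v)
  # brute-force ball count
  ctr <- (dims + 1) / 2
  cnt <- 0L
  for (z in 1:16) for (y in 1:16) for (x in 1:16)
    if (sum((c(x, y, z) - ctr)^2) <= r^2) cnt <- cnt + 1L
  expect_identical(sum(a == 1), cnt)
  expect_true(all(a %in% c(0, 1)))

  single <- makeSpherePhantom(c(5, 5, 5), center = c(3, 3, 3), radius = 0)
  expect_identical(sum(asArray(single) == 1), 1L)
  expect_equal(asArray(single)[3, 3, 3], 1)

  n1 <- makeSpherePhantom(dims, radius = r, noiseSd = 0.05, seed = 99)
  n2 <- makeSpherePhantom(dims, radius = r, noiseSd = 0.05, seed = 99)
  expect_identical(asArray(n1), asArray(n2))
  expect_false(identical(asArray(n1), a))
  # phantom seeding does not disturb the caller's RNG stream
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(makeSpherePhantom(dims, radius = r, noiseSd = 0.1,
                                           seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("head phantom ships three disjoint tissue classes plus background", {
  ph <- makeHeadPhantom(c(48, 48, 48))
  lab <- asArray(ph$labels)
  expect_setequal(sort(unique(as.vector(lab))), 0:3)
  vol <- asArray(ph$volume)
  # class intensity ranges are disjoint at zero noise
  rngs <- lapply(0:3, function(l) range(vol[lab == l]))
  ord <- order(vapply(rngs, `[`, numeric(1), 1))
  for (i in seq_len(3))
    expect_lt(rngs[[ord[i]]][2], rngs[[ord[i + 1]]][1])
})

test_that("shipped graphs validate and the segmentation recovers all labels", {
  out <- withr::local_tempdir()
  res <- runGraph(example_graph("segmentation.yaml"), outDir = out,
                  quiet = TRUE)
  expect_true(all(res$report$status == "ok"))
  lab_file <- file.path(out, "labels.vxvf")
  expect_true(file.exists(lab_file))
  expect_true(file.exists(file.path(out, "segmented_slice.png")))
  got <- round(asArray(readVolume(lab_file)))
  truth <- asArray(nodeOutput(res$graph, "ph.labels"))
  expect_identical(mean(got == truth), 1)  # 100% voxel agreement
  # slice file reads back as an image
  img <- detectAndRead(file.path(out, "segmented_slice.png"))
  expect_identical(length(voxelDims(img)), 2L)
})

test_that("segmentation agreement degrades monotonically with noise", {
  agree <- function(noise, seed) {
    out <- withr::local_tempdir()
    res <- runGraph(example_graph("segmentation.yaml"),
                    overrides = c(sprintf("ph.noiseSd=%g", noise),
                                  sprintf("ph.seed=%d", seed),
                                  "ph.dims=[32, 32, 32]",
                                  "slice.index=16"),
                    outDir = out, quiet = TRUE)
    got <- round(asArray(readVolume(file.path(out, "labels.vxvf"))))
    truth <- asArray(nodeOutput(res$graph, "ph.labels"))
    mean(got == truth)
  }
  levels <- c(0, 0.05, 0.15)
  means <- vapply(levels, function(ns)
    mean(vapply(1:3, function(s) agree(ns, s), numeric(1))), numeric(1))
  expect_identical(means[1], 1)
  expect_true(all(diff(means) <= 0))
  expect_lt(means[3], means[1])
})

test_that("the shell-removal and two-view graphs run end to end", {
  out <- withr::local_tempdir()
  res <- runGraph(example_graph("shell_removal.yaml"),
                  overrides = c("ph.dims=[32, 32, 32]",
                                "render.width=32", "render.height=32"),
                  outDir = out, quiet = TRUE)
  expect_true(all(res$report$status == "ok"))
  stripped <- readVolume(file.path(out, "shell_removed.vxvf"))
  # skull/skin material (>= 0.8) is gone from the stripped volume
  expect_lt(max(asArray(stripped)), 0.8)
  # but the brain interior survives
  expect_gt(sum(asArray(stripped) > 0.5), 100)
  ana <- detectAndRead(file.path(out, "shell_removed_anaglyph.png"))
  expect_identical(nChannels(ana), 3L)

  out2 <- withr::local_tempdir()
  res2 <- runGraph(example_graph("two_views.yaml"),
                   overrides = c("src.dims=[24, 24, 24]", "src.radius=7",
                                 "view_front.eye=[12, -30, 12]",
                                 "view_front.target=[12, 12, 12]",
                                 "view_above.eye=[40, 12, 45]",
                                 "view_above.target=[12, 12, 12]",
                                 "view_front.width=32", "view_front.height=32",
                                 "view_above.width=32", "view_above.height=32"),
                   outDir = out2, quiet = TRUE)
  expect_true(all(res2$report$status == "ok"))
  expect_true(file.exists(file.path(out2, "view_front.png")))
  expect_true(file.exists(file.path(out2, "view_above.png")))
})

test_that("overrides re-run exactly the dirty cone", {
  out <- withr::local_tempdir()
  res <- runGraph(example_graph("two_views.yaml"),
                  overrides = c("src.dims=[16, 16, 16]", "src.radius=5",
                                "view_front.eye=[8, -20, 8]",
                                "view_front.target=[8, 8, 8]",
                                "view_above.eye=[26, 8, 30]",
                                "view_above.target=[8, 8, 8]",
                                "view_front.width=16", "view_front.height=16",
                                "view_above.width=16", "view_above.height=16"),
                  outDir = out, quiet = TRUE)
  g <- res$graph
  before_front <- asArray(nodeOutput(g, "view_front.image"), drop = FALSE)
  before_above <- asArray(nodeOutput(g, "view_above.image"), drop = FALSE)
  dirty <- setParam(g, "view_above", "mode", "solid")
  expect_setequal(dirty, c("view_above", "out_above"))
  rep2 <- executeGraph(g)
  expect_setequal(rep2$id, dirty)
  # untouched branch keeps its cached output; changed branch differs
  expect_identical(asArray(nodeOutput(g, "view_front.image"), drop = FALSE),
                   before_front)
  expect_false(identical(asArray(nodeOutput(g, "view_above.image"),
                                 drop = FALSE), before_above))
})

test_that("a graph file containing a cycle fails validation, writing nothing", {
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nodes:",
               "  - {id: a, kind: gaussian_blur}",
               "  - {id: b, kind: median_filter}",
               "edges:",
               "  - a.output -> b.input",
               "  - b.output -> a.input"), bad)
  out <- withr::local_tempdir()
  expect_error(runGraph(bad, outDir = out, quiet = TRUE), "cycle rejected")
  expect_identical(list.files(out), character(0))
})
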