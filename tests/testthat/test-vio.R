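test_that("native format round-trips bit-exactly across the full grid", {
  seed <- 0
  for (dtype in c("u8", "u16", "f32")) {
    for (ch in 1:4) {
      for (nax in 1:3) {
        seed <- seed + 1
        dims <- c(7, 5, 4)[seq_len(nax)]
        v <- rand_volume(dims, seed, channels = ch, dtype = dtype)
        f <- withr::local_tempfile(fileext = ".vxvf")
        writeVolume(v, f)
        r <- readVolume(f)
        expect_identical(voxelType(r), dtype)
        expect_identical(nChannels(r), ch)
        expect_identical(voxelDims(r), voxelDims(v))
        expect_identical(asArray(r, drop = FALSE), asArray(v, drop = FALSE))
      }
    }
  }
})

test_that("constant volumes compress well below raw size", {
  v <- makeVolume(c(16, 16, 16), dtype = "u16", fill = 1234L)
  f <- withr::local_tempfile(fileext = ".vxvf")
  writeVolume(v, f)
  raw_bytes <- prod(voxelDims(v)) * 2
  expect_lt(file.size(f), raw_bytes)
  expect_identical(asArray(readVolume(f)), asArray(v))
})

test_that("header corruption yields documented errors, never a crash", {
  v <- rand_volume(c(6, 6), 77, dtype = "u8")
  f <- withr::local_tempfile(fileext = ".vxvf")
  writeVolume(v, f)
  good <- readBin(f, "raw", n = file.size(f))
  poke <- function(bytes, at, val) {
    bytes[at] <- as.raw(val)
    g <- withr::local_tempfile(.local_envir = parent.frame())
    writeBin(bytes, g)
    g
  }
  # flipped magic byte
  expect_error(readVolume(poke(good, 1, 0x58)), "unrecognized format")
  # future version
  expect_error(readVolume(poke(good, 5, 0x02)), "unsupported format version")
  # nonsense dtype code
  expect_error(readVolume(poke(good, 9, 0x7f)), "unknown dtype code")
  # implausible axis count
  expect_error(readVolume(poke(good, 7, 9)), "implausible")
  # truncated payload
  g <- withr::local_tempfile()
  writeBin(good[1:(length(good) - 5)], g)
  expect_error(readVolume(g), "truncated file")
  # truncated header
  g2 <- withr::local_tempfile()
  writeBin(good[1:8], g2)
  expect_error(readVolume(g2), "truncated file")
  # dims inconsistent with the stored payload length
  bad_dim <- good
  bad_dim[13] <- as.raw(9)  # first extent 6 -> 9
  g3 <- withr::local_tempfile()
  writeBin(bad_dim, g3)
  expect_error(readVolume(g3), "corrupt header")
  # uncompressed-length field corrupted
  expect_error(readVolume(poke(good, 21, 0x01)), "corrupt header")
  # compressed-length field inflated beyond the file
  expect_error(readVolume(poke(good, 29, 0xff)), "truncated file")
})

test_that("readers skip unknown trailing header fields (forward compat)", {
  v <- rand_volume(c(4, 3), 5, dtype = "u8")
  f <- withr::local_tempfile(fileext = ".vxvf")
  writeVolume(v, f)
  bytes <- readBin(f, "raw", n = file.size(f))
  # splice 4 extra header bytes after the fixed fields and declare them
  extra <- as.raw(c(0xde, 0xad, 0xbe, 0xef))
  bytes2 <- c(bytes[1:10], as.raw(c(4, 0)), extra,
              bytes[13:length(bytes)])
  g <- withr::local_tempfile()
  writeBin(bytes2, g)
  expect_identical(asArray(readVolume(g)), asArray(v))
})

test_that("detection prefers content probes over extensions", {
  v <- rand_volume(c(5, 5, 5), 88, dtype = "u16")
  f <- withr::local_tempfile(fileext = ".png")  # native file, lying extension
  writeVolume(v, f)
  r <- detectAndRead(f)
  expect_identical(asArray(r), asArray(v))

  blob <- withr::local_tempfile(fileext = ".xyz")
  writeBin(as.raw(1:64), blob)
  expect_error(detectAndRead(blob), "no plugin claims.*native")
})

test_that("the PNG plugin round-trips through its own writer", {
  img <- rand_volume(c(9, 7), 90, dtype = "u8")
  f <- withr::local_tempfile(fileext = ".png")
  writeAuto(img, f)
  r <- detectAndRead(f)
  expect_identical(voxelDims(r), voxelDims(img))
  expect_equal(normalizedArray(r), normalizedArray(img), tolerance = 1e-6)
})

test_that("the medical-imaging plugin reads NIfTI and TIFF", {
  a <- array(round(runif(4 * 5 * 6), 3), dim = c(4, 5, 6))
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(a), f)
  r <- detectAndRead(f)
  expect_identical(voxelDims(r), c(4L, 5L, 6L))
  expect_equal(asArray(r), a, tolerance = 1e-6)

  img <- rand_volume(c(6, 4), 91, dtype = "u8")
  ft <- withr::local_tempfile(fileext = ".tiff")
  writeAuto(img, ft)
  rt <- detectAndRead(ft)
  expect_equal(normalizedArray(rt), normalizedArray(img), tolerance = 1e-6)
})

test_that("plugin registration is dynamic and probes are consulted", {
  probed <- new.env()
  probed$n <- 0L
  spy <- formatPlugin(
    name = "spy", extensions = "spy",
    probe = function(bytes) {
      probed$n <- probed$n + 1L
      length(bytes) >= 3L && identical(bytes[1:3], charToRaw("SPY"))
    },
    reader = function(path) volumeFromArray(42))
  registerPlugin(spy)
  withr::defer(try(deregisterPlugin("spy"), silent = TRUE))
  expect_error(registerPlugin(spy), "already registered")

  f <- withr::local_tempfile()
  writeBin(charToRaw("SPYDATA"), f)
  r <- detectAndRead(f)
  expect_gt(probed$n, 0L)
  expect_equal(asArray(r)[1], 42)

  deregisterPlugin("spy")
  expect_error(detectAndRead(f), "no plugin claims")
  expect_false("spy" %in% listPlugins())
})
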