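# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (full sorts, O(n^2) scans, dense sums) so it cannot
# share a defect with the fast implementations it checks.

rand_volume <- function(dims, seed, channels = 1L, dtype = "f32") {
  set.seed(seed)
  n <- prod(dims) * channels
  a <- switch(dtype,
              f32 = array(runif(n), dim = c(dims, channels)),
              u8 = array(sample.int(256L, n, replace = TRUE) - 1L,
                         dim = c(dims, channels)),
              u16 = array(sample.int(65536L, n, replace = TRUE) - 1L,
                          dim = c(dims, channels)))
  if (channels == 1L)
    volumeFromArray(array(a, dim = dims), dtype = dtype)
  else
    volumeFromArray(a, dtype = dtype, channels = channels)
}

# O(n^2) nearest-solid Euclidean distance
brute_edt <- function(solid) {
  d <- dim(solid)
  coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                  z = seq_len(d[3])))
  sc <- coords[as.vector(solid), , drop = FALSE]
  stopifnot(nrow(sc) > 0L)
  out <- numeric(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    dd <- sweep(sc, 2, coords[i, ])
    out[i] <- sqrt(min(rowSums(dd^2)))
  }
  array(out, dim = d)
}

clamp_idx <- function(n, shift) pmin(pmax(seq_len(n) + shift, 1L), n)

# full-sort 27-neighborhood median with clamped borders
median_oracle <- function(a) {
  d <- dim(a)
  out <- array(0, dim = d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    xs <- pmin(pmax(x + (-1:1), 1L), d[1])
    ys <- pmin(pmax(y + (-1:1), 1L), d[2])
    zs <- pmin(pmax(z + (-1:1), 1L), d[3])
    vals <- as.vector(a[xs, ys, zs])
    out[x, y, z] <- sort(vals)[14]
  }
  out
}

# dense separable convolution by direct summation with clamped indices
dense_conv_oracle <- function(a, kx, ky, kz) {
  d <- dim(a)
  rx <- (length(kx) - 1L) / 2L
  ry <- (length(ky) - 1L) / 2L
  rz <- (length(kz) - 1L) / 2L
  out <- array(0, dim = d)
  for (i in seq_along(kx)) for (j in seq_along(ky)) for (k in seq_along(kz)) {
    w <- kx[i] * ky[j] * kz[k]
    out <- out + w * a[clamp_idx(d[1], i - rx - 1L),
                       clamp_idx(d[2], j - ry - 1L),
                       clamp_idx(d[3], k - rz - 1L)]
  }
  out
}

# direct box reduce
region_oracle <- function(a, op, r) {
  d <- dim(a)
  out <- array(0, dim = d)
  f <- switch(op, min = min, max = max, avg = mean)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    xs <- pmin(pmax(x + (-r:r), 1L), d[1])
    ys <- pmin(pmax(y + (-r:r), 1L), d[2])
    zs <- pmin(pmax(z + (-r:r), 1L), d[3])
    out[x, y, z] <- f(a[xs, ys, zs])
  }
  out
}

# graph-search reachability over an edge data.frame (node -> downstream set)
reach_oracle <- function(edges, start) {
  seen <- start
  frontier <- start
  while (length(frontier) > 0L) {
    nxt <- setdiff(unique(edges$dst_node[edges$src_node %in% frontier]), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# back-to-front closed-form compositing: sum_i c_i a_i prod_{j<i} (1 - a_j)
composite_closed_form <- function(alpha, color) {
  trans <- cumprod(c(1, 1 - alpha))[seq_along(alpha)]
  list(color = sum(color * alpha * trans),
       alpha = 1 - prod(1 - alpha))
}

# random executable DAG: sources feed binary 'elementwise' combiners
rand_dag <- function(seed, n_src = 2L, n_mid = 5L) {
  set.seed(seed)
  g <- flowGraph()
  srcs <- paste0("s", seq_len(n_src))
  for (s in srcs)
    addNode(g, s, "sphere_phantom",
            list(dims = c(4, 4, 4), radius = sample(1:2, 1)))
  mids <- paste0("n", seq_len(n_mid))
  avail <- data.frame(node = srcs, portname = "volume",
                      stringsAsFactors = FALSE)
  for (m in mids) {
    addNode(g, m, "elementwise", list(op = "add"))
    pick <- sample(nrow(avail), 1)
    connect(g, paste0(avail$node[pick], ".", avail$portname[pick]),
            paste0(m, ".a"))
    if (runif(1) < 0.6) {
      pick2 <- sample(nrow(avail), 1)
      connect(g, paste0(avail$node[pick2], ".", avail$portname[pick2]),
              paste0(m, ".b"))
    }
    avail <- rbind(avail, data.frame(node = m, portname = "output",
                                     stringsAsFactors = FALSE))
  }
  g
}

example_graph <- function(name) {
  system.file("examples", name, package = "voxelflow", mustWork = TRUE)
}
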