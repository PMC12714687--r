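# shared fixture builders (all generated in code; no stored data)

# random blob mask: union of a few random balls, plus salt noise
randomMask <- function(dims, n_balls = 3, p_noise = 0.02) {
  m <- array(FALSE, dims)
  idx <- which(!m, arr.ind = TRUE)
  for (b in seq_len(n_balls)) {
    c0 <- runif(3, 1, dims)
    r <- runif(1, 1, max(2, min(dims) / 3))
    d2 <- (idx[, 1] - c0[1])^2 + (idx[, 2] - c0[2])^2 + (idx[, 3] - c0[3])^2
    m[idx[d2 <= r^2]] <- TRUE
  }
  m | array(runif(prod(dims)) < p_noise, dims)
}

# straight z-axis tube as a LabelMap (world offset controls grid alignment)
tubeMap <- function(D, h, length_mm = 8, off = c(0, 0), pv = 0,
                    label = 2L) {
  r <- D / 2 + pv * h
  fov <- rbind(c(-r - 2 + off[1], -r - 2 + off[2], 0),
               c(r + 2 + off[1], r + 2 + off[2], length_mm + 2 * r + 2))
  tb <- tubeSpec(label, rbind(c(off[1], off[2], r + 1.5),
                              c(off[1], off[2], r + 1.5 + length_mm)), D)
  rasterize(phantomSpec(list(tb), fov, h,
                        vocabulary = stats::setNames("ICA-R", label),
                        pv_frac = pv))
}

# mean local thickness along the skeleton of the full foreground
maskDiameter <- function(labelmap) {
  lt <- localThickness(labelmap)
  sk <- which(skeletonize3d(gridValues(labelmap) > 0), arr.ind = TRUE)
  mean(gridValues(lt)[sk])
}

# number of 26-connected foreground components (plain BFS; test oracle)
nComponents26 <- function(m) {
  dims <- dim(m)
  lab <- array(0L, dims)
  nc <- 0L
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  idx <- which(m, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    p <- idx[s, ]
    if (lab[p[1], p[2], p[3]] > 0) next
    nc <- nc + 1L
    queue <- matrix(p, 1)
    lab[p[1], p[2], p[3]] <- nc
    while (nrow(queue)) {
      q <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(off, 2, q, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      for (t in seq_len(nrow(nb))) {
        v <- nb[t, ]
        if (m[v[1], v[2], v[3]] && lab[v[1], v[2], v[3]] == 0L) {
          lab[v[1], v[2], v[3]] <- nc
          queue <- rbind(queue, v)
        }
      }
    }
  }
  nc
}

# brute-force spacing-aware distance to nearest background center (oracle)
bruteDistanceMap <- function(m, spacing) {
  dims <- dim(m)
  bg <- which(!m, arr.ind = TRUE)
  out <- array(0, dims)
  fg <- which(m, arr.ind = TRUE)
  for (s in seq_len(nrow(fg))) {
    p <- fg[s, ]
    d2 <- (bg[, 1] - p[1])^2 * spacing[1]^2 +
      (bg[, 2] - p[2])^2 * spacing[2]^2 +
      (bg[, 3] - p[3])^2 * spacing[3]^2
    out[p[1], p[2], p[3]] <- sqrt(min(d2))
  }
  out
}

# exact one-sided signed-rank margin p-value by 2^n sign enumeration (oracle)
bruteWilcoxonLess <- function(diffs, margin) {
  x <- abs(diffs) - margin
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  wobs <- sum(r[x > 0])
  count <- 0
  for (bits in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(bits, 2^(0:(n - 1))))
    if (sum(r[signs]) <= wobs + 1e-9) count <- count + 1
  }
  count / 2^n
}
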