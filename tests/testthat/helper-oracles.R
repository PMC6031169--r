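# Independent brute-force oracles, deliberately naive: they recompute the
# quantities by per-pixel / per-term loops and never share code with the
# package's implementations.

# per-pixel double loop over mask pixels, layer by layer
bruteLayerCounts <- function(mask, bounds) {
  counts <- numeric(nrow(bounds))
  for (k in seq_len(nrow(bounds))) {
    s <- 0
    for (y in bounds[k, "yT"]:bounds[k, "yB"]) {
      for (x in seq_len(ncol(mask))) {
        if (mask[y, x] != 0) s <- s + 1
      }
    }
    counts[k] <- s
  }
  counts
}

# per-pixel sums of the masked depth, layer by layer
bruteLayerDepthSums <- function(depthProfile, bounds) {
  sums <- numeric(nrow(bounds))
  for (k in seq_len(nrow(bounds))) {
    s <- 0
    for (y in bounds[k, "yT"]:bounds[k, "yB"]) {
      for (x in seq_len(ncol(depthProfile))) {
        s <- s + depthProfile[y, x]
      }
    }
    sums[k] <- s
  }
  sums
}

# naive term-by-term polynomial evaluation (coefficients as printed,
# highest degree first)
brutePolyCm <- function(x) {
  coefs <- c(1.2512e-10, -1.0370e-7, 3.5014e-5, -0.0061, 0.5775,
             -27.6342, 5.6759e2)
  degs <- 6:0
  s <- 0
  for (i in seq_along(coefs)) s <- s + coefs[i] * x^degs[i]
  s
}

# BFS 8-connected component labeling on a binary matrix
bruteLabel8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] != 0 && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1] + di; nj <- p[2] + dj
          if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              mask[ni, nj] != 0 && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# reference binary morphology with a side x side all-ones square element
bruteErode <- function(mask, side) {
  r <- (side - 1) %/% 2
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (di in (-r):(side - 1 - r)) for (dj in (-r):(side - 1 - r)) {
      ni <- i + di; nj <- j + dj
      v <- if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc) mask[ni, nj] else 0
      if (v == 0) ok <- FALSE
    }
    out[i, j] <- if (ok) 1L else 0L
  }
  out
}

bruteDilate <- function(mask, side) {
  r <- (side - 1) %/% 2
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    any1 <- FALSE
    for (di in (-r):(side - 1 - r)) for (dj in (-r):(side - 1 - r)) {
      ni <- i + di; nj <- j + dj
      if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc && mask[ni, nj] != 0)
        any1 <- TRUE
    }
    out[i, j] <- if (any1) 1L else 0L
  }
  out
}

bruteOpen <- function(mask, side) bruteDilate(bruteErode(mask, side), side)
bruteClose <- function(mask, side) bruteErode(bruteDilate(mask, side), side)

# elementwise repeated multiplication, one view at a time
bruteProduct <- function(vectors) {
  out <- rep(1, length(vectors[[1]]))
  for (v in vectors) {
    for (k in seq_along(out)) out[k] <- out[k] * v[k]
  }
  out
}

# random blob mask: a filled ellipse-ish region plus speckle, never empty
randomBlobMask <- function(nr = 50, nc = 80) {
  cy <- runif(1, nr * 0.3, nr * 0.7); cx <- runif(1, nc * 0.3, nc * 0.7)
  ry <- runif(1, nr * 0.15, nr * 0.45); rx <- runif(1, nc * 0.1, nc * 0.4)
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  m <- (((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1) * 1L
  m[sample(nr * nc, round(0.02 * nr * nc))] <- 1L
  if (sum(m) == 0) m[round(cy), round(cx)] <- 1L
  storage.mode(m) <- "integer"
  m
}

# random blob with a depth profile attached
randomBlob <- function(nr = 50, nc = 80) {
  m <- randomBlobMask(nr, nc)
  frame <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
  extractBlob(frame, m)
}

# tight bbox of a binary matrix, computed naively
bruteBbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  c(x = min(idx[, 2]), y = min(idx[, 1]),
    w = max(idx[, 2]) - min(idx[, 2]) + 1L,
    h = max(idx[, 1]) - min(idx[, 1]) + 1L)
}

# minimal PNG-like file: valid signature + IHDR declaring the given bit
# depth; enough for dialect-rejection tests (the reader rejects on IHDR
# before decoding)
writeFakePng <- function(path, bitDepth = 16L, colorType = 0L) {
  sig <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))
  lenBytes <- as.raw(c(0, 0, 0, 13))
  type <- charToRaw("IHDR")
  wh <- as.raw(c(0, 0, 0, 4, 0, 0, 0, 4)) # 4x4
  rest <- as.raw(c(bitDepth, colorType, 0, 0, 0))
  crc <- as.raw(c(0, 0, 0, 0)) # CRC not validated by the header check
  con <- file(path, "wb")
  writeBin(c(sig, lenBytes, type, wh, rest, crc), con)
  close(con)
  path
}
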