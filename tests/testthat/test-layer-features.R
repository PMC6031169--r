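test_that("layer bounds partition the blob rows exactly", {
  b <- layerBounds(30, 1)
  expect_equal(unname(b[, "yT"]), c(1, 11, 21))
  expect_equal(unname(b[, "yB"]), c(10, 20, 30))

  b2 <- layerBounds(10, 2)
  expect_equal(unname(b2[, "yT"]), c(1, 3, 5, 7, 9))
  expect_equal(unname(b2[, "yB"]), c(2, 4, 6, 8, 10))

  b3 <- layerBounds(3, 1)
  expect_equal(unname(b3[, "yT"]), 1:3)
  expect_equal(unname(b3[, "yB"]), 1:3)

  expect_error(layerBounds(4, 2), "too few rows")

  # partition property over a representative sweep
  for (N in c(1L, 3L, 6L, 9L)) {
    L <- 2L * N + 1L
    for (Hh in c(L, L + 1L, 57L, 200L, 499L)) {
      bb <- layerBounds(Hh, N)
      expect_equal(bb[1, "yT"], 1L)
      expect_equal(bb[L, "yB"], Hh)
      if (L > 1)
        expect_true(all(bb[-1, "yT"] == bb[-L, "yB"] + 1L))
      if (Hh >= L) expect_true(all(bb[, "yB"] >= bb[, "yT"]))
    }
  }
})

test_that("layer densities count mask pixels and normalize by the max", {
  # full 6-row x 4-col mask: each of 3 layers holds 2 rows x 4 cols = 8
  mask <- matrix(1L, 6, 4)
  b <- layerBounds(6, 1)
  d <- layerDensity(mask, b)
  expect_equal(d$rhoRaw, c(8, 8, 8))
  expect_equal(d$rho, c(1, 1, 1))

  expect_equal(LayerFusion:::.maxNormalize(c(10, 20, 40)), c(0.25, 0.5, 1))
  expect_equal(LayerFusion:::.maxNormalize(c(0, 5, 5)), c(0, 1, 1))
  expect_equal(LayerFusion:::.maxNormalize(c(0, 0)), c(0, 0))
})

test_that("layer density matches the per-pixel double-loop oracle", {
  set.seed(5)
  for (i in 1:60) {
    blob <- randomBlob(50, 80)
    Hh <- bbox(blob)[4]
    N <- sample(1:3, 1)
    if (Hh < 2 * N + 1) next
    b <- layerBounds(Hh, N)
    d <- layerDensity(blob, b)
    ref <- bruteLayerCounts(blobMask(blob), b)
    expect_identical(d$rhoRaw, ref)               # bit-exact counts
    expect_equal(sum(d$rhoRaw), sum(blobMask(blob)))  # conservation
    expect_equal(max(d$rho), 1)                   # non-empty blob
  }
})

test_that("depth-value-to-cm polynomial evaluates exactly as printed", {
  expect_identical(depthToCm(0), 5.6759e2)
  expect_equal(depthToCm(1), brutePolyCm(1), tolerance = 1e-12)
  # Horner equals naive summation across the domain
  xs <- c(0.5, 1, 17, 63.2, 128, 200, 255)
  expect_equal(depthToCm(xs), brutePolyCm(xs), tolerance = 1e-9)
  expect_error(depthToCm(-1), "0, 255")
  expect_error(depthToCm(256), "0, 255")
})

test_that("real-range depth averages foreground depth and normalizes", {
  # single layer, all foreground at depth value 0 -> D' = 567.59, D = 1
  mask <- matrix(1L, 3, 3)
  blob <- new("HumanBlob", rawBbox = c(1L, 1L, 3L, 3L),
              bbox = c(1L, 1L, 3L, 3L), mask = mask,
              depthProfile = matrix(0L, 3, 3))
  b <- layerBounds(3, 0)
  d <- layerRealDepth(blob, b, rhoRaw = c(9))
  expect_equal(d$depthRaw, 567.59)
  expect_equal(d$depth, 1)

  expect_equal(LayerFusion:::.maxNormalize(c(100, 50)), c(1, 0.5))
  # empty middle layer contributes 0, not NaN
  expect_equal(LayerFusion:::.maxNormalize(c(80, 0, 80)), c(1, 0, 1))
})

test_that("real-range depth matches a per-pixel oracle on random blobs", {
  set.seed(6)
  for (i in 1:40) {
    blob <- randomBlob(50, 80)
    Hh <- bbox(blob)[4]
    if (Hh < 3) next
    b <- layerBounds(Hh, 1)
    rr <- layerDensity(blob, b)$rhoRaw
    d <- layerRealDepth(blob, b, rr)
    sums <- bruteLayerDepthSums(depthProfile(blob), b)
    ref <- ifelse(rr > 0, brutePolyCm(ifelse(rr > 0, sums / pmax(rr, 1), 0)), 0)
    expect_equal(d$depthRaw, ref, tolerance = 1e-12)
  }
})

test_that("inverse depth min-max flips and handles flat profiles", {
  expect_equal(inverseDepth(c(1, 0.5, 0.25)), c(0, 2 / 3, 1))
  expect_equal(inverseDepth(c(0.3, 0.3, 0.3)), c(0, 0, 0))
  expect_equal(inverseDepth(c(1, 0)), c(0, 1))
})

test_that("weighted depth density blends Q and rho under both conventions", {
  # alpha limits
  rho <- c(0.2, 0.7, 1); di <- c(1, 0.4, 0)
  expect_equal(weightedDensity(rho, di, alpha = 1)$z, rho)
  expect_equal(weightedDensity(rho, di, alpha = 0)$z, di * rho)
  # hand evaluation
  wd <- weightedDensity(c(1, 0.5), c(0, 1), alpha = 0.9)
  expect_equal(wd$q, c(0, 0.5))
  expect_equal(wd$z, c(0.9, 0.5))
  # prose convention swaps the weights
  wp <- weightedDensity(c(1, 0.5), c(0, 1), alpha = 0.9,
                        convention = "prose")
  expect_equal(wp$z, 0.9 * c(0, 0.5) + 0.1 * c(1, 0.5))
  expect_error(weightedDensity(rho, di, alpha = 1.2), "alpha")
})

test_that("proportion value is width over height", {
  expect_equal(proportionValue(c(1, 1, 50, 100)), 0.5)
  expect_equal(proportionValue(c(1, 1, 120, 60)), 2)
  expect_equal(proportionValue(c(1, 1, 33, 33)), 1)
  expect_error(proportionValue(c(1, 1, 10, 0)), "height")
})

test_that("full layer profiles keep all normalized features in [0, 1]", {
  set.seed(9)
  for (i in 1:30) {
    blob <- randomBlob(60, 60)
    lp <- layerProfile(blob, layers = 5, alpha = 0.9)
    if (is.null(lp)) next
    for (v in list(lp@rho, lp@depth, lp@depthInv, lp@q, lp@z)) {
      expect_true(all(v >= 0 & v <= 1))
    }
    expect_equal(max(lp@rho), 1)
    expect_equal(sum(lp@rhoRaw), sum(blobMask(blob)))
    expect_gt(lp@proportion, 0)
  }
})

test_that("pixel-replication doubling leaves rho unchanged", {
  set.seed(12)
  for (i in 1:10) {
    m <- randomBlobMask(30, 30)
    blob <- extractBlob(matrix(100L, 30, 30), m)
    Hh <- bbox(blob)[4]
    # need height divisible by 3 for exact layer alignment after doubling
    Hh3 <- Hh - (Hh %% 3L)
    if (Hh3 < 3) next
    msk <- blobMask(blob)[seq_len(Hh3), , drop = FALSE]
    if (sum(msk) == 0) next
    big <- msk[rep(seq_len(nrow(msk)), each = 2),
               rep(seq_len(ncol(msk)), each = 2)]
    d1 <- layerDensity(msk, layerBounds(nrow(msk), 1))
    d2 <- layerDensity(big, layerBounds(nrow(big), 1))
    expect_equal(d2$rhoRaw, 4 * d1$rhoRaw)
    expect_equal(d2$rho, d1$rho)
  }
})
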