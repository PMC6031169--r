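test_that("background model takes per-pixel lower median and robust spread", {
  const <- replicate(40, matrix(100L, 4, 4), simplify = FALSE)
  bm <- buildBackgroundModel(const)
  expect_true(all(bm@reference == 100))
  expect_true(all(bm@spread == 0))

  # alternating 100/102: lower median rule picks 100
  alt <- lapply(1:40, function(i) matrix(if (i %% 2) 100L else 102L, 4, 4))
  bm2 <- buildBackgroundModel(alt)
  expect_true(all(bm2@reference == 100))

  single <- buildBackgroundModel(list(matrix(7L, 3, 3)))
  expect_true(all(single@reference == 7))
  expect_equal(single@frameCount, 1L)

  expect_error(buildBackgroundModel(list()), "at least one")
})

test_that("foreground extraction thresholds against the reference depth", {
  bg <- buildBackgroundModel(replicate(30, matrix(200L, 30, 40),
                                       simplify = FALSE))
  fr <- matrix(200L, 30, 40)
  expect_true(all(extractForeground(fr, bg, tau = 15) == 0))

  fr[10:19, 5:24] <- 80L   # 10x20 region at depth 80
  fg <- extractForeground(fr, bg, tau = 15)
  expected <- matrix(0L, 30, 40); expected[10:19, 5:24] <- 1L
  expect_identical(fg, expected)

  expect_true(all(extractForeground(fr, bg, tau = 255) == 0))
  expect_error(extractForeground(matrix(1L, 2, 2), bg), "dimensions")

  # pluggable extractor replaces the default entirely
  custom <- extractForeground(fr, bg,
    extractor = function(frame, model) (frame < 100) * 1L)
  expect_identical(custom, expected)
})

test_that("mask denoising is opening-then-closing and matches the reference", {
  m <- matrix(0L, 30, 30); m[5:24, 5:24] <- 1L; m[10, 10] <- 0L  # hole
  m[2, 2] <- 1L                                                  # speckle
  expect_identical(denoiseMask(m, 0L), m)

  out <- denoiseMask(m, 1L)
  expect_equal(out[2, 2], 0)        # isolated pixel removed
  expect_equal(out[10, 10], 1)      # interior hole filled
  expect_identical(out, bruteClose(bruteOpen(m, 3L), 3L))

  # idempotence on already open-closed shapes
  expect_identical(denoiseMask(out, 1L), out)
})

test_that("maskedDepth is the AND of mask and depth", {
  fr <- matrix(7L, 4, 4)
  expect_identical(maskedDepth(matrix(1L, 4, 4), fr), fr)
  expect_true(all(maskedDepth(matrix(0L, 4, 4), fr) == 0))
  chk <- matrix((1:16) %% 2L, 4, 4)
  out <- maskedDepth(chk, fr)
  expect_true(all(out[chk == 1] == 7) && all(out[chk == 0] == 0))
  expect_error(maskedDepth(matrix(1L, 2, 2), fr), "dimensions")
})

test_that("locateBlob finds the largest 8-connected component's tight box", {
  m <- matrix(0L, 20, 20); m[4:11, 3:7] <- 1L   # 8x5 rectangle at (3,4)
  expect_equal(locateBlob(m), c(3L, 4L, 5L, 8L))

  # two components, areas 40 and 12: box of the large one
  m2 <- matrix(0L, 25, 25)
  m2[3:10, 3:7] <- 1L   # 40 px
  m2[20:22, 15:18] <- 1L # 12 px
  expect_equal(locateBlob(m2), c(3L, 3L, 5L, 8L))

  expect_null(locateBlob(matrix(0L, 5, 5)))

  # diagonal-only connection counts as one component (8-connectivity)
  m3 <- matrix(0L, 6, 6); m3[2, 2] <- 1L; m3[3, 3] <- 1L; m3[4, 4] <- 1L
  expect_equal(locateBlob(m3), c(2L, 2L, 3L, 3L))
})

test_that("component labeling agrees with a BFS oracle on random masks", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(rbinom(30 * 30, 1, 0.35), 30, 30)
    if (sum(m) == 0) next
    lab <- LayerFusion:::labelComponents(m)
    ref <- bruteLabel8(m)
    # same partition: component count and identical pixel grouping
    expect_equal(max(lab), max(ref))
    expect_equal(length(unique(paste(lab, ref))) - 1L, max(ref))
    # largest-component bbox agrees with choosing it from the oracle labels
    areasRef <- tabulate(ref[ref > 0])
    compRef <- (ref == which.max(areasRef)) * 1L
    if (sum(areasRef == max(areasRef)) == 1L)
      expect_equal(locateBlob(m), unname(as.integer(bruteBbox(compRef))))
  }
})

test_that("blob boxes are tight: shrinking any side drops a foreground pixel", {
  set.seed(7)
  for (i in 1:20) {
    m <- randomBlobMask(40, 40)
    bb <- locateBlob(m)
    blob <- extractBlob(matrix(100L, 40, 40), m)
    msk <- blobMask(blob)
    expect_true(any(msk[1, ] > 0))
    expect_true(any(msk[nrow(msk), ] > 0))
    expect_true(any(msk[, 1] > 0))
    expect_true(any(msk[, ncol(msk)] > 0))
    # depth profile zero exactly off-mask
    expect_true(all(depthProfile(blob)[msk == 0] == 0))
    expect_true(all(depthProfile(blob)[msk == 1] != 0))
    expect_equal(bb, bbox(blob))
  }
})

test_that("arm rejection removes thin protrusions and never enlarges the mask", {
  # torso 20 px wide with a 2-px-thick arm; H_h = 60, s = 0.05 -> side 3
  fr <- matrix(0L, 80, 80); msk <- matrix(0L, 80, 80)
  msk[11:70, 30:49] <- 1L    # torso 60 tall, 20 wide
  msk[20:21, 50:70] <- 1L    # arm sticking right
  fr[msk == 1] <- 120L
  blob <- extractBlob(fr, msk)
  expect_equal(bbox(blob)[3], 41L)  # arm included before rejection

  trimmed <- removeArms(blob, strength = 0.05)
  expect_equal(bbox(trimmed)[3], 20L)  # back to torso width
  expect_equal(bbox(trimmed)[4], 60L)
  expect_lte(sum(blobMask(trimmed)), sum(blobMask(blob)))
  expect_identical(rawBbox(trimmed), bbox(blob))

  # s = 0 disables
  expect_identical(removeArms(blob, 0), blob)

  # blob thinner than the element everywhere -> no-subject signal
  thin <- matrix(0L, 40, 40); thin[5:34, 20] <- 1L
  tb <- extractBlob(matrix(50L, 40, 40), thin)
  expect_null(removeArms(tb, strength = 0.2))

  # matches the reference morphology oracle on the explicit grid
  side <- max(1L, round(0.05 * 60))
  opened <- bruteOpen(blobMask(blob), side)
  bbRef <- bruteBbox(opened)
  expect_equal(unname(bbox(trimmed)[3:4]),
               unname(as.integer(bbRef[c("w", "h")])))
})

test_that("recovered bbox matches ground truth within 2 px under 1% noise", {
  cfg <- sceneConfig(maskFlipRate = 0.01, depthJitter = 2)
  bgm <- buildBackgroundModel(
    lapply(1:40, function(i) LayerFusion:::.renderBackgroundFrame(cfg)))
  set.seed(101)
  for (action in actionClasses()) {
    body <- sampleBodyParams()
    seq <- renderAction(action, body, 0, cfg, distance = 4, cx = 0.5)
    gt <- attr(seq, "gtMask")
    gtBox <- bruteBbox(gt)
    blob <- detectSubject(pixels(seq[[1]]), bgm, armStrength = 0)
    expect_false(is.null(blob))
    expect_true(all(abs(bbox(blob) - as.integer(gtBox)) <= 2),
                label = paste("bbox recovery for", action))
  }
})
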