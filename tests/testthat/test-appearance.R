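test_that("default configuration yields a 110-bin histogram", {
  cfg <- histogramConfig()
  expect_equal(cfg$B, 110L)
  h <- hsvHistogram(randomMaskedFrame(8, 8))
  expect_length(h@bins, 110L)
})

test_that("uniform-color regions fill exactly two bins", {
  # one known HSV triple, hand-binned: pure red -> H=0, S=1, V=1
  fr <- blankFrame(5, 10, c(1, 0, 0))
  h <- hsvHistogram(fr)
  expect_equal(h@nPixels, 50L)
  cfg <- histogramConfig()
  chromaBin <- 0 * cfg$nS + (cfg$nS - 1) + 1          # H bin 0, S bin 9
  valueBin <- cfg$nH * cfg$nS + (cfg$nV - 1) + 1      # V bin 9
  expect_equal(which(h@bins > 0), sort(c(chromaBin, valueBin)))
  expect_equal(h@bins[chromaBin], 50L)
  expect_equal(h@bins[valueBin], 50L)
  expect_equal(sum(h@bins), 2L * h@nPixels)
})

test_that("all-background regions give a valid empty histogram", {
  h <- hsvHistogram(blankFrame(6, 6, c(0, 0, 0)))
  expect_equal(h@nPixels, 0L)
  expect_true(all(h@bins == 0L))
})

test_that("integral histogram queries equal brute force bitwise", {
  set.seed(123)
  for (rep in 1:3) {
    fr <- randomMaskedFrame(64, 64)
    ih <- integralHistogram(fr)
    for (k in 1:30) {
      x0 <- sample(0:60, 1); x1 <- sample(x0:63, 1)
      y0 <- sample(0:60, 1); y1 <- sample(y0:63, 1)
      got <- regionHistogram(ih, c(x0, y0, x1, y1))
      want <- hsvHistogram(fr[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), ,
                              drop = FALSE])
      expect_identical(got@bins, want@bins)
      expect_identical(got@nPixels, want@nPixels)
    }
    # full-frame query telescopes to the plain histogram
    full <- regionHistogram(ih, c(0, 0, 63, 63))
    expect_identical(full@bins, hsvHistogram(fr)@bins)
  }
  # 1x1 image
  one <- array(c(0.2, 0.5, 0.9), c(1, 1, 3))
  expect_identical(regionHistogram(integralHistogram(one), c(0, 0, 0, 0))@bins,
                   hsvHistogram(one)@bins)
})

test_that("Bhattacharyya distance has its analytic values and bounds", {
  expect_equal(bhattacharyya(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(bhattacharyya(c(1, 0), c(0, 1)), 1)
  expect_equal(bhattacharyya(c(0.5, 0.5), c(1, 0)), sqrt(1 - sqrt(0.5)))
  expect_equal(bhattacharyya(numeric(5), numeric(5)), 1)  # no evidence
  expect_error(bhattacharyya(c(1, 0), c(1, 0, 0)), "bin")
  set.seed(9)
  for (i in 1:50) {
    a <- runif(20); b <- runif(20)
    d <- bhattacharyya(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bhattacharyya(b, a))                  # symmetric
  }
})

test_that("color score couples upper subwindows multiplicatively", {
  cw <- cueWeights()
  expect_equal(colorScore(rep(0, 4), cw), 100^3 + 100)    # 1,000,100
  expect_equal(colorScore(c(1, 0, 0, 0), cw), 100)        # veto -> lowest only
  expect_equal(colorScore(c(0, 0, 0, 1), cw), 100^3)      # additive term 0
  # monotone: increasing any distance never increases the score
  set.seed(2)
  for (i in 1:25) {
    d <- runif(4)
    k <- sample(4, 1)
    d2 <- d; d2[k] <- min(1, d[k] + runif(1, 0, 1 - d[k]))
    expect_lte(colorScore(d2, cw), colorScore(d, cw) + 1e-12)
  }
  # empty reference bands are skipped, not vetoing
  expect_equal(colorScore(c(1, 0, 0, 0), cw,
                          refEmpty = c(TRUE, FALSE, FALSE, FALSE)),
               100^2 + 100)
  expect_equal(colorScore(c(0, 0, 0, 1), cw,
                          refEmpty = c(FALSE, FALSE, FALSE, TRUE)), 100^3)
})

test_that("count score sums width-normalized nonzero counts", {
  m <- matrix(0L, 40, 20)
  bands <- lapply(0:3, function(k) c(2, k * 10, 11, k * 10 + 9))
  expect_equal(countScore(m, bands, 10), 0)
  m1 <- matrix(1L, 40, 20)
  expect_equal(countScore(m1, bands, 10), 4 * (10 * 10) / 10)   # 4h
  # content outside the box does not matter
  m2 <- m; m2[1:40, 15:20] <- 1L
  expect_equal(countScore(m2, bands, 10), 0)
  expect_error(countScore(m, bands, 0), "width")
})

test_that("total weight combines cues with the alpha weights", {
  cw <- cueWeights()
  expect_equal(totalWeight(1, 1, 1, cw), 1.5)
  expect_equal(totalWeight(0, 0, 0, cw), 0)
  expect_equal(totalWeight(0.5, 1, 0, cw), 0.5 + 0.4)
  # per-cue normalization puts the max at exactly 1
  x <- c(3, 7, 0.5)
  expect_equal(max(courtTrack:::.normCue(x)), 1)
  expect_equal(courtTrack:::.normCue(numeric(3)), numeric(3))
})
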