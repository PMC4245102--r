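test_that("a constant scene becomes the background", {
  gray <- blankFrame(20, 30, c(0.5, 0.5, 0.5))
  cfg <- backgroundConfig(feedStride = 1L)
  st <- newBackgroundModel(c(30, 20), cfg)
  for (i in 1:100) st <- updateBackground(st, gray, cfg)
  expect_lt(max(abs(st@background - 0.5)), 1 / 255)
  fb <- foregroundMask(st, gray, cfg)
  expect_equal(sum(fb$mask), 0)
})

test_that("feed stride ingests every N-th frame only", {
  gray <- blankFrame(10, 10, c(0.4, 0.4, 0.4))
  cfg <- backgroundConfig(feedStride = 10L)
  st <- newBackgroundModel(c(10, 10), cfg)
  for (i in 1:25) st <- updateBackground(st, gray, cfg)
  expect_equal(st@ingested, 3L)    # frames 0, 10, 20
  expect_equal(st@framesSeen, 25L)
})

test_that("a blob present in few fed frames stays out of the background", {
  set.seed(3)
  sand <- blankFrame(24, 32, c(0.6, 0.55, 0.4))
  cfg <- backgroundConfig(feedStride = 1L, lrNormal = 0.05)
  st <- newBackgroundModel(c(32, 24), cfg)
  blobRect <- c(10, 8, 15, 13)
  for (i in 1:60) {
    fr <- sand
    if (i %% 12 == 0)  # blob present in <10% of fed frames
      fr <- paintRect(fr, blobRect, c(0.9, 0.1, 0.1))
    st <- updateBackground(st, fr, cfg)
  }
  blobPx <- st@background[(blobRect[2] + 1):(blobRect[4] + 1),
                          (blobRect[1] + 1):(blobRect[3] + 1), 1]
  # dominant mode stays sand-colored: red channel near 0.6, not 0.9
  expect_lt(max(abs(blobPx - 0.6)), 0.05)
})

test_that("the adaptive learning rate recovers faster from a light step", {
  set.seed(1)
  base <- array(runif(40 * 60 * 3, 0.3, 0.7), c(40, 60, 3))
  recover <- function(cfg) {
    st <- newBackgroundModel(c(60, 40), cfg)
    for (i in 1:30) st <- updateBackground(st, base, cfg)
    stepped <- pmax(pmin(base * 1.6, 1), 0)
    n <- 0
    repeat {
      n <- n + 1
      st <- updateBackground(st, stepped, cfg)
      if (foregroundMask(st, stepped, cfg)$fgFraction < 0.01 || n > 300)
        break
    }
    n
  }
  nAdaptive <- recover(backgroundConfig(feedStride = 1L))
  nFixed <- recover(backgroundConfig(feedStride = 1L, lrHigh = 0.01))
  expect_lt(nAdaptive, nFixed)
})

test_that("foreground pipeline matches set arithmetic on a painted square", {
  sand <- blankFrame(60, 80, c(0.5, 0.5, 0.5))
  cfg <- backgroundConfig(feedStride = 1L)
  st <- newBackgroundModel(c(80, 60), cfg)
  for (i in 1:20) st <- updateBackground(st, sand, cfg)
  fr <- paintRect(sand, c(30, 20, 49, 39), c(1, 1, 1))
  fb <- foregroundMask(st, fr, cfg)
  want <- matrix(0L, 60, 80); want[21:40, 31:50] <- 1L
  # a 20x20 square survives a 3x3 opening unchanged
  expect_equal(fb$mask, want)
  # masked frame zero outside, original inside
  expect_true(all(fb$maskedFrame[want == 0] == 0 |
                  rep(want, 3)[fb$maskedFrame != 0] == 1))
  expect_equal(sum(fb$maskedFrame != 0), 3 * 400)
})

test_that("opening removes isolated pixels and is idempotent", {
  set.seed(11)
  m <- matrix(0L, 100, 100)
  m[cbind(sample(5:95, 250, TRUE), sample(5:95, 250, TRUE))] <- 1L
  op <- courtTrack:::.openMask(m, 1L)
  # salt noise: no 2x2 solid blocks at 250/8100 density w.h.p., but allow
  # the opening's survivors to be exactly the 3x3-covered pixels
  brush <- EBImage::makeBrush(3L, "box")
  oracle <- EBImage::dilate(EBImage::erode(m, brush), brush)
  expect_equal(op, matrix(as.integer(oracle > 0.5), 100))
  expect_equal(courtTrack:::.openMask(op, 1L), op)   # idempotent
})

test_that("movement mask sees moving disks only", {
  f1 <- blankFrame(60, 80, c(0.5, 0.5, 0.5))
  f2 <- f1
  cfg <- backgroundConfig()
  expect_equal(sum(movementMask(f1, f2, cfg)), 0)

  disk <- function(fr, cx, cy, r) {
    for (x in (cx - r):(cx + r)) for (y in (cy - r):(cy + r))
      if ((x - cx)^2 + (y - cy)^2 <= r^2)
        fr[y + 1, x + 1, ] <- c(1, 1, 1)
    fr
  }
  a <- disk(f1, 30, 30, 6)
  b <- disk(f1, 35, 30, 6)           # translated by 5 px
  mv <- movementMask(a, b, cfg)
  # movement only within the symmetric difference (dilated by the opening)
  symdiff <- (disk(f1, 30, 30, 6)[, , 1] != disk(f1, 35, 30, 6)[, , 1])
  grown <- EBImage::dilate(symdiff + 0, EBImage::makeBrush(3, "box")) > 0.5
  expect_true(all(mv[!grown] == 0))
  expect_gt(sum(mv), 0)

  # static disk + new blob: only the new blob shows
  c2 <- disk(a, 60, 45, 4)
  mv2 <- movementMask(a, c2, cfg)
  lab <- courtTrack:::label8(mv2)
  expect_equal(max(lab), 1L)
  sel <- which(lab == 1L, arr.ind = TRUE)
  expect_lt(abs(mean(sel[, 2]) - 1 - 60), 1.5)
})

test_that("model_diff movement source uses the foreground masks", {
  cfg <- backgroundConfig(movementSource = "model_diff")
  m1 <- matrix(0L, 10, 10); m2 <- m1; m2[3:5, 3:5] <- 1L
  out <- movementMask(NULL, NULL, cfg, prevMask = m1, mask = m2)
  expect_equal(out, m2)
  expect_error(movementMask(NULL, NULL, cfg), "masks")
})

test_that("stationary foreground count decays after burn-in", {
  set.seed(5)
  scene <- array(runif(30 * 40 * 3, 0.2, 0.8), c(30, 40, 3))
  cfg <- backgroundConfig(feedStride = 1L)
  st <- newBackgroundModel(c(40, 30), cfg)
  fracs <- numeric(40)
  for (i in 1:40) {
    st <- updateBackground(st, scene, cfg)
    fracs[i] <- foregroundMask(st, scene, cfg)$fgFraction
  }
  expect_lt(fracs[40], 0.01)
  expect_true(all(diff(fracs[5:40]) <= 0.01))
})
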