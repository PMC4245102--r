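# Shared fixtures, built in code.

# perspective calibration: trapezoid seen from behind the baseline
perspectiveCalibration <- function() {
  courtCalibration(rbind(c(100, 400), c(540, 400), c(480, 120), c(160, 120)))
}

perspectiveHomography <- function() estimateHomography(perspectiveCalibration())

# a homography whose world -> image map scales by `s` pixels per meter
scaleHomography <- function(s) homography(diag(c(1 / s, 1 / s, 1)))

# blank H x W x 3 frame of one color
blankFrame <- function(h, w, color = c(0, 0, 0)) {
  fr <- array(0, c(h, w, 3))
  for (ch in 1:3) fr[, , ch] <- color[ch]
  fr
}

# paint an axis-aligned rectangle (0-based, inclusive) into a frame
paintRect <- function(frame, rect, color) {
  rows <- (rect[2] + 1):(rect[4] + 1)
  cols <- (rect[1] + 1):(rect[3] + 1)
  for (ch in 1:3) frame[rows, cols, ch] <- color[ch]
  frame
}

# random masked frame: uniform colors where a Bernoulli mask is 1
randomMaskedFrame <- function(h, w, p = 0.5) {
  mask <- matrix(rbinom(h * w, 1L, p), h, w)
  fr <- array(runif(h * w * 3), c(h, w, 3))
  fr * as.vector(mask)
}

# a minimal FrameBundle around a given color frame (identity-free: the
# foreground is any nonzero pixel, movement mask supplied or zero)
makeBundle <- function(frame, movMask = NULL, frameIndex = 0L,
                       config = histogramConfig()) {
  mask <- (frame[, , 1] != 0 | frame[, , 2] != 0 | frame[, , 3] != 0) + 0L
  if (is.null(movMask)) movMask <- matrix(0L, dim(frame)[1], dim(frame)[2])
  bi <- courtTrack:::binIndices(frame, mask, config)
  new("FrameBundle", frameIndex = frameIndex, frame = frame, fgMask = mask,
      maskedFrame = frame, movMask = movMask,
      chromaBin = bi$chromaBin, valueBin = bi$valueBin)
}

# reference appearance built directly from a painted player blob
refFromFrame <- function(bundle, clickPx, h, playerId = 1L,
                         config = histogramConfig(), cw = cueWeights()) {
  referenceAppearance(playerId, bundle, clickPx, h, config, cw)
}

# four-band player blob painted bottom-anchored at a world foot point
paintPlayer <- function(frame, h, foot, bandColors, heightM = 1.8,
                        widthM = 0.6) {
  px <- worldToImage(h, foot)
  sc <- localScale(h, foot)
  bw <- max(2L, round(widthM * sc)); bh <- max(4L, round(heightM * sc))
  x0 <- round(px[1] - bw / 2); y1 <- round(px[2])
  cuts <- y1 - bh + round(bh * seq(0, 1, length.out = 5))
  for (k in 1:4)
    frame <- paintRect(frame, c(x0, cuts[k], x0 + bw - 1, cuts[k + 1] - 1),
                       bandColors[k, ])
  frame
}

testBandColors <- rbind(c(0.9, 0.7, 0.5), c(0.8, 0.1, 0.1),
                        c(0.1, 0.2, 0.9), c(0.3, 0.8, 0.2))
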