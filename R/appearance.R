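# HSV histogram machinery (direct and integral forms), Bhattacharyya color
# scoring with subwindow coupling, and the count-based mask/movement cues.
#
# A histogram is one-dimensional: an N_H x N_S jointly binned chroma block
# with N_V value bins appended (110 bins with the 10/10/10 default). Every
# masked pixel contributes one chroma count and one value count.

#' Histogram configuration
#'
#' @param nH,nS,nV bin counts for hue, saturation and value (10 each,
#'   giving B = 10 * 10 + 10 = 110 bins).
#' @return list with nH, nS, nV and B = nH * nS + nV.
#' @export
histogramConfig <- function(nH = 10L, nS = 10L, nV = 10L) {
  stopifnot(nH >= 1, nS >= 1, nV >= 1)
  list(nH = as.integer(nH), nS = as.integer(nS), nV = as.integer(nV),
       B = as.integer(nH * nS + nV))
}

# Per-pixel histogram bin indices of a masked color frame. Returns integer
# matrices (1-based bins; 0 where masked out). H in [0,360) scaled from
# rgb2hsv's [0,1]; S, V in [0,1]; top-of-range values fall in the last bin.
binIndices <- function(maskedFrame, mask = NULL, config = histogramConfig()) {
  .assertFrame(maskedFrame)
  d <- dim(maskedFrame)
  if (is.null(mask))
    mask <- (maskedFrame[, , 1] != 0 | maskedFrame[, , 2] != 0 |
             maskedFrame[, , 3] != 0) + 0L
  chroma <- matrix(0L, d[1], d[2])
  value <- matrix(0L, d[1], d[2])
  sel <- which(mask != 0)
  if (length(sel) > 0) {
    hsv <- grDevices::rgb2hsv(
      r = maskedFrame[, , 1][sel], g = maskedFrame[, , 2][sel],
      b = maskedFrame[, , 3][sel], maxColorValue = 1)
    hBin <- pmin(config$nH - 1L, as.integer(floor(hsv[1, ] * config$nH)))
    sBin <- pmin(config$nS - 1L, as.integer(floor(hsv[2, ] * config$nS)))
    vBin <- pmin(config$nV - 1L, as.integer(floor(hsv[3, ] * config$nV)))
    chroma[sel] <- hBin * config$nS + sBin + 1L
    value[sel] <- config$nH * config$nS + vBin + 1L
  }
  list(chromaBin = chroma, valueBin = value, mask = mask)
}

.histFromBins <- function(chromaBin, valueBin, config) {
  sel <- chromaBin > 0L
  bins <- tabulate(c(chromaBin[sel], valueBin[sel]), nbins = config$B)
  new("HSVHistogram", bins = as.integer(bins), nPixels = sum(sel))
}

#' HSV histogram of a masked color region
#'
#' Only pixels with a nonzero mask contribute; each contributes one count
#' to its joint hue-saturation chroma bin and one count to its appended
#' value bin, so \code{sum(bins) == 2 * nPixels}. An all-background region
#' yields a valid empty histogram (nPixels = 0).
#'
#' @param region H x W x 3 array from a masked frame (background zeroed).
#' @param config a \code{\link{histogramConfig}}.
#' @param mask optional explicit 0/1 matrix; by default any pixel with a
#'   nonzero channel counts as foreground.
#' @return An \linkS4class{HSVHistogram}.
#' @export
hsvHistogram <- function(region, config = histogramConfig(), mask = NULL) {
  bi <- binIndices(region, mask, config)
  .histFromBins(bi$chromaBin, bi$valueBin, config)
}

#' Normalize a histogram to unit sum
#'
#' @param h an \linkS4class{HSVHistogram} or a non-negative numeric vector.
#' @return numeric vector summing to 1, or all zeros for an empty histogram.
#' @export
normalizeHistogram <- function(h) {
  b <- if (is(h, "HSVHistogram")) as.numeric(h@bins) else as.numeric(h)
  s <- sum(b)
  if (s > 0) b / s else b
}

#' Integral histogram of a masked frame
#'
#' Cumulative per-bin count image after the integral-histogram scheme:
#' any axis-aligned rectangle's histogram is recovered from four corner
#' lookups by \code{\link{regionHistogram}}, bit-identically to computing
#' \code{\link{hsvHistogram}} on that rectangle directly.
#'
#' @inheritParams hsvHistogram
#' @param maskedFrame H x W x 3 masked color array.
#' @return An \linkS4class{IntegralHistogram}.
#' @export
integralHistogram <- function(maskedFrame, config = histogramConfig(),
                              mask = NULL) {
  bi <- binIndices(maskedFrame, mask, config)
  integralHistogramFromBins(bi$chromaBin, bi$valueBin, config)
}

#' @rdname integralHistogram
#' @param chromaBin,valueBin precomputed bin-index matrices (see
#'   \linkS4class{FrameBundle}); this avoids re-deriving HSV per region.
#' @export
integralHistogramFromBins <- function(chromaBin, valueBin,
                                      config = histogramConfig()) {
  d <- dim(chromaBin); hgt <- d[1]; w <- d[2]; B <- config$B
  counts <- array(0L, c(hgt, w, B))
  sel <- which(chromaBin > 0L)
  if (length(sel) > 0) {
    rr <- ((sel - 1L) %% hgt) + 1L
    cc <- ((sel - 1L) %/% hgt) + 1L
    counts[cbind(rr, cc, chromaBin[sel])] <- 1L
    counts[cbind(rr, cc, valueBin[sel])] <- 1L
  }
  # double cumulative sum over rows then columns, robust to 1-px extents
  cum2d <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    if (nr > 1L) m <- matrix(apply(m, 2, cumsum), nr, nc)
    if (nc > 1L) m <- matrix(t(apply(m, 1, cumsum)), nr, nc)
    m
  }
  cum <- array(0L, c(hgt + 1L, w + 1L, B))
  for (b in seq_len(B))
    cum[-1, -1, b] <- as.integer(cum2d(matrix(counts[, , b], hgt, w)))
  npx <- matrix(0L, hgt + 1L, w + 1L)
  npx[-1, -1] <- as.integer(cum2d((chromaBin > 0L) + 0L))
  new("IntegralHistogram", cum = cum, nPixCum = npx, config = config)
}

#' Region histogram from an integral histogram
#'
#' @param ih an \linkS4class{IntegralHistogram}.
#' @param rect integer pixel rectangle c(x0, y0, x1, y1), 0-based inclusive.
#' @return An \linkS4class{HSVHistogram}, exactly equal to the directly
#'   computed histogram of the rectangle.
#' @export
regionHistogram <- function(ih, rect) {
  d <- dim(ih@cum)
  if (rect[1] < 0 || rect[2] < 0 || rect[3] >= d[2] - 1L ||
      rect[4] >= d[1] - 1L || rect[1] > rect[3] || rect[2] > rect[4])
    stop("rectangle outside image or empty")
  r0 <- rect[2] + 1L; r1 <- rect[4] + 2L
  c0 <- rect[1] + 1L; c1 <- rect[3] + 2L
  bins <- ih@cum[r1, c1, ] - ih@cum[r0, c1, ] - ih@cum[r1, c0, ] +
          ih@cum[r0, c0, ]
  npx <- ih@nPixCum[r1, c1] - ih@nPixCum[r0, c1] - ih@nPixCum[r1, c0] +
         ih@nPixCum[r0, c0]
  new("HSVHistogram", bins = as.integer(bins), nPixels = as.integer(npx))
}

#' Bhattacharyya distance between two histograms
#'
#' D = sqrt(1 - sum_b sqrt(p_b q_b)) on the normalized histograms; 0 for
#' identical histograms, 1 for disjoint support, and defined as 1 when both
#' histograms are empty (no evidence).
#'
#' @param hRef,hHyp \linkS4class{HSVHistogram}s or numeric vectors of equal
#'   length (normalized internally).
#' @return distance in [0, 1].
#' @export
bhattacharyya <- function(hRef, hHyp) {
  p <- normalizeHistogram(hRef)
  q <- normalizeHistogram(hHyp)
  if (length(p) != length(q)) stop("histograms have different bin counts")
  if (sum(p) == 0 && sum(q) == 0) return(1)
  bc <- sum(sqrt(p * q))
  sqrt(max(0, 1 - bc))
}

#' Cue weighting configuration
#'
#' @param alphaColor,alphaMask,alphaMov cue weights for the summed total
#'   (1.0, 0.4, 0.1).
#' @param c scaling constant of the per-subwindow color score, avoiding too
#'   small weights (100).
#' @param ns number of stacked subwindows per bounding box (4).
#' @param weightForm per-subwindow color score form: \code{"linear"} gives
#'   s_k = c (1 - D_k); \code{"exp"} gives s_k = c exp(-lambda D_k^2). The
#'   per-set maximum normalization makes either monotone form
#'   order-equivalent within a frame.
#' @param lambda decay of the exponential form.
#' @return A configuration list (class \code{CueWeights}).
#' @export
cueWeights <- function(alphaColor = 1.0, alphaMask = 0.4, alphaMov = 0.1,
                       c = 100, ns = 4L, weightForm = c("linear", "exp"),
                       lambda = 20) {
  weightForm <- match.arg(weightForm)
  stopifnot(alphaColor >= 0, alphaMask >= 0, alphaMov >= 0, c > 0, ns >= 1)
  structure(list(alphaColor = alphaColor, alphaMask = alphaMask,
                 alphaMov = alphaMov, c = c, ns = as.integer(ns),
                 weightForm = weightForm, lambda = lambda),
            class = c("CueWeights", "list"))
}

#' Color score from per-subwindow Bhattacharyya distances
#'
#' The upper subwindows are coupled tightly by multiplying their individual
#' color scores; the lowest subwindow (usually just the lower legs) is only
#' loosely coupled, its score added to the product:
#' score = prod_{k=1..NS-1} s_k + s_NS with s_k = c (1 - D_k).
#'
#' @param distances vector of subwindow distances D_1..D_NS (top to
#'   bottom), each in [0, 1].
#' @param cw a \code{\link{cueWeights}}.
#' @param refEmpty optional logical vector marking subwindows whose
#'   reference histogram is empty (e.g. the top band above a short player's
#'   head, or legs lost to the foreground mask at calibration). Such bands
#'   carry no color information and are skipped -- identically for every
#'   hypothesis of the set -- instead of vetoing the product.
#' @return non-negative scalar, strictly decreasing in every informative
#'   D_k.
#' @export
colorScore <- function(distances, cw = cueWeights(), refEmpty = NULL) {
  ns <- length(distances)
  stopifnot(ns >= 2)
  if (is.null(refEmpty)) refEmpty <- rep(FALSE, ns)
  s <- if (cw$weightForm == "linear") cw$c * (1 - distances)
       else cw$c * exp(-cw$lambda * distances^2)
  upper <- seq_len(ns - 1L)
  liveUpper <- upper[!refEmpty[upper]]
  prodTerm <- if (length(liveUpper) > 0) prod(s[liveUpper]) else 0
  addTerm <- if (refEmpty[ns]) 0 else s[ns]
  prodTerm + addTerm
}

#' Count score of a binary cue image over subwindows
#'
#' Number of nonzero pixels of the mask or movement image counted in each
#' subwindow of the bounding box, normalized to the subwindow width:
#' sum_k NZP_k / S_width.
#'
#' @param binary 0/1 matrix (foreground or movement mask).
#' @param bands list of subwindow rects c(x0, y0, x1, y1), 0-based
#'   inclusive; NULL entries (fully clipped bands) count zero.
#' @param widthPx subwindow width in pixels used for normalization.
#' @return non-negative scalar.
#' @export
countScore <- function(binary, bands, widthPx) {
  .assertMask(binary)
  if (widthPx <= 0) stop("zero-width subwindow")
  nzp <- vapply(bands, function(r) {
    if (is.null(r)) 0 else rectSum(binary != 0, r)
  }, numeric(1))
  sum(nzp) / widthPx
}

#' Total particle weight from normalized cues
#'
#' The total weight is the weighted sum of the color, foreground-mask and
#' movement cues, each already normalized to the set's per-frame maximum.
#'
#' @param colorN,maskN,movN normalized cue scores in [0, 1] (scalars or
#'   equal-length vectors).
#' @param cw a \code{\link{cueWeights}}.
#' @return total weight(s): alphaColor * colorN + alphaMask * maskN +
#'   alphaMov * movN.
#' @export
totalWeight <- function(colorN, maskN, movN, cw = cueWeights()) {
  cw$alphaColor * colorN + cw$alphaMask * maskN + cw$alphaMov * movN
}

# normalize a vector of raw cue scores to its maximum (0s stay 0)
.normCue <- function(x) {
  m <- max(x)
  if (m > 0) x / m else x
}
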