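# Adaptive per-pixel Gaussian-mixture background model and the two binary
# cue images derived from it: the foreground mask and the frame-to-frame
# movement mask.
#
# The mixture is fed every N-th frame only (players average out between
# inputs), the current background image is recursively fed back as every
# k-th model input (keeps the players out of the background), and the
# learning rate switches high while the foreground-pixel count spikes
# (sudden illumination change / camera bump).

#' Background model configuration
#'
#' @param nModes maximum Gaussian modes per pixel (16).
#' @param feedStride N: the mixture ingests every N-th frame (10).
#' @param feedbackPeriod every k-th ingested input is the current background
#'   image instead of the camera frame (3).
#' @param lrNormal,lrHigh learning rates in (0, 1); the high rate is used
#'   while the foreground fraction exceeds \code{fgSpikeFraction}.
#' @param fgSpikeFraction fraction of frame pixels above which the
#'   foreground count switches the model to \code{lrHigh}.
#' @param diffThreshold grayscale threshold (on [0,1] intensities) for
#'   binarizing difference images.
#' @param openingRadius structuring-element radius in pixels for the
#'   morphological opening (1 gives a 3 x 3 box).
#' @param movementSource \code{"frame_diff"} (thresholded consecutive-frame
#'   difference, default) or \code{"model_diff"} (change between consecutive
#'   foreground masks).
#' @param matchSigmas mode-match gate in standard deviations.
#' @param initVar,minVar initial and minimum mode variance (intensity^2).
#' @return A validated configuration list (class \code{BackgroundConfig}).
#' @export
backgroundConfig <- function(nModes = 16L, feedStride = 10L,
                             feedbackPeriod = 3L, lrNormal = 0.01,
                             lrHigh = 0.1, fgSpikeFraction = 0.3,
                             diffThreshold = 25 / 255, openingRadius = 1L,
                             movementSource = c("frame_diff", "model_diff"),
                             matchSigmas = 2.5, initVar = 0.0025,
                             minVar = 1e-4) {
  movementSource <- match.arg(movementSource)
  stopifnot(nModes >= 1, feedStride >= 1, feedbackPeriod >= 1,
            lrNormal > 0, lrNormal <= lrHigh, lrHigh < 1,
            fgSpikeFraction > 0, diffThreshold > 0, openingRadius >= 0)
  structure(list(nModes = as.integer(nModes),
                 feedStride = as.integer(feedStride),
                 feedbackPeriod = as.integer(feedbackPeriod),
                 lrNormal = lrNormal, lrHigh = lrHigh,
                 fgSpikeFraction = fgSpikeFraction,
                 diffThreshold = diffThreshold,
                 openingRadius = as.integer(openingRadius),
                 movementSource = movementSource, matchSigmas = matchSigmas,
                 initVar = initVar, minVar = minVar),
            class = c("BackgroundConfig", "list"))
}

#' Create an empty background model
#'
#' @param frameDim c(width, height) in pixels.
#' @param config a \code{\link{backgroundConfig}}.
#' @return A \linkS4class{BackgroundModel} with no ingested frames.
#' @export
newBackgroundModel <- function(frameDim, config = backgroundConfig()) {
  w <- frameDim[1]; hgt <- frameDim[2]; k <- config$nModes
  new("BackgroundModel",
      weightArr = array(0, c(hgt, w, k)),
      meanArr = array(0, c(hgt, w, k, 3)),
      varArr = array(config$initVar, c(hgt, w, k)),
      background = array(0, c(hgt, w, 3)),
      framesSeen = 0L, ingested = 0L, highRate = FALSE,
      lastFgFraction = 0, initialized = FALSE)
}

# grayscale luminance of a H x W x 3 array
.luminance <- function(a) {
  0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
}

.openMask <- function(mask, radius) {
  if (radius < 1L || !any(mask != 0)) return((mask != 0) + 0L)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "box")
  out <- EBImage::opening((mask != 0) + 0, brush)
  matrix(as.integer(out > 0.5), nrow = nrow(mask))
}

# One mixture ingestion with learning rate lr, vectorized over pixels.
.mogIngest <- function(state, frame, lr, config) {
  d <- dim(frame); n <- d[1] * d[2]; k <- config$nModes
  w <- matrix(state@weightArr, n, k)
  v <- matrix(state@varArr, n, k)
  mu <- array(state@meanArr, c(n, k, 3))
  x <- matrix(frame, n, 3)

  if (!state@initialized) {
    w[, 1] <- 1
    for (ch in 1:3) mu[, 1, ch] <- x[, ch]
    v[, 1] <- config$initVar
  } else {
    d2 <- (mu[, , 1] - x[, 1])^2 + (mu[, , 2] - x[, 2])^2 +
          (mu[, , 3] - x[, 3])^2
    active <- w > 0
    matched <- active & (d2 < (config$matchSigmas^2 * 3) * v)
    hasMatch <- rowSums(matched) > 0
    score <- ifelse(matched, w, -Inf)
    kStar <- max.col(score, ties.method = "first")

    sel <- cbind(seq_len(n), kStar)
    o <- matrix(0, n, k)
    o[sel[hasMatch, , drop = FALSE]] <- 1
    w <- (1 - lr) * w + lr * o

    # matched-mode mean/variance update
    rho <- lr
    upd <- sel[hasMatch, , drop = FALSE]
    if (nrow(upd) > 0) {
      dx2 <- numeric(nrow(upd))
      for (ch in 1:3) {
        slice <- cbind(upd, ch)
        dxc <- x[upd[, 1], ch] - mu[slice]
        mu[slice] <- mu[slice] + rho * dxc
        dx2 <- dx2 + dxc^2
      }
      v[upd] <- pmax(config$minVar, v[upd] + rho * (dx2 / 3 - v[upd]))
    }

    # unmatched pixels: replace the weakest mode with a fresh one
    if (any(!hasMatch)) {
      idx <- which(!hasMatch)
      kMin <- max.col(-w[idx, , drop = FALSE], ties.method = "last")
      rep <- cbind(idx, kMin)
      w[rep] <- lr
      for (ch in 1:3) mu[cbind(rep, ch)] <- x[idx, ch]
      v[rep] <- config$initVar
    }
    w <- w / rowSums(w)
  }

  kMax <- max.col(w, ties.method = "first")
  bg <- array(0, d)
  selMax <- cbind(seq_len(n), kMax)
  for (ch in 1:3) bg[, , ch][seq_len(n)] <- mu[cbind(selMax, ch)]

  state@weightArr <- array(w, c(d[1], d[2], k))
  state@meanArr <- array(mu, c(d[1], d[2], k, 3))
  state@varArr <- array(v, c(d[1], d[2], k))
  state@background <- bg
  state@ingested <- state@ingested + 1L
  state@initialized <- TRUE
  state
}

#' Offer one frame to the background model
#'
#' Advances the frame counter; the mixture actually ingests the frame only
#' when the counter hits the feed stride (every N-th frame). Every
#' \code{feedbackPeriod}-th ingested input is replaced by the current
#' background image. Before ingesting, the foreground fraction against the
#' current background is measured; while it exceeds
#' \code{fgSpikeFraction}, the high learning rate is used.
#'
#' @param state a \linkS4class{BackgroundModel}.
#' @param frame H x W x 3 array in [0, 1].
#' @param config a \code{\link{backgroundConfig}}.
#' @return The updated \linkS4class{BackgroundModel}.
#' @export
updateBackground <- function(state, frame, config = backgroundConfig()) {
  .assertFrame(frame)
  if (!all(dim(frame) == dim(state@background)))
    stop("frame shape does not match background model")
  idx <- state@framesSeen            # 0-based index of this frame
  state@framesSeen <- state@framesSeen + 1L
  if (idx %% config$feedStride != 0L) return(state)

  if (state@initialized) {
    diff <- .luminance(abs(frame - state@background))
    state@lastFgFraction <- mean(diff > config$diffThreshold)
    state@highRate <- state@lastFgFraction > config$fgSpikeFraction
  }
  lr <- if (state@highRate) config$lrHigh else config$lrNormal

  input <- frame
  if (state@initialized &&
      (state@ingested + 1L) %% config$feedbackPeriod == 0L)
    input <- state@background
  .mogIngest(state, input, lr, config)
}

#' Foreground mask and masked color frame
#'
#' The pipeline is: absolute difference between the frame and the learned
#' background, luminance-weighted grayscale conversion, binary threshold,
#' morphological opening, and finally application of the mask to the
#' original frame so background pixels become zero valued.
#'
#' @inheritParams updateBackground
#' @return list(mask = 0/1 matrix, maskedFrame = H x W x 3 array,
#'   fgFraction = foreground pixel fraction before opening).
#' @export
foregroundMask <- function(state, frame, config = backgroundConfig()) {
  .assertFrame(frame)
  if (!state@initialized)
    stop("background model has no ingested frames yet")
  diff <- .luminance(abs(frame - state@background))
  raw <- (diff > config$diffThreshold) + 0L
  mask <- .openMask(raw, config$openingRadius)
  masked <- frame * as.vector(mask)
  list(mask = mask, maskedFrame = masked, fgFraction = mean(raw))
}

#' Movement mask between consecutive frames
#'
#' Binary image of the pixels whose value changed beyond the threshold
#' between two consecutive frames, cleaned with the same morphological
#' opening as the foreground path. Static objects yield zeros. With
#' \code{movementSource = "model_diff"} the mask is the change between the
#' two frames' foreground masks instead (both must then be supplied).
#'
#' @param prevFrame,frame consecutive H x W x 3 arrays.
#' @param config a \code{\link{backgroundConfig}}.
#' @param prevMask,mask the frames' foreground masks (only used by
#'   \code{"model_diff"}).
#' @return 0/1 matrix.
#' @export
movementMask <- function(prevFrame, frame, config = backgroundConfig(),
                         prevMask = NULL, mask = NULL) {
  if (config$movementSource == "model_diff") {
    if (is.null(prevMask) || is.null(mask))
      stop("model_diff movement source needs both foreground masks")
    return(.openMask(abs(mask - prevMask), config$openingRadius))
  }
  .assertFrame(prevFrame); .assertFrame(frame)
  if (!all(dim(prevFrame) == dim(frame))) stop("frame shape mismatch")
  diff <- .luminance(abs(frame - prevFrame))
  .openMask((diff > config$diffThreshold) + 0L, config$openingRadius)
}
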