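# Classical per-player particle filter: uniform initialization, multi-cue
# weighting, weighted-mean state estimate, roulette-wheel resampling with
# two-tier Gaussian jitter, and the inter-set confusion safeguard.

#' Resampling configuration
#'
#' @param sigmaBase Gaussian jitter standard deviation in meters applied to
#'   resampled particles (0.2 m).
#' @param sigmaTop reduced jitter for particles whose weight lies in the
#'   upper 0.1 percent of the set's maximum (0.04 m).
#' @param topBand relative band below the maximum weight that receives
#'   \code{sigmaTop} (0.001).
#' @param guardFrames overlap frames after which the confusion safeguard
#'   fires (strictly more than 10).
#' @param guardOverlapDistM world distance below which two sets are
#'   considered to track the same player (1.0 m: half the 2 m bounding-box
#'   width, so two estimates inside one player's box count as overlapping;
#'   two trackers sharing a blob settle at stable offsets up to this size).
#' @param courtRect c(x0, y0, x1, y1) world rectangle used for uniform
#'   re-initialization (the court).
#' @param colorWeightMode how the safeguard compares the sets' color
#'   evidence: mean raw color score over the particles
#'   (\code{"mean_particles"}) or the score at the estimate point
#'   (\code{"at_estimate"}).
#' @return A configuration list (class \code{ResampleConfig}).
#' @export
resampleConfig <- function(sigmaBase = 0.2, sigmaTop = 0.04, topBand = 0.001,
                           guardFrames = 10L, guardOverlapDistM = 1.0,
                           courtRect = c(0, 0, 8, 16),
                           colorWeightMode = c("mean_particles",
                                               "at_estimate")) {
  colorWeightMode <- match.arg(colorWeightMode)
  stopifnot(sigmaTop > 0, sigmaTop < sigmaBase, guardFrames >= 1,
            guardOverlapDistM > 0)
  structure(list(sigmaBase = sigmaBase, sigmaTop = sigmaTop,
                 topBand = topBand, guardFrames = as.integer(guardFrames),
                 guardOverlapDistM = guardOverlapDistM,
                 courtRect = courtRect, colorWeightMode = colorWeightMode),
            class = c("ResampleConfig", "list"))
}

#' Reference appearance from the calibration frame
#'
#' Builds the player's per-subwindow reference histograms from the masked
#' calibration frame: the user's click between the feet becomes the foot
#' point; its bounding box is projected and each subwindow's normalized HSV
#' histogram stored for all later comparisons.
#'
#' @param playerId integer id (1..4).
#' @param bundle the calibration frame's \linkS4class{FrameBundle}.
#' @param clickPx pixel position clicked between the player's feet.
#' @param h the court \linkS4class{Homography}.
#' @param config a \code{\link{histogramConfig}}.
#' @param cw a \code{\link{cueWeights}} (supplies the subwindow count).
#' @param heightM physical bounding-box height in meters.
#' @return A \linkS4class{ReferenceAppearance}.
#' @export
referenceAppearance <- function(playerId, bundle, clickPx, h,
                                config = histogramConfig(),
                                cw = cueWeights(), heightM = 2) {
  d <- dim(bundle@frame)
  foot <- imageToWorld(h, clickPx)
  box <- projectBox(h, foot, heightM, cw$ns, frameDim = c(d[2], d[1]))
  if (box$empty) stop("calibration box fully off-frame for player ", playerId)
  hists <- lapply(box$bands, function(r) {
    if (is.null(r)) return(numeric(config$B))
    sub <- .cropBins(bundle, r)
    normalizeHistogram(.histFromBins(sub$chromaBin, sub$valueBin, config))
  })
  npx <- vapply(box$bands, function(r) {
    if (is.null(r)) 0L else as.integer(rectSum(bundle@fgMask != 0, r))
  }, integer(1))
  new("ReferenceAppearance", playerId = as.integer(playerId),
      histograms = hists, nPixels = npx)
}

.cropBins <- function(bundle, r) {
  rows <- (r[2] + 1):(r[4] + 1); cols <- (r[1] + 1):(r[3] + 1)
  list(chromaBin = bundle@chromaBin[rows, cols, drop = FALSE],
       valueBin = bundle@valueBin[rows, cols, drop = FALSE])
}

#' Initialize a particle set
#'
#' Particles are placed uniformly in a world region (a team half, a
#' pre-structured area, or the whole court) with equal weights. The set
#' carries a private RNG stream derived from the seed and the player id, so
#' per-player randomness does not depend on evaluation order.
#'
#' @param playerId integer id.
#' @param region world rectangle c(x0, y0, x1, y1) in meters.
#' @param n particle count (20-50 sensible, default 30).
#' @param reference the player's \linkS4class{ReferenceAppearance}.
#' @param seed integer seed.
#' @param homeRect world rectangle searched when the set is lost or reset
#'   (the player's team half under pre-structuring; default the whole
#'   court).
#' @return A \linkS4class{ParticleSet}.
#' @export
initParticleSet <- function(playerId, region, n = 30L, reference, seed = 1L,
                            homeRect = c(0, 0, 8, 16)) {
  stopifnot(n >= 1, region[3] > region[1], region[4] > region[2])
  rng <- withRNG(childSeed(seed, playerId), {
    cbind(runif(n, region[1], region[3]), runif(n, region[2], region[4]))
  })
  pos <- rng$value
  new("ParticleSet", playerId = as.integer(playerId), positions = pos,
      weights = rep(1 / n, n), cueScores = matrix(0, n, 3),
      reference = reference, estimate = colMeans(pos), lost = FALSE,
      homeRect = as.numeric(homeRect), rngState = rng$state)
}

# raw cue scores of arbitrary world positions against one reference
.scorePositions <- function(positions, reference, bundle, h, cw,
                            config, heightM) {
  d <- dim(bundle@frame); frameDim <- c(d[2], d[1])
  n <- nrow(positions)
  out <- matrix(0, n, 3, dimnames = list(NULL, c("color", "mask", "mov")))
  refs <- reference@histograms
  refEmpty <- vapply(refs, function(x) sum(x) == 0, logical(1))
  for (j in seq_len(n)) {
    box <- tryCatch(projectBox(h, positions[j, ], heightM, cw$ns, frameDim),
                    error = function(e) NULL)
    if (is.null(box) || box$empty) next
    dists <- vapply(seq_along(box$bands), function(k) {
      r <- box$bands[[k]]
      if (is.null(r)) return(1)
      sub <- .cropBins(bundle, r)
      hyp <- .histFromBins(sub$chromaBin, sub$valueBin, config)
      bhattacharyya(refs[[k]], hyp)
    }, numeric(1))
    out[j, 1] <- colorScore(dists, cw, refEmpty)
    out[j, 2] <- countScore(bundle@fgMask, box$bands, box$widthPx)
    out[j, 3] <- countScore(bundle@movMask, box$bands, box$widthPx)
  }
  out
}

#' Weight a particle set against one frame
#'
#' For every particle, the bounding box at its world position is projected
#' into the image and the three cues computed: the subwindow-coupled color
#' score against the reference histograms, and the width-normalized nonzero
#' pixel counts of the foreground and movement masks. Each cue is then
#' normalized to the set's per-frame maximum and summed with the cue
#' weights. If every cue is zero everywhere, weights become uniform and the
#' lost-track flag is raised.
#'
#' @param set a \linkS4class{ParticleSet}.
#' @param bundle the frame's \linkS4class{FrameBundle}.
#' @param h the court \linkS4class{Homography}.
#' @param cw a \code{\link{cueWeights}}.
#' @param config a \code{\link{histogramConfig}}.
#' @param heightM bounding-box height in meters.
#' @return The set with updated cue scores, weights and estimate.
#' @export
weightParticleSet <- function(set, bundle, h, cw = cueWeights(),
                              config = histogramConfig(), heightM = 2) {
  raw <- .scorePositions(set@positions, set@reference, bundle, h, cw,
                         config, heightM)
  set@cueScores <- raw
  searching <- set@lost
  if (searching) {
    # a searching set relocks on color evidence alone: the count cues do
    # not discriminate players and would latch onto any moving blob
    if (max(raw[, 1]) > 0) {
      set@weights <- .normCue(raw[, 1])
      set@lost <- FALSE
      set@estimate <- estimateState(set)
    } else {
      set@weights <- rep(1 / nrow(raw), nrow(raw))
    }
    return(set)
  }
  tw <- totalWeight(.normCue(raw[, 1]), .normCue(raw[, 2]),
                    .normCue(raw[, 3]), cw)
  if (all(tw == 0)) {
    set@weights <- rep(1 / nrow(raw), nrow(raw))
    set@lost <- TRUE
  } else {
    set@weights <- tw
    set@estimate <- estimateState(set)
  }
  set
}

#' Weighted-mean state estimate
#'
#' @param set a weighted \linkS4class{ParticleSet}.
#' @return world point sum(w_j p_j) / sum(w_j); with an all-zero weight sum
#'   the previous estimate is retained.
#' @export
estimateState <- function(set) {
  s <- sum(set@weights)
  if (s <= 0) return(set@estimate)
  as.numeric(colSums(set@positions * set@weights) / s)
}

#' Roulette-wheel resampling with two-tier jitter
#'
#' Draws n offspring with probability proportional to total weight
#' (multinomial / roulette wheel) and jitters each with isotropic Gaussian
#' noise: 0.04 m standard deviation for offspring of particles whose weight
#' lies within the upper 0.1 percent of the set's maximum, 0.2 m otherwise.
#' Weights are reset to uniform. With all-zero weights the set is redrawn
#' uniformly over the court (lost-track recovery).
#'
#' @param set a \linkS4class{ParticleSet} with computed weights.
#' @param rc a \code{\link{resampleConfig}}.
#' @return The resampled \linkS4class{ParticleSet}.
#' @export
resampleSet <- function(set, rc = resampleConfig()) {
  n <- nrow(set@positions)
  w <- set@weights
  hr <- if (length(set@homeRect) == 4) set@homeRect else rc$courtRect
  rng <- withRNG(set@rngState, {
    if (sum(w) <= 0 || set@lost) {
      cbind(runif(n, hr[1], hr[3]), runif(n, hr[2], hr[4]))
    } else {
      src <- sample.int(n, n, replace = TRUE, prob = w)
      top <- w[src] >= (1 - rc$topBand) * max(w)
      sigma <- ifelse(top, rc$sigmaTop, rc$sigmaBase)
      set@positions[src, , drop = FALSE] +
        cbind(rnorm(n, 0, sigma), rnorm(n, 0, sigma))
    }
  })
  set@positions <- rng$value
  set@rngState <- rng$state
  set@weights <- rep(1 / n, n)
  set@cueScores <- matrix(0, n, 3)
  set
}

#' Re-initialize a set uniformly over the court
#'
#' @param set a \linkS4class{ParticleSet}.
#' @param rc a \code{\link{resampleConfig}}.
#' @return The redrawn set (weights uniform, lost flag set).
#' @export
reinitSet <- function(set, rc = resampleConfig()) {
  n <- nrow(set@positions)
  hr <- if (length(set@homeRect) == 4) set@homeRect else rc$courtRect
  rng <- withRNG(set@rngState, {
    cbind(runif(n, hr[1], hr[3]), runif(n, hr[2], hr[4]))
  })
  set@positions <- rng$value
  set@rngState <- rng$state
  set@weights <- rep(1 / n, n)
  set@cueScores <- matrix(0, n, 3)
  set@lost <- TRUE
  set
}

#' Confusion safeguard across trackers
#'
#' When two trackers' estimates stay within the overlap distance for
#' strictly more than \code{guardFrames} consecutive frames, they are
#' deemed to track the same player and the one with the smaller average
#' color evidence is re-initialized uniformly over the court; the pair's
#' counter resets.
#'
#' Works on particle sets and rigid grids alike: the object only needs an
#' estimate, raw color scores and a uniform re-initialization.
#'
#' @param trackers list of \linkS4class{ParticleSet} or
#'   \linkS4class{RigidGrid} objects.
#' @param counters symmetric integer matrix of consecutive-overlap counts
#'   (as returned by a previous call; start with a zero matrix).
#' @param rc a \code{\link{resampleConfig}}.
#' @return list(trackers, counters, reset = integer ids re-initialized).
#' @export
confusionGuard <- function(trackers, counters, rc = resampleConfig()) {
  k <- length(trackers)
  est <- t(vapply(trackers, trackerEstimate, numeric(2)))
  reset <- integer(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- sqrt(sum((est[i, ] - est[j, ])^2))
    if (d < rc$guardOverlapDistM) {
      counters[i, j] <- counters[j, i] <- counters[i, j] + 1L
      if (counters[i, j] > rc$guardFrames) {
        ci <- .meanColorScore(trackers[[i]])
        cj <- .meanColorScore(trackers[[j]])
        loser <- if (ci < cj) i else j
        trackers[[loser]] <- reinitTracker(trackers[[loser]], rc)
        reset <- c(reset, loser)
        counters[i, j] <- counters[j, i] <- 0L
      }
    } else {
      counters[i, j] <- counters[j, i] <- 0L
    }
  }
  list(trackers = trackers, counters = counters, reset = reset)
}

.meanColorScore <- function(tracker) {
  mean(tracker@cueScores[, 1])
}

#' Current estimate of a tracker
#'
#' @param tracker a \linkS4class{ParticleSet} or \linkS4class{RigidGrid}.
#' @return length-2 world position.
#' @export
trackerEstimate <- function(tracker) {
  if (is(tracker, "ParticleSet")) tracker@estimate else tracker@anchor
}

#' Uniform re-initialization of a tracker
#'
#' @inheritParams trackerEstimate
#' @param rc a \code{\link{resampleConfig}}.
#' @return The re-initialized tracker.
#' @export
reinitTracker <- function(tracker, rc = resampleConfig()) {
  if (is(tracker, "ParticleSet")) return(reinitSet(tracker, rc))
  hr <- if (length(tracker@homeRect) == 4) tracker@homeRect else rc$courtRect
  rng <- withRNG(tracker@rngState, {
    c(runif(1, hr[1], hr[3]), runif(1, hr[2], hr[4]))
  })
  tracker@anchor <- rng$value
  tracker@rngState <- rng$state
  tracker@lost <- TRUE
  tracker
}
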