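#' @import methods
NULL

# S3 configuration lists usable inside S4 slots
setOldClass(c("GridLayout", "list"))
setOldClass(c("CueWeights", "list"))
setOldClass(c("BackgroundConfig", "list"))
setOldClass(c("ResampleConfig", "list"))

#' Court calibration
#'
#' Four image-pixel corner positions of the court paired with their
#' court-plane coordinates in meters. Pixel coordinates are 0-based, origin
#' top-left, y pointing down; world coordinates are meters with the origin
#' at one court corner, y running along the court length. The default world
#' corners describe an 8 x 16 m court: (0,0), (8,0), (8,16), (0,16).
#'
#' @slot imageCorners 4 x 2 numeric matrix of pixel corners (x, y).
#' @slot worldCorners 4 x 2 numeric matrix of court corners in meters,
#'   matched row-by-row to \code{imageCorners}.
#' @slot playerClicks 4 x 2 numeric matrix of initial player pixel positions
#'   (clicked between the feet), or a 0 x 2 matrix when absent.
#' @slot calibrationFrame integer index (0-based) of the calibration frame.
#' @slot courtWidthM,courtLengthM court dimensions in meters.
#' @export
setClass("CourtCalibration",
  representation(imageCorners = "matrix", worldCorners = "matrix",
                 playerClicks = "matrix", calibrationFrame = "integer",
                 courtWidthM = "numeric", courtLengthM = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@imageCorners) == c(4L, 2L)))
      msg <- c(msg, "imageCorners must be 4 x 2")
    if (!all(dim(object@worldCorners) == c(4L, 2L)))
      msg <- c(msg, "worldCorners must be 4 x 2")
    if (ncol(object@playerClicks) != 2L)
      msg <- c(msg, "playerClicks must have 2 columns")
    if (is.null(msg) && .anyCollinear(object@imageCorners))
      msg <- c(msg, "image corners are degenerate (three collinear)")
    if (is.null(msg)) TRUE else msg
  })

#' Planar homography
#'
#' A 3 x 3 invertible projective map between the image plane (pixels) and
#' the court ground plane (meters), normalized so the bottom-right entry
#' is 1. The stored direction is image -> world.
#'
#' @slot matrix 3 x 3 numeric matrix, image -> world.
#' @export
setClass("Homography", representation(matrix = "matrix"),
  validity = function(object) {
    m <- object@matrix
    if (!all(dim(m) == c(3L, 3L))) return("matrix must be 3 x 3")
    if (!is.finite(det(m)) || abs(det(m)) < 1e-14) return("matrix is singular")
    if (abs(m[3, 3] - 1) > 1e-9) return("matrix must be normalized (m[3,3] == 1)")
    TRUE
  })

#' Per-frame cue bundle
#'
#' One color frame together with its derived cue images: the binary
#' foreground mask from the background model, the masked color frame
#' (background pixels zeroed), and the binary frame-to-frame movement mask.
#' Histogram bin-index images are precomputed once per frame so that region
#' histograms reduce to tabulation.
#'
#' @slot frameIndex 0-based frame index.
#' @slot frame height x width x 3 array in [0, 1].
#' @slot fgMask,movMask height x width 0/1 matrices.
#' @slot maskedFrame frame with background pixels set to zero.
#' @slot chromaBin,valueBin integer matrices of per-pixel histogram bin
#'   indices (1-based; 0 where the foreground mask is zero).
#' @export
setClass("FrameBundle",
  representation(frameIndex = "integer", frame = "array", fgMask = "matrix",
                 maskedFrame = "array", movMask = "matrix",
                 chromaBin = "matrix", valueBin = "matrix"),
  validity = function(object) {
    d <- dim(object@frame)
    if (length(d) != 3L || d[3] != 3L) return("frame must be H x W x 3")
    for (nm in c("fgMask", "movMask", "chromaBin", "valueBin")) {
      m <- slot(object, nm)
      if (!all(dim(m) == d[1:2])) return(paste(nm, "does not match frame size"))
    }
    if (any(object@maskedFrame[object@fgMask == 0] != 0))
      return("maskedFrame must be zero outside the foreground mask")
    TRUE
  })

#' HSV appearance histogram
#'
#' One-dimensional HSV histogram: an N_H x N_S chroma block (hue-saturation
#' jointly binned) with N_V value bins appended, B = N_H * N_S + N_V bins in
#' total (110 with the 10/10/10 default). Every masked pixel contributes one
#' chroma count and one value count, so \code{sum(bins) == 2 * nPixels}.
#'
#' @slot bins integer vector of length B.
#' @slot nPixels number of contributing (nonzero-mask) pixels.
#' @export
setClass("HSVHistogram",
  representation(bins = "integer", nPixels = "integer"),
  validity = function(object) {
    if (any(object@bins < 0L)) return("bins must be non-negative")
    if (sum(object@bins) != 2L * object@nPixels)
      return("sum(bins) must equal 2 * nPixels")
    TRUE
  })

#' Integral histogram
#'
#' Cumulative per-bin count image: slice b holds, at (i, j), the number of
#' contributions to bin b in the pixel rectangle [0, j) x [0, i). Any
#' axis-aligned rectangle's histogram follows from four corner lookups and
#' equals the directly computed histogram exactly.
#'
#' @slot cum (H+1) x (W+1) x B integer array of cumulative counts.
#' @slot nPixCum (H+1) x (W+1) cumulative masked-pixel counts.
#' @slot config histogram configuration list.
#' @export
setClass("IntegralHistogram",
  representation(cum = "array", nPixCum = "matrix", config = "list"))

#' Reference appearance of one player
#'
#' Normalized HSV histograms of the player's bounding-box subwindows,
#' extracted from the masked calibration frame and kept fixed for all
#' later frame-to-frame comparisons.
#'
#' @slot playerId integer player id (1..4).
#' @slot histograms list of length-NS numeric vectors, each a normalized
#'   histogram (or all zero if the subwindow was empty).
#' @slot nPixels integer vector of contributing pixel counts per subwindow.
#' @export
setClass("ReferenceAppearance",
  representation(playerId = "integer", histograms = "list",
                 nPixels = "integer"),
  validity = function(object) {
    if (length(object@histograms) < 1L) return("needs at least one subwindow")
    B <- length(object@histograms[[1]])
    if (!all(vapply(object@histograms, length, 1L) == B))
      return("all subwindow histograms must have equal length")
    TRUE
  })

#' Particle set for one player
#'
#' The classical particle-filter hypothesis container: particle positions in
#' world coordinates (meters on the court plane), per-particle cue scores
#' and total weights, the current weighted-mean estimate, and a private RNG
#' state so per-player randomness is independent of evaluation order.
#'
#' @slot playerId integer player id.
#' @slot positions n x 2 matrix of world positions (x_m, y_m).
#' @slot weights length-n total weights (>= 0).
#' @slot cueScores n x 3 matrix of raw cue scores (color, mask, movement).
#' @slot reference a \linkS4class{ReferenceAppearance}.
#' @slot estimate length-2 world position estimate.
#' @slot lost TRUE when the last weighting found no evidence (the set is
#'   searching).
#' @slot homeRect world rectangle searched when the set is lost or reset
#'   (the player's team half under pre-structuring; the whole court
#'   otherwise).
#' @slot rngState saved .Random.seed vector for this set's private stream.
#' @export
setClass("ParticleSet",
  representation(playerId = "integer", positions = "matrix",
                 weights = "numeric", cueScores = "matrix",
                 reference = "ReferenceAppearance", estimate = "numeric",
                 lost = "logical", homeRect = "numeric",
                 rngState = "integer"),
  validity = function(object) {
    n <- nrow(object@positions)
    if (n < 1L) return("at least one particle required")
    if (length(object@weights) != n) return("weights length mismatch")
    if (any(object@weights < 0)) return("weights must be non-negative")
    if (!all(is.finite(object@positions))) return("positions must be finite")
    TRUE
  })

#' Rigid particle grid for one player
#'
#' The integral-histogram tracker's hypothesis container: a fixed world-space
#' grid of particle offsets around the current estimate (the anchor).
#' Offsets never change between frames; only the anchor moves.
#'
#' @slot playerId integer player id.
#' @slot anchor length-2 world position of the grid center.
#' @slot offsets k x 2 matrix of fixed world offsets of the particles
#'   (row-major over the particle rows).
#' @slot cols,rows layout of the particle block (cols columns, rows rows).
#' @slot layout full grid-layout list (see \code{\link{gridLayout}}).
#' @slot reference a \linkS4class{ReferenceAppearance}.
#' @slot weights per-particle total weights from the last step.
#' @slot cueScores k x 3 matrix of raw cue scores from the last step.
#' @slot lost TRUE when the last step found no evidence (the grid is
#'   searching).
#' @slot homeRect world rectangle searched while lost.
#' @slot colorEma exponential moving average of the grid's best raw color
#'   score (hysteresis for the home-region sweep: a briefly invisible
#'   target should not make the grid yield to a distractor).
#' @slot rngState saved .Random.seed vector for uniform re-initialization.
#' @export
setClass("RigidGrid",
  representation(playerId = "integer", anchor = "numeric", offsets = "matrix",
                 cols = "integer", rows = "integer", layout = "list",
                 reference = "ReferenceAppearance", weights = "numeric",
                 cueScores = "matrix", lost = "logical",
                 homeRect = "numeric", colorEma = "numeric",
                 rngState = "integer"),
  validity = function(object) {
    if (nrow(object@offsets) != object@cols * object@rows)
      return("offsets must have cols * rows entries")
    TRUE
  })

#' Ballistic ball trajectory
#'
#' Piecewise model of the ball's image motion over a frame range: x is
#' linear in the frame index t (x = m t + b) and the height is quadratic
#' (y_h = a2 t^2 + a1 t + a0 with a2 < 0; heights are measured upward from
#' the frame bottom so gravity gives a negative leading coefficient).
#'
#' @slot a2,a1,a0 parabola coefficients of height vs frame (NA until >= 3
#'   members are available).
#' @slot m,b line coefficients of x vs frame.
#' @slot frameStart,frameEnd integer frame range covered by members.
#' @slot members data.frame with columns frame, x, yh (member candidates).
#' @slot missingRun consecutive unmatched frames while growing.
#' @slot status one of "growing", "terminated", "selected".
#' @slot extStart,extEnd extrapolated frame range (equal to
#'   frameStart/frameEnd until \code{\link{extrapolateTrajectories}} runs).
#' @export
setClass("BallTrajectory",
  representation(a2 = "numeric", a1 = "numeric", a0 = "numeric",
                 m = "numeric", b = "numeric",
                 frameStart = "integer", frameEnd = "integer",
                 members = "data.frame", missingRun = "integer",
                 status = "character", extStart = "numeric",
                 extEnd = "numeric"),
  validity = function(object) {
    if (object@frameStart > object@frameEnd) return("frameStart > frameEnd")
    if (!object@status %in% c("growing", "terminated", "selected"))
      return("invalid status")
    if (is.unsorted(object@members$frame)) return("members must be frame-sorted")
    TRUE
  })

#' Adaptive Gaussian-mixture background model
#'
#' Per-pixel mixture of up to \code{nModes} Gaussians over RGB intensity,
#' updated recursively from every N-th frame, with the current background
#' image fed back as every k-th model input and an adaptive learning rate
#' that rises while the foreground-pixel count spikes.
#'
#' @slot weightArr H x W x K mode weights (rows sum to <= 1).
#' @slot meanArr H x W x K x 3 mode means.
#' @slot varArr H x W x K mode variances (isotropic over channels).
#' @slot background H x W x 3 current most-probable background image.
#' @slot framesSeen frames offered to the model (including skipped ones).
#' @slot ingested frames actually fed to the mixture.
#' @slot highRate TRUE while the adaptive high learning rate is active.
#' @slot lastFgFraction foreground fraction measured at the last mask call.
#' @slot initialized TRUE after the first ingestion.
#' @export
setClass("BackgroundModel",
  representation(weightArr = "array", meanArr = "array", varArr = "array",
                 background = "array", framesSeen = "integer",
                 ingested = "integer", highRate = "logical",
                 lastFgFraction = "numeric", initialized = "logical"))

# --- show methods ------------------------------------------------------

setMethod("show", "Homography", function(object) {
  cat("Homography (image -> world)\n")
  print(round(object@matrix, 6))
})

setMethod("show", "CourtCalibration", function(object) {
  cat(sprintf("CourtCalibration: %g x %g m court, calibration frame %d\n",
              object@courtWidthM, object@courtLengthM, object@calibrationFrame))
  cat("image corners (px):\n"); print(object@imageCorners)
})

setMethod("show", "HSVHistogram", function(object) {
  cat(sprintf("HSVHistogram: %d bins, %d pixels, %d nonzero bins\n",
              length(object@bins), object@nPixels, sum(object@bins > 0L)))
})

setMethod("show", "ParticleSet", function(object) {
  cat(sprintf("ParticleSet player %d: %d particles, estimate (%.2f, %.2f) m%s\n",
              object@playerId, nrow(object@positions),
              object@estimate[1], object@estimate[2],
              if (object@lost) " [lost]" else ""))
})

setMethod("show", "RigidGrid", function(object) {
  cat(sprintf("RigidGrid player %d: %d x %d particles, anchor (%.2f, %.2f) m%s\n",
              object@playerId, object@rows, object@cols,
              object@anchor[1], object@anchor[2],
              if (object@lost) " [lost]" else ""))
})

setMethod("show", "BallTrajectory", function(object) {
  cat(sprintf(
    "BallTrajectory [%d, %d] (%s): %d members, x = %.3f t + %.1f, yh = %.4f t^2 + %.2f t + %.1f\n",
    object@frameStart, object@frameEnd, object@status, nrow(object@members),
    object@m, object@b, object@a2, object@a1, object@a0))
})

setMethod("show", "BackgroundModel", function(object) {
  d <- dim(object@background)
  cat(sprintf("BackgroundModel %d x %d: %d modes, %d ingested (%d seen)%s\n",
              d[1], d[2], dim(object@weightArr)[3], object@ingested,
              object@framesSeen, if (object@highRate) " [high rate]" else ""))
})
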