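# Rigid-grid integral-histogram tracker: a perspective-scaled world grid of
# fixed-offset particles around the last estimate, scored by the same three
# cues as the particle filter plus a quadratic center-column positional
# factor. Region color histograms come from an integral histogram built
# over the grid's image footprint, so overlapping particle boxes share the
# cumulative computation.

#' Grid layout
#'
#' The grid is an area around the player partitioned into rows and columns
#' with particles on the lowest rows: the default 6 x 7 layout carries
#' particles on the lower 3 rows; the evaluation presets arrange 15 and 33
#' particles in 3 rows (5 and 11 columns).
#'
#' @param totalRows,totalCols grid partition (6, 7).
#' @param particleRows number of lowest rows carrying particles (3).
#' @param widthM,heightM physical grid size in world meters (2 x 2,
#'   matching the player bounding box).
#' @param beta quadratic positional-weight strength: center columns are
#'   favored over outer columns by 1 - beta ((col - center)/maxOffset)^2.
#' @return A layout list (class \code{GridLayout}).
#' @export
gridLayout <- function(totalRows = 6L, totalCols = 7L, particleRows = 3L,
                       widthM = 2, heightM = 2, beta = 0.5) {
  stopifnot(particleRows >= 1, particleRows <= totalRows, totalCols >= 1,
            widthM > 0, heightM > 0, beta >= 0, beta <= 1)
  structure(list(totalRows = as.integer(totalRows),
                 totalCols = as.integer(totalCols),
                 particleRows = as.integer(particleRows),
                 widthM = widthM, heightM = heightM, beta = beta,
                 nParticles = as.integer(particleRows * totalCols)),
            class = c("GridLayout", "list"))
}

#' Grid layout for a particle count
#'
#' The evaluation presets fix 3 particle rows, so the column count follows
#' from the particle count: 15 particles give 5 columns, 33 give 11.
#'
#' @param nParticles total particle count.
#' @param particleRows particle rows (3).
#' @param ... further arguments to \code{\link{gridLayout}}.
#' @return A \code{\link{gridLayout}}.
#' @export
gridLayoutForParticles <- function(nParticles, particleRows = 3L, ...) {
  if (nParticles %% particleRows != 0L)
    stop("particle count must be a multiple of the particle rows")
  gridLayout(totalCols = nParticles %/% particleRows,
             particleRows = particleRows, ...)
}

#' Build a rigid grid around a world point
#'
#' Cell centers are evenly spaced over widthM x heightM in world units,
#' centered on the anchor; particles sit on the lowest \code{particleRows}
#' rows (nearest the camera). The offsets are fixed once and never change
#' between frames -- only the anchor moves -- so the image footprint scales
#' with the local homography resolution automatically.
#'
#' @param center world anchor point (the current estimate).
#' @param layout a \code{\link{gridLayout}}.
#' @param reference the player's \linkS4class{ReferenceAppearance}.
#' @param playerId integer id.
#' @param seed integer seed for the grid's private recovery stream.
#' @param homeRect world rectangle searched while the grid is lost (the
#'   player's team half under pre-structuring; default the whole court).
#' @return A \linkS4class{RigidGrid}.
#' @export
makeGrid <- function(center, layout = gridLayout(), reference,
                     playerId = reference@playerId, seed = 1L,
                     homeRect = c(0, 0, 8, 16)) {
  nc <- layout$totalCols; nrTot <- layout$totalRows
  pr <- layout$particleRows
  xs <- (seq_len(nc) - 0.5) / nc * layout$widthM - layout$widthM / 2
  # particle rows (the lowest rows of the grid) keep the grid's row pitch
  # but are centered on the anchor, so the estimate is unbiased; the rows
  # above them contribute appearance context through each particle's
  # subwindowed bounding box
  pitch <- layout$heightM / nrTot
  ys <- (seq_len(pr) - (pr + 1) / 2) * pitch
  offsets <- cbind(rep(xs, times = pr), rep(ys, each = nc))  # row-major
  rng <- withRNG(childSeed(seed, playerId), runif(1))
  new("RigidGrid", playerId = as.integer(playerId),
      anchor = as.numeric(center), offsets = offsets,
      cols = as.integer(nc), rows = as.integer(pr), layout = layout,
      reference = reference, weights = rep(0, nrow(offsets)),
      cueScores = matrix(0, nrow(offsets), 3), lost = FALSE,
      homeRect = as.numeric(homeRect), colorEma = 0, rngState = rng$state)
}

#' Quadratic positional factor of a grid column
#'
#' Particles in the center columns are favored over the outer columns:
#' factor = 1 - beta ((col - center)/maxOffset)^2, equal to 1 at the center
#' column, symmetric, and minimal (1 - beta) at the edge columns.
#'
#' @param col 0-based column index (0..cols-1); vectorized.
#' @param layout a \code{\link{gridLayout}}.
#' @return factor(s) in (0, 1].
#' @export
positionalFactor <- function(col, layout = gridLayout()) {
  nc <- layout$totalCols
  if (nc == 1L) return(rep(1, length(col)))
  center <- (nc - 1) / 2
  1 - layout$beta * ((col - center) / center)^2
}

#' One grid tracking step
#'
#' Every grid particle's bounding box is projected into the image; color
#' histograms of the subwindows are queried from an integral histogram
#' built over the grid's image footprint (exactly equal to direct
#' per-region histograms), and the mask and movement counts computed. Cues
#' are normalized to the grid's per-frame maximum, summed, and multiplied
#' by the quadratic positional factor of the particle's column. The new
#' estimate is the weighted mean of the particle world positions, and the
#' grid anchor moves there. With zero evidence the anchor is held and the
#' lost flag raised.
#'
#' @param grid a \linkS4class{RigidGrid}.
#' @param bundle the frame's \linkS4class{FrameBundle}.
#' @param h the court \linkS4class{Homography}.
#' @param cw a \code{\link{cueWeights}}.
#' @param config a \code{\link{histogramConfig}}.
#' @param heightM bounding-box height in meters.
#' @param useIntegral FALSE computes every region histogram directly
#'   (brute force); results are identical by construction.
#' @param scanStride every scanStride-th frame a coarse color sweep of the
#'   grid's home region checks for a clearly better-matching position
#'   (2x the grid's own best color score); the grid is local, so without
#'   the sweep a capture by a similarly colored distractor goes unnoticed
#'   while the true player sits outside the footprint. 0 disables it.
#' @return list(grid = updated grid, estimate = world point).
#' @export
gridStep <- function(grid, bundle, h, cw = cueWeights(),
                     config = histogramConfig(), heightM = 2,
                     useIntegral = TRUE, scanStride = 10L) {
  d <- dim(bundle@frame); frameDim <- c(d[2], d[1])
  pos <- sweep(grid@offsets, 2, grid@anchor, "+")
  n <- nrow(pos)
  boxes <- lapply(seq_len(n), function(j) {
    tryCatch(projectBox(h, pos[j, ], heightM, cw$ns, frameDim),
             error = function(e) NULL)
  })

  ih <- NULL
  if (useIntegral) {
    # footprint union of all boxes, cropped from the frame's bin images
    live <- Filter(Negate(is.null), lapply(boxes, function(b)
      if (!is.null(b) && !b$empty) b$box else NULL))
    if (length(live) > 0) {
      fp <- c(min(vapply(live, `[`, 0, 1)), min(vapply(live, `[`, 0, 2)),
              max(vapply(live, `[`, 0, 3)), max(vapply(live, `[`, 0, 4)))
      rows <- (fp[2] + 1):(fp[4] + 1); cols <- (fp[1] + 1):(fp[3] + 1)
      ih <- integralHistogramFromBins(
        bundle@chromaBin[rows, cols, drop = FALSE],
        bundle@valueBin[rows, cols, drop = FALSE], config)
      attr(ih, "origin") <- fp[1:2]
    }
  }

  raw <- matrix(0, n, 3, dimnames = list(NULL, c("color", "mask", "mov")))
  refs <- grid@reference@histograms
  refEmpty <- vapply(refs, function(x) sum(x) == 0, logical(1))
  for (j in seq_len(n)) {
    box <- boxes[[j]]
    if (is.null(box) || box$empty) next
    dists <- vapply(seq_along(box$bands), function(k) {
      r <- box$bands[[k]]
      if (is.null(r)) return(1)
      hyp <- if (!is.null(ih)) {
        org <- attr(ih, "origin")
        regionHistogram(ih, c(r[1] - org[1], r[2] - org[2],
                              r[3] - org[1], r[4] - org[2]))
      } else {
        sub <- .cropBins(bundle, r)
        .histFromBins(sub$chromaBin, sub$valueBin, config)
      }
      bhattacharyya(refs[[k]], hyp)
    }, numeric(1))
    raw[j, 1] <- colorScore(dists, cw, refEmpty)
    raw[j, 2] <- countScore(bundle@fgMask, box$bands, box$widthPx)
    raw[j, 3] <- countScore(bundle@movMask, box$bands, box$widthPx)
  }

  colIdx <- rep(seq_len(grid@cols) - 1L, times = grid@rows)
  pf <- positionalFactor(colIdx, grid@layout)
  searching <- grid@lost
  tw <- if (searching) .normCue(raw[, 1]) * pf
        else totalWeight(.normCue(raw[, 1]), .normCue(raw[, 2]),
                         .normCue(raw[, 3]), cw) * pf
  grid@cueScores <- raw
  grid@weights <- tw
  # recent color evidence with exponential forgetting: the sweep must beat
  # this, not just the current frame, so a briefly occluded or mask-dropped
  # target does not make the grid yield to a weaker distractor
  grid@colorEma <- if (searching) grid@colorEma * 0.8
                   else 0.8 * grid@colorEma + 0.2 * max(raw[, 1])
  sweepDue <- searching ||
    (scanStride > 0L && bundle@frameIndex %% scanStride == 0L)
  if (sweepDue) {
    # the grid is local: a coarse color sweep of the home region finds the
    # player when the grid is lost, and detects capture by a similarly
    # colored distractor while tracking (the true player then scores
    # clearly higher somewhere outside the footprint)
    hr <- if (length(grid@homeRect) == 4) grid@homeRect else c(0, 0, 8, 16)
    lattice <- as.matrix(expand.grid(
      x = seq(hr[1] + 0.4, hr[3] - 0.4, by = 0.75),
      y = seq(hr[2] + 0.4, hr[4] - 0.4, by = 0.75)))
    colorAt <- .scorePositions(lattice, grid@reference, bundle, h, cw,
                               config, heightM)[, 1]
    best <- which.max(colorAt)
    # a tracking grid only yields to a clearly better spot genuinely
    # elsewhere; lattice points around its own target (within the grid's
    # own reach) are refinements the normal step handles
    farEnough <- searching ||
      sqrt(sum((lattice[best, ] - grid@anchor)^2)) > grid@layout$widthM / 2
    if ((searching && max(raw[, 1]) <= 0) ||
        (farEnough && max(colorAt) > 2 * max(raw[, 1], grid@colorEma))) {
      # re-anchor at the sweep's best spot and relock on the next step
      if (colorAt[best] > 0) grid@anchor <- as.numeric(lattice[best, ])
      grid@lost <- TRUE
      return(list(grid = grid, estimate = grid@anchor))
    }
  }
  if (sum(tw) <= 0) {
    grid@lost <- TRUE
    return(list(grid = grid, estimate = grid@anchor))
  }
  grid@lost <- FALSE
  est <- as.numeric(colSums(pos * tw) / sum(tw))
  grid@anchor <- est
  list(grid = grid, estimate = est)
}
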