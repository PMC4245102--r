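# Alternative Hough-line ball trajectory estimator: horizontal-line clutter
# (static flickering blobs) is removed from the x-t and y-t candidate
# scatters, non-horizontal lines honoring a minimum length and maximum point
# gap group the remaining candidates, each group gets a line + parabola fit,
# and neighboring groups are joined at consistent intersections.

#' Hough estimator configuration
#'
#' @param minLineLen minimum detected segment length in scatter pixels (20).
#' @param maxGap maximum gap between consecutive points of a segment (10).
#' @param horizontalAngleTolDeg slopes below this angle count as horizontal
#'   (5 degrees).
#' @param assignDistPx candidate-to-line distance gate (3 px).
#' @param joinMaxDy maximum height mismatch at the line-intersection frame
#'   for joining neighboring sets (15 px).
#' @param thetaResDeg,rhoRes Hough accumulator resolution (1 degree, 1 px).
#' @param skipHorizontalRemoval disable the clutter-removal stage (the
#'   removal can also delete true arc candidates; off by default).
#' @return A configuration list (class \code{HoughConfig}).
#' @export
houghConfig <- function(minLineLen = 20, maxGap = 10,
                        horizontalAngleTolDeg = 5, assignDistPx = 3,
                        joinMaxDy = 15, thetaResDeg = 1, rhoRes = 1,
                        skipHorizontalRemoval = FALSE) {
  stopifnot(minLineLen > 0, maxGap > 0, horizontalAngleTolDeg > 0,
            assignDistPx > 0, joinMaxDy > 0)
  structure(list(minLineLen = minLineLen, maxGap = maxGap,
                 horizontalAngleTolDeg = horizontalAngleTolDeg,
                 assignDistPx = assignDistPx, joinMaxDy = joinMaxDy,
                 thetaResDeg = thetaResDeg, rhoRes = rhoRes,
                 skipHorizontalRemoval = skipHorizontalRemoval),
            class = c("HoughConfig", "list"))
}

#' Candidate scatter images
#'
#' Binary images of the candidates plotted over time: the x-t image has one
#' set pixel per candidate at column t+1, row x+1; the y-t image likewise
#' with the upward height yh = frameHeight - 1 - y. Ballistic motion
#' renders as straight lines in x-t and parabolic arcs in y-t.
#'
#' @param candidates data.frame(frame, x, y) in pixel coordinates.
#' @param clipLength number of frames (columns).
#' @param frameHeight frame height in pixels.
#' @param frameWidth frame width in pixels (rows of the x-t image).
#' @return list(xt, yt) of 0/1 matrices (value/height in rows, t in
#'   columns).
#' @export
scatterImages <- function(candidates, clipLength, frameHeight, frameWidth) {
  xt <- matrix(0L, frameWidth, clipLength)
  yt <- matrix(0L, frameHeight, clipLength)
  if (nrow(candidates) > 0) {
    t1 <- pmin(pmax(round(candidates$frame), 0), clipLength - 1) + 1L
    x1 <- pmin(pmax(round(candidates$x), 0), frameWidth - 1) + 1L
    yh <- frameHeight - 1 - candidates$y
    y1 <- pmin(pmax(round(yh), 0), frameHeight - 1) + 1L
    xt[cbind(x1, t1)] <- 1L
    yt[cbind(y1, t1)] <- 1L
  }
  list(xt = xt, yt = yt)
}

# Hough peak lines over a 2-D point set (t, v). Returns a list of segments,
# each a list(idx = point indices, theta, rho). Points are consumed once.
.houghSegments <- function(t, v, cfg, horizontalOnly = FALSE,
                           minPoints = 3L) {
  n <- length(t)
  segs <- list()
  if (n < minPoints) return(segs)
  thetas <- seq(0, 180 - cfg$thetaResDeg, by = cfg$thetaResDeg) * pi / 180
  if (horizontalOnly) {
    # horizontal in the scatter (constant v over t): normal along v
    tol <- cfg$horizontalAngleTolDeg * pi / 180
    thetas <- thetas[abs(thetas - pi / 2) <= tol]
  }
  cosT <- cos(thetas); sinT <- sin(thetas)
  avail <- rep(TRUE, n)
  repeat {
    idxAvail <- which(avail)
    if (length(idxAvail) < minPoints) break
    rho <- outer(t[idxAvail], cosT) + outer(v[idxAvail], sinT)
    rhoBin <- round(rho / cfg$rhoRes)
    keys <- sweep(rhoBin, 2, seq_along(thetas) * (2 * ceiling(
      max(abs(rhoBin)) + 1)), "+")   # unique (theta, rhoBin) key
    tab <- table(as.vector(keys))
    best <- as.integer(names(tab)[which.max(tab)])
    support <- max(tab)
    if (support < minPoints) break
    hit <- which(keys == best, arr.ind = TRUE)
    thIdx <- hit[1, 2]
    theta <- thetas[thIdx]
    rhoVal <- stats::median(rho[hit[, 1], thIdx])
    # collect all available points within the assign distance of the line
    dist <- abs(t[idxAvail] * cos(theta) + v[idxAvail] * sin(theta) - rhoVal)
    close <- idxAvail[dist <= cfg$assignDistPx]
    if (length(close) < minPoints) { # spurious peak: drop its points
      avail[idxAvail[hit[, 1]]] <- FALSE
      next
    }
    # order along the line and split at gaps
    dirT <- -sin(theta); dirV <- cos(theta)
    proj <- t[close] * dirT + v[close] * dirV
    ord <- close[order(proj)]
    projS <- sort(proj)
    brk <- c(0, which(diff(projS) > cfg$maxGap), length(ord))
    for (s in seq_len(length(brk) - 1)) {
      part <- ord[(brk[s] + 1):brk[s + 1]]
      if (length(part) < minPoints) next
      span <- sqrt((max(t[part]) - min(t[part]))^2 +
                   (max(v[part]) - min(v[part]))^2)
      if (span < cfg$minLineLen) next
      segs[[length(segs) + 1L]] <- list(idx = part, theta = theta,
                                        rho = rhoVal)
      avail[part] <- FALSE
    }
    # points near the peak line but in too-short/gappy pieces are consumed
    avail[close] <- FALSE
  }
  segs
}

# is a Hough segment horizontal (constant v over t) within tolerance?
.isHorizontal <- function(theta, tolDeg) {
  abs(theta - pi / 2) <= tolDeg * pi / 180
}

#' Remove horizontal-line clutter
#'
#' Static flickering blobs (spectators, net shimmer) appear as horizontal
#' point lines in the x-t or y-t scatter. Candidates within the assign
#' distance of a near-horizontal line in either image are disregarded.
#'
#' @param candidates data.frame(frame, x, y).
#' @param frameHeight frame height in pixels.
#' @param cfg a \code{\link{houghConfig}}.
#' @return The filtered candidate data.frame.
#' @export
removeHorizontal <- function(candidates, frameHeight, cfg = houghConfig()) {
  if (nrow(candidates) == 0 || cfg$skipHorizontalRemoval) return(candidates)
  yh <- frameHeight - 1 - candidates$y
  drop <- rep(FALSE, nrow(candidates))
  for (v in list(candidates$x, yh)) {
    # horizontal lines: groups of >= 3 points sharing v within the gate
    segs <- .houghSegments(candidates$frame, v, cfg, horizontalOnly = TRUE)
    for (s in segs) {
      vLine <- stats::median(v[s$idx])
      drop <- drop | abs(v - vLine) <= cfg$assignDistPx
    }
  }
  candidates[!drop, , drop = FALSE]
}

#' Group candidates by non-horizontal scatter lines
#'
#' Probabilistic-Hough-style segment detection on the x-t scatter of the
#' (already filtered) candidates: segments need the minimum length and
#' tolerate at most the maximum gap between consecutive points; each
#' candidate is assigned to at most one line, and sets with fewer than
#' three members are dropped.
#'
#' @inheritParams removeHorizontal
#' @return list of candidate data.frames, one per detected line, ordered by
#'   their first frame.
#' @export
detectLineSets <- function(candidates, frameHeight, cfg = houghConfig()) {
  if (nrow(candidates) < 3) return(list())
  segs <- .houghSegments(candidates$frame, candidates$x, cfg)
  segs <- Filter(function(s)
    !.isHorizontal(s$theta, cfg$horizontalAngleTolDeg), segs)
  sets <- lapply(segs, function(s) candidates[s$idx, , drop = FALSE])
  sets <- Filter(function(s) nrow(s) >= 3, sets)
  if (length(sets) == 0) return(sets)
  sets[order(vapply(sets, function(s) min(s$frame), numeric(1)))]
}

#' Fit line sets and join neighbors
#'
#' Each candidate set receives a least-squares line (m, b) in x-t and
#' parabola (a2, a1, a0) in height-t over its frame range. Consecutive sets
#' are joined by interpolation when their x-t line intersection frame lies
#' inside the inter-set gap and the two height models differ by less than
#' \code{joinMaxDy} pixels there; joined trajectories extend to the
#' intersection frame from both sides.
#'
#' @param lineSets list of candidate data.frames (frame, x, y), frame
#'   ordered.
#' @param frameHeight frame height in pixels.
#' @param cfg a \code{\link{houghConfig}}.
#' @return list of \linkS4class{BallTrajectory} (status "selected").
#' @export
fitAndJoin <- function(lineSets, frameHeight, cfg = houghConfig()) {
  trajs <- list()
  for (s in lineSets) {
    members <- data.frame(frame = s$frame, x = s$x,
                          yh = frameHeight - 1 - s$y)
    tr <- tryCatch(.newTrajectory(members), error = function(e) NULL)
    if (is.null(tr)) { warning("singular fit; line set dropped"); next }
    tr@status <- "selected"
    trajs[[length(trajs) + 1L]] <- tr
  }
  if (length(trajs) <= 1) return(trajs)
  trajs <- trajs[order(vapply(trajs, function(t) t@frameStart, numeric(1)))]
  for (i in seq_len(length(trajs) - 1)) {
    a <- trajs[[i]]; b <- trajs[[i + 1]]
    if (abs(a@m - b@m) < 1e-12) next
    tStar <- (b@b - a@b) / (a@m - b@m)
    if (tStar <= a@frameEnd || tStar >= b@frameStart) next
    ya <- predictTrajectory(a, tStar)[1, "yh"]
    yb <- predictTrajectory(b, tStar)[1, "yh"]
    if (abs(ya - yb) >= cfg$joinMaxDy) next
    trajs[[i]]@extEnd <- tStar
    trajs[[i + 1]]@extStart <- tStar
  }
  trajs
}

#' Hough-based ball trajectory estimation
#'
#' Runs the full alternative estimator: horizontal clutter removal,
#' non-horizontal line grouping, per-set fitting and joining.
#'
#' @inheritParams removeHorizontal
#' @return list of \linkS4class{BallTrajectory}.
#' @export
houghTrajectories <- function(candidates, frameHeight, cfg = houghConfig()) {
  filtered <- removeHorizontal(candidates, frameHeight, cfg)
  sets <- detectLineSets(filtered, frameHeight, cfg)
  fitAndJoin(sets, frameHeight, cfg)
}
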