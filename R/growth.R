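# Incremental trajectory growth over per-frame ball candidates: seed from
# collinear triples, predict with the ballistic model (line in x-t,
# parabola in height-t), absorb nearby candidates, terminate after too many
# missing frames, select among parallel trajectories and extrapolate.
#
# Heights are measured upward from the frame bottom (yh = frameHeight - 1 -
# y_px) so gravity gives a negative leading parabola coefficient.

#' Trajectory growth configuration
#'
#' @param seedMinCandidates candidates needed to seed (3).
#' @param seedMaxDistPx maximum pairwise image distance between the seed
#'   candidates (20 px).
#' @param seedCollinearityTolPx maximum x-t collinearity residual of the
#'   seed triple (2 px).
#' @param matchTolPx prediction-to-candidate gate while growing (10 px).
#' @param maxMissing consecutive missing frames tolerated; more terminates
#'   the trajectory (3).
#' @param maxRmsPx a candidate is only absorbed if the refreshed fit keeps
#'   the RMS residual below this (3 px): points beyond a ball contact bend
#'   the parabola and are rejected, so trajectories end at contacts.
#' @return A configuration list (class \code{GrowthConfig}).
#' @export
growthConfig <- function(seedMinCandidates = 3L, seedMaxDistPx = 20,
                         seedCollinearityTolPx = 2, matchTolPx = 10,
                         maxMissing = 3L, maxRmsPx = 3) {
  stopifnot(seedMinCandidates >= 3, seedMaxDistPx > 0,
            seedCollinearityTolPx > 0, matchTolPx > 0, maxMissing >= 0,
            maxRmsPx > 0)
  structure(list(seedMinCandidates = as.integer(seedMinCandidates),
                 seedMaxDistPx = seedMaxDistPx,
                 seedCollinearityTolPx = seedCollinearityTolPx,
                 matchTolPx = matchTolPx, maxMissing = as.integer(maxMissing),
                 maxRmsPx = maxRmsPx),
            class = c("GrowthConfig", "list"))
}

#' Least-squares ballistic fit
#'
#' Fits x = m t + b and yh = a2 t^2 + a1 t + a0 to member candidates. With
#' fewer than three distinct frames the parabola is deferred (a linear
#' height model is used for prediction instead). Noiseless inputs generated
#' from known coefficients are recovered exactly (to numerical precision).
#'
#' @param members data.frame with columns frame, x, yh.
#' @return list(a2, a1, a0, m, b, rms) -- a2..a0 are NA while deferred; rms
#'   is the root-mean-square residual over both models.
#' @export
fitTrajectory <- function(members) {
  t <- members$frame
  if (length(unique(t)) < 2L) stop("members span fewer than 2 frames")
  tc <- mean(t)                         # center for conditioning
  ts <- t - tc
  lin <- stats::lm.fit(cbind(1, ts), members$x)$coefficients
  m <- lin[2]; b <- lin[1] - m * tc
  resx <- members$x - (m * t + b)
  if (length(unique(t)) >= 3L) {
    par <- stats::lm.fit(cbind(1, ts, ts^2), members$yh)$coefficients
    a2 <- par[3]
    a1 <- par[2] - 2 * par[3] * tc
    a0 <- par[1] - par[2] * tc + par[3] * tc^2
    resy <- members$yh - (a2 * t^2 + a1 * t + a0)
  } else {
    linY <- stats::lm.fit(cbind(1, ts), members$yh)$coefficients
    a2 <- NA_real_; a1 <- linY[2]; a0 <- linY[1] - linY[2] * tc
    resy <- members$yh - (a1 * t + a0)
  }
  list(a2 = unname(a2), a1 = unname(a1), a0 = unname(a0),
       m = unname(m), b = unname(b),
       rms = sqrt(mean(c(resx^2, resy^2))))
}

.newTrajectory <- function(members) {
  members <- members[order(members$frame), c("frame", "x", "yh")]
  f <- fitTrajectory(members)
  new("BallTrajectory", a2 = f$a2, a1 = f$a1, a0 = f$a0, m = f$m, b = f$b,
      frameStart = as.integer(min(members$frame)),
      frameEnd = as.integer(max(members$frame)),
      members = members, missingRun = 0L, status = "growing",
      extStart = min(members$frame), extEnd = max(members$frame))
}

#' Predict the trajectory position at a frame
#'
#' @param traj a \linkS4class{BallTrajectory}.
#' @param t frame index (vectorized).
#' @return matrix with columns x and yh; the height uses the parabola when
#'   available and the deferred linear model otherwise.
#' @export
predictTrajectory <- function(traj, t) {
  x <- traj@m * t + traj@b
  yh <- if (is.na(traj@a2)) traj@a1 * t + traj@a0
        else traj@a2 * t^2 + traj@a1 * t + traj@a0
  cbind(x = x, yh = yh)
}

#' Extend a trajectory with one frame's candidates
#'
#' Predicts the next ball position from the current fit; the nearest
#' candidate within the match gate is absorbed (ties broken toward lower x,
#' then lower y) and the fit refreshed. With no candidate near the
#' prediction the frame counts as missing, and more than \code{maxMissing}
#' consecutive missing frames terminate the trajectory.
#'
#' @param traj a growing \linkS4class{BallTrajectory}.
#' @param candidates data.frame(frame, x, yh) of this frame's candidates
#'   (may be empty).
#' @param t the frame index.
#' @param cfg a \code{\link{growthConfig}}.
#' @return The updated trajectory.
#' @export
extendTrajectory <- function(traj, candidates, t, cfg = growthConfig()) {
  if (traj@status != "growing") return(traj)
  pred <- predictTrajectory(traj, t)
  hit <- NULL
  if (nrow(candidates) > 0) {
    dd <- sqrt((candidates$x - pred[1, "x"])^2 +
               (candidates$yh - pred[1, "yh"])^2)
    ok <- which(dd <= cfg$matchTolPx)
    if (length(ok) > 0) {
      best <- ok[order(dd[ok], candidates$x[ok], candidates$yh[ok])][1]
      hit <- candidates[best, , drop = FALSE]
    }
  }
  if (!is.null(hit)) {
    members <- rbind(traj@members,
                     data.frame(frame = t, x = hit$x, yh = hit$yh))
    f <- fitTrajectory(members)
    if (f$rms > cfg$maxRmsPx) hit <- NULL     # would bend the model
    else {
      traj@members <- members
      traj@missingRun <- 0L
      traj@frameEnd <- as.integer(t)
      traj@extEnd <- t
      traj@a2 <- f$a2; traj@a1 <- f$a1; traj@a0 <- f$a0
      traj@m <- f$m; traj@b <- f$b
    }
  }
  if (is.null(hit)) {
    traj@missingRun <- traj@missingRun + 1L
    if (traj@missingRun > cfg$maxMissing) {
      traj@status <- "terminated"
      traj@extEnd <- traj@frameEnd
    }
  }
  traj
}

# seed search: triples of unused candidates from distinct frames within the
# allowed gap, pairwise close and collinear in x-t
.seedFromBuffer <- function(buffer, cfg, skip = NULL) {
  if (nrow(buffer) < 3L) return(NULL)
  frames <- sort(unique(buffer$frame))
  if (length(frames) < 3L) return(NULL)
  tNew <- max(frames)
  newIdx <- which(buffer$frame == tNew)
  oldIdx <- which(buffer$frame < tNew)
  if (length(oldIdx) < 2L) return(NULL)
  for (ci in newIdx) {
    for (bi in oldIdx[order(-buffer$frame[oldIdx])]) {
      if (buffer$frame[bi] >= tNew) next
      if (tNew - buffer$frame[bi] > cfg$maxMissing + 1L) next
      for (ai in oldIdx) {
        if (buffer$frame[ai] >= buffer$frame[bi]) next
        if (buffer$frame[bi] - buffer$frame[ai] > cfg$maxMissing + 1L) next
        tri <- buffer[c(ai, bi, ci), ]
        # chain gate: consecutive seed candidates within the distance
        d12 <- sqrt((tri$x[2] - tri$x[1])^2 + (tri$yh[2] - tri$yh[1])^2)
        d23 <- sqrt((tri$x[3] - tri$x[2])^2 + (tri$yh[3] - tri$yh[2])^2)
        if (max(d12, d23) >= cfg$seedMaxDistPx) next
        # collinearity of x over t: middle point vs line through outer two
        slope <- (tri$x[3] - tri$x[1]) / (tri$frame[3] - tri$frame[1])
        xPred <- tri$x[1] + slope * (tri$frame[2] - tri$frame[1])
        if (abs(tri$x[2] - xPred) >= cfg$seedCollinearityTolPx) next
        if (!is.null(skip) && skip(tri)) next
        return(c(ai, bi, ci))
      }
    }
  }
  NULL
}

#' Grow ball trajectories over a candidate stream
#'
#' Processes frames in order. Growing trajectories absorb matching
#' candidates first; candidates not claimed by any trajectory enter a seed
#' buffer, and a new trajectory starts whenever three buffered candidates
#' from distinct nearby frames lie within 20 px of each other and on a
#' straight line in the x-t scatter (so four consistent candidates extend
#' one trajectory rather than spawning duplicates).
#'
#' @param candidates data.frame(frame, x, y) of ball candidates over the
#'   clip (pixel coordinates, y down).
#' @param frameHeight frame height in pixels (for the upward height
#'   convention).
#' @param cfg a \code{\link{growthConfig}}.
#' @param frameRange optional c(first, last) frame of the clip; defaults to
#'   the candidate range.
#' @return list of \linkS4class{BallTrajectory} (growing ones terminated at
#'   the end of the stream).
#' @export
growTrajectories <- function(candidates, frameHeight,
                             cfg = growthConfig(), frameRange = NULL) {
  if (nrow(candidates) == 0) return(list())
  cand <- data.frame(frame = candidates$frame, x = candidates$x,
                     yh = frameHeight - 1 - candidates$y)
  if (is.null(frameRange)) frameRange <- range(cand$frame)
  trajs <- list()
  buffer <- cand[0, ]
  inOneTraj <- function(rows) {
    for (tr in trajs) {
      if (tr@status != "growing") next
      key <- paste(tr@members$frame, tr@members$x, tr@members$yh)
      if (all(paste(rows$frame, rows$x, rows$yh) %in% key)) return(TRUE)
    }
    FALSE
  }
  for (t in seq(frameRange[1], frameRange[2])) {
    atT <- cand[cand$frame == t, , drop = FALSE]
    for (i in seq_along(trajs)) {
      if (trajs[[i]]@status != "growing") next
      trajs[[i]] <- extendTrajectory(trajs[[i]], atT, t, cfg)
    }
    # every candidate may still seed; duplicates are suppressed when the
    # whole triple already belongs to one growing trajectory
    buffer <- rbind(buffer, atT)
    buffer <- buffer[t - buffer$frame <= 2L * (cfg$maxMissing + 1L), ,
                     drop = FALSE]
    repeat {
      seed <- .seedFromBuffer(buffer, cfg, skip = inOneTraj)
      if (is.null(seed)) break
      trajs[[length(trajs) + 1L]] <- .newTrajectory(buffer[seed, ])
      buffer <- buffer[-seed, , drop = FALSE]
    }
  }
  lapply(trajs, function(tr) {
    if (tr@status == "growing") tr@status <- "terminated"
    tr
  })
}

#' Select among time-parallel trajectories
#'
#' Among trajectories overlapping in time, the one with the most member
#' candidates (ties broken by the lower RMS residual) is kept, so at most
#' one trajectory is present at any frame. Consecutive arcs legitimately
#' share a frame or two around the contact (the contact-frame candidate
#' belongs to both), so only overlaps beyond a small slack count as
#' parallel.
#'
#' @param trajs list of \linkS4class{BallTrajectory}.
#' @param overlapSlack frames of overlap tolerated between neighbors (2).
#' @return frame-ordered list of selected trajectories (status "selected").
#' @export
selectParallel <- function(trajs, overlapSlack = 2L) {
  if (length(trajs) == 0) return(list())
  counts <- vapply(trajs, function(tr) nrow(tr@members), numeric(1))
  rms <- vapply(trajs, function(tr) fitTrajectory(tr@members)$rms,
                numeric(1))
  ord <- order(-counts, rms)
  kept <- list()
  for (i in ord) {
    tr <- trajs[[i]]
    overlap <- any(vapply(kept, function(k)
      min(tr@frameEnd, k@frameEnd) - max(tr@frameStart, k@frameStart) >=
        overlapSlack, logical(1)))
    if (!overlap) {
      tr@status <- "selected"
      kept[[length(kept) + 1L]] <- tr
    }
  }
  kept[order(vapply(kept, function(k) k@frameStart, numeric(1)))]
}

#' Extrapolate selected trajectories across gaps
#'
#' Each trajectory's model is evaluated beyond its members: neighbors meet
#' at the intersection frame of their x-t lines when it falls inside the
#' gap (the gap midpoint otherwise), and the first/last trajectories extend
#' to the clip bounds. Member points are never altered; only the
#' extrapolated frame range (extStart/extEnd) changes.
#'
#' @param trajs frame-ordered non-overlapping list (from
#'   \code{\link{selectParallel}}).
#' @param frameRange c(first, last) clip frame bounds.
#' @return The list with extended extStart/extEnd.
#' @export
extrapolateTrajectories <- function(trajs, frameRange) {
  k <- length(trajs)
  if (k == 0) return(trajs)
  trajs[[1]]@extStart <- as.numeric(frameRange[1])
  trajs[[k]]@extEnd <- as.numeric(frameRange[2])
  if (k > 1) for (i in seq_len(k - 1)) {
    a <- trajs[[i]]; b <- trajs[[i + 1]]
    tStar <- if (abs(a@m - b@m) > 1e-12) (b@b - a@b) / (a@m - b@m)
             else NA_real_
    mid <- (a@frameEnd + b@frameStart) / 2
    if (!is.finite(tStar) || tStar <= a@frameEnd || tStar >= b@frameStart)
      tStar <- mid
    trajs[[i]]@extEnd <- tStar
    trajs[[i + 1]]@extStart <- tStar
  }
  trajs
}

#' Per-frame ball positions of a trajectory set
#'
#' Evaluates each trajectory's model over its extrapolated frame range and
#' converts heights back to image y.
#'
#' @param trajs list of \linkS4class{BallTrajectory}.
#' @param frameHeight frame height in pixels.
#' @param frames integer frames to evaluate (default: union of the
#'   trajectories' extended ranges).
#' @return data.frame(frame, x, y, interpolated) with NA rows for frames no
#'   trajectory covers; interpolated marks non-member frames.
#' @export
trajectoryPoints <- function(trajs, frameHeight, frames = NULL) {
  if (is.null(frames)) {
    if (length(trajs) == 0) return(data.frame(frame = integer(0),
                                              x = numeric(0), y = numeric(0),
                                              interpolated = logical(0)))
    frames <- seq(floor(min(vapply(trajs, function(t) t@extStart, 0))),
                  ceiling(max(vapply(trajs, function(t) t@extEnd, 0))))
  }
  out <- data.frame(frame = frames, x = NA_real_, y = NA_real_,
                    interpolated = NA)
  for (tr in trajs) {
    sel <- which(frames >= tr@extStart & frames <= tr@extEnd)
    if (length(sel) == 0) next
    p <- predictTrajectory(tr, frames[sel])
    out$x[sel] <- p[, "x"]
    out$y[sel] <- frameHeight - 1 - p[, "yh"]
    out$interpolated[sel] <- !(frames[sel] %in% tr@members$frame)
  }
  out
}
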