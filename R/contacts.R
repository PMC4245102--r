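# Ball-contact time points: intersections of consecutive height parabolas,
# with the serve rule for the first contact (the serve cannot be an
# intersection, so the first trajectory's initial frame is used).

#' Intersection of two height parabolas
#'
#' Solves (a2 - a2') t^2 + (a1 - a1') t + (a0 - a0') = 0 and, among the real
#' roots, picks the one closest to the midpoint of the inter-trajectory
#' frame gap; no event is returned when no real root lies within the gap
#' extended by the slack.
#'
#' @param t1,t2 \linkS4class{BallTrajectory}, t1 preceding t2 (both with
#'   parabola fits).
#' @param slackFrames allowed overshoot of the intersection outside the gap
#'   (15 frames).
#' @return list(frame, frameRounded, y) or NULL when there is no valid
#'   intersection (identical parabolas warn and return NULL).
#' @export
intersectParabolas <- function(t1, t2, slackFrames = 15) {
  if (is.na(t1@a2) || is.na(t2@a2)) return(NULL)
  dA <- t1@a2 - t2@a2; dB <- t1@a1 - t2@a1; dC <- t1@a0 - t2@a0
  scale <- max(1, abs(t1@a2), abs(t1@a1), abs(t1@a0))
  if (max(abs(dA), abs(dB), abs(dC)) < 1e-9 * scale) {
    warning("identical parabolas; no unique intersection")
    return(NULL)
  }
  roots <- if (abs(dA) < 1e-12) {
    if (abs(dB) < 1e-12) numeric(0) else -dC / dB
  } else {
    disc <- dB^2 - 4 * dA * dC
    if (disc < 0) numeric(0)
    else (-dB + c(-1, 1) * sqrt(disc)) / (2 * dA)
  }
  if (length(roots) == 0) return(NULL)
  lo <- t1@frameEnd - slackFrames
  hi <- t2@frameStart + slackFrames
  roots <- roots[roots >= lo & roots <= hi]
  if (length(roots) == 0) return(NULL)
  mid <- (t1@frameEnd + t2@frameStart) / 2
  tStar <- roots[which.min(abs(roots - mid))]
  list(frame = tStar, frameRounded = as.integer(round(tStar)),
       y = t1@a2 * tStar^2 + t1@a1 * tStar + t1@a0)
}

#' Contact events of a trajectory sequence
#'
#' The first contact (the serve) is the initial frame of the first
#' trajectory; every further contact is the height-parabola intersection of
#' a consecutive trajectory pair. Pairs without a valid intersection are
#' skipped; events are strictly increasing in frame.
#'
#' @param trajs time-ordered, non-overlapping list of
#'   \linkS4class{BallTrajectory} (e.g. from \code{\link{selectParallel}}).
#' @param slackFrames see \code{\link{intersectParabolas}}.
#' @return data.frame(event, frame, frameFractional, kind, trajA, trajB)
#'   with kind "serve" or "intersection".
#' @export
contactEvents <- function(trajs, slackFrames = 15) {
  empty <- data.frame(event = integer(0), frame = integer(0),
                      frameFractional = numeric(0), kind = character(0),
                      trajA = integer(0), trajB = integer(0))
  if (length(trajs) == 0) return(empty)
  rows <- list(data.frame(event = 1L, frame = trajs[[1]]@frameStart,
                          frameFractional = as.numeric(trajs[[1]]@frameStart),
                          kind = "serve", trajA = 1L, trajB = NA_integer_))
  last <- as.numeric(trajs[[1]]@frameStart)
  if (length(trajs) > 1) for (i in seq_len(length(trajs) - 1)) {
    ev <- intersectParabolas(trajs[[i]], trajs[[i + 1]], slackFrames)
    if (is.null(ev) || ev$frame <= last) next
    rows[[length(rows) + 1L]] <- data.frame(
      event = length(rows) + 1L, frame = ev$frameRounded,
      frameFractional = ev$frame, kind = "intersection",
      trajA = i, trajB = i + 1L)
    last <- ev$frame
  }
  do.call(rbind, rows)
}
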