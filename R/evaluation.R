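# Accuracy protocol for players, ball and contacts against reference
# annotations: a player frame is correct within 0.5 m world distance or 20
# pixels; the ball within 20 pixels; a contact within (strictly less than)
# 10 frames. Player evaluation samples every 3rd frame after a warm-up of
# two consecutive all-correct frames.

#' Evaluation configuration
#'
#' @param playerDistM world correctness radius for players (0.5 m).
#' @param playerDistPx pixel correctness radius for players (20 px; matters
#'   mostly in the back of the field where a meter is few pixels).
#' @param ballDistPx pixel correctness radius for the ball (20 px).
#' @param contactTolFrames contact correctness: |delta frame| strictly less
#'   than this (10).
#' @param evalStride evaluate every n-th frame (3).
#' @param warmupConsecutive consecutive all-correct frames starting the
#'   evaluation (2).
#' @param allowTeamSwaps allow identity swaps between players of the same
#'   team (teammates often dress alike).
#' @param teams list of player-id vectors forming the teams.
#' @return A configuration list (class \code{EvalConfig}).
#' @export
evalConfig <- function(playerDistM = 0.5, playerDistPx = 20, ballDistPx = 20,
                       contactTolFrames = 10L, evalStride = 3L,
                       warmupConsecutive = 2L, allowTeamSwaps = FALSE,
                       teams = list(c(1L, 2L), c(3L, 4L))) {
  stopifnot(playerDistM > 0, playerDistPx > 0, ballDistPx > 0,
            contactTolFrames > 0, evalStride >= 1, warmupConsecutive >= 1)
  structure(list(playerDistM = playerDistM, playerDistPx = playerDistPx,
                 ballDistPx = ballDistPx,
                 contactTolFrames = as.integer(contactTolFrames),
                 evalStride = as.integer(evalStride),
                 warmupConsecutive = as.integer(warmupConsecutive),
                 allowTeamSwaps = allowTeamSwaps, teams = teams),
            class = c("EvalConfig", "list"))
}

# per-frame per-player correctness matrix under the dual radius, with
# optional same-team identity swaps; tracks/reference have columns
# frame, player_id, x_m, y_m, x_px, y_px
.correctMatrix <- function(tracks, reference, cfg) {
  frames <- sort(intersect(unique(tracks$frame), unique(reference$frame)))
  players <- sort(unique(reference$player_id))
  ok <- matrix(NA, length(frames), length(players),
               dimnames = list(frames, players))
  tKey <- paste(tracks$frame, tracks$player_id)
  rKey <- paste(reference$frame, reference$player_id)
  isCorrect <- function(tRow, rRow) {
    dw <- sqrt((tRow$x_m - rRow$x_m)^2 + (tRow$y_m - rRow$y_m)^2)
    dp <- sqrt((tRow$x_px - rRow$x_px)^2 + (tRow$y_px - rRow$y_px)^2)
    dw < cfg$playerDistM || dp < cfg$playerDistPx
  }
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    for (pi in seq_along(players)) {
      p <- players[pi]
      ti <- match(paste(f, p), tKey)
      ri <- match(paste(f, p), rKey)
      if (is.na(ti) || is.na(ri)) next
      ok[fi, pi] <- isCorrect(tracks[ti, ], reference[ri, ])
    }
    if (cfg$allowTeamSwaps) {
      for (team in cfg$teams) {
        ids <- match(team, players)
        if (any(is.na(ids)) || length(team) != 2L) next
        ti <- match(paste(f, team), tKey); ri <- match(paste(f, team), rKey)
        if (any(is.na(ti)) || any(is.na(ri))) next
        swapped <- c(isCorrect(tracks[ti[1], ], reference[ri[2], ]),
                     isCorrect(tracks[ti[2], ], reference[ri[1], ]))
        if (sum(swapped) > sum(ok[fi, ids]))
          ok[fi, ids] <- swapped
      }
    }
  }
  ok
}

#' Player tracking accuracy
#'
#' A frame is correct for a player when the estimate lies within 0.5 m
#' world distance or 20 px of the reference. Evaluation starts at the first
#' frame where all players are correct for the warm-up run of consecutive
#' frames, then samples every 3rd frame. Front/back groups are the two
#' players nearest/farthest from the camera (smaller/larger mean reference
#' court depth) unless given.
#'
#' @param tracks,reference data.frames with columns frame, player_id, x_m,
#'   y_m, x_px, y_px.
#' @param cfg an \code{\link{evalConfig}}.
#' @param frontPlayers optional integer ids of the front players.
#' @return list(perPlayer = named percent vector, front, back, overall =
#'   percents, framesEvaluated, warmupFrame, missingReference).
#' @export
playerAccuracy <- function(tracks, reference, cfg = evalConfig(),
                           frontPlayers = NULL) {
  ok <- .correctMatrix(tracks, reference, cfg)
  frames <- as.integer(rownames(ok))
  players <- as.integer(colnames(ok))
  missing <- sum(is.na(ok))
  allOk <- apply(ok, 1, function(r) all(r %in% TRUE))
  run <- 0L; start <- NA_integer_
  for (i in seq_along(allOk)) {
    run <- if (allOk[i]) run + 1L else 0L
    if (run >= cfg$warmupConsecutive) { start <- i - cfg$warmupConsecutive + 1L; break }
  }
  if (is.na(start))
    return(list(perPlayer = stats::setNames(rep(NA_real_, length(players)),
                                            players),
                front = NA_real_, back = NA_real_, overall = NA_real_,
                framesEvaluated = 0L, warmupFrame = NA_integer_,
                missingReference = missing))
  sel <- seq(start, nrow(ok), by = cfg$evalStride)
  sub <- ok[sel, , drop = FALSE]
  pct <- function(m) 100 * mean(m[!is.na(m)])
  perPlayer <- vapply(seq_along(players),
                      function(pi) pct(sub[, pi]), numeric(1))
  names(perPlayer) <- players
  if (is.null(frontPlayers)) {
    depth <- vapply(players, function(p)
      mean(reference$y_m[reference$player_id == p]), numeric(1))
    frontPlayers <- players[order(depth)][1:2]
  }
  backPlayers <- setdiff(players, frontPlayers)
  list(perPlayer = perPlayer,
       front = pct(sub[, match(frontPlayers, players), drop = FALSE]),
       back = pct(sub[, match(backPlayers, players), drop = FALSE]),
       overall = pct(sub),
       framesEvaluated = length(sel),
       warmupFrame = frames[start],
       missingReference = missing)
}

#' Ball tracking accuracy
#'
#' Every 3rd frame of the reference range is evaluated: a frame is tracked
#' when a trajectory covers it, and correct when the trajectory point lies
#' within 20 px of the reference. Percentages are reported against both the
#' total evaluated frames and the tracked frames.
#'
#' @param points data.frame(frame, x, y) of per-frame trajectory positions
#'   (NA x/y where no trajectory covers the frame), e.g. from
#'   \code{\link{trajectoryPoints}}.
#' @param reference data.frame(frame, x_px, y_px).
#' @param cfg an \code{\link{evalConfig}}.
#' @return list(total, tracked, correct, pctTotal, pctTracked).
#' @export
ballAccuracy <- function(points, reference, cfg = evalConfig()) {
  frames <- seq(min(reference$frame), max(reference$frame),
                by = cfg$evalStride)
  frames <- frames[frames %in% reference$frame]
  ri <- match(frames, reference$frame)
  pi <- match(frames, points$frame)
  px <- points$x[pi]; py <- points$y[pi]
  tracked <- !is.na(px)
  d <- sqrt((px - reference$x_px[ri])^2 + (py - reference$y_px[ri])^2)
  correct <- tracked & !is.na(d) & d < cfg$ballDistPx
  list(total = length(frames), tracked = sum(tracked),
       correct = sum(correct),
       pctTotal = if (length(frames)) 100 * sum(correct) / length(frames)
                  else NA_real_,
       pctTracked = if (sum(tracked)) 100 * sum(correct) / sum(tracked)
                    else NA_real_)
}

#' Contact estimation accuracy
#'
#' Greedy one-to-one matching in time order: each reference contact takes
#' the nearest unmatched event; the match is correct when the frame numbers
#' differ by strictly less than the tolerance.
#'
#' @param events numeric vector of estimated contact frames (or the
#'   data.frame from \code{\link{contactEvents}}).
#' @param reference numeric vector of annotated contact frames.
#' @param cfg an \code{\link{evalConfig}}.
#' @return list(nReference, nEvents, correct, pct).
#' @export
contactAccuracy <- function(events, reference, cfg = evalConfig()) {
  if (is.data.frame(events)) events <- events$frame
  events <- sort(events); reference <- sort(reference)
  used <- rep(FALSE, length(events))
  correct <- 0L
  for (r in reference) {
    free <- which(!used)
    if (length(free) == 0) break
    j <- free[which.min(abs(events[free] - r))]
    used[j] <- TRUE
    if (abs(events[j] - r) < cfg$contactTolFrames) correct <- correct + 1L
  }
  list(nReference = length(reference), nEvents = length(events),
       correct = correct,
       pct = if (length(reference)) 100 * correct / length(reference)
             else NA_real_)
}
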