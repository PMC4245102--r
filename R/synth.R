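# Seeded synthetic court scenes with exact ground truth: a textured static
# background viewed by a fixed perspective camera, four distinctly colored
# player blobs moving along waypoint paths, a small fast ball on ballistic
# arcs between scheduled contacts, and optional illumination steps, static
# occluders and spectator flicker. The generator is the test substrate for
# the whole tracking stack.

#' Perspective court preset
#'
#' Image corner positions of an 8 x 16 m court seen from behind the
#' baseline: the near edge spans most of the frame width near the bottom,
#' the far edge is narrower and higher (higher resolution in the front of
#' the field than in the back).
#'
#' @param frameWidth,frameHeight frame size in pixels.
#' @return 4 x 2 matrix of pixel corners matching the default world corner
#'   order (0,0), (8,0), (8,16), (0,16).
#' @export
courtCornersPreset <- function(frameWidth = 640, frameHeight = 480) {
  rbind(c(0.10 * frameWidth, 0.92 * frameHeight),
        c(0.90 * frameWidth, 0.92 * frameHeight),
        c(0.68 * frameWidth, 0.30 * frameHeight),
        c(0.32 * frameWidth, 0.30 * frameHeight))
}

#' Player specification
#'
#' @param id integer player id.
#' @param bandColors 4 x 3 RGB matrix (rows top to bottom: head/torso/
#'   shorts/legs bands).
#' @param waypoints n x 2 matrix of world points; the player walks the
#'   polyline at constant speed and stays at the last point.
#' @param speedMps walking speed in meters per second.
#' @param heightM,widthM rendered blob size in meters.
#' @return A specification list.
#' @export
playerSpec <- function(id, bandColors, waypoints, speedMps = 1.5,
                       heightM = 1.8, widthM = 0.6) {
  waypoints <- matrix(as.numeric(waypoints), ncol = 2)
  stopifnot(nrow(bandColors) == 4, ncol(bandColors) == 3, speedMps >= 0)
  list(id = as.integer(id), bandColors = bandColors, waypoints = waypoints,
       speedMps = speedMps, heightM = heightM, widthM = widthM)
}

#' Scenario configuration
#'
#' The generator's defaults describe a plausible amateur recording: 640 x
#' 480 at 25 fps, mild sand texture, no illumination events. Player and
#' ball content comes from the supplied specs.
#'
#' @param frameWidth,frameHeight,fps video geometry.
#' @param nFrames clip length.
#' @param imageCorners court corner pixels (perspective preset by default).
#' @param players list of \code{\link{playerSpec}}s.
#' @param ballSchedule data.frame(frame, x_m, y_m, height_m) of ball
#'   contacts (NULL for no ball); frames strictly increasing.
#' @param noiseSigma background texture standard deviation (intensity
#'   units).
#' @param flickerRate fraction of pixels toggling per frame (spectator
#'   noise).
#' @param illuminationSteps data.frame(frame, gain): global gain applied
#'   from the given frame on.
#' @param occluders list of static pixel rects c(x0, y0, x1, y1) drawn over
#'   the scene (net posts, banners).
#' @param seed integer seed controlling all generator randomness.
#' @return A configuration list (class \code{ScenarioConfig}).
#' @export
scenarioConfig <- function(frameWidth = 640L, frameHeight = 480L, fps = 25,
                          nFrames = 100L, imageCorners = NULL,
                          players = list(), ballSchedule = NULL,
                          noiseSigma = 0.02, flickerRate = 0,
                          illuminationSteps = NULL, occluders = list(),
                          seed = 1L) {
  if (is.null(imageCorners))
    imageCorners <- courtCornersPreset(frameWidth, frameHeight)
  if (!is.null(ballSchedule)) {
    stopifnot(all(diff(ballSchedule$frame) > 0))
    if (is.null(ballSchedule$height_m)) ballSchedule$height_m <- 2
  }
  structure(list(frameWidth = as.integer(frameWidth),
                 frameHeight = as.integer(frameHeight), fps = fps,
                 nFrames = as.integer(nFrames), imageCorners = imageCorners,
                 players = players, ballSchedule = ballSchedule,
                 noiseSigma = noiseSigma, flickerRate = flickerRate,
                 illuminationSteps = illuminationSteps,
                 occluders = occluders, seed = as.integer(seed)),
            class = c("ScenarioConfig", "list"))
}

#' Default four-player setup
#'
#' Two teams of two with distinct band colors: team 1 (near half, reddish
#' kits) and team 2 (far half, bluish kits). Each player walks between two
#' waypoints inside their half.
#'
#' @param crossing make the paths of the two players of each team cross
#'   twice (forth and back), exercising mutual occlusion.
#' @return list of four \code{\link{playerSpec}}s.
#' @export
defaultPlayers <- function(crossing = FALSE) {
  cols <- list(
    rbind(c(0.9, 0.75, 0.6), c(0.85, 0.1, 0.1), c(0.95, 0.55, 0.1), c(0.9, 0.75, 0.6)),
    rbind(c(0.55, 0.4, 0.3), c(0.95, 0.9, 0.1), c(0.1, 0.5, 0.1), c(0.55, 0.4, 0.3)),
    rbind(c(0.9, 0.75, 0.6), c(0.1, 0.2, 0.8), c(0.1, 0.8, 0.85), c(0.9, 0.75, 0.6)),
    rbind(c(0.55, 0.4, 0.3), c(0.6, 0.1, 0.7), c(0.85, 0.85, 0.9), c(0.55, 0.4, 0.3)))
  if (crossing) {
    # speeds and phases tuned so each team pair meets once over ~300 frames
    # at 25 fps (two mutual-occlusion events in the scene)
    paths <- list(rbind(c(1.5, 3), c(6.5, 4.5)),
                  rbind(c(6.5, 3.5), c(1.5, 5)),
                  rbind(c(1.5, 12), c(6, 13)),
                  rbind(c(6, 12.5), c(1.5, 13.5)))
    speeds <- c(1.0, 0.8, 1.0, 0.8)
  } else {
    paths <- list(rbind(c(1.5, 3), c(3.5, 6)), rbind(c(6.5, 4), c(4.5, 2)),
                  rbind(c(1.5, 12), c(4, 13.5)),
                  rbind(c(6.5, 13), c(4, 11)))
    speeds <- rep(1.5, 4)
  }
  lapply(1:4, function(i) playerSpec(i, cols[[i]], paths[[i]],
                                     speedMps = speeds[i]))
}

# position along a waypoint polyline after walking dist meters; the walk
# ping-pongs between the endpoints so players keep moving
.pathPosition <- function(waypoints, dist) {
  if (nrow(waypoints) == 1L) return(waypoints[1, ])
  seg <- diff(waypoints)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  d <- dist %% (2 * total)
  if (d > total) d <- 2 * total - d
  i <- min(findInterval(d, cum, rightmost.closed = TRUE), nrow(seg))
  f <- (d - cum[i]) / len[i]
  waypoints[i, ] + f * seg[i, ]
}

#' Default six-arc rally schedule
#'
#' Seven contacts (serve plus six hits) alternating across the net with
#' realistic hang times (~1.6 s per arc at 25 fps) and contact heights
#' around 2 m.
#'
#' @param startFrame frame of the serve.
#' @param arcFrames frames per arc.
#' @return data.frame(frame, x_m, y_m, height_m) for
#'   \code{\link{scenarioConfig}}.
#' @export
defaultRally <- function(startFrame = 10L, arcFrames = 30L) {
  data.frame(
    frame = startFrame + arcFrames * 0:6,
    x_m = c(1.5, 6, 2, 6.5, 1.5, 6, 2.5),
    y_m = c(2, 11, 5, 12.5, 4, 11.5, 3),
    height_m = c(2.2, 2.0, 2.1, 1.9, 2.2, 2.0, 2.1))
}

#' Render a ball rally from a contact schedule
#'
#' Between consecutive contacts the ball's image x is linear in the frame
#' index and its height above the frame bottom parabolic, with the leading
#' coefficient fixed by gravity scaled into pixels and frames
#' (a2 = -g/2 * pixels-per-meter / fps^2); the arc through the two contact
#' points is then unique, and positions are continuous at contacts.
#'
#' @param schedule data.frame(frame, x_m, y_m, height_m) of contacts; the
#'   contact image point is the court ground point raised by height_m at
#'   the local image scale.
#' @param h the scene \linkS4class{Homography}.
#' @param fps frames per second.
#' @param frameHeight frame height in pixels.
#' @return list(points = data.frame(frame, x, y, yh, arc),
#'   arcs = data.frame(arc, a2, a1, a0, m, b, frameStart, frameEnd)).
#' @export
renderRally <- function(schedule, h, fps, frameHeight) {
  if (is.null(schedule$height_m)) schedule$height_m <- 2
  nC <- nrow(schedule)
  if (nC < 2) stop("schedule needs at least two contacts")
  ground <- worldToImage(h, cbind(schedule$x_m, schedule$y_m))
  scale <- vapply(seq_len(nC), function(i)
    localScale(h, c(schedule$x_m[i], schedule$y_m[i])), numeric(1))
  cx <- ground[, 1]
  cyh <- (frameHeight - 1) - (ground[, 2] - schedule$height_m * scale)
  pts <- list(); arcs <- list()
  for (i in seq_len(nC - 1)) {
    t1 <- schedule$frame[i]; t2 <- schedule$frame[i + 1]
    ppm <- mean(scale[i:(i + 1)])
    a2 <- -0.5 * 9.81 * ppm / fps^2
    a1 <- (cyh[i + 1] - cyh[i] - a2 * (t2^2 - t1^2)) / (t2 - t1)
    a0 <- cyh[i] - a2 * t1^2 - a1 * t1
    m <- (cx[i + 1] - cx[i]) / (t2 - t1)
    b <- cx[i] - m * t1
    tt <- seq(t1, t2 - 1L)
    if (i == nC - 1) tt <- seq(t1, t2)
    yh <- a2 * tt^2 + a1 * tt + a0
    apexYh <- a0 - a1^2 / (4 * a2)
    if (any(yh < 0) || apexYh > frameHeight - 1)
      stop("infeasible contact schedule: arc ", i,
           " leaves the frame (apex ", round(apexYh),
           " px) or goes below ground")
    # ground track (world) interpolates linearly between the contacts; it
    # sets the rendered ball size at each frame (depth-dependent)
    fgnd <- (tt - t1) / (t2 - t1)
    gx <- schedule$x_m[i] + fgnd * (schedule$x_m[i + 1] - schedule$x_m[i])
    gy <- schedule$y_m[i] + fgnd * (schedule$y_m[i + 1] - schedule$y_m[i])
    pts[[i]] <- data.frame(frame = tt, x = m * tt + b,
                           y = (frameHeight - 1) - yh, yh = yh, arc = i,
                           gx = gx, gy = gy)
    arcs[[i]] <- data.frame(arc = i, a2 = a2, a1 = a1, a0 = a0, m = m,
                            b = b, frameStart = t1, frameEnd = t2)
  }
  list(points = do.call(rbind, pts), arcs = do.call(rbind, arcs))
}

.drawRect <- function(frame, rect, color) {
  d <- dim(frame)
  r <- clipRect(rect, c(d[2], d[1]))
  if (is.null(r)) return(frame)
  rows <- (r[2] + 1):(r[4] + 1); cols <- (r[1] + 1):(r[3] + 1)
  for (ch in 1:3) frame[rows, cols, ch] <- color[ch]
  frame
}

.drawDisk <- function(frame, cx, cy, radius, color) {
  d <- dim(frame)
  r <- clipRect(c(floor(cx - radius), floor(cy - radius),
                  ceiling(cx + radius), ceiling(cy + radius)),
                c(d[2], d[1]))
  if (is.null(r)) return(frame)
  rows <- (r[2] + 1):(r[4] + 1); cols <- (r[1] + 1):(r[3] + 1)
  dy <- rows - 1 - cy; dx <- cols - 1 - cx
  inside <- outer(dy^2, dx^2, "+") <= radius^2
  for (ch in 1:3) {
    sub <- frame[rows, cols, ch]
    sub[inside] <- color[ch]
    frame[rows, cols, ch] <- sub
  }
  frame
}

#' Generate a synthetic scene
#'
#' Deterministic given the scenario seed: two runs with the same scenario
#' produce bit-identical frames. Ground-truth pixel positions are exactly
#' \code{worldToImage} of the ground-truth world positions.
#'
#' @param scenario a \code{\link{scenarioConfig}}.
#' @return list(frames = list of H x W x 3 arrays, homography, calibration,
#'   truth = list(players, ball, contacts), rally = renderRally output or
#'   NULL).
#' @export
generateScene <- function(scenario) {
  w <- scenario$frameWidth; hgt <- scenario$frameHeight
  cal <- courtCalibration(scenario$imageCorners)
  h <- estimateHomography(cal)
  rally <- NULL
  if (!is.null(scenario$ballSchedule))
    rally <- renderRally(scenario$ballSchedule, h, scenario$fps, hgt)
  ballRadiusAt <- function(gx, gy)
    max(1.5, 0.105 * localScale(h, c(gx, gy)))

  playersTruth <- list()
  gain <- rep(1, scenario$nFrames)
  if (!is.null(scenario$illuminationSteps))
    for (i in seq_len(nrow(scenario$illuminationSteps))) {
      s <- scenario$illuminationSteps[i, ]
      gain[seq(s$frame + 1L, scenario$nFrames)] <- s$gain
    }

  out <- withRNG(scenario$seed, {
    sand <- c(0.76, 0.66, 0.50)
    tex <- matrix(rnorm(hgt * w, 0, scenario$noiseSigma), hgt, w)
    background <- array(0, c(hgt, w, 3))
    for (ch in 1:3) background[, , ch] <- pmin(1, pmax(0, sand[ch] + tex))
    frames <- vector("list", scenario$nFrames)
    for (t in seq_len(scenario$nFrames) - 1L) {
      fr <- background
      for (sp in scenario$players) {
        pos <- .pathPosition(sp$waypoints, sp$speedMps * t / scenario$fps)
        foot <- worldToImage(h, pos)
        sc <- localScale(h, pos)
        bw <- max(2L, round(sp$widthM * sc))
        bh <- max(4L, round(sp$heightM * sc))
        x0 <- round(foot[1] - bw / 2); y1 <- round(foot[2])
        cuts <- y1 - bh + round(bh * seq(0, 1, length.out = 5))
        for (k in 1:4)
          fr <- .drawRect(fr, c(x0, cuts[k], x0 + bw - 1, cuts[k + 1] - 1),
                          sp$bandColors[k, ])
        playersTruth[[length(playersTruth) + 1L]] <- data.frame(
          frame = t, player_id = sp$id, x_m = pos[1], y_m = pos[2],
          x_px = foot[1], y_px = foot[2])
      }
      if (!is.null(rally)) {
        bp <- rally$points[rally$points$frame == t, ]
        if (nrow(bp) == 1)
          fr <- .drawDisk(fr, bp$x, bp$y, ballRadiusAt(bp$gx, bp$gy),
                          c(1, 1, 1))
      }
      for (oc in scenario$occluders)
        fr <- .drawRect(fr, oc, c(0.15, 0.15, 0.18))
      if (scenario$flickerRate > 0) {
        nFlick <- round(scenario$flickerRate * hgt * w)
        if (nFlick > 0) {
          sel <- sample.int(hgt * w, nFlick)
          for (ch in 1:3) {
            plane <- fr[, , ch]
            plane[sel] <- runif(nFlick)
            fr[, , ch] <- plane
          }
        }
      }
      if (gain[t + 1L] != 1) fr <- pmax(pmin(fr * gain[t + 1L], 1), 0)
      frames[[t + 1L]] <- fr
    }
    frames
  })

  ballTruth <- if (is.null(rally))
    data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0))
  else data.frame(frame = rally$points$frame, x_px = rally$points$x,
                  y_px = rally$points$y)
  playersTruth <- get("playersTruth")
  if (length(playersTruth) > 0) {
    t0 <- do.call(rbind, playersTruth)
    first <- t0[t0$frame == 0, ]
    first <- first[order(first$player_id), ]
    cal@playerClicks <- cbind(first$x_px, first$y_px)
  }
  list(frames = out$value, homography = h, calibration = cal,
       # the final schedule row only ends the rally (the ball stops there);
       # it is not a recoverable contact, so ground truth excludes it
       truth = list(players = do.call(rbind, playersTruth),
                    ball = ballTruth,
                    contacts = if (is.null(scenario$ballSchedule)) integer(0)
                               else utils::head(scenario$ballSchedule$frame,
                                                -1)),
       rally = rally)
}
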