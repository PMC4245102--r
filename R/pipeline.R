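# End-to-end drivers binding the pipeline: background -> masks -> cues ->
# trackers for the players, movement mask -> candidates -> trajectories ->
# contacts for the ball; plus frame and annotation I/O.

#' Build the cue bundle for one frame
#'
#' Computes the foreground mask and masked color frame from the background
#' model, the movement mask against the previous frame, and the per-pixel
#' histogram bin indices shared by all trackers.
#'
#' @param state an initialized \linkS4class{BackgroundModel}.
#' @param frame,prevFrame current and previous H x W x 3 frames (NULL
#'   previous gives an all-zero movement mask).
#' @param frameIndex 0-based index.
#' @param bgConfig a \code{\link{backgroundConfig}}.
#' @param histConfig a \code{\link{histogramConfig}}.
#' @param prevMask previous foreground mask (for the model_diff movement
#'   source).
#' @return A \linkS4class{FrameBundle}.
#' @export
frameBundle <- function(state, frame, prevFrame = NULL, frameIndex = 0L,
                        bgConfig = backgroundConfig(),
                        histConfig = histogramConfig(), prevMask = NULL) {
  fg <- foregroundMask(state, frame, bgConfig)
  mov <- if (is.null(prevFrame)) matrix(0L, dim(frame)[1], dim(frame)[2])
         else movementMask(prevFrame, frame, bgConfig,
                           prevMask = prevMask, mask = fg$mask)
  bi <- binIndices(fg$maskedFrame, fg$mask, histConfig)
  new("FrameBundle", frameIndex = as.integer(frameIndex), frame = frame,
      fgMask = fg$mask, maskedFrame = fg$maskedFrame, movMask = mov,
      chromaBin = bi$chromaBin, valueBin = bi$valueBin)
}

# Train the background model on the clip start so the calibration frame has
# a usable background. The model's first ingestion dominates its memory, so
# it is seeded with the per-pixel temporal median of strided frames (the
# moving players median out of it); normal strided updates follow.
.bootstrapBackground <- function(frames, bgConfig, ingestions = 12L) {
  d <- dim(frames[[1]])
  state <- newBackgroundModel(c(d[2], d[1]), bgConfig)
  need <- min(length(frames), ingestions * bgConfig$feedStride)
  sampleIdx <- unique(round(seq(1, need, length.out = min(9, need))))
  med <- array(0, d)
  stack <- vapply(sampleIdx, function(i) frames[[i]], frames[[1]])
  for (ch in 1:3)
    med[, , ch] <- apply(stack[, , ch, , drop = FALSE], c(1, 2), stats::median)
  state <- updateBackground(state, med, bgConfig)
  state@framesSeen <- 0L
  for (i in seq_len(need)) state <- updateBackground(state, frames[[i]],
                                                     bgConfig)
  state@framesSeen <- 0L
  state
}

#' Track the four players over a clip
#'
#' Runs the full player pipeline: background bootstrap, reference
#' appearance extraction at the calibration frame from the player clicks,
#' then per frame one shared \linkS4class{FrameBundle} and either the
#' classical particle filter (weight, estimate, roulette-wheel resample) or
#' the rigid-grid integral-histogram tracker, with the confusion safeguard
#' across all four trackers.
#'
#' @param frames list of H x W x 3 arrays.
#' @param calibration a \linkS4class{CourtCalibration} with player clicks.
#' @param tracker \code{"grid"} or \code{"particle"}.
#' @param nParticles particle count per set (particle tracker).
#' @param layout a \code{\link{gridLayout}} (grid tracker).
#' @param cw,histConfig,bgConfig,rc module configurations.
#' @param heightM bounding-box height in meters.
#' @param seed integer seed for all tracker randomness.
#' @param initRegions optional list of world rects to initialize the
#'   particle sets in; default is a 2 m box around each click.
#' @return data.frame(frame, player_id, x_m, y_m, x_px, y_px, lost, method).
#' @export
trackPlayers <- function(frames, calibration, tracker = c("grid", "particle"),
                         nParticles = 30L, layout = gridLayout(),
                         cw = cueWeights(), histConfig = histogramConfig(),
                         bgConfig = backgroundConfig(),
                         rc = resampleConfig(), heightM = 2, seed = 1L,
                         initRegions = NULL) {
  tracker <- match.arg(tracker)
  if (nrow(calibration@playerClicks) < 1)
    stop("calibration has no player clicks")
  h <- estimateHomography(calibration)
  rc$courtRect <- c(0, 0, calibration@courtWidthM, calibration@courtLengthM)
  state <- .bootstrapBackground(frames, bgConfig)

  calIdx <- calibration@calibrationFrame + 1L
  prev <- if (calIdx > 1) frames[[calIdx - 1L]] else NULL
  calBundle <- frameBundle(state, frames[[calIdx]], prev,
                           calibration@calibrationFrame, bgConfig, histConfig)
  nPlayers <- nrow(calibration@playerClicks)
  refs <- lapply(seq_len(nPlayers), function(p)
    referenceAppearance(p, calBundle, calibration@playerClicks[p, ], h,
                        histConfig, cw, heightM))
  clicksW <- imageToWorld(h, calibration@playerClicks)

  # team halves from the pre-structured clicks: lost trackers search their
  # own half (the confusion safeguard targets same-team identity mix-ups)
  wM <- calibration@courtWidthM; lM <- calibration@courtLengthM
  homes <- lapply(seq_len(nPlayers), function(p) {
    if (clicksW[p, 2] < lM / 2) c(0, 0, wM, lM / 2) else c(0, lM / 2, wM, lM)
  })
  trackers <- lapply(seq_len(nPlayers), function(p) {
    if (tracker == "particle") {
      reg <- if (!is.null(initRegions)) initRegions[[p]] else {
        c(pmax(rc$courtRect[1:2], clicksW[p, ] - 1),
          pmin(rc$courtRect[3:4], clicksW[p, ] + 1))
      }
      initParticleSet(p, reg, nParticles, refs[[p]], seed,
                      homeRect = homes[[p]])
    } else {
      makeGrid(clicksW[p, ], layout, refs[[p]], p, seed,
               homeRect = homes[[p]])
    }
  })
  counters <- matrix(0L, nPlayers, nPlayers)

  rows <- vector("list", length(frames) * nPlayers)
  prevFrame <- NULL; prevMask <- NULL
  for (t in seq_along(frames) - 1L) {
    fr <- frames[[t + 1L]]
    state <- updateBackground(state, fr, bgConfig)
    bundle <- frameBundle(state, fr, prevFrame, t, bgConfig, histConfig,
                          prevMask)
    for (p in seq_len(nPlayers)) {
      if (tracker == "particle") {
        set <- weightParticleSet(trackers[[p]], bundle, h, cw, histConfig,
                                 heightM)
        est <- set@estimate
        trackers[[p]] <- resampleSet(set, rc)
        trackers[[p]]@estimate <- est
        trackers[[p]]@cueScores <- set@cueScores
        lost <- set@lost
      } else {
        stepped <- gridStep(trackers[[p]], bundle, h, cw, histConfig,
                            heightM)
        trackers[[p]] <- stepped$grid
        est <- stepped$estimate
        lost <- stepped$grid@lost
      }
      px <- worldToImage(h, est)
      rows[[t * nPlayers + p]] <- data.frame(
        frame = t, player_id = p, x_m = est[1], y_m = est[2],
        x_px = px[1], y_px = px[2], lost = lost, method = tracker)
    }
    guard <- confusionGuard(trackers, counters, rc)
    trackers <- guard$trackers
    counters <- guard$counters
    prevFrame <- fr
    prevMask <- bundle@fgMask
  }
  do.call(rbind, rows)
}

#' Track the ball over a clip
#'
#' Movement masks between consecutive frames feed the candidate detector;
#' candidates feed the chosen trajectory estimator(s); contacts follow from
#' the selected trajectories' parabola intersections plus the serve rule.
#'
#' @param frames list of H x W x 3 arrays.
#' @param h the court \linkS4class{Homography}.
#' @param method \code{"growth"}, \code{"hough"} or \code{"both"}.
#' @param candConfig a \code{\link{candidateConfig}}.
#' @param growthCfg a \code{\link{growthConfig}}.
#' @param houghCfg a \code{\link{houghConfig}}.
#' @param bgConfig a \code{\link{backgroundConfig}} (movement threshold and
#'   opening).
#' @return list per method: list(candidates, trajectories, points,
#'   contacts).
#' @export
trackBall <- function(frames, h, method = c("growth", "hough", "both"),
                      candConfig = candidateConfig(),
                      growthCfg = growthConfig(), houghCfg = houghConfig(),
                      bgConfig = backgroundConfig()) {
  method <- match.arg(method)
  d <- dim(frames[[1]])
  cands <- vector("list", length(frames))
  for (t in seq_along(frames)[-1] - 1L) {
    mov <- movementMask(frames[[t]], frames[[t + 1L]], bgConfig)
    cands[[t + 1L]] <- detectCandidates(mov, h, candConfig, frame = t)
  }
  candidates <- do.call(rbind, Filter(Negate(is.null), cands))
  if (is.null(candidates) || nrow(candidates) == 0) {
    warning("no ball candidates detected")
    candidates <- data.frame(frame = integer(0), x = numeric(0),
                             y = numeric(0), area = integer(0),
                             margin = integer(0))
  }
  frameRange <- c(0L, length(frames) - 1L)
  runOne <- function(m) {
    trajs <- if (m == "growth") {
      grown <- growTrajectories(candidates, d[1], growthCfg, frameRange)
      extrapolateTrajectories(selectParallel(grown), frameRange)
    } else {
      houghTrajectories(candidates, d[1], houghCfg)
    }
    list(candidates = candidates, trajectories = trajs,
         points = trajectoryPoints(trajs, d[1],
                                   seq(frameRange[1], frameRange[2])),
         contacts = contactEvents(trajs))
  }
  if (method == "both") list(growth = runOne("growth"), hough = runOne("hough"))
  else stats::setNames(list(runOne(method)), method)
}

# ---- I/O --------------------------------------------------------------

#' Read a directory of PNG frames
#'
#' Frames are the lexicographically sorted *.png files (zero-padded names).
#'
#' @param dir directory path.
#' @return list of H x W x 3 arrays in [0, 1].
#' @export
readFrameDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames in ", dir)
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
    a[, , 1:3, drop = FALSE]
  })
}

#' Write frames as zero-padded PNGs
#'
#' @param frames list of H x W x 3 arrays.
#' @param dir output directory (created).
#' @return invisibly, the file paths.
#' @export
writeFrameDir <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(frames) - 1L, function(t) {
    p <- file.path(dir, sprintf("frame_%06d.png", t))
    png::writePNG(frames[[t + 1L]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Serialize trajectories to JSON
#'
#' @param trajs list of \linkS4class{BallTrajectory}.
#' @param path output file; NULL returns the JSON string.
#' @param method tag recorded with the trajectories.
#' @param seed seed recorded with the output.
#' @return the JSON string, invisibly when written to a file.
#' @export
writeTrajectoriesJSON <- function(trajs, path = NULL, method = "growth",
                                  seed = NA_integer_) {
  obj <- list(method = method, seed = seed,
              trajectories = lapply(trajs, function(tr) list(
                a2 = tr@a2, a1 = tr@a1, a0 = tr@a0, m = tr@m, b = tr@b,
                frame_start = tr@frameStart, frame_end = tr@frameEnd,
                ext_start = tr@extStart, ext_end = tr@extEnd,
                status = tr@status, member_frames = tr@members$frame)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Persist reference appearances as JSON
#'
#' Stores each player's normalized per-subwindow histograms so a
#' calibration can be reused across game points of the same game.
#'
#' @param refs list of \linkS4class{ReferenceAppearance}.
#' @param path output JSON file.
#' @return invisibly, the path.
#' @export
writeReferencesJSON <- function(refs, path) {
  obj <- lapply(refs, function(r) list(player_id = r@playerId,
                                       n_pixels = r@nPixels,
                                       histograms = r@histograms))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeReferencesJSON
#' @export
readReferencesJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  lapply(obj, function(r)
    new("ReferenceAppearance", playerId = as.integer(r$player_id),
        histograms = lapply(r$histograms, as.numeric),
        nPixels = as.integer(unlist(r$n_pixels))))
}

#' @rdname writeTrajectoriesJSON
#' @param contacts the data.frame from \code{\link{contactEvents}}.
#' @export
writeContactsCSV <- function(contacts, path) {
  utils::write.csv(contacts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoriesJSON
#' @param tracks the data.frame from \code{\link{trackPlayers}}.
#' @export
writeTrackCSV <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

# ---- command-level wrappers (used by the CLI script) ------------------

#' Run player tracking from paths
#'
#' @param inputDir directory of PNG frames.
#' @param calibrationPath JSON/YAML calibration config.
#' @param outPath output CSV.
#' @param tracker,seed,... forwarded to \code{\link{trackPlayers}}.
#' @return the track data.frame, invisibly.
#' @export
runTrackPlayers <- function(inputDir, calibrationPath, outPath,
                            tracker = "grid", seed = 1L, ...) {
  cal <- readCalibration(calibrationPath)
  frames <- readFrameDir(inputDir)
  tracks <- trackPlayers(frames, cal, tracker = tracker, seed = seed, ...)
  writeTrackCSV(tracks, outPath)
  message(sprintf("tracked %d players over %d frames (%s) -> %s",
                  length(unique(tracks$player_id)),
                  length(unique(tracks$frame)), tracker, outPath))
  invisible(tracks)
}

#' Run ball tracking from paths
#'
#' @param inputDir directory of PNG frames.
#' @param calibrationPath JSON/YAML calibration config.
#' @param outDir output directory for trajectory JSON and contacts CSV.
#' @param method,seed,... forwarded to \code{\link{trackBall}}.
#' @return the \code{\link{trackBall}} result, invisibly.
#' @export
runTrackBall <- function(inputDir, calibrationPath, outDir,
                         method = "growth", seed = 1L, ...) {
  cal <- readCalibration(calibrationPath)
  h <- estimateHomography(cal)
  frames <- readFrameDir(inputDir)
  res <- trackBall(frames, h, method = method, ...)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(res)) {
    writeTrajectoriesJSON(res[[m]]$trajectories,
                          file.path(outDir, paste0("trajectories_", m, ".json")),
                          method = m, seed = seed)
    writeContactsCSV(res[[m]]$contacts,
                     file.path(outDir, paste0("contacts_", m, ".csv")))
  }
  invisible(res)
}

#' Run the evaluation protocol from paths
#'
#' @param trackPath player track CSV (NULL to skip).
#' @param playerRefPath reference player CSV (frame, player_id, x_m, y_m,
#'   x_px, y_px).
#' @param ballPointsPath per-frame ball position CSV (frame, x, y; NULL to
#'   skip).
#' @param ballRefPath reference ball CSV (frame, x_px, y_px).
#' @param contactsPath contacts CSV from \code{\link{contactEvents}} (NULL
#'   to skip).
#' @param contactRefPath reference contact frames CSV (column frame).
#' @param cfg an \code{\link{evalConfig}}.
#' @param outPath optional JSON report path.
#' @return report list, invisibly when written.
#' @export
runEval <- function(trackPath = NULL, playerRefPath = NULL,
                    ballPointsPath = NULL, ballRefPath = NULL,
                    contactsPath = NULL, contactRefPath = NULL,
                    cfg = evalConfig(), outPath = NULL) {
  report <- list()
  if (!is.null(trackPath)) {
    tracks <- utils::read.csv(trackPath)
    ref <- utils::read.csv(playerRefPath)
    report$players <- playerAccuracy(tracks, ref, cfg)
  }
  if (!is.null(ballPointsPath)) {
    pts <- utils::read.csv(ballPointsPath)
    ref <- utils::read.csv(ballRefPath)
    report$ball <- ballAccuracy(pts, ref, cfg)
  }
  if (!is.null(contactsPath)) {
    ev <- utils::read.csv(contactsPath)
    ref <- utils::read.csv(contactRefPath)
    report$contacts <- contactAccuracy(ev$frame, ref$frame, cfg)
  }
  if (!is.null(outPath)) {
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA),
               outPath)
    return(invisible(report))
  }
  report
}
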