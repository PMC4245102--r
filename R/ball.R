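# Ball candidate detection on the movement mask: size-filtered connected
# components (8-connectivity) passing the concentric-square isolation test.

#' Ball candidate configuration
#'
#' @param ballDiameterM physical ball diameter in meters (0.21).
#' @param areaRatioLo,areaRatioHi accepted blob area as multiples of the
#'   expected ball area at the blob's court depth (0.25, 4).
#' @param innerSide,outerSide concentric square sides in pixels (40, 60);
#'   fixed in pixels, only the area gate is perspective-scaled.
#' @param q minimum nonzero count inside the inner square (30).
#' @param r outer-square slack in pixels (5, kept low so candidates are
#'   isolated blobs).
#' @param isolationMode \code{"inner_plus_R"} (default) bounds the outer
#'   count by the inner count + R; \code{"Q_plus_R"} is the literal Q + R
#'   bound, which also rejects large isolated blobs.
#' @param diffFactor multiple of the ball cross-section taken as the
#'   expected blob area (2: the frame-difference image of a moving ball
#'   holds up to two ball disks, the appearing and the vanishing position).
#' @return A configuration list (class \code{CandidateConfig}).
#' @export
candidateConfig <- function(ballDiameterM = 0.21, areaRatioLo = 0.25,
                            areaRatioHi = 4, innerSide = 40L,
                            outerSide = 60L, q = 30L, r = 5L,
                            isolationMode = c("inner_plus_R", "Q_plus_R"),
                            diffFactor = 2) {
  isolationMode <- match.arg(isolationMode)
  stopifnot(innerSide < outerSide, q > 0, r >= 0,
            areaRatioLo > 0, areaRatioLo < areaRatioHi, diffFactor > 0)
  structure(list(ballDiameterM = ballDiameterM, areaRatioLo = areaRatioLo,
                 areaRatioHi = areaRatioHi, innerSide = as.integer(innerSide),
                 outerSide = as.integer(outerSide), q = as.integer(q),
                 r = as.integer(r), isolationMode = isolationMode,
                 diffFactor = diffFactor),
            class = c("CandidateConfig", "list"))
}

# nonzero count in a square of given side centered at (cx, cy), clipped
.squareCount <- function(mask, cx, cy, side) {
  half <- side %/% 2L
  r <- clipRect(c(round(cx) - half, round(cy) - half,
                  round(cx) + half, round(cy) + half),
                c(ncol(mask), nrow(mask)))
  if (is.null(r)) return(0L)
  rectSum(mask != 0, r)
}

#' Detect ball candidates in a movement mask
#'
#' Connected components (8-connectivity) of the binary movement mask are
#' filtered by area against the expected ball size -- the 21 cm ball
#' diameter scaled by the homography's local resolution at the blob's
#' back-projected ground point -- and must be isolated: the inner
#' 40 x 40 px square centered on the centroid holds more than Q nonzero
#' pixels while the outer 60 x 60 px square holds at most R more.
#'
#' @param movMask 0/1 movement mask.
#' @param h the court \linkS4class{Homography}.
#' @param cfg a \code{\link{candidateConfig}}.
#' @param frame 0-based frame index stored with the candidates.
#' @return data.frame(frame, x, y, area, margin) sorted by x; x, y are the
#'   blob centroid in 0-based pixels, margin the outer - inner count.
#' @export
detectCandidates <- function(movMask, h, cfg = candidateConfig(),
                             frame = NA_integer_) {
  .assertMask(movMask)
  lab <- label8(movMask)
  k <- max(lab)
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0), margin = integer(0))
  if (k == 0L) return(empty)
  sel <- which(lab > 0L)
  ids <- lab[sel]
  rows <- ((sel - 1L) %% nrow(lab))        # 0-based y
  cols <- ((sel - 1L) %/% nrow(lab))       # 0-based x
  area <- tabulate(ids, nbins = k)
  cx <- as.numeric(rowsum(cols, ids)) / area
  cy <- as.numeric(rowsum(rows, ids)) / area

  keep <- logical(k); margin <- integer(k)
  for (i in seq_len(k)) {
    ground <- tryCatch(imageToWorld(h, c(cx[i], cy[i])),
                       error = function(e) NULL)
    if (is.null(ground)) next
    dPx <- tryCatch(cfg$ballDiameterM * localScale(h, ground),
                    error = function(e) NA_real_)
    if (!is.finite(dPx)) next
    expArea <- cfg$diffFactor * pi * (dPx / 2)^2
    if (area[i] < cfg$areaRatioLo * expArea ||
        area[i] > cfg$areaRatioHi * expArea) next
    inner <- .squareCount(movMask, cx[i], cy[i], cfg$innerSide)
    if (inner <= cfg$q) next
    outer <- .squareCount(movMask, cx[i], cy[i], cfg$outerSide)
    bound <- if (cfg$isolationMode == "inner_plus_R") inner + cfg$r
             else cfg$q + cfg$r
    if (outer > bound) next
    keep[i] <- TRUE
    margin[i] <- outer - inner
  }
  if (!any(keep)) return(empty)
  out <- data.frame(frame = frame, x = cx[keep], y = cy[keep],
                    area = as.integer(area[keep]),
                    margin = margin[keep])
  out[order(out$x), , drop = FALSE]
}
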