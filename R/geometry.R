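# Court calibration and image <-> world coordinate conversion.
#
# The camera observes the court ground plane, so pixel positions and
# court-plane positions are related by a 3x3 planar projective map
# (homography). Four corner correspondences determine it exactly.

.anyCollinear <- function(pts, tol = 1e-9) {
  idx <- utils::combn(nrow(pts), 3)
  for (k in seq_len(ncol(idx))) {
    p <- pts[idx[, k], , drop = FALSE]
    area2 <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                 (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
    scale <- max(abs(p)) + 1
    if (area2 <= tol * scale^2) return(TRUE)
  }
  FALSE
}

#' Construct a court calibration
#'
#' @param imageCorners 4 x 2 matrix of court-corner pixel positions
#'   (0-based, origin top-left, y down), in the same order as
#'   \code{worldCorners}.
#' @param worldCorners 4 x 2 matrix of court-plane corner positions in
#'   meters; defaults to the corners of a \code{courtWidthM} x
#'   \code{courtLengthM} rectangle with origin (0,0):
#'   (0,0), (W,0), (W,L), (0,L).
#' @param playerClicks optional 4 x 2 matrix of initial player pixel
#'   positions (clicked between the feet on the calibration frame).
#' @param calibrationFrame 0-based index of the calibration frame.
#' @param courtWidthM,courtLengthM court dimensions in meters (8 x 16 for
#'   beach volleyball).
#' @return A \linkS4class{CourtCalibration}.
#' @export
courtCalibration <- function(imageCorners, worldCorners = NULL,
                             playerClicks = NULL, calibrationFrame = 0L,
                             courtWidthM = 8, courtLengthM = 16) {
  imageCorners <- matrix(as.numeric(imageCorners), ncol = 2)
  if (is.null(worldCorners))
    worldCorners <- matrix(c(0, 0, courtWidthM, 0, courtWidthM, courtLengthM,
                             0, courtLengthM), ncol = 2, byrow = TRUE)
  worldCorners <- matrix(as.numeric(worldCorners), ncol = 2)
  if (is.null(playerClicks)) playerClicks <- matrix(numeric(0), ncol = 2)
  else playerClicks <- matrix(as.numeric(playerClicks), ncol = 2)
  new("CourtCalibration", imageCorners = imageCorners,
      worldCorners = worldCorners, playerClicks = playerClicks,
      calibrationFrame = as.integer(calibrationFrame),
      courtWidthM = courtWidthM, courtLengthM = courtLengthM)
}

#' Read a calibration config file
#'
#' Reads a JSON or YAML calibration file with fields \code{image_corners}
#' (4 [x,y] pixel pairs), optional \code{world_corners} (4 [x,y] meter
#' pairs), optional \code{player_clicks} and \code{calibration_frame}.
#'
#' @param path file path; format chosen by extension (.json vs .yml/.yaml).
#' @return A \linkS4class{CourtCalibration}.
#' @export
readCalibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  toMat <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) return(x)
    matrix(unlist(x), ncol = 2, byrow = TRUE)
  }
  courtCalibration(
    imageCorners = toMat(cfg$image_corners),
    worldCorners = toMat(cfg$world_corners),
    playerClicks = toMat(cfg$player_clicks),
    calibrationFrame = if (is.null(cfg$calibration_frame)) 0L
                       else cfg$calibration_frame)
}

#' Estimate the court homography
#'
#' Solves for the 3 x 3 projective map taking image-pixel corners to their
#' world (court-plane) positions from the four calibration correspondences,
#' via a normalized direct linear transform. With four non-degenerate
#' correspondences the solution is exact: each image corner maps to its
#' world corner to machine precision.
#'
#' @param calibration a \linkS4class{CourtCalibration}.
#' @return A \linkS4class{Homography} (direction image -> world).
#' @examples
#' cal <- courtCalibration(rbind(c(100, 400), c(540, 400),
#'                               c(480, 120), c(160, 120)))
#' H <- estimateHomography(cal)
#' imageToWorld(H, c(100, 400))   # first corner -> (0, 0)
#' @export
estimateHomography <- function(calibration) {
  stopifnot(is(calibration, "CourtCalibration"))
  validObject(calibration)
  src <- calibration@imageCorners
  dst <- calibration@worldCorners
  if (.anyCollinear(dst))
    stop("world corners are degenerate (three collinear)")

  normalize <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    t <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = t, p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])))
  }
  ns <- normalize(src); nd <- normalize(dst)
  a <- matrix(0, 8, 9)
  for (i in 1:4) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    a[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    a[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(a, nu = 0, nv = 9)$v[, 9]
  hm <- matrix(h, 3, 3, byrow = TRUE)
  hm <- solve(nd$T) %*% hm %*% ns$T
  if (abs(hm[3, 3]) < 1e-12) stop("degenerate homography (h33 ~ 0)")
  hm <- hm / hm[3, 3]
  H <- new("Homography", matrix = hm)
  # exact-solve sanity: corners must reproduce to numerical precision
  w <- imageToWorld(H, src)
  if (max(abs(w - dst)) > 1e-6)
    stop("homography failed to reproduce calibration corners")
  H
}

#' Construct a homography from an explicit matrix
#'
#' @param m 3 x 3 matrix, direction image -> world; rescaled so m[3,3] = 1.
#' @return A \linkS4class{Homography}.
#' @export
homography <- function(m) {
  m <- as.matrix(m)
  if (abs(m[3, 3]) < 1e-12) stop("m[3,3] must be nonzero")
  new("Homography", matrix = m / m[3, 3])
}

.applyH <- function(m, p) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  q <- cbind(p, 1) %*% t(m)
  w <- q[, 3]
  if (any(abs(w) < 1e-12))
    stop("point maps to the plane at infinity (w ~ 0)")
  out <- q[, 1:2, drop = FALSE] / w
  if (nrow(out) == 1L) as.numeric(out) else out
}

#' Map image pixels to world meters
#'
#' @param h a \linkS4class{Homography}.
#' @param p a length-2 pixel point (x, y) or an n x 2 matrix of points.
#' @return World point(s) in meters, same shape as the input.
#' @export
imageToWorld <- function(h, p) {
  stopifnot(is(h, "Homography"))
  .applyH(h@matrix, p)
}

#' Map world meters to image pixels
#'
#' @inheritParams imageToWorld
#' @param p a length-2 world point (x_m, y_m) or an n x 2 matrix.
#' @return Pixel point(s), same shape as the input.
#' @export
worldToImage <- function(h, p) {
  stopifnot(is(h, "Homography"))
  .applyH(solve(h@matrix), p)
}

#' Local image scale at a world point
#'
#' The image-space length, in pixels, of a 1 m segment centered at the
#' world point \code{p} along the court's x-axis (finite difference over
#' +/- 0.5 m). Under a perspective view this is larger near the camera
#' than at the far end of the court, and it is what sizes player bounding
#' boxes and the expected ball area.
#'
#' @inheritParams worldToImage
#' @return A strictly positive scalar (pixels per meter at \code{p}).
#' @export
localScale <- function(h, p) {
  q <- worldToImage(h, rbind(c(p[1] - 0.5, p[2]), c(p[1] + 0.5, p[2])))
  s <- sqrt(sum((q[2, ] - q[1, ])^2))
  if (!is.finite(s) || s <= 0) stop("non-positive local scale at point")
  s
}

#' Project a player bounding box into the image
#'
#' Builds the square image bounding box of a player standing at the world
#' foot point: side length \code{heightM * localScale(h, footPoint)} pixels,
#' anchored with its bottom-center at \code{worldToImage(h, footPoint)}
#' (calibration clicks are between the feet). The square is subdivided into
#' \code{nSubwindows} equal-height horizontal bands, ordered top to bottom;
#' integer band heights differ by at most one pixel and tile the box
#' exactly.
#'
#' @inheritParams worldToImage
#' @param footPoint world point (x_m, y_m) at the player's feet.
#' @param heightM physical box height in meters (default 2, an upright
#'   adult).
#' @param nSubwindows number of horizontal bands (default 4).
#' @param frameDim optional c(width, height) in pixels; when given, the box
#'   and bands are clipped to the frame and \code{clipped} is flagged.
#' @return A list with elements \code{box} (c(x0, y0, x1, y1), 0-based
#'   inclusive), \code{bands} (list of band rects, top to bottom; clipped
#'   bands may be NULL), \code{widthPx} (unclipped box width), \code{clipped}
#'   and \code{empty} flags.
#' @export
projectBox <- function(h, footPoint, heightM = 2, nSubwindows = 4L,
                       frameDim = NULL) {
  stopifnot(heightM > 0, nSubwindows >= 1)
  foot <- worldToImage(h, footPoint)
  side <- max(1L, as.integer(round(heightM * localScale(h, footPoint))))
  x0 <- as.integer(round(foot[1] - side / 2))
  x1 <- x0 + side - 1L
  y1 <- as.integer(round(foot[2]))
  y0 <- y1 - side + 1L
  box <- c(x0, y0, x1, y1)
  # partition rows into nSubwindows nearly equal bands, top to bottom
  cuts <- y0 + round(side * seq(0, 1, length.out = nSubwindows + 1))
  bands <- lapply(seq_len(nSubwindows), function(k) {
    c(x0, cuts[k], x1, cuts[k + 1] - 1)
  })
  clipped <- FALSE
  if (!is.null(frameDim)) {
    cb <- clipRect(box, frameDim)
    clipped <- is.null(cb) || any(cb != box)
    bands <- lapply(bands, clipRect, frameDim = frameDim)
    box <- cb
  }
  empty <- is.null(box)
  list(box = box, bands = bands, widthPx = side, clipped = clipped,
       empty = empty)
}
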