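test_that("scatter images place one pixel per candidate", {
  cand <- data.frame(frame = c(3, 10), x = c(50.2, 100.7), y = c(200, 150))
  si <- scatterImages(cand, clipLength = 20, frameHeight = 480,
                      frameWidth = 640)
  expect_equal(sum(si$xt), 2)
  expect_equal(sum(si$yt), 2)
  expect_equal(si$xt[50 + 1, 3 + 1], 1L)
  expect_equal(si$xt[101 + 1, 10 + 1], 1L)
  expect_equal(si$yt[(479 - 200) + 1, 3 + 1], 1L)
  # a parabola renders as a parabolic arc in y-t
  t <- 0:30
  yh <- -0.5 * t^2 + 15 * t + 30
  cand2 <- data.frame(frame = t, x = 2 * t + 10, y = 479 - yh)
  si2 <- scatterImages(cand2, 31, 480, 640)
  on <- which(si2$yt == 1L, arr.ind = TRUE)
  expect_equal(nrow(on), 31)
  got <- on[order(on[, 2]), 1] - 1
  expect_true(all(abs(got - yh) <= 0.5))
})

test_that("horizontal clutter is removed, true arcs survive", {
  t <- 0:29
  flicker <- data.frame(frame = t, x = 320, y = 240)       # static blob
  yh <- -0.3 * t^2 + 9 * t + 100
  arc <- data.frame(frame = t, x = 3 * t + 40, y = 479 - yh)
  both <- rbind(flicker, arc)
  out <- removeHorizontal(both, 480)
  expect_true(all(out$x != 320))                # flicker gone
  expect_gte(nrow(out[out$x %in% arc$x, ]), 20) # most of the arc survives
  # empty input passes through
  expect_equal(nrow(removeHorizontal(both[0, ], 480)), 0)
  # the skip switch disables removal
  cfgOff <- houghConfig(skipHorizontalRemoval = TRUE)
  expect_equal(nrow(removeHorizontal(both, 480, cfgOff)), nrow(both))
})

test_that("no over-deletion: survivors were near no horizontal line", {
  set.seed(13)
  cand <- data.frame(frame = sample(0:60, 40, TRUE),
                     x = runif(40, 0, 600), y = runif(40, 0, 450))
  cfg <- houghConfig()
  out <- removeHorizontal(cand, 480, cfg)
  expect_gte(nrow(out), 0)
  expect_lte(nrow(out), nrow(cand))
})

test_that("line sets honor length and gap gates and partition candidates", {
  # 10 collinear candidates spanning ~43 px, small gaps
  t <- 0:9
  cand <- data.frame(frame = t, x = 4 * t + 100, y = 300 - 2 * t)
  sets <- detectLineSets(cand, 480)
  expect_length(sets, 1)
  expect_equal(nrow(sets[[1]]), 10)

  # a 15 px hole splits the segment; the 12 px piece is then too short
  t2 <- c(0:4, 9:13)
  cand2 <- data.frame(frame = t2, x = 4 * t2 + 100, y = 300 - 2 * t2)
  sets2 <- detectLineSets(cand2, 480)
  lens <- vapply(sets2, nrow, integer(1))
  expect_true(all(lens >= 3))
  # no candidate lands in two sets
  all_members <- do.call(rbind, sets2)
  if (!is.null(all_members))
    expect_equal(anyDuplicated(all_members[, c("frame", "x")]), 0)

  # a short segment (< 20 px span) is dropped
  t3 <- 0:3
  cand3 <- data.frame(frame = t3, x = 2 * t3 + 50, y = 200 - t3)
  expect_length(detectLineSets(cand3, 480), 0)
})

test_that("neighboring sets join only at consistent intersections", {
  mkset <- function(t, m, b, a2, a1, a0)
    data.frame(frame = t, x = m * t + b, y = 479 - (a2 * t^2 + a1 * t + a0))
  # intersection of the x lines at t = 25, equal heights there
  s1 <- mkset(10:22, 2, 0, -0.1, 4, 50)
  yh25 <- -0.1 * 625 + 4 * 25 + 50
  # second parabola tuned to meet the first at t = 25
  a1b <- 9
  a0b <- yh25 + 0.1 * 625 - a1b * 25
  s2 <- mkset(28:40, -2, 100, -0.1, a1b, a0b)
  tr <- fitAndJoin(list(s1, s2), 480)
  expect_length(tr, 2)
  expect_equal(tr[[1]]@extEnd, 25)
  expect_equal(tr[[2]]@extStart, 25)

  # height mismatch of 20 px at the intersection frame: no join
  s2off <- mkset(28:40, -2, 100, -0.1, a1b, a0b + 20)
  troff <- fitAndJoin(list(s1, s2off), 480)
  expect_equal(troff[[1]]@extEnd, troff[[1]]@frameEnd * 1.0)

  # intersection outside the inter-set gap: no join
  s3 <- mkset(28:40, 2.5, -20, -0.1, a1b, a0b)   # near-parallel x lines
  tr3 <- fitAndJoin(list(s1, s3), 480)
  expect_equal(tr3[[1]]@extEnd, tr3[[1]]@frameEnd * 1.0)
})

test_that("growth and Hough agree on a clean rally", {
  # on exact (noiseless) candidates both methods reduce to least squares;
  # arcs whose member sets coincide agree to machine precision, and arcs
  # where the Hough grouping clips a contact-frame point still agree to a
  # fraction of a pixel at mid-arc
  sched <- defaultRally()
  H <- estimateHomography(courtCalibration(courtCornersPreset(640, 480)))
  rally <- renderRally(sched, H, 25, 480)
  cand <- data.frame(frame = rally$points$frame, x = rally$points$x,
                     y = rally$points$y)
  sel <- selectParallel(growTrajectories(cand, 480))
  hough <- houghTrajectories(cand, 480)
  expect_gte(length(hough), 6)
  exactMatches <- 0
  for (tr in sel) {
    mid <- round((tr@frameStart + tr@frameEnd) / 2)
    hit <- Filter(function(k) k@frameStart <= mid && k@frameEnd >= mid,
                  hough)
    expect_gte(length(hit), 1)
    dx <- abs(predictTrajectory(hit[[1]], mid)[1, "x"] -
              predictTrajectory(tr, mid)[1, "x"])
    expect_lt(dx, 0.5)
    if (abs(hit[[1]]@m - tr@m) < 1e-6 && abs(hit[[1]]@a2 - tr@a2) < 1e-6)
      exactMatches <- exactMatches + 1
  }
  expect_gte(exactMatches, 1)
})
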