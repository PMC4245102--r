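# candidates on an exact ballistic arc (yh upward, y = frameHeight-1-yh)
arcCandidates <- function(t, a2, a1, a0, m, b, frameHeight = 480) {
  yh <- a2 * t^2 + a1 * t + a0
  data.frame(frame = t, x = m * t + b, y = frameHeight - 1 - yh)
}

test_that("noiseless fits recover the generating coefficients", {
  t <- 0:5
  members <- data.frame(frame = t, x = 2 * t + 7, yh = -0.5 * t^2 + 10 * t + 3)
  f <- fitTrajectory(members)
  expect_lt(abs(f$a2 - (-0.5)) / 0.5, 1e-9)
  expect_lt(abs(f$a1 - 10) / 10, 1e-9)
  expect_lt(abs(f$a0 - 3) / 3, 1e-9)
  expect_lt(abs(f$m - 2) / 2, 1e-9)
  expect_lt(abs(f$b - 7) / 7, 1e-9)
  expect_lt(f$rms, 1e-9)
  # conditioning holds for large frame indices too
  t2 <- 500:540
  m2 <- data.frame(frame = t2, x = 1.5 * t2 - 100,
                   yh = -0.3 * t2^2 + 320 * t2 - 85000)
  f2 <- fitTrajectory(m2)
  expect_lt(abs(f2$a2 - (-0.3)) / 0.3, 1e-8)
})

test_that("two members fit the line only; the parabola is deferred", {
  f <- fitTrajectory(data.frame(frame = c(0, 1), x = c(5, 8), yh = c(2, 4)))
  expect_true(is.na(f$a2))
  expect_equal(f$m, 3)
  expect_equal(f$b, 5)
  expect_error(fitTrajectory(data.frame(frame = c(3, 3), x = 1:2,
                                        yh = 1:2)), "frames")
})

test_that("noisy fits stay within analytic least-squares standard errors", {
  t <- 0:19
  sigma <- 1
  Xp <- cbind(1, t, t^2)
  covP <- sigma^2 * solve(crossprod(Xp))
  seP <- sqrt(diag(covP))          # a0, a1, a2 order
  Xl <- cbind(1, t)
  seL <- sqrt(diag(sigma^2 * solve(crossprod(Xl))))
  set.seed(17)
  hits <- 0; total <- 0
  for (r in 1:200) {
    members <- data.frame(frame = t,
                          x = 2 * t + 7 + rnorm(20, 0, sigma),
                          yh = -0.5 * t^2 + 10 * t + 3 + rnorm(20, 0, sigma))
    f <- fitTrajectory(members)
    dev <- abs(c(f$a0 - 3, f$a1 - 10, f$a2 + 0.5, f$b - 7, f$m - 2))
    se <- c(seP, seL)
    hits <- hits + sum(dev <= 3 * se)
    total <- total + 5
  }
  expect_gte(hits / total, 0.98)
})

test_that("three close collinear candidates seed one trajectory", {
  cand <- arcCandidates(0:2, -0.1, 5, 100, 3, 50)    # ~6 px steps
  trajs <- growTrajectories(cand, 480)
  expect_length(trajs, 1)
  expect_equal(nrow(trajs[[1]]@members), 3)

  # a 25 px jump breaks the chain gate
  cand2 <- cand; cand2$x[3] <- cand2$x[2] + 25; cand2$y[3] <- cand2$y[2]
  expect_length(growTrajectories(cand2, 480), 0)

  # four consistent candidates extend one trajectory, no duplicates
  cand4 <- arcCandidates(0:3, -0.1, 5, 100, 3, 50)
  trajs4 <- growTrajectories(cand4, 480)
  expect_length(trajs4, 1)
  expect_equal(nrow(trajs4[[1]]@members), 4)
})

test_that("extension absorbs matches and terminates after four misses", {
  cand <- arcCandidates(0:10, -0.2, 6, 80, 2, 30)
  tr <- growTrajectories(cand[cand$frame <= 4, ], 480,
                         frameRange = c(0, 4))[[1]]
  tr@status <- "growing"
  at5 <- data.frame(frame = 5, x = 2 * 5 + 30,
                    yh = -0.2 * 25 + 6 * 5 + 80)
  tr2 <- extendTrajectory(tr, at5, 5)
  expect_equal(tr2@frameEnd, 5L)
  expect_equal(tr2@missingRun, 0L)
  # four consecutive missing frames terminate
  none <- data.frame(frame = numeric(0), x = numeric(0), yh = numeric(0))
  for (t in 6:8) {
    tr2 <- extendTrajectory(tr2, none, t)
    expect_equal(tr2@status, "growing")
  }
  tr2 <- extendTrajectory(tr2, none, 9)
  expect_equal(tr2@status, "terminated")
  expect_equal(tr2@frameEnd, 5L)
})

test_that("equidistant candidates break ties toward lower x", {
  tr <- growTrajectories(arcCandidates(0:3, 0, 0, 100, 0, 50), 480,
                         cfg = growthConfig(seedCollinearityTolPx = 2))[[1]]
  tr@status <- "growing"
  two <- data.frame(frame = 4, x = c(53, 47), yh = c(100, 100))
  tr2 <- extendTrajectory(tr, two, 4)
  expect_equal(tr2@members$x[nrow(tr2@members)], 47)
})

test_that("parallel selection keeps the strongest, never true overlaps", {
  mk <- function(t0, t1, n, noise = 0) {
    cand <- arcCandidates(seq(t0, t1, length.out = n), -0.1, 5, 100, 2, 10)
    members <- data.frame(frame = cand$frame, x = cand$x + noise,
                          yh = 479 - cand$y)
    courtTrack:::.newTrajectory(members)
  }
  a <- mk(0, 20, 8)
  b <- mk(5, 15, 4)
  kept <- selectParallel(list(a, b))
  expect_length(kept, 1)
  expect_equal(nrow(kept[[1]]@members), 8)
  # equal counts: lower residual wins
  c1 <- mk(0, 20, 6)
  c2 <- mk(2, 18, 6, noise = 0)
  c2@members$x <- c2@members$x + rnorm(6, 0, 2)
  k2 <- selectParallel(list(c2, c1))
  expect_equal(k2[[1]]@members$frame, c1@members$frame)
  # disjoint trajectories are both kept
  d <- mk(30, 50, 6)
  expect_length(selectParallel(list(a, d)), 2)
  # randomized inputs never leave overlaps beyond the slack
  set.seed(31)
  pool <- lapply(1:12, function(i) {
    t0 <- sample(0:80, 1); mk(t0, t0 + sample(5:20, 1), sample(4:9, 1))
  })
  sel <- selectParallel(pool)
  if (length(sel) > 1) for (i in seq_len(length(sel) - 1)) {
    ov <- min(sel[[i]]@frameEnd, sel[[i + 1]]@frameEnd) -
      max(sel[[i]]@frameStart, sel[[i + 1]]@frameStart)
    expect_lt(ov, 2)
  }
})

test_that("extrapolation meets at model intersections, members untouched", {
  mkm <- function(t, m, b, a2, a1, a0)
    courtTrack:::.newTrajectory(data.frame(frame = t, x = m * t + b,
                                           yh = a2 * t^2 + a1 * t + a0))
  # x lines intersect at t = 25 inside the 5-frame gap
  a <- mkm(10:22, 2, 0, -0.1, 4, 50)
  b <- mkm(28:40, -2, 100, -0.1, 9, -75)
  out <- extrapolateTrajectories(list(a, b), c(0, 60))
  expect_equal(out[[1]]@extEnd, 25)
  expect_equal(out[[2]]@extStart, 25)
  expect_equal(out[[1]]@extStart, 0)
  expect_equal(out[[2]]@extEnd, 60)
  expect_identical(out[[1]]@members, a@members)
  # single trajectory extends to the clip bounds
  solo <- extrapolateTrajectories(list(a), c(0, 99))
  expect_equal(c(solo[[1]]@extStart, solo[[1]]@extEnd), c(0, 99))
})

test_that("a six-arc noiseless rally is recovered with high coverage", {
  sched <- defaultRally()
  H <- estimateHomography(courtCalibration(courtCornersPreset(640, 480)))
  rally <- renderRally(sched, H, 25, 480)
  cand <- data.frame(frame = rally$points$frame, x = rally$points$x,
                     y = rally$points$y)
  grown <- growTrajectories(cand, 480)
  sel <- selectParallel(grown)
  expect_gte(length(sel), 6)
  covered <- unlist(lapply(sel, function(tr) tr@members$frame))
  expect_gte(length(intersect(covered, cand$frame)) / nrow(cand), 0.9)
  # contacts within one frame of the schedule
  ev <- contactEvents(sel)
  truth <- utils::head(sched$frame, -1)
  errs <- vapply(truth, function(r) min(abs(ev$frame - r)), numeric(1))
  expect_true(all(errs <= 1))
})
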