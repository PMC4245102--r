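# A compact tracking stage: identity-scaled world (s px/m), one painted
# player, bundles built directly so the particle machinery is exercised
# without the background model.
particleStage <- function(foot = c(4, 4), s = 30) {
  h <- scaleHomography(s)
  fr <- paintPlayer(blankFrame(300, 300), h, foot, testBandColors)
  bundle <- makeBundle(fr)
  ref <- refFromFrame(bundle, worldToImage(h, foot), h)
  list(h = h, bundle = bundle, ref = ref, frame = fr)
}

test_that("initialization is uniform, contained and seed-deterministic", {
  st <- particleStage()
  a <- initParticleSet(1L, c(0, 0, 8, 16), 30L, st$ref, seed = 5L)
  b <- initParticleSet(1L, c(0, 0, 8, 16), 30L, st$ref, seed = 5L)
  expect_identical(a@positions, b@positions)
  expect_true(all(a@positions[, 1] >= 0 & a@positions[, 1] <= 8))
  expect_true(all(a@positions[, 2] >= 0 & a@positions[, 2] <= 16))
  big <- initParticleSet(1L, c(0, 0, 8, 16), 10000L, st$ref, seed = 6L)
  # CLT bound on the mean position: 3 sigma/sqrt(n) per axis
  expect_lt(abs(mean(big@positions[, 1]) - 4), 3 * (8 / sqrt(12)) / 100)
  expect_lt(abs(mean(big@positions[, 2]) - 8), 3 * (16 / sqrt(12)) / 100)
  expect_error(initParticleSet(1L, c(0, 0, 0, 16), 5L, st$ref), "region")
})

test_that("the particle at the player has the maximum weight", {
  st <- particleStage(foot = c(4, 4))
  grid <- as.matrix(expand.grid(x = seq(2, 6, by = 0.5),
                                y = seq(2, 6, by = 0.5)))
  set <- initParticleSet(1L, c(0, 0, 8, 16), nrow(grid), st$ref, seed = 1L)
  set@positions <- grid
  set <- weightParticleSet(set, st$bundle, st$h)
  best <- grid[which.max(set@weights), ]
  expect_lt(sqrt(sum((best - c(4, 4))^2)), 0.71)
  expect_false(set@lost)
  # duplicated particles get identical weights (purity)
  set2 <- set; set2@positions <- grid[c(1, 1, 5, 5), ]
  set2@weights <- rep(1, 4); set2@cueScores <- matrix(0, 4, 3)
  set2@lost <- FALSE
  set2 <- weightParticleSet(set2, st$bundle, st$h)
  expect_equal(set2@weights[1], set2@weights[2])
  expect_equal(set2@weights[3], set2@weights[4])
})

test_that("a blank frame raises the lost flag with uniform weights", {
  st <- particleStage()
  blank <- makeBundle(blankFrame(300, 300))
  set <- initParticleSet(1L, c(0, 0, 8, 16), 20L, st$ref, seed = 2L)
  set <- weightParticleSet(set, blank, st$h)
  expect_true(set@lost)
  expect_equal(set@weights, rep(1 / 20, 20))
})

test_that("the state estimate is the weighted mean", {
  st <- particleStage()
  set <- initParticleSet(1L, c(0, 0, 8, 16), 2L, st$ref, seed = 3L)
  set@positions <- rbind(c(0, 0), c(2, 2))
  set@weights <- c(1, 1)
  expect_equal(estimateState(set), c(1, 1))
  set@weights <- c(1, 0)
  expect_equal(estimateState(set), c(0, 0))
  # high-precision oracle on random sets
  set.seed(8)
  n <- 40
  set2 <- initParticleSet(1L, c(0, 0, 8, 16), n, st$ref, seed = 4L)
  w <- runif(n)
  set2@weights <- w
  oracle <- c(sum(set2@positions[, 1] * w), sum(set2@positions[, 2] * w)) /
    sum(w)
  expect_lt(max(abs(estimateState(set2) - oracle)), 1e-12)
})

test_that("resampling follows the weights within multinomial bounds", {
  st <- particleStage()
  # 10 source locations, far apart so offspring map back unambiguously
  k <- 10
  src <- cbind(rep(seq(5, 95, by = 10), each = 1), rep(50, k)) * 1.0
  p <- (1:k) / sum(1:k)
  n <- 100000L
  set <- initParticleSet(1L, c(0, 0, 100, 100), n, st$ref, seed = 7L,
                         homeRect = c(0, 0, 100, 100))
  set@positions <- src[rep(seq_len(k), length.out = n), ]
  set@weights <- p[rep(seq_len(k), length.out = n)] / (n / k)
  rc <- resampleConfig(courtRect = c(0, 0, 100, 100))
  out <- resampleSet(set, rc)
  srcIdx <- apply(abs(outer(out@positions[, 1], src[, 1], "-")), 1,
                  which.min)
  counts <- tabulate(srcIdx, k)
  bound <- 4 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= bound))
  expect_equal(nrow(out@positions), n)          # count conserved
  # weights reset
  expect_equal(out@weights, rep(1 / n, n))
})

test_that("two-tier jitter has the configured standard deviations", {
  st <- particleStage()
  n <- 10000L
  # two sources: weight 1 (top band) and weight 0.5 (base tier)
  set <- initParticleSet(1L, c(0, 0, 200, 200), n, st$ref, seed = 9L)
  set@positions <- rbind(c(50, 50), c(150, 150))[rep(1:2, length.out = n), ]
  set@weights <- c(1, 0.5)[rep(1:2, length.out = n)]
  rc <- resampleConfig(courtRect = c(0, 0, 200, 200))
  out <- resampleSet(set, rc)
  nearTop <- out@positions[, 1] < 100
  sdTop <- sd(out@positions[nearTop, 1] - 50)
  sdBase <- sd(out@positions[!nearTop, 1] - 150)
  expect_lt(abs(sdTop - 0.04), 0.004)    # within 10%
  expect_lt(abs(sdBase - 0.2), 0.02)
  # weights [1,0,0]: all offspring jittered copies of particle 0
  set3 <- initParticleSet(1L, c(0, 0, 8, 16), 3L, st$ref, seed = 10L)
  set3@positions <- rbind(c(1, 1), c(5, 5), c(7, 7))
  set3@weights <- c(1, 0, 0)
  out3 <- resampleSet(set3, resampleConfig())
  expect_true(all(sqrt(rowSums(sweep(out3@positions, 2, c(1, 1))^2)) < 1))
})

test_that("resampling is deterministic given the set's stream", {
  st <- particleStage()
  mk <- function() {
    s <- initParticleSet(1L, c(0, 0, 8, 16), 25L, st$ref, seed = 11L)
    s@weights <- seq_len(25) / 25
    resampleSet(s, resampleConfig())@positions
  }
  expect_identical(mk(), mk())
})

test_that("the confusion safeguard fires strictly after the frame budget", {
  st <- particleStage()
  mkset <- function(id, pos, color) {
    s <- initParticleSet(id, c(0, 0, 8, 16), 5L, st$ref, seed = id)
    s@estimate <- pos
    s@cueScores <- matrix(c(rep(color, 5), rep(0, 10)), 5, 3)
    s
  }
  rc <- resampleConfig()
  sets <- list(mkset(1L, c(2, 2), 10), mkset(2L, c(2.1, 2), 1),
               mkset(3L, c(6, 14), 5))
  counters <- matrix(0L, 3, 3)
  resets <- integer(0)
  for (f in 1:10) {   # exactly 10 overlap frames: no action
    g <- confusionGuard(sets, counters, rc)
    counters <- g$counters
    resets <- c(resets, g$reset)
  }
  expect_length(resets, 0)
  g <- confusionGuard(sets, counters, rc)   # the 11th fires
  expect_equal(g$reset, 2L)                 # weaker color loses
  expect_true(g$trackers[[2]]@lost)
  expect_equal(g$counters[1, 2], 0L)        # counter reset
  # distant sets never interact
  expect_equal(sum(g$counters[, 3]), 0L)
})

test_that("a stationary unambiguous target is found and held", {
  # The masked color histogram is position-invariant while the player blob
  # stays inside the hypothesis box, so the weighted-mean estimate performs
  # a bounded random walk on that plateau rather than contracting to a
  # point. The lock is therefore assessed over replicates: errors shrink
  # from the initial cloud, stay inside the plateau half-width, and their
  # median ends well inside the evaluation radius.
  st <- particleStage(foot = c(4, 4))
  rc <- resampleConfig()
  early <- c(); late <- c(); finals <- c()
  for (sd in 1:10) {
    set <- initParticleSet(1L, c(2, 2, 6, 6), 30L, st$ref, seed = sd)
    errs <- numeric(20)
    for (f in 1:20) {
      set <- weightParticleSet(set, st$bundle, st$h)
      errs[f] <- sqrt(sum((set@estimate - c(4, 4))^2))
      est <- set@estimate
      set <- resampleSet(set, rc)
      set@estimate <- est
    }
    early <- c(early, errs[1:10]); late <- c(late, errs[11:20])
    finals <- c(finals, errs[20])
  }
  expect_lte(median(late), median(early) + 1e-9)   # errors do not grow
  expect_lt(max(finals), 0.7)                      # plateau half-width
  expect_lt(median(finals), 0.35)                  # well inside 0.5 m
})
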