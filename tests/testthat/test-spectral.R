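# Frequency-tagging statistics: DFT grid, EP, EPn, ITPC formulas and their
# invariants, plus the target-vs-neighbour group test.

test_that("DFT grid spacing is 1/epoch_length and exact bins are clean", {
  srate <- 100
  n <- round(12.64 * srate)
  t <- (seq_len(n) - 1) / srate
  f0 <- 8 / 12.64  # 8 cycles per epoch = chunk bin
  x <- array(cos(2 * pi * f0 * t), c(1, 1, n))
  co <- dft_coefficients(epoch_set(x, srate), fmin = 0.1, fmax = 10)
  expect_equal(diff(co$freqs)[1], 1 / 12.64, tolerance = 1e-12)
  expect_equal(round(diff(co$freqs)[1], 3), 0.079)
  mags <- Mod(co$X[1, 1, ])
  on <- which.max(mags)
  expect_equal(co$freqs[on], f0, tolerance = 1e-9)
  expect_lt(max(mags[-on]), 1e-10)        # off-bin leakage ~ 0
  expect_equal(mags[on], 0.5, tolerance = 1e-9)
  # phase of a sine at its own bin is -pi/2
  xs <- array(sin(2 * pi * f0 * t), c(1, 1, n))
  cs <- dft_coefficients(epoch_set(xs, srate), fmin = 0.1, fmax = 10)
  expect_equal(Arg(cs$X[1, 1, on]), -pi / 2, tolerance = 1e-9)
})

test_that("unequal epoch construction is impossible by container design", {
  # epoch_set enforces a rectangular trials x channels x samples array;
  # ragged epochs cannot be represented, so dft_coefficients sees equal
  # lengths by construction
  expect_error(epoch_set(matrix(0, 2, 10), srate = 100))
})

test_that("evoked power follows |sum X|^2 / N", {
  X1 <- array(complex(real = 1, imaginary = 2), c(1, 1, 1))
  expect_equal(evoked_power(fake_coeffs(X1))$EP[1, 1], 5)  # N=1: |X|^2
  # N identical trials: EP = N |X|^2
  Xn <- array(rep(complex(real = 1, imaginary = 2), 4), c(4, 1, 1))
  expect_equal(evoked_power(fake_coeffs(Xn))$EP[1, 1], 4 * 5)
  # opposite coefficients cancel
  Xc <- array(c(1 + 1i, -1 - 1i), c(2, 1, 1))
  expect_equal(evoked_power(fake_coeffs(Xc))$EP[1, 1], 0)
})

test_that("EP grows linearly in N when phase-locked, stays bounded when not", {
  set.seed(31)
  lockedEP <- function(N) {
    X <- array(exp(2i * pi * 0.1), c(N, 1, 1))
    evoked_power(fake_coeffs(X))$EP[1, 1]
  }
  expect_equal(lockedEP(40) / lockedEP(10), 4, tolerance = 1e-9)
  randomEP <- function(N) {
    mean(replicate(200, {
      X <- array(exp(2i * pi * runif(N)), c(N, 1, 1))
      evoked_power(fake_coeffs(X))$EP[1, 1]
    }))
  }
  # E[EP] = 1 for uniform random phases, independent of N
  expect_lt(abs(randomEP(10) - 1), 0.25)
  expect_lt(abs(randomEP(40) - 1), 0.25)
})

test_that("ITPC formula: alignment, cancellation, hand-computed case", {
  mk <- function(th) fake_coeffs(array(exp(1i * th), c(length(th), 1, 1)))
  expect_equal(itpc(mk(rep(0.7, 5)))$ITPC[1, 1], 1)
  expect_equal(itpc(mk(c(0, pi / 2, pi, 3 * pi / 2)))$ITPC[1, 1], 0,
               tolerance = 1e-12)
  expect_equal(itpc(mk(c(0, pi / 2)))$ITPC[1, 1], sqrt(2) / 2)
  # zero-magnitude coefficients are excluded and counted
  X <- array(c(1 + 0i, 0 + 0i, 1 + 0i), c(3, 1, 1))
  r <- itpc(fake_coeffs(X))
  expect_equal(r$n_excluded, 1L)
  expect_equal(r$ITPC[1, 1], 1)
})

test_that("ITPC is bounded, rotation-invariant, and Rayleigh-calibrated", {
  set.seed(77)
  th <- matrix(runif(50 * 20, 0, 2 * pi), 50, 20)
  X <- array(exp(1i * th), c(50, 1, 20))
  r0 <- itpc(fake_coeffs(X))$ITPC
  expect_true(all(r0 >= 0 & r0 <= 1))
  # common phase rotation leaves ITPC unchanged
  r1 <- itpc(fake_coeffs(X * exp(1.234i)))$ITPC
  expect_equal(r0, r1, tolerance = 1e-12)
  # E[ITPC] for uniform phases at N = 72 is sqrt(pi)/2 / sqrt(72)
  N <- 72
  reps <- 4000
  Xu <- array(exp(2i * pi * runif(N * reps)), c(N, 1, reps))
  got <- mean(itpc(fake_coeffs(Xu))$ITPC)
  expect_lt(abs(got / (sqrt(pi) / 2 / sqrt(N)) - 1), 0.05)
})

test_that("normalize_power: window contents and degenerate limits", {
  freqs <- seq(0.1, 10, by = 1 / 12.64)
  flat <- rep(2, length(freqs))
  # 12 neighbour bins inside +/-0.5 Hz at 0.0791 Hz spacing: EPn = 1/12
  expect_equal(normalize_power(flat, freqs, 0.63), 1 / 12)
  expect_equal(normalize_power(flat, freqs, 0.63, method = "avg"), 1)
  # hand case: target 2 with 4 neighbours of 1 each
  f5 <- c(1, 2, 3, 4, 5)
  expect_equal(normalize_power(c(1, 1, 2, 1, 1), f5, 3, halfwidth = 2.5), 0.5)
  # all power at the target: +Inf flag
  expect_equal(normalize_power(c(0, 0, 5, 0, 0), f5, 3, halfwidth = 2.5), Inf)
  # no neighbours in the window: error
  expect_error(normalize_power(f5, f5, 3, halfwidth = 0.5), "neighbour")
  # matrix input normalizes per channel
  m <- rbind(flat, 2 * flat)
  expect_equal(unname(normalize_power(m, freqs, 0.63)), c(1 / 12, 1 / 12))
})

test_that("target and neighbour bin selection", {
  freqs <- seq(0.1, 10, by = 1 / 12.64)
  it <- target_bin(freqs, 0.63)
  expect_equal(freqs[it], 0.1 + 7 / 12.64, tolerance = 1e-9)
  nb <- neighbor_bins(freqs, 0.63, 2)
  expect_equal(nb, c(it - 2L, it - 1L, it + 1L, it + 2L))
  expect_error(neighbor_bins(numeric(1), 0.5), "neighbour")
})

test_that("target_vs_neighbors: null identity, effect detection, errors", {
  tgt <- c(1, 2, 3, 4)
  nb <- cbind(tgt, tgt, tgt, tgt)
  r <- target_vs_neighbors(tgt, nb)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  set.seed(4)
  tgt2 <- rnorm(20, mean = 1)
  nb2 <- matrix(rnorm(80), 20, 4)
  r2 <- target_vs_neighbors(tgt2, nb2)
  expect_lt(r2$p, 0.05)
  expect_gt(r2$mean_diff, 0)
  expect_error(target_vs_neighbors(1, matrix(1, 1, 4)), "2 subjects")
})

test_that("small synthetic cohort shows the chunk-bin group peak", {
  # scaled-down version of the learning-phase group analysis: 8 subjects,
  # 18 epochs each (one within audio), generator amplitude defaults
  t0 <- timing_spec()
  vals <- lapply(1:8, function(s) {
    p <- synth_params(srate = 100, n_channels = 4L, seed = 100L + s)
    ev <- make_within_stream(c("FU", "LA"), 72, seed = s)
    rec <- render_recording(ev, p)
    co <- dft_coefficients(epoch_stream(rec), 0.1, 10)
    pw <- evoked_power(co)
    epn <- function(ix) normalize_power(pw$EP_avg, co$freqs, co$freqs[ix])
    itg <- target_bin(co$freqs, chunk_rate(t0))
    nb <- neighbor_bins(co$freqs, chunk_rate(t0))
    list(t = epn(itg), nb = vapply(nb, epn, 1.0))
  })
  r <- target_vs_neighbors(vapply(vals, `[[`, 1.0, "t"),
                           t(vapply(vals, `[[`, numeric(4), "nb")))
  expect_lt(r$p, 0.05)
  expect_gt(r$mean_diff, 0)
})
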