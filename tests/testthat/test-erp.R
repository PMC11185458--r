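# ERP stage: zero-phase low-pass, epoching/baseline, and the
# cluster-permutation test (exactness, invariances, power).

test_that("low-pass filter: passband, stopband and zero phase", {
  sr <- 500
  t <- seq(0, 4, 1 / sr)
  mid <- 500:1500
  rms <- function(x) sqrt(mean(x^2))
  x2 <- sin(2 * pi * 2 * t)
  expect_lt(1 - rms(lowpass(x2, sr)[mid]) / rms(x2[mid]), 0.01)
  x100 <- sin(2 * pi * 100 * t)
  expect_gt(1 - rms(lowpass(x100, sr)[mid]) / rms(x100[mid]), 0.95)
  # single-pass response at 100 Hz from the designed filter itself
  ba <- butter_lowpass(4, 25, sr)
  expect_gt(1 - Mod(chunktag:::filter_response(ba$b, ba$a, 100, sr)), 0.95)
  expect_equal(Mod(chunktag:::filter_response(ba$b, ba$a, 25, sr)),
               sqrt(0.5), tolerance = 1e-9)  # -3 dB at cutoff
  expect_equal(Mod(chunktag:::filter_response(ba$b, ba$a, 0, sr)), 1,
               tolerance = 1e-12)            # exact unity DC gain
  # zero phase: peak latency of a 5 Hz burst unchanged within 1 sample
  burst <- exp(-((t - 2)^2) / (2 * 0.05^2)) * cos(2 * pi * 5 * (t - 2))
  expect_lte(abs(which.max(lowpass(burst, sr)) - which.max(burst)), 1)
  expect_error(lowpass(x2, sr, cutoff = 300), "Nyquist")
})

test_that("epoching windows, sample counts and baseline correction", {
  ev <- make_within_stream(c("FU", "LA"), 4, seed = 2)
  # constant recording: everything baselines to zero
  rec <- recording(matrix(7, 2, 1500), srate = 100)
  eps <- epoch_events(rec, ev)
  expect_true(all(abs(eps$data) < 1e-12))
  expect_equal(dim(eps$data)[3], round(0.4 * 100) + 1)  # 41 samples at 100 Hz
  expect_equal(eps$tmin, -0.1)
  # at 500 Hz the window is 201 samples
  rec5 <- recording(matrix(0, 1, 10000), srate = 500)
  ev5 <- make_within_stream(c("FU", "LA"), 2, seed = 1)
  expect_equal(dim(epoch_events(rec5, ev5)$data)[3], 201L)
  # events whose window leaves the recording are dropped and counted
  expect_error(epoch_events(recording(matrix(0, 2, 60), srate = 100), ev),
               "outside")
  rec3 <- recording(matrix(0, 2, 150), srate = 100)  # 1.5 s: 1 of 4 fits
  eps3 <- epoch_events(rec3, ev)
  expect_gte(attr(eps3, "n_dropped"), 1L)
  expect_equal(dim(eps3$data)[1] + attr(eps3, "n_dropped"),
               sum(ev$role %in% c("dep_second", "dep_second_violation")))
})

test_that("single-point cluster p equals the exhaustive sign-flip oracle", {
  set.seed(5)
  for (shift in c(0.8, 1.5)) {
    ns <- 10
    A <- array(rnorm(ns) + shift, c(ns, 1, 1))
    B <- array(rnorm(ns), c(ns, 1, 1))
    ct <- cluster_permutation(A, B, matrix(FALSE, 1, 1), exhaustive = TRUE)
    d <- A[, 1, 1] - B[, 1, 1]
    tobs <- mean(d) / (sd(d) / sqrt(ns))
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), ns)))
    tp <- apply(signs, 1, function(s) {
      ds <- s * d
      mean(ds) / (sd(ds) / sqrt(ns))
    })
    if (abs(tobs) > qt(0.975, ns - 1)) {
      expect_equal(nrow(ct$clusters), 1L)
      expect_equal(ct$clusters$p, mean(abs(tp) >= abs(tobs)))
    } else {
      expect_equal(nrow(ct$clusters), 0L)
    }
  }
})

test_that("cluster members are connected, homogeneous and supra-threshold", {
  set.seed(12)
  ns <- 9; nch <- 6; nsamp <- 15
  A <- array(rnorm(ns * nch * nsamp), c(ns, nch, nsamp))
  B <- array(rnorm(ns * nch * nsamp), c(ns, nch, nsamp))
  A[, 2:3, 4:8] <- A[, 2:3, 4:8] + 1.5
  adj <- grid_adjacency(nch)
  ct <- cluster_permutation(A, B, adj, n_perm = 200, seed = 3)
  expect_true(all(ct$clusters$p >= 0 & ct$clusters$p <= 1))
  for (k in seq_len(nrow(ct$clusters))) {
    m <- ct$members[[k]]
    tv <- ct$tmap[m]
    expect_true(all(abs(tv) > ct$tcrit))
    expect_true(all(sign(tv) == ct$clusters$sign[k]))
    expect_equal(ct$clusters$mass[k], sum(abs(tv)^ct$eta), tolerance = 1e-9)
    if (nrow(m) > 1) {
      # connectivity: BFS over the spatio-temporal neighbour relation
      key <- paste(m[, 1], m[, 2])
      reach <- key[1]
      repeat {
        grew <- FALSE
        for (i in seq_len(nrow(m))) {
          if (key[i] %in% reach) next
          for (j in seq_len(nrow(m))) {
            if (!(key[j] %in% reach)) next
            same_ch <- m[i, 1] == m[j, 1] && abs(m[i, 2] - m[j, 2]) == 1
            same_t <- m[i, 2] == m[j, 2] && adj[m[i, 1], m[j, 1]]
            if (same_ch || same_t) {
              reach <- c(reach, key[i]); grew <- TRUE; break
            }
          }
        }
        if (!grew) break
      }
      expect_setequal(reach, key)
    }
  }
})

test_that("cluster test is deterministic and invariant to relabelings", {
  set.seed(8)
  ns <- 8; nch <- 4; nsamp <- 10
  A <- array(rnorm(ns * nch * nsamp), c(ns, nch, nsamp))
  B <- array(rnorm(ns * nch * nsamp), c(ns, nch, nsamp))
  A[, 1, 3:6] <- A[, 1, 3:6] + 2
  adj <- grid_adjacency(nch)
  c1 <- cluster_permutation(A, B, adj, n_perm = 300, seed = 21)
  c2 <- cluster_permutation(A, B, adj, n_perm = 300, seed = 21)
  expect_identical(c1$null_max, c2$null_max)
  expect_identical(c1$clusters, c2$clusters)
  # consistent sign flip of both conditions leaves p unchanged
  c3 <- cluster_permutation(-A, -B, adj, n_perm = 300, seed = 21)
  expect_equal(sort(c3$clusters$p), sort(c1$clusters$p))
  # channel relabeling (with matching adjacency permutation) preserves p
  perm <- c(3L, 1L, 4L, 2L)
  c4 <- cluster_permutation(A[, perm, , drop = FALSE],
                            B[, perm, , drop = FALSE],
                            adj[perm, perm], n_perm = 300, seed = 21)
  expect_equal(sort(c4$clusters$p), sort(c1$clusters$p))
  expect_error(cluster_permutation(A[1, , , drop = FALSE],
                                   B[1, , , drop = FALSE], adj),
               "2 subjects")
  expect_error(cluster_permutation(A, B, adj, n_perm = 0), "n_perm")
})

test_that("a strong brief effect is detected where it was injected", {
  # mirrors the paradigm's early (0-50 ms) effect: 5x noise SD over the
  # first post-onset samples, 12 subjects; detection should be essentially
  # certain, so 3/3 replicates must flag an overlapping cluster
  srate <- 100
  nch <- 4; nsamp <- 41; ns <- 12
  onset0 <- 11  # t = 0
  win <- onset0:(onset0 + 5)  # 0-50 ms
  adj <- grid_adjacency(nch)
  for (r in 1:3) {
    set.seed(400 + r)
    A <- array(rnorm(ns * nch * nsamp), c(ns, nch, nsamp))
    B <- array(rnorm(ns * nch * nsamp), c(ns, nch, nsamp))
    A[, , win] <- A[, , win] + 5
    ct <- cluster_permutation(A, B, adj, n_perm = 500, seed = r)
    sig <- which(ct$clusters$p < 0.05)
    expect_gte(length(sig), 1L)
    hits <- unique(unlist(lapply(sig, function(k)
      ct$members[[k]][, "sample"])))
    expect_gt(length(intersect(hits, win)), 0L)
  }
})
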