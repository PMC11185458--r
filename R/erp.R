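# Test-phase ERP analysis: zero-phase IIR low-pass, event epoching with
# baseline correction, and the spatio-temporal cluster-mass sign-flip
# permutation test.

# polynomial coefficients (highest order first) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Butterworth low-pass filter design
#'
#' All-pole analog Butterworth prototype mapped by the bilinear transform
#' (with frequency pre-warping); the digital zeros sit at z = -1 and the
#' gain is normalized to exactly 1 at DC.
#'
#' @param order filter order (default 4).
#' @param cutoff -3 dB cutoff frequency, Hz.
#' @param srate sampling rate, Hz; `cutoff` must be below Nyquist.
#' @return A list with numerator `b` and denominator `a` coefficients.
#' @export
butter_lowpass <- function(order = 4L, cutoff, srate) {
  stopifnot(order >= 1)
  if (cutoff >= srate / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p <- exp(1i * theta)                        # unit-circle LHP poles
  warped <- 2 * srate * tan(pi * cutoff / srate)
  p <- p * warped
  fs2 <- 2 * srate
  pz <- (1 + p / fs2) / (1 - p / fs2)         # bilinear transform
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)                    # unity gain at z = 1 (DC)
  list(b = b, a = a)
}

# complex frequency response of (b, a) at frequency f (Hz)
filter_response <- function(b, a, f, srate) {
  z <- exp(-2i * pi * f / srate)
  zp_b <- outer(z, 0:(length(b) - 1L), `^`)
  zp_a <- outer(z, 0:(length(a) - 1L), `^`)
  as.vector((zp_b %*% b) / (zp_a %*% a))
}

# forward-backward (zero-phase) filtering with odd-symmetric edge padding
filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  nfact <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 5L)
  pre <- 2 * x[1L] - x[seq(nfact + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - nfact)]
  y <- .iir_filter(b, a, c(pre, x, post))
  y <- rev(.iir_filter(b, a, rev(y)))
  y[nfact + seq_len(n)]
}

#' Zero-phase IIR low-pass filter
#'
#' Two-pass (forward-backward) Butterworth low-pass, applied per channel.
#' The two passes cancel the phase response, so peak latencies are
#' preserved; the amplitude response is squared (the effective attenuation
#' is twice the single-pass attenuation in dB).
#'
#' @param x an `eeg_recording`, an [epoch_set()], a channels x samples
#'   matrix, or a numeric vector.
#' @param srate sampling rate, Hz (taken from the object when available).
#' @param cutoff low-pass cutoff, Hz (default 25); must be below Nyquist.
#' @param order Butterworth order per pass (default 4).
#' @return The filtered object, same class as the input.
#' @export
lowpass <- function(x, srate = NULL, cutoff = 25, order = 4L) {
  if (inherits(x, "eeg_recording")) {
    x$data <- lowpass(x$data, x$srate, cutoff, order)
    return(x)
  }
  if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    for (tr in seq_len(d[1L])) {
      seg <- matrix(x$data[tr, , ], d[2L], d[3L])
      x$data[tr, , ] <- lowpass(seg, x$srate, cutoff, order)
    }
    return(x)
  }
  if (is.null(srate)) stop("srate is required for matrix/vector input",
                           call. = FALSE)
  if (cutoff >= srate / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  ba <- butter_lowpass(order, cutoff, srate)
  if (is.matrix(x)) {
    for (ch in seq_len(nrow(x))) x[ch, ] <- filtfilt_ba(ba$b, ba$a, x[ch, ])
    return(x)
  }
  filtfilt_ba(ba$b, ba$a, as.numeric(x))
}

#' Epoch a recording around events, with baseline correction
#'
#' Cuts `[tmin, tmax]` windows around the onsets of events whose role is in
#' `roles`, and subtracts the per-epoch, per-channel mean over the baseline
#' window `[tmin, 0]`.  Events whose window falls outside the recording are
#' dropped and counted (attribute `n_dropped`).
#'
#' @param rec an `eeg_recording`.
#' @param events an [event_table()].
#' @param roles event roles to epoch (default the second dependency element
#'   and its violation counterpart).
#' @param tmin,tmax epoch window relative to event onset, seconds (defaults
#'   -0.1 and 0.3).
#' @param baseline subtract the `[tmin, 0]` mean (default TRUE).
#' @return An [epoch_set()] with `labels` carrying the event fields and an
#'   `n_dropped` attribute.
#' @export
epoch_events <- function(rec, events,
                         roles = c("dep_second", "dep_second_violation"),
                         tmin = -0.1, tmax = 0.3, baseline = TRUE) {
  stopifnot(tmin < 0 || !baseline, tmax > tmin)
  ev <- events[events$role %in% roles, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no events with the requested roles", call. = FALSE)
  srate <- rec$srate
  i0 <- round(tmin * srate)
  i1 <- round(tmax * srate)
  rel <- i0:i1
  onset_idx <- round(ev$onset_s * srate) + 1L
  lo <- onset_idx + i0
  hi <- onset_idx + i1
  ok <- lo >= 1L & hi <= ncol(rec$data)
  n_dropped <- sum(!ok)
  ev <- ev[ok, , drop = FALSE]
  onset_idx <- onset_idx[ok]
  if (nrow(ev) == 0L) stop("all epochs fall outside the recording",
                           call. = FALSE)
  n_ch <- nrow(rec$data)
  out <- array(0, c(nrow(ev), n_ch, length(rel)))
  base_cols <- which(rel <= 0)
  for (e in seq_len(nrow(ev))) {
    seg <- rec$data[, onset_idx[e] + rel, drop = FALSE]
    if (baseline) seg <- seg - rowMeans(seg[, base_cols, drop = FALSE])
    out[e, , ] <- seg
  }
  es <- epoch_set(out, srate, tmin = rel[1L] / srate,
                  labels = as.data.frame(ev))
  attr(es, "n_dropped") <- n_dropped
  es
}

#' Per-subject evoked response (trial average)
#'
#' @param epochs an [epoch_set()].
#' @param which optional logical/integer trial selector.
#' @return A channels x samples matrix.
#' @export
subject_evoked <- function(epochs, which = NULL) {
  d <- dim(epochs$data)
  sel <- if (is.null(which)) seq_len(d[1L]) else which
  dat <- epochs$data[sel, , , drop = FALSE]
  apply(dat, c(2L, 3L), mean)
}

#' Spatio-temporal cluster-mass permutation test (paired)
#'
#' Paired t statistics are computed at every (channel, sample) point across
#' subjects; points with two-sided p below `alpha_cluster` are clustered
#' under spatio-temporal adjacency (same channel and adjacent samples, or
#' neighbouring channels and the same sample), keeping clusters
#' sign-homogeneous.  The cluster statistic is the weighted cluster mass
#' `sum(|t|^eta)` over members (`eta = 1`: classic cluster mass, reflecting
#' both extent and intensity).  The null distribution is the maximum
#' cluster mass under within-subject condition swaps (sign flips of the
#' paired differences); a cluster's p-value is the proportion of the null
#' at or above its mass.
#'
#' @param condA,condB numeric arrays `subjects x channels x samples` of
#'   per-subject condition means (same shape).
#' @param adjacency logical channel adjacency matrix (symmetric,
#'   irreflexive), e.g. [grid_adjacency()].
#' @param alpha_cluster two-sided point-wise threshold (default 0.05).
#' @param n_perm number of random sign-flip permutations (default 1000).
#' @param seed integer seed for the permutation draw.
#' @param eta exponent of the weighted cluster mass (default 1).
#' @param exhaustive enumerate all `2^n_subjects` sign assignments instead
#'   of sampling (requires <= 20 subjects); p-values are then exact
#'   proportions over the full enumeration.
#' @return An object of class `cluster_test`: `tmap` (channels x samples),
#'   `clusters` (data.frame: id, sign, n_members, mass, p), `members`
#'   (list of channel/sample index matrices), `null_max`, `alpha_cluster`,
#'   `n_perm`, `tcrit`.
#' @export
cluster_permutation <- function(condA, condB, adjacency,
                                alpha_cluster = 0.05, n_perm = 1000L,
                                seed = NULL, eta = 1,
                                exhaustive = FALSE) {
  stopifnot(length(dim(condA)) == 3L, all(dim(condA) == dim(condB)))
  n_subj <- dim(condA)[1L]
  n_ch <- dim(condA)[2L]
  n_s <- dim(condA)[3L]
  if (n_subj < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (!exhaustive && n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  stopifnot(nrow(adjacency) == n_ch)
  Darr <- condA - condB
  # flatten channel-fastest: point = (s-1)*n_ch + ch
  D <- matrix(0, n_subj, n_ch * n_s)
  for (i in seq_len(n_subj)) D[i, ] <- as.vector(matrix(Darr[i, , ], n_ch, n_s))
  tcrit <- qt(1 - alpha_cluster / 2, df = n_subj - 1L)
  chan_adj <- lapply(seq_len(n_ch),
                     function(c) as.integer(which(adjacency[c, ]) - 1L))
  if (exhaustive) {
    if (n_subj > 20L) stop("exhaustive enumeration limited to 20 subjects",
                           call. = FALSE)
    m <- 2L^n_subj
    signs <- matrix(1L, m, n_subj)
    for (i in seq_len(n_subj)) {
      signs[, i] <- ifelse(bitwAnd(seq_len(m) - 1L, 2L^(i - 1L)) > 0L, -1L, 1L)
    }
  } else {
    signs <- with_seed(seed, {
      matrix(sample(c(-1L, 1L), n_perm * n_subj, replace = TRUE),
             n_perm, n_subj)
    })
  }
  res <- .cluster_perm(D, n_ch, n_s, chan_adj, tcrit, eta,
                       signs)
  tmap <- matrix(res$tmap, n_ch, n_s)
  labels <- matrix(res$labels, n_ch, n_s)
  masses <- res$masses
  null_max <- res$null_max
  k <- length(masses)
  p <- if (k) {
    vapply(masses, function(m) {
      b <- sum(null_max >= m - 1e-12)
      if (exhaustive) b / length(null_max) else (1 + b) / (1 + length(null_max))
    }, 1.0)
  } else numeric(0)
  members <- lapply(seq_len(k), function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    colnames(w) <- c("channel", "sample")
    w
  })
  sign_of <- vapply(seq_len(k), function(id) {
    sign(tmap[labels == id][1L])
  }, 1.0)
  clusters <- data.frame(
    id = seq_len(k),
    sign = if (k) sign_of else numeric(0),
    n_members = if (k) vapply(members, nrow, 1L) else integer(0),
    mass = masses, p = p
  )
  structure(list(tmap = tmap, clusters = clusters, members = members,
                 null_max = null_max, alpha_cluster = alpha_cluster,
                 n_perm = nrow(signs), tcrit = tcrit, eta = eta,
                 exhaustive = exhaustive),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d x %d t-map, |t| > %.3f, %d permutations%s\n",
              nrow(x$tmap), ncol(x$tmap), x$tcrit, x$n_perm,
              if (x$exhaustive) " (exhaustive)" else ""))
  if (nrow(x$clusters)) {
    print(x$clusters[order(x$clusters$p), ], row.names = FALSE)
  } else {
    cat("no supra-threshold clusters\n")
  }
  invisible(x)
}

#' Smallest cluster p-value (1 if there are no clusters)
#'
#' Convenience accessor used by the pipeline report and calibration tests.
#' @param x a `cluster_test`.
#' @return Numeric scalar in (0, 1].
#' @export
min_cluster_p <- function(x) {
  if (nrow(x$clusters) == 0L) return(1)
  min(x$clusters$p)
}
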