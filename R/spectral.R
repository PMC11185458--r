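# Frequency tagging: DFT coefficients per epoch, evoked power, neighbour-
# normalized evoked power, inter-trial phase coherence, and the group-level
# target-vs-neighbour-bin paired test.

#' Construct an epoch set
#'
#' Container for epoched data: trials x channels x samples plus the epoch
#' time axis and per-trial labels.
#'
#' @param data numeric array `trials x channels x samples`.
#' @param srate sampling rate, Hz.
#' @param tmin time of the first sample relative to the time-locking event,
#'   seconds (0 for stream epochs).
#' @param labels data.frame with one row per trial (conditions, roles, ...),
#'   or NULL.
#' @param subject optional subject identifier.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, srate, tmin = 0, labels = NULL, subject = NULL) {
  stopifnot(length(dim(data)) == 3L, srate > 0)
  if (!is.null(labels)) stopifnot(nrow(labels) == dim(data)[1L])
  structure(list(data = data, srate = srate, tmin = tmin,
                 labels = labels, subject = subject),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$srate))
  invisible(x)
}

#' Cut a continuous recording into consecutive fixed-length epochs
#'
#' Learning-phase epoching: non-overlapping windows of `n_chunks` chunk
#' periods, starting at the stream onset, so that the chunk rate falls on an
#' exact DFT bin (`n_chunks` cycles per epoch).
#'
#' @param rec an `eeg_recording`.
#' @param timing a [timing_spec()].
#' @param n_chunks chunks per epoch (default 8, i.e. 12.64 s epochs).
#' @param n_epochs cap on the number of epochs (default: as many complete
#'   epochs as fit).
#' @return An [epoch_set()].
#' @export
epoch_stream <- function(rec, timing = timing_spec(), n_chunks = 8L,
                         n_epochs = NULL) {
  len <- epoch_length(timing, n_chunks)
  nsamp <- round(len * rec$srate)
  if (abs(nsamp - len * rec$srate) > 1e-6)
    stop("epoch length is not an integer number of samples at this srate",
         call. = FALSE)
  total <- ncol(rec$data)
  nep <- total %/% nsamp
  if (!is.null(n_epochs)) nep <- min(nep, n_epochs)
  if (nep < 1L) stop("recording shorter than one epoch", call. = FALSE)
  n_ch <- nrow(rec$data)
  out <- array(0, c(nep, n_ch, nsamp))
  for (e in seq_len(nep)) {
    out[e, , ] <- rec$data[, (e - 1L) * nsamp + seq_len(nsamp), drop = FALSE]
  }
  epoch_set(out, rec$srate, tmin = 0)
}

#' Concatenate epoch sets (e.g. pooling conditions)
#'
#' @param ... `epoch_set` objects with matching channel/sample dimensions.
#' @return An [epoch_set()].
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, TRUE)]
  stopifnot(length(sets) >= 1L)
  dims <- vapply(sets, function(s) dim(s$data)[2:3], numeric(2))
  if (!all(dims == dims[, 1L]))
    stop("epoch sets have mismatched channel/sample dimensions", call. = FALSE)
  data <- do.call(abind3, lapply(sets, function(s) s$data))
  labels <- if (all(vapply(sets, function(s) !is.null(s$labels), TRUE))) {
    do.call(rbind, lapply(sets, function(s) s$labels))
  }
  epoch_set(data, sets[[1L]]$srate, sets[[1L]]$tmin, labels,
            sets[[1L]]$subject)
}

# rbind 3-d arrays along dim 1
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n1 <- sum(vapply(arrs, function(a) dim(a)[1L], 1L))
  out <- array(0, c(n1, d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Per-epoch DFT coefficients on a restricted frequency grid
#'
#' Rectangular-window DFT per epoch and channel (per-epoch mean removal, no
#' taper: frequency tagging relies on exact-bin periodicity of the
#' stimulus).  The grid has spacing `1/epoch_length` and is restricted to
#' `[fmin, fmax]`.
#'
#' @param epochs an [epoch_set()]; all epochs must have equal length.
#' @param fmin,fmax frequency band, Hz.
#' @return A list of class `spectral_coefficients`: `X` (complex array
#'   trials x channels x frequencies), `freqs` (Hz), `N` (trial count),
#'   `srate`.
#' @export
dft_coefficients <- function(epochs, fmin = 0.1, fmax = 10) {
  d <- dim(epochs$data)
  n_tr <- d[1L]; n_ch <- d[2L]; n_s <- d[3L]
  if (n_tr < 1L) stop("need at least one epoch", call. = FALSE)
  freqs_all <- (seq_len(n_s) - 1L) / n_s * epochs$srate
  keep <- which(freqs_all >= fmin - 1e-9 & freqs_all <= fmax + 1e-9 &
                  freqs_all <= epochs$srate / 2)
  if (!length(keep)) stop("no DFT bins inside [fmin, fmax]", call. = FALSE)
  X <- array(complex(real = 0), c(n_tr, n_ch, length(keep)))
  # flatten to samples x (trials*channels) and run one mvfft
  flat <- matrix(0, n_s, n_tr * n_ch)
  for (tr in seq_len(n_tr)) {
    seg <- t(epochs$data[tr, , , drop = TRUE])
    if (n_ch == 1L) seg <- matrix(epochs$data[tr, 1L, ], ncol = 1L)
    seg <- sweep(seg, 2L, colMeans(seg))  # per-epoch mean removal
    flat[, (tr - 1L) * n_ch + seq_len(n_ch)] <- seg
  }
  co <- stats::mvfft(flat) / n_s
  for (tr in seq_len(n_tr)) {
    X[tr, , ] <- t(co[keep, (tr - 1L) * n_ch + seq_len(n_ch), drop = FALSE])
  }
  structure(list(X = X, freqs = freqs_all[keep], N = n_tr,
                 srate = epochs$srate),
            class = "spectral_coefficients")
}

#' Evoked power
#'
#' `EP(f) = |sum_n X_n(f)|^2 / N`: the power of the across-trial coherent sum
#' of complex Fourier coefficients.  Phase-locked activity grows linearly in
#' N; activity with random phase across trials stays bounded.
#'
#' @param coeffs a [dft_coefficients()] result.
#' @return A list: `freqs`, `EP` (channels x frequencies matrix), `EP_avg`
#'   (channel average), `N`.
#' @export
evoked_power <- function(coeffs) {
  if (coeffs$N < 1L) stop("evoked power needs N >= 1 trials", call. = FALSE)
  S <- apply(coeffs$X, c(2L, 3L), sum)
  if (is.null(dim(S))) S <- matrix(S, nrow = dim(coeffs$X)[2L])
  EP <- Mod(S)^2 / coeffs$N
  list(freqs = coeffs$freqs, EP = EP, EP_avg = colMeans(EP), N = coeffs$N)
}

#' Inter-trial phase coherence
#'
#' `ITPC(f) = sqrt((sum_n cos(theta_n))^2 + (sum_n sin(theta_n))^2) / N`:
#' the length of the mean unit phase vector across trials (1 = perfectly
#' phase-locked, ~0 = uniform phases).  Trials whose coefficient has zero
#' magnitude carry no phase; they are excluded bin-wise and counted in
#' `n_excluded`.
#'
#' @param coeffs a [dft_coefficients()] result.
#' @return A list: `freqs`, `ITPC` (channels x frequencies), `ITPC_avg`
#'   (channel average), `N`, `n_excluded`.
#' @export
itpc <- function(coeffs) {
  if (coeffs$N < 1L) stop("ITPC needs N >= 1 trials", call. = FALSE)
  m <- Mod(coeffs$X)
  U <- coeffs$X
  ok <- m > 0
  U[ok] <- U[ok] / m[ok]
  U[!ok] <- 0
  n_eff <- apply(ok, c(2L, 3L), sum)
  S <- apply(U, c(2L, 3L), sum)
  if (is.null(dim(S))) {
    S <- matrix(S, nrow = dim(coeffs$X)[2L])
    n_eff <- matrix(n_eff, nrow = dim(coeffs$X)[2L])
  }
  denom <- pmax(n_eff, 1L)
  IT <- Mod(S) / denom
  list(freqs = coeffs$freqs, ITPC = IT, ITPC_avg = colMeans(IT),
       N = coeffs$N, n_excluded = sum(coeffs$N - n_eff))
}

#' Neighbour-normalized power at a target frequency
#'
#' Divides the value at the target bin by the aggregated values of
#' neighbouring bins within `halfwidth` Hz (excluding the target bin
#' itself).  `method = "sum"` divides by the sum over neighbours (the
#' primary reading; a flat spectrum with 0.0791 Hz bins gives 12 neighbours
#' and a baseline of 1/12); `method = "avg"` divides by their mean.
#'
#' @param power numeric vector of power values per frequency bin (or a
#'   channels x frequencies matrix; each row is normalized).
#' @param freqs frequency grid, Hz, matching `power`.
#' @param f_target target frequency, Hz; snapped to the nearest bin.
#' @param halfwidth neighbourhood half width, Hz (default 0.5; strict `<`).
#' @param method `"sum"` (default) or `"avg"`.
#' @return Normalized value(s) at the target bin (`Inf` if the neighbour
#'   aggregate is zero and the target is positive).
#' @export
normalize_power <- function(power, freqs, f_target, halfwidth = 0.5,
                            method = c("sum", "avg")) {
  method <- match.arg(method)
  if (is.matrix(power)) {
    return(apply(power, 1L, normalize_power, freqs = freqs,
                 f_target = f_target, halfwidth = halfwidth, method = method))
  }
  stopifnot(length(power) == length(freqs))
  it <- which.min(abs(freqs - f_target))
  nb <- which(abs(freqs - freqs[it]) < halfwidth - 1e-12)
  nb <- setdiff(nb, it)
  if (!length(nb))
    stop("no neighbour bins inside the +/-", halfwidth, " Hz window",
         call. = FALSE)
  denom <- if (method == "sum") sum(power[nb]) else mean(power[nb])
  if (denom == 0) {
    if (power[it] == 0) return(NaN)
    return(Inf)
  }
  power[it] / denom
}

#' Index of the DFT bin nearest a target frequency
#'
#' @param freqs frequency grid, Hz.
#' @param f_target target frequency, Hz.
#' @return Integer bin index into `freqs`.
#' @export
target_bin <- function(freqs, f_target) which.min(abs(freqs - f_target))

#' Indices of the nearest non-target neighbour bins
#'
#' The `n_side` grid bins on each side of the target bin (2 each side by
#' default, matching the 4-bin group comparison).
#'
#' @param freqs frequency grid, Hz.
#' @param f_target target frequency, Hz.
#' @param n_side bins per side (default 2).
#' @return Integer vector of neighbour bin indices.
#' @export
neighbor_bins <- function(freqs, f_target, n_side = 2L) {
  it <- target_bin(freqs, f_target)
  nb <- c(it - seq_len(n_side), it + seq_len(n_side))
  nb <- nb[nb >= 1L & nb <= length(freqs)]
  if (length(nb) < 1L) stop("no neighbour bins available", call. = FALSE)
  sort(nb)
}

#' Paired target-vs-neighbour group test
#'
#' For each subject, the mean over the neighbour bins is compared with the
#' value at the target bin by a two-sided paired t-test.
#'
#' @param target numeric vector: per-subject value at the target bin.
#' @param neighbors numeric matrix, subjects x neighbour bins.
#' @return A list: `t`, `df`, `p`, `mean_diff` (target minus neighbour mean),
#'   `n`.
#' @export
target_vs_neighbors <- function(target, neighbors) {
  neighbors <- as.matrix(neighbors)
  n <- length(target)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  stopifnot(nrow(neighbors) == n)
  nb_mean <- rowMeans(neighbors)
  d <- target - nb_mean
  if (sd(d) == 0) {
    # degenerate: identical differences; t undefined unless all zero
    if (all(d == 0)) return(list(t = 0, df = n - 1L, p = 1,
                                 mean_diff = 0, n = n))
  }
  tt <- t.test(target, nb_mean, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), n = n)
}
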