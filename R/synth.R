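# Synthetic EEG: event-driven kernel superposition on 1/f background noise.
# The chunk-rate spectral peak is induced by a gain on chunk-initial
# syllables (so it emerges from the event structure, not from an explicit
# sinusoid at the analysis frequency), and the NAD effect is an additive
# deflection at the second dependency element.

#' Parameters of the synthetic EEG generator
#'
#' Defaults follow the recording conventions of the paradigm (500 Hz
#' sampling) at a reduced, labelled 32-channel grid montage.  Response
#' amplitudes and noise are calibrated so that the chunk- and syllable-rate
#' peaks and the within-condition NAD effect are detectable at the study's
#' trial counts (72 learning epochs per condition, 36 test trials per cell,
#' 31 subjects); see the methods vignette.
#'
#' @param srate sampling rate, Hz.  Must make the syllable duration and
#'   boundary silence integer numbers of samples (e.g. 100, 200, 500 for the
#'   default timing).
#' @param n_channels channel count (laid out on a near-square grid with
#'   rook adjacency).
#' @param kernel_dur_s duration of the raised-cosine response kernel, s.
#' @param kernel_amp kernel peak amplitude at ordinary syllable onsets, µV.
#' @param chunk_initial_gain multiplier (>= 1) applied to the kernel of each
#'   chunk's first syllable; values above 1 create the chunk-rate response.
#' @param nad_effect list mapping condition (`within`, `across`) to a named
#'   vector `c(match =, violation =)` of additive deflection amplitudes (µV)
#'   at `dep_second` / `dep_second_violation` onsets.
#' @param noise_alpha exponent of the 1/f background (amplitude spectrum
#'   proportional to `f^(-alpha/2)`); 0 gives white noise.
#' @param noise_sd standard deviation of the background noise, µV.
#' @param topography per-channel weight vector applied to the event-locked
#'   signal (default: all 1).
#' @param seed integer seed used when the generator draws noise.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(srate = 500, n_channels = 32L,
                         kernel_dur_s = 0.2, kernel_amp = 5,
                         chunk_initial_gain = 2,
                         nad_effect = list(
                           within = c(match = 3, violation = 1),
                           across = c(match = 1, violation = 1)),
                         noise_alpha = 1, noise_sd = 10,
                         topography = NULL, seed = 1L) {
  stopifnot(srate > 0, n_channels >= 1, kernel_dur_s > 0)
  if (chunk_initial_gain < 1)
    stop("chunk_initial_gain must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_alpha < 0)
    stop("invalid parameter: noise_alpha must be >= 0", call. = FALSE)
  n_channels <- as.integer(n_channels)
  if (is.null(topography)) topography <- rep(1, n_channels)
  stopifnot(length(topography) == n_channels)
  for (cond in c("within", "across")) {
    e <- nad_effect[[cond]]
    if (is.null(e) || !all(c("match", "violation") %in% names(e)))
      stop("nad_effect must map each condition to c(match=, violation=)",
           call. = FALSE)
  }
  structure(list(srate = srate, n_channels = n_channels,
                 kernel_dur_s = kernel_dur_s, kernel_amp = kernel_amp,
                 chunk_initial_gain = chunk_initial_gain,
                 nad_effect = nad_effect, noise_alpha = noise_alpha,
                 noise_sd = noise_sd, topography = topography,
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Grid channel adjacency
#'
#' Channels are laid out row-major on a near-square grid; two channels are
#' neighbours if they sit side by side horizontally or vertically (rook
#' moves).  The result is symmetric and irreflexive.
#'
#' @param n_channels channel count.
#' @return A logical `n_channels x n_channels` adjacency matrix.
#' @export
grid_adjacency <- function(n_channels) {
  n_channels <- as.integer(n_channels)
  stopifnot(n_channels >= 1)
  nc <- ceiling(sqrt(n_channels))
  row <- (seq_len(n_channels) - 1L) %/% nc
  col <- (seq_len(n_channels) - 1L) %% nc
  adj <- outer(seq_len(n_channels), seq_len(n_channels), function(i, j) {
    (abs(row[i] - row[j]) + abs(col[i] - col[j])) == 1L
  })
  diag(adj) <- FALSE
  adj
}

#' Construct a recording object
#'
#' @param data channels x samples numeric matrix, µV.
#' @param srate sampling rate, Hz.
#' @param labels channel labels; default `C01`, `C02`, ...
#' @param adjacency symmetric, irreflexive logical channel-neighbour matrix;
#'   default [grid_adjacency()].
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, srate, labels = NULL, adjacency = NULL) {
  data <- as.matrix(data)
  stopifnot(srate > 0)
  if (!all(is.finite(data))) stop("recording data must be finite", call. = FALSE)
  n_ch <- nrow(data)
  if (is.null(labels)) labels <- sprintf("C%02d", seq_len(n_ch))
  stopifnot(length(labels) == n_ch)
  if (is.null(adjacency)) adjacency <- grid_adjacency(n_ch)
  adjacency <- as.matrix(adjacency)
  if (!isTRUE(all.equal(adjacency, t(adjacency))) || any(diag(adjacency)))
    stop("adjacency must be symmetric and irreflexive", call. = FALSE)
  structure(list(data = data, srate = srate, labels = labels,
                 adjacency = adjacency),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  invisible(x)
}

#' 1/f ("pink") background noise
#'
#' Each channel is generated independently by shaping the spectrum of white
#' Gaussian noise with `|f|^(-alpha/2)` (DC removed) and scaling so the
#' expected sample standard deviation equals `noise_sd`.  `alpha = 0`
#' reduces to white noise; `alpha = 1` gives the canonical 1/f power decay
#' of background EEG.
#'
#' @param params a [synth_params()].
#' @param n_samples samples per channel (> 0).
#' @param seed optional integer seed overriding `params$seed`.
#' @return An `eeg_recording` containing noise only.
#' @export
one_over_f_noise <- function(params, n_samples, seed = NULL) {
  stopifnot(n_samples > 0)
  n <- as.integer(n_samples)
  if (is.null(seed)) seed <- params$seed
  alpha <- params$noise_alpha
  freqs <- c(0, seq_len(n - 1L)) / n * params$srate
  freqs <- pmin(freqs, params$srate - freqs)  # fold to |f|
  w <- numeric(n)
  nz <- freqs > 0
  w[nz] <- freqs[nz]^(-alpha / 2)
  scale <- if (params$noise_sd > 0) params$noise_sd / sqrt(mean(w^2)) else 0
  data <- with_seed(seed, {
    out <- matrix(0, params$n_channels, n)
    for (ch in seq_len(params$n_channels)) {
      x0 <- rnorm(n)
      x <- Re(fft(fft(x0) * w, inverse = TRUE)) / n
      out[ch, ] <- x * scale
    }
    out
  })
  recording(data, params$srate)
}

# raised-cosine bump of unit peak amplitude, length = kernel_dur_s * srate
response_kernel <- function(params) {
  nk <- max(2L, round(params$kernel_dur_s * params$srate))
  t <- seq_len(nk) - 1L
  0.5 * (1 - cos(2 * pi * t / (nk - 1L)))
}

#' Render a recording from an event table
#'
#' Superposition of (a) a raised-cosine response kernel at every syllable
#' onset, scaled by `chunk_initial_gain` for position-1 syllables, (b) the
#' condition-dependent `nad_effect` deflection at `dep_second` /
#' `dep_second_violation` onsets, and (c) 1/f background noise.  The
#' event-locked component is weighted per channel by `topography`.
#'
#' @param events an [event_table()].
#' @param params a [synth_params()].
#' @param duration_s total duration; default is the last event offset plus
#'   0.5 s of padding.  Events overrunning a requested duration are an error.
#' @param seed optional integer seed for the noise (default `params$seed`).
#' @return An `eeg_recording`.
#' @export
render_recording <- function(events, params, duration_s = NULL, seed = NULL) {
  if (nrow(events) == 0L) stop("empty event table", call. = FALSE)
  srate <- params$srate
  needed <- max(events$onset_s + events$duration_s) +
    max(params$kernel_dur_s, 0.3)
  if (is.null(duration_s)) duration_s <- needed + 0.2
  if (duration_s < needed)
    stop("events overrun the requested duration", call. = FALSE)
  n <- as.integer(ceiling(duration_s * srate))
  kernel <- response_kernel(params)
  nk <- length(kernel)
  base <- numeric(n + nk)  # tail scratch, trimmed below
  onset_idx <- as.integer(round(events$onset_s * srate)) + 1L
  amp <- rep(params$kernel_amp, nrow(events))
  amp[events$position == 1L] <- params$kernel_amp * params$chunk_initial_gain
  extra <- numeric(nrow(events))
  is_match <- events$role == "dep_second"
  is_viol <- events$role == "dep_second_violation"
  for (cond in c("within", "across")) {
    e <- params$nad_effect[[cond]]
    k <- events$condition == cond
    extra[k & is_match] <- e[["match"]]
    extra[k & is_viol] <- e[["violation"]]
  }
  amp <- amp + extra
  for (i in seq_along(onset_idx)) {
    idx <- onset_idx[i] + seq_len(nk) - 1L
    base[idx] <- base[idx] + amp[i] * kernel
  }
  base <- base[seq_len(n)]
  noise <- if (params$noise_sd > 0) {
    one_over_f_noise(params, n, seed = if (is.null(seed)) params$seed else seed)$data
  } else {
    matrix(0, params$n_channels, n)
  }
  data <- params$topography %o% base + noise
  recording(data, srate)
}
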