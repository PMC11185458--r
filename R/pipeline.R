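# End-to-end pipeline: simulate a cohort, run the learning-phase spectral
# analysis (conditions pooled) and the test-phase ERP cluster analysis per
# condition, and emit a machine-readable report.

#' Pipeline configuration
#'
#' Bundles the design, simulation and analysis parameters of a full
#' synthetic study.  The defaults mirror the reference paradigm: 31
#' analyzed subjects, 4 learning audios per condition (72 target chunks per
#' within audio, 144 chunks per across audio, i.e. 72 eight-chunk epochs
#' per condition), 36 test trials per design cell, spectra from 0.1-10 Hz,
#' +/-0.5 Hz normalization windows, a 25 Hz low-pass and 10,000
#' permutations.
#'
#' @param n_subjects cohort size (default 31).
#' @param audios_per_condition learning audios per condition (default 4).
#' @param target_chunks_per_audio target chunks per within-condition audio
#'   (default 72; the across audio then has `2 *` this many chunks).
#' @param epoch_chunks chunks per spectral epoch (default 8).
#' @param n_test_per_cell test trials per design cell (default 36).
#' @param fmin,fmax spectral band, Hz.
#' @param halfwidth normalization window half width, Hz.
#' @param n_neighbors neighbour bins per side in the group test (default 2).
#' @param lowpass_hz ERP low-pass cutoff, Hz.
#' @param tmin,tmax ERP epoch window, seconds.
#' @param n_perm cluster permutations.
#' @param alpha,alpha_cluster significance levels (cluster-level and
#'   point-wise).
#' @param timing a [timing_spec()].
#' @param inventory a [syllable_inventory()].
#' @param synth a [synth_params()].
#' @param seed master seed; all subject seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 31L,
                            audios_per_condition = 4L,
                            target_chunks_per_audio = 72L,
                            epoch_chunks = 8L,
                            n_test_per_cell = 36L,
                            fmin = 0.1, fmax = 10,
                            halfwidth = 0.5, n_neighbors = 2L,
                            lowpass_hz = 25, tmin = -0.1, tmax = 0.3,
                            n_perm = 10000L,
                            alpha = 0.05, alpha_cluster = 0.05,
                            timing = timing_spec(),
                            inventory = default_inventory(),
                            synth = synth_params(),
                            seed = 1L) {
  stopifnot(n_subjects >= 1, audios_per_condition >= 1,
            target_chunks_per_audio >= epoch_chunks / 2,
            n_test_per_cell >= 1, n_perm >= 1)
  structure(list(
    n_subjects = as.integer(n_subjects),
    audios_per_condition = as.integer(audios_per_condition),
    target_chunks_per_audio = as.integer(target_chunks_per_audio),
    epoch_chunks = as.integer(epoch_chunks),
    n_test_per_cell = as.integer(n_test_per_cell),
    fmin = fmin, fmax = fmax, halfwidth = halfwidth,
    n_neighbors = as.integer(n_neighbors),
    lowpass_hz = lowpass_hz, tmin = tmin, tmax = tmax,
    n_perm = as.integer(n_perm), alpha = alpha,
    alpha_cluster = alpha_cluster,
    timing = timing, inventory = inventory, synth = synth,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Reduced-scale pipeline preset
#'
#' Small cohort for smoke tests and CI: 5 subjects, 1 audio per condition,
#' 9 test trials per cell, 100 Hz sampling on 8 channels, 500 permutations.
#' Completes in well under 5 minutes on one CPU.
#'
#' @param ... overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
reduced_config <- function(...) {
  defaults <- list(
    n_subjects = 5L, audios_per_condition = 1L,
    target_chunks_per_audio = 24L, n_test_per_cell = 9L,
    n_perm = 500L,
    synth = synth_params(srate = 100, n_channels = 8L)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(pipeline_config, args)
}

#' Read / write a pipeline configuration file
#'
#' Plain-text JSON with a versioned schema (`schema = "chunktag-config/1"`).
#' Scalar fields map directly onto [pipeline_config()] arguments; `timing`
#' and `synth` are nested objects with the corresponding constructor
#' arguments.  Unknown fields are an error, so typos fail loudly.
#'
#' @param path file path.
#' @return A `pipeline_config` (reader); `path`, invisibly (writer).
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- raw$schema
  if (is.null(schema) || !identical(schema, "chunktag-config/1"))
    stop("unsupported or missing config schema (want chunktag-config/1)",
         call. = FALSE)
  raw$schema <- NULL
  if (!is.null(raw$timing)) raw$timing <- do.call(timing_spec, raw$timing)
  if (!is.null(raw$synth)) {
    if (!is.null(raw$synth$nad_effect))
      raw$synth$nad_effect <- lapply(raw$synth$nad_effect, unlist)
    raw$synth <- do.call(synth_params, raw$synth)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$timing <- unclass(out$timing)
  out$synth <- unclass(out$synth)
  # named atomic vectors would serialize as bare arrays; keep the names
  out$synth$nad_effect <- lapply(out$synth$nad_effect, as.list)
  out$inventory <- NULL  # inventory overrides not serialized; default applies
  out <- c(list(schema = "chunktag-config/1"), out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

subject_seed <- function(config, subject, stage) {
  # deterministic per-subject, per-stage seeds below 2^31
  (config$seed * 7919 + subject * 104729 + stage * 7) %% 2147483647L
}

#' Simulate and analyze one subject
#'
#' Learning phase: per condition, `audios_per_condition` streams are
#' rendered and cut into `epoch_chunks`-chunk epochs; conditions are pooled
#' before the spectral statistics, and normalized EP / ITPC are extracted
#' (channel-averaged) at the chunk- and syllable-rate bins and their
#' neighbour bins.  Test phase: trials are rendered one at a time,
#' low-pass filtered, epoched around the second dependency element and
#' averaged into per-subject condition means.
#'
#' @param config a [pipeline_config()].
#' @param subject 1-based subject index (drives pair rotation and seeds).
#' @return A list with elements `spectral` (per-subject target/neighbour
#'   values) and `erp` (per condition: `match`/`violation` channels x
#'   samples means).
#' @export
simulate_subject <- function(config, subject) {
  timing <- config$timing
  synth <- config$synth
  inv <- config$inventory
  # pair-to-condition rotation across subjects (list counterbalancing)
  pw <- inv$pairs[[1L + (subject - 1L) %% 4L]]
  pa <- inv$pairs[[1L + subject %% 4L]]

  # ---- learning phase ----------------------------------------------------
  all_epochs <- NULL
  for (cond in c("within", "across")) {
    pair <- if (cond == "within") pw else pa
    for (audio in seq_len(config$audios_per_condition)) {
      sd0 <- subject_seed(config, subject,
                          stage = audio + 10L * (cond == "across"))
      ev <- if (cond == "within") {
        make_within_stream(pair, config$target_chunks_per_audio,
                           inventory = inv, timing = timing, seed = sd0)
      } else {
        make_across_stream(pair, 2L * config$target_chunks_per_audio,
                           inventory = inv, timing = timing, seed = sd0)
      }
      rec <- render_recording(ev, synth, seed = sd0 + 1L)
      ep <- epoch_stream(rec, timing, n_chunks = config$epoch_chunks)
      all_epochs <- if (is.null(all_epochs)) ep else bind_epochs(all_epochs, ep)
    }
  }
  co <- dft_coefficients(all_epochs, fmin = config$fmin, fmax = config$fmax)
  ep <- evoked_power(co)
  it <- itpc(co)
  targets <- c(chunk = chunk_rate(timing), syllable = syllable_rate(timing))
  spectral <- list(freqs = co$freqs, EP_avg = ep$EP_avg, ITPC_avg = it$ITPC_avg)
  for (tn in names(targets)) {
    ft <- targets[[tn]]
    itg <- target_bin(co$freqs, ft)
    nb <- neighbor_bins(co$freqs, ft, config$n_neighbors)
    epn_at <- function(ix) normalize_power(ep$EP_avg, co$freqs, co$freqs[ix],
                                           halfwidth = config$halfwidth)
    spectral[[paste0("EPn_", tn)]] <- epn_at(itg)
    spectral[[paste0("EPn_", tn, "_nb")]] <- vapply(nb, epn_at, 1.0)
    spectral[[paste0("ITPC_", tn)]] <- it$ITPC_avg[itg]
    spectral[[paste0("ITPC_", tn, "_nb")]] <- it$ITPC_avg[nb]
  }

  # ---- test phase --------------------------------------------------------
  trials <- make_test_trials(list(pw, pa), n_per_cell = config$n_test_per_cell,
                             inventory = inv, timing = timing,
                             seed = subject_seed(config, subject, stage = 50L))
  acc <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    cond <- attr(tr, "condition")
    viol <- attr(tr, "violation")
    rec <- render_recording(tr, synth,
                            seed = subject_seed(config, subject,
                                                stage = 100L + i))
    rec <- lowpass(rec, cutoff = config$lowpass_hz)
    eps <- epoch_events(rec, tr, tmin = config$tmin, tmax = config$tmax)
    key <- paste(cond, if (viol) "violation" else "match", sep = ".")
    acc[[key]] <- if (is.null(acc[[key]])) eps else bind_epochs(acc[[key]], eps)
  }
  erp <- list()
  for (cond in c("within", "across")) {
    erp[[cond]] <- list(
      match = subject_evoked(acc[[paste0(cond, ".match")]]),
      violation = subject_evoked(acc[[paste0(cond, ".violation")]]),
      tmin = config$tmin, srate = synth$srate
    )
  }
  list(spectral = spectral, erp = erp)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates `n_subjects` subjects, runs the learning-phase spectral group
#' tests (normalized EP and ITPC at the chunk- and syllable-rate bins vs
#' their neighbour bins) and the test-phase cluster-permutation ERP test
#' per condition, and returns — optionally writes — a report.  With a fixed
#' `config$seed` the report is byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; if given, `report.json` and
#'   `report.txt` are written there.
#' @param progress print one line per subject.
#' @return A list of class `chunktag_report`: `spectral` (group tests and
#'   group-mean spectra), `erp` (cluster tests per condition), `config_hash`,
#'   `seed`, `n_subjects`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL,
                    progress = FALSE) {
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    if (progress) message("subject ", s, "/", config$n_subjects)
    subjects[[s]] <- tryCatch(
      simulate_subject(config, s),
      error = function(e) stop("stage [simulate subject ", s, "]: ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  # ---- group spectral tests ----------------------------------------------
  spectral <- list()
  for (measure in c("EPn", "ITPC")) {
    for (tn in c("chunk", "syllable")) {
      tgt <- vapply(subjects, function(x)
        x$spectral[[paste0(measure, "_", tn)]], 1.0)
      nb <- t(vapply(subjects, function(x)
        x$spectral[[paste0(measure, "_", tn, "_nb")]],
        numeric(2L * config$n_neighbors)))
      res <- tryCatch(target_vs_neighbors(tgt, nb),
                      error = function(e) stop("stage [spectral group test]: ",
                                               conditionMessage(e),
                                               call. = FALSE))
      res$target_mean <- mean(tgt)
      res$neighbor_mean <- mean(nb)
      spectral[[paste0(measure, "_", tn)]] <- res
    }
  }
  freqs <- subjects[[1L]]$spectral$freqs
  spectral$group_spectrum <- data.frame(
    frequency = freqs,
    EP = rowMeans(vapply(subjects, function(x) x$spectral$EP_avg,
                         numeric(length(freqs)))),
    ITPC = rowMeans(vapply(subjects, function(x) x$spectral$ITPC_avg,
                           numeric(length(freqs))))
  )
  # ---- group ERP cluster tests -------------------------------------------
  adjacency <- grid_adjacency(config$synth$n_channels)
  erp <- list()
  for (cond in c("within", "across")) {
    A <- stack_subject_means(subjects, cond, "match")
    B <- stack_subject_means(subjects, cond, "violation")
    erp[[cond]] <- tryCatch(
      cluster_permutation(A, B, adjacency,
                          alpha_cluster = config$alpha_cluster,
                          n_perm = config$n_perm,
                          seed = subject_seed(config, 0L, stage = 999L)),
      error = function(e) stop("stage [erp cluster test ", cond, "]: ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  report <- structure(list(
    spectral = spectral, erp = erp,
    seed = config$seed,
    config_hash = config_hash(deparse(unclass(config))),
    n_subjects = config$n_subjects,
    version = .chunktag_version()
  ), class = "chunktag_report")
  if (!is.null(out_dir)) write_report(report, out_dir, config)
  report
}

stack_subject_means <- function(subjects, cond, which) {
  mats <- lapply(subjects, function(x) x$erp[[cond]][[which]])
  d <- dim(mats[[1L]])
  out <- array(0, c(length(mats), d[1L], d[2L]))
  for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
  out
}

report_summary_df <- function(report, config) {
  rows <- list()
  for (key in c("EPn_chunk", "EPn_syllable", "ITPC_chunk", "ITPC_syllable")) {
    r <- report$spectral[[key]]
    rows[[key]] <- data.frame(stage = "spectral", name = key,
                              value = r$target_mean, statistic = r$t,
                              p = r$p)
  }
  for (cond in c("within", "across")) {
    ct <- report$erp[[cond]]
    rows[[cond]] <- data.frame(stage = "erp",
                               name = paste0("cluster_min_p_", cond),
                               value = min_cluster_p(ct),
                               statistic = if (nrow(ct$clusters))
                                 max(ct$clusters$mass) else 0,
                               p = min_cluster_p(ct))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

write_report <- function(report, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_df <- report_summary_df(report, config)
  json <- list(
    generator = paste("chunktag", report$version),
    seed = report$seed, config_hash = report$config_hash,
    n_subjects = report$n_subjects,
    spectral = lapply(report$spectral[
      c("EPn_chunk", "EPn_syllable", "ITPC_chunk", "ITPC_syllable")],
      function(r) r[c("t", "df", "p", "mean_diff", "target_mean",
                      "neighbor_mean")]),
    erp = lapply(report$erp, function(ct) list(
      min_cluster_p = min_cluster_p(ct),
      n_clusters = nrow(ct$clusters),
      clusters = ct$clusters))
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(
    provenance_lines(report$seed, c(config_hash = report$config_hash)),
    sprintf("chunktag pipeline report (%d subjects)", report$n_subjects),
    "",
    "Learning phase (pooled conditions), target vs 4 neighbour bins:",
    vapply(c("EPn_chunk", "EPn_syllable", "ITPC_chunk", "ITPC_syllable"),
           function(key) {
             r <- report$spectral[[key]]
             sprintf("  %-13s target %.4f  neighbours %.4f  t(%d) = %.2f, p = %.3g",
                     key, r$target_mean, r$neighbor_mean, r$df, r$t, r$p)
           }, ""),
    "",
    "Test phase, NAD vs violation cluster test:",
    vapply(c("within", "across"), function(cond) {
      ct <- report$erp[[cond]]
      sprintf("  %-7s min cluster p = %.4g (%d clusters, %d permutations)",
              cond, min_cluster_p(ct), nrow(ct$clusters), ct$n_perm)
    }, "")
  )
  writeLines(txt, file.path(out_dir, "report.txt"))
  utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.chunktag_report <- function(x, ...) {
  cat(sprintf("<chunktag_report> %d subjects, seed %d\n",
              x$n_subjects, x$seed))
  for (key in c("EPn_chunk", "EPn_syllable", "ITPC_chunk", "ITPC_syllable")) {
    r <- x$spectral[[key]]
    cat(sprintf("  %-13s target %.4f vs neighbours %.4f, p = %.3g\n",
                key, r$target_mean, r$neighbor_mean, r$p))
  }
  for (cond in c("within", "across")) {
    cat(sprintf("  ERP %-7s min cluster p = %.4g\n",
                cond, min_cluster_p(x$erp[[cond]])))
  }
  invisible(x)
}
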