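# Artificial-grammar design: syllable inventories, timing, learning-phase
# streams and test-phase trials, all expressed as event tables.

#' Syllable inventory for the artificial grammar
#'
#' Holds the 12 target syllables (free positions of target chunks), the 12
#' filler syllables (filler chunks) and the 4 ordered dependency pairs whose
#' members occupy the dependency positions.  All 28 labels must be distinct
#' and pair members may appear in neither the target nor the filler list.
#'
#' @param target character vector of 12 target-chunk syllables.
#' @param filler character vector of 12 filler-chunk syllables.
#' @param pairs list of 4 ordered pairs (length-2 character vectors).
#' @return An object of class `syllable_inventory`.
#' @seealso [default_inventory()]
#' @export
syllable_inventory <- function(target, filler, pairs) {
  target <- as.character(target)
  filler <- as.character(filler)
  stopifnot(is.list(pairs))
  if (length(pairs) != 4L || !all(vapply(pairs, length, 1L) == 2L))
    stop("inventory must contain exactly 4 ordered dependency pairs", call. = FALSE)
  pair_syl <- unlist(pairs, use.names = FALSE)
  labels <- c(target, filler, pair_syl)
  if (anyDuplicated(labels))
    stop("all syllable labels must be distinct across target, filler and pairs",
         call. = FALSE)
  if (length(target) != 12L || length(filler) != 12L)
    stop("inventory requires 12 target and 12 filler syllables", call. = FALSE)
  structure(list(target = target, filler = filler, pairs = pairs),
            class = "syllable_inventory")
}

#' Default syllable inventory
#'
#' The stock inventory of the paradigm: 12 target syllables, 12 filler
#' syllables, and 4 dependency pairs (FU-LA, TA-PI, KE-MÖ, WE-HO).
#'
#' @return A [syllable_inventory()].
#' @examples
#' inv <- default_inventory()
#' inv$pairs[[1]]
#' @export
default_inventory <- function() {
  syllable_inventory(
    target = c("BA", "BO", "FA", "FI", "GU", "ME",
               "MI", "MO", "NA", "NO", "PU", "SU"),
    filler = c("BI", "BU", "DE", "GO", "HE", "KI",
               "LE", "LI", "LU", "MA", "PE", "TU"),
    pairs = list(c("FU", "LA"),
                 c("TA", "PI"),
                 c("KE", "MÖ"),
                 c("WE", "HO"))
  )
}

#' Stream timing specification
#'
#' Isochronous syllables of `syllable_dur_s` seconds are grouped into chunks
#' of `chunk_size` syllables; an extra `boundary_silence_s` silence follows
#' each chunk.  The chunk period is therefore
#' `chunk_size * syllable_dur_s + boundary_silence_s` (1.58 s by default,
#' i.e. a chunk rate of ~0.63 Hz and a syllable rate of ~3.8 Hz).
#'
#' @param syllable_dur_s syllable duration in seconds (default 0.250).
#' @param chunk_size syllables per chunk (default 6).
#' @param boundary_silence_s silence appended after each chunk, seconds
#'   (default 0.080).
#' @return An object of class `timing_spec`.
#' @export
timing_spec <- function(syllable_dur_s = 0.250, chunk_size = 6L,
                        boundary_silence_s = 0.080) {
  stopifnot(syllable_dur_s > 0, chunk_size >= 1, boundary_silence_s >= 0)
  structure(list(syllable_dur_s = syllable_dur_s,
                 chunk_size = as.integer(chunk_size),
                 boundary_silence_s = boundary_silence_s),
            class = "timing_spec")
}

#' Chunk period, chunk rate, syllable rate and epoch length
#'
#' `chunk_period()` is `chunk_size * syllable_dur_s + boundary_silence_s`
#' seconds; `chunk_rate()` its reciprocal in Hz; `syllable_rate()` is
#' `chunk_size / chunk period` (the mean syllable presentation rate, which
#' differs from `1/syllable_dur_s` because of the boundary silences);
#' `epoch_length()` is `n_chunks` chunk periods in seconds.
#'
#' @param timing a [timing_spec()].
#' @param n_chunks number of chunks per analysis epoch.
#' @return A numeric scalar.
#' @examples
#' chunk_rate(timing_spec())          # ~0.633 Hz, rounds to 0.63
#' epoch_length(timing_spec(), 8)     # 12.64 s
#' @export
chunk_period <- function(timing = timing_spec()) {
  timing$chunk_size * timing$syllable_dur_s + timing$boundary_silence_s
}

#' @rdname chunk_period
#' @export
chunk_rate <- function(timing = timing_spec()) 1 / chunk_period(timing)

#' @rdname chunk_period
#' @export
syllable_rate <- function(timing = timing_spec()) {
  timing$chunk_size / chunk_period(timing)
}

#' @rdname chunk_period
#' @export
epoch_length <- function(timing = timing_spec(), n_chunks = 8L) {
  stopifnot(n_chunks >= 1)
  n_chunks * chunk_period(timing)
}

event_roles <- c("dep_first", "dep_second", "dep_second_violation",
                 "other_target", "filler")

#' Construct and validate an event table
#'
#' The event table is the package's exchange format for stimulus timelines:
#' one row per syllable with onset/duration in seconds, chunk index (0-based),
#' position within chunk (1-based), condition (`within`/`across`), phase
#' (`learning`/`test`), dependency role and 0-based trial index.
#'
#' @param df a data.frame with columns `onset_s`, `duration_s`, `syllable`,
#'   `chunk_index`, `position`, `condition`, `phase`, `role`, `trial_index`.
#' @param timing the [timing_spec()] used to build it (attached as an
#'   attribute and used to validate inter-onset intervals).
#' @return A data.frame of class `event_table`.
#' @export
event_table <- function(df, timing = timing_spec()) {
  needed <- c("onset_s", "duration_s", "syllable", "chunk_index", "position",
              "condition", "phase", "role", "trial_index")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("event table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[needed]
  rownames(df) <- NULL
  attr(df, "timing") <- timing
  class(df) <- c("event_table", "data.frame")
  validate_events(df)
  df
}

#' @rdname event_table
#' @param events an `event_table`.
#' @export
validate_events <- function(events) {
  timing <- attr(events, "timing")
  if (is.null(timing)) timing <- timing_spec()
  if (nrow(events) == 0L) stop("empty event table", call. = FALSE)
  if (any(diff(events$onset_s) <= 0))
    stop("event onsets must be strictly increasing", call. = FALSE)
  if (!all(events$role %in% event_roles))
    stop("unknown event role", call. = FALSE)
  if (!all(events$position >= 1 & events$position <= timing$chunk_size))
    stop("positions must lie in 1..chunk_size", call. = FALSE)
  # inter-onset intervals: syllable duration within a chunk, plus the
  # boundary silence across chunk boundaries (within the same trial)
  d <- diff(events$onset_s)
  same_trial <- diff(events$trial_index) == 0
  cross <- diff(events$chunk_index) != 0
  expected <- ifelse(cross, timing$syllable_dur_s + timing$boundary_silence_s,
                     timing$syllable_dur_s)
  bad <- same_trial & abs(d - expected) > 1e-9
  if (any(bad))
    stop("inter-onset intervals do not match the timing spec", call. = FALSE)
  # every dep_first must be matched by exactly one dep_second(_violation)
  n_first <- sum(events$role == "dep_first")
  n_second <- sum(events$role %in% c("dep_second", "dep_second_violation"))
  if (n_first != n_second)
    stop("unbalanced dependency roles: ", n_first, " dep_first vs ",
         n_second, " dep_second(_violation)", call. = FALSE)
  invisible(events)
}

# onset of a syllable at `position` (1-based) of chunk `chunk_index` (0-based)
event_onset <- function(chunk_index, position, timing) {
  chunk_index * chunk_period(timing) +
    (position - 1) * timing$syllable_dur_s
}

# balanced sampling: concatenated independent permutations of `pool`, so any
# prefix uses each syllable within +/- 1 occurrence of any other
balanced_fill <- function(pool, n) {
  if (n == 0L) return(character(0))
  cycles <- ceiling(n / length(pool))
  out <- unlist(lapply(seq_len(cycles), function(i) sample(pool)),
                use.names = FALSE)
  out[seq_len(n)]
}

# assemble an event table from per-chunk syllable/role matrices
build_stream <- function(syllables, roles, chunk_index, position, condition,
                         phase, trial_index, timing) {
  event_table(data.frame(
    onset_s = event_onset(chunk_index, position, timing),
    duration_s = timing$syllable_dur_s,
    syllable = syllables,
    chunk_index = chunk_index,
    position = position,
    condition = condition,
    phase = phase,
    role = roles,
    trial_index = trial_index,
    stringsAsFactors = FALSE
  ), timing = timing)
}

#' Learning-phase stream with within-chunk dependencies
#'
#' Alternating target and filler chunks (1:1).  In every target chunk the
#' dependency pair occupies positions 2 and 5 (roles `dep_first` and
#' `dep_second`); the remaining target-chunk positions are drawn from the
#' target syllables and filler chunks from the filler syllables, each
#' balanced to within one occurrence.  The transitional probability from the
#' first to the second pair element is 1 within the stream.
#'
#' @param pair length-2 character vector, the dependency pair (first, second).
#' @param n_target_chunks number of target chunks (the stream then has
#'   `2 * n_target_chunks` chunks).  One learning audio uses 72.
#' @param inventory a [syllable_inventory()].
#' @param timing a [timing_spec()].
#' @param seed optional integer; same seed gives a byte-identical table.
#' @return An [event_table()] with `condition = "within"`.
#' @export
make_within_stream <- function(pair, n_target_chunks,
                               inventory = default_inventory(),
                               timing = timing_spec(), seed = NULL) {
  check_pair(pair)
  if (!is.numeric(n_target_chunks) || n_target_chunks < 1)
    stop("invalid design: n_target_chunks must be >= 1", call. = FALSE)
  n_target_chunks <- as.integer(n_target_chunks)
  cs <- timing$chunk_size
  dep_pos <- dep_positions_within(cs)
  with_seed(seed, {
    n_chunks <- 2L * n_target_chunks
    is_target <- (seq_len(n_chunks) - 1L) %% 2L == 0L
    free_pos <- setdiff(seq_len(cs), dep_pos)
    target_free <- balanced_fill(inventory$target,
                                 n_target_chunks * length(free_pos))
    filler_syl <- balanced_fill(inventory$filler, n_target_chunks * cs)
    syl <- character(n_chunks * cs)
    role <- character(n_chunks * cs)
    ti <- fi <- 0L
    for (c in seq_len(n_chunks)) {
      idx <- (c - 1L) * cs + seq_len(cs)
      if (is_target[c]) {
        s <- character(cs); r <- rep("other_target", cs)
        s[dep_pos[1L]] <- pair[1L]; r[dep_pos[1L]] <- "dep_first"
        s[dep_pos[2L]] <- pair[2L]; r[dep_pos[2L]] <- "dep_second"
        s[free_pos] <- target_free[ti + seq_along(free_pos)]
        ti <- ti + length(free_pos)
        syl[idx] <- s; role[idx] <- r
      } else {
        syl[idx] <- filler_syl[fi + seq_len(cs)]
        fi <- fi + cs
        role[idx] <- "filler"
      }
    }
    chunk_index <- rep(seq_len(n_chunks) - 1L, each = cs)
    position <- rep(seq_len(cs), times = n_chunks)
    build_stream(syl, role, chunk_index, position,
                 condition = "within", phase = "learning",
                 trial_index = 0L, timing = timing)
  })
}

#' Learning-phase stream with across-chunk dependencies
#'
#' All chunks are target chunks; consecutive chunk pairs carry the first
#' pair element at position 5 of the first chunk (`dep_first`) and the second
#' element at position 2 of the next chunk (`dep_second`).  Free positions
#' are drawn balanced from the target syllables.
#'
#' @inheritParams make_within_stream
#' @param n_chunks total chunk count; must be even and at least 2.  One
#'   learning audio uses 144.
#' @return An [event_table()] with `condition = "across"`.
#' @export
make_across_stream <- function(pair, n_chunks,
                               inventory = default_inventory(),
                               timing = timing_spec(), seed = NULL) {
  check_pair(pair)
  if (!is.numeric(n_chunks) || n_chunks < 2 || n_chunks %% 2 != 0)
    stop("invalid design: n_chunks must be even and >= 2", call. = FALSE)
  n_chunks <- as.integer(n_chunks)
  cs <- timing$chunk_size
  pos_first <- cs - 1L   # position 5 of the leading chunk
  pos_second <- 2L       # position 2 of the trailing chunk
  with_seed(seed, {
    free_n <- n_chunks * cs - n_chunks  # one dependency slot per chunk
    free_syl <- balanced_fill(inventory$target, free_n)
    syl <- character(n_chunks * cs)
    role <- rep("other_target", n_chunks * cs)
    fi <- 0L
    for (c in seq_len(n_chunks)) {
      idx <- (c - 1L) * cs + seq_len(cs)
      s <- character(cs)
      if (c %% 2L == 1L) {            # leading chunk of a pair
        s[pos_first] <- pair[1L]; role[idx[pos_first]] <- "dep_first"
        free_pos <- setdiff(seq_len(cs), pos_first)
      } else {                        # trailing chunk
        s[pos_second] <- pair[2L]; role[idx[pos_second]] <- "dep_second"
        free_pos <- setdiff(seq_len(cs), pos_second)
      }
      s[free_pos] <- free_syl[fi + seq_along(free_pos)]
      fi <- fi + length(free_pos)
      syl[idx] <- s
    }
    chunk_index <- rep(seq_len(n_chunks) - 1L, each = cs)
    position <- rep(seq_len(cs), times = n_chunks)
    build_stream(syl, role, chunk_index, position,
                 condition = "across", phase = "learning",
                 trial_index = 0L, timing = timing)
  })
}

dep_positions_within <- function(chunk_size) {
  # positions 2 and 5 in the canonical 6-syllable chunk; for other chunk
  # sizes keep "second position" and "second-to-last-but-one" spacing
  c(2L, chunk_size - 1L)
}

check_pair <- function(pair) {
  if (!is.character(pair) || length(pair) != 2L || pair[1L] == pair[2L])
    stop("a dependency pair is two distinct syllable labels", call. = FALSE)
  invisible(pair)
}

#' Test-phase trials: 2 x 2 balanced design
#'
#' Builds `n_per_cell` trials in each cell of the (within/across) x
#' (NAD/violation) design — 144 trials at the default of 36 — and randomizes
#' their order.  A within-condition trial has 4 target chunks interleaved
#' with 4 filler chunks; an across-condition trial has 4 target chunks
#' forming 2 dependency spans.  Violation trials replace the second pair
#' element with a non-matching syllable (by default the second element of
#' the other learned pair), tagged `dep_second_violation`.
#'
#' @param pairs list of two pairs: `pairs[[1]]` is learned in the within
#'   condition, `pairs[[2]]` in the across condition.
#' @param n_per_cell trials per design cell (default 36).
#' @param violation_second named character vector mapping condition to the
#'   syllable used in violations; default is the other pair's second element.
#' @inheritParams make_within_stream
#' @return A list of [event_table()]s, one per trial, in randomized order.
#'   Each carries attributes `condition` and `violation`; `trial_index` is
#'   the 0-based position in the randomized order.
#' @export
make_test_trials <- function(pairs, n_per_cell = 36L,
                             inventory = default_inventory(),
                             timing = timing_spec(), seed = NULL,
                             violation_second = NULL) {
  stopifnot(is.list(pairs), length(pairs) == 2L)
  lapply(pairs, check_pair)
  if (is.null(violation_second))
    violation_second <- c(within = pairs[[2L]][2L], across = pairs[[1L]][2L])
  with_seed(seed, {
    grid <- expand.grid(condition = c("within", "across"),
                        violation = c(FALSE, TRUE),
                        rep = seq_len(n_per_cell),
                        stringsAsFactors = FALSE)
    ord <- sample.int(nrow(grid))
    grid <- grid[ord, , drop = FALSE]
    trials <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      cond <- grid$condition[i]
      viol <- grid$violation[i]
      pair <- if (cond == "within") pairs[[1L]] else pairs[[2L]]
      tab <- if (cond == "within") {
        make_within_stream(pair, n_target_chunks = 4L,
                           inventory = inventory, timing = timing)
      } else {
        make_across_stream(pair, n_chunks = 4L,
                           inventory = inventory, timing = timing)
      }
      tab$phase <- "test"
      tab$trial_index <- i - 1L
      if (viol) {
        k <- tab$role == "dep_second"
        tab$syllable[k] <- violation_second[[cond]]
        tab$role[k] <- "dep_second_violation"
      }
      attr(tab, "condition") <- cond
      attr(tab, "violation") <- viol
      trials[[i]] <- tab
    }
    trials
  })
}

#' Concatenate test trials into one continuous event table
#'
#' Shifts each trial's onsets by the running end time plus an inter-trial
#' gap, yielding a single timeline (e.g. for writing one events file for a
#' whole test block).  `trial_index` distinguishes the trials.
#'
#' @param trials a list of [event_table()]s as returned by
#'   [make_test_trials()].
#' @param gap_s silence between trials, seconds (default 1).
#' @return An [event_table()].
#' @export
concat_trials <- function(trials, gap_s = 1) {
  stopifnot(length(trials) >= 1L)
  timing <- attr(trials[[1L]], "timing")
  offset <- 0
  out <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tab <- as.data.frame(trials[[i]])
    end <- max(tab$onset_s + tab$duration_s)
    tab$onset_s <- tab$onset_s + offset
    offset <- offset + end + gap_s
    out[[i]] <- tab
  }
  event_table(do.call(rbind, out), timing = timing)
}
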