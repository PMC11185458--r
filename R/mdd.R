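# Chunk-aware mean dependency distance: linear arc spans split into a
# within-chunk component (cdd) and a between-chunk component (ldd).

#' Dependency structure over a chunked element sequence
#'
#' @param chunk_of integer vector: chunk index (1-based) of each element in
#'   linear order.  Chunk assignment must be contiguous (all elements of a
#'   chunk consecutive) and chunk indices consecutive from 1.
#' @param arcs two-column matrix (or data.frame) of ordered element pairs
#'   `(u, v)`, 1-based, `u != v`.
#' @return An object of class `dependency_structure` with fields `n`,
#'   `chunk_of`, `arcs`.
#' @export
dependency_structure <- function(chunk_of, arcs) {
  chunk_of <- as.integer(chunk_of)
  n <- length(chunk_of)
  if (n < 2L) stop("need at least 2 elements", call. = FALSE)
  r <- rle(chunk_of)
  if (anyDuplicated(r$values) || !identical(sort(unique(chunk_of)),
                                            seq_len(max(chunk_of))))
    stop("chunk assignment must be contiguous with consecutive indices",
         call. = FALSE)
  arcs <- as.matrix(arcs)
  if (ncol(arcs) != 2L || nrow(arcs) < 1L)
    stop("need at least one arc (u, v)", call. = FALSE)
  storage.mode(arcs) <- "integer"
  if (any(arcs < 1L) || any(arcs > n) || any(arcs[, 1L] == arcs[, 2L]))
    stop("arcs must reference distinct valid elements", call. = FALSE)
  colnames(arcs) <- c("u", "v")
  structure(list(n = n, chunk_of = chunk_of, arcs = arcs),
            class = "dependency_structure")
}

#' Mean dependency distance over a chunked sequence
#'
#' For each arc `(u, v)`: if both ends lie in the same chunk `i`, the
#' word-level span `|v - u|` accrues to that chunk's within-chunk distance
#' `cdd_i`; if the arc crosses chunks, its contribution accrues to the
#' between-chunk distance `ldd`.  The score is
#' `MDD = (sum_i |cdd_i| + |ldd_i|) / (n - 1)`.
#'
#' For crossing arcs two readings are exposed: `"combined"` (default) counts
#' the word-level span plus the chunk-level distance
#' (`|v - u| + |chunk(v) - chunk(u)|`) — the minimal reading that reduces to
#' the classical `sum |v - u| / (n - 1)` when all elements share one chunk
#' and makes boundary-crossing strictly more expensive; `"chunk_only"`
#' counts only the chunk-level distance.
#'
#' @param structure a [dependency_structure()].
#' @param ldd `"combined"` (default) or `"chunk_only"`.
#' @return Numeric scalar, the mean dependency distance.
#' @examples
#' # one 6-element chunk with an arc from position 2 to 5: MDD = 3/5
#' s <- dependency_structure(rep(1, 6), rbind(c(2, 5)))
#' mean_dependency_distance(s)
#' @export
mean_dependency_distance <- function(structure,
                                     ldd = c("combined", "chunk_only")) {
  ldd <- match.arg(ldd)
  st <- structure
  if (!inherits(st, "dependency_structure"))
    stop("expected a dependency_structure", call. = FALSE)
  u <- st$arcs[, 1L]; v <- st$arcs[, 2L]
  cu <- st$chunk_of[u]; cv <- st$chunk_of[v]
  span <- abs(v - u)
  cdist <- abs(cv - cu)
  same <- cu == cv
  cdd_total <- sum(span[same])
  ldd_total <- if (ldd == "combined") sum(span[!same] + cdist[!same])
               else sum(cdist[!same])
  (cdd_total + ldd_total) / (st$n - 1L)
}

#' Canonical NAD design structures of the two conditions
#'
#' Both conditions are represented over 12 elements in 2 chunks of 6, with a
#' single dependency arc, mirroring the stimulus layout: in the within
#' condition the arc spans positions 2-5 of the first (target) chunk, the
#' second chunk being the interleaved filler; in the across condition the
#' arc runs from position 5 of the first chunk to position 2 of the second
#' (element 8).  The across arc crosses a boundary, so its score is strictly
#' higher.
#'
#' @param condition `"within"` or `"across"`.
#' @param chunk_size elements per chunk (default 6).
#' @return A [dependency_structure()].
#' @export
nad_design_structure <- function(condition = c("within", "across"),
                                 chunk_size = 6L) {
  condition <- match.arg(condition)
  chunk_of <- rep(1:2, each = chunk_size)
  pos <- dep_positions_within(chunk_size)
  arcs <- if (condition == "within") {
    rbind(c(pos[1L], pos[2L]))
  } else {
    rbind(c(pos[2L], chunk_size + 2L))
  }
  dependency_structure(chunk_of, arcs)
}

#' Random dependency structures (for property testing)
#'
#' Draws a random element count, a random contiguous chunking and random
#' arcs.  Used to exercise invariants such as boundary monotonicity.
#'
#' @param max_n maximum element count (minimum 4).
#' @return A [dependency_structure()].
#' @export
random_dependency_structure <- function(max_n = 20L) {
  n <- sample(4:max_n, 1L)
  n_chunks <- sample(seq_len(max(1L, n %/% 2L)), 1L)
  cuts <- sort(sample(seq_len(n - 1L), n_chunks - 1L))
  chunk_of <- findInterval(seq_len(n), c(1L, cuts + 1L))
  n_arcs <- sample(1:5, 1L)
  arcs <- t(replicate(n_arcs, sample(n, 2L)))
  dependency_structure(chunk_of, arcs)
}

#' Insert a chunk boundary after a given element
#'
#' Splits the chunk containing `after` so that elements up to `after` keep
#' its chunk and later elements of that chunk start a new one.  Used to
#' state boundary monotonicity: adding a boundary between an arc's endpoints
#' never decreases the MDD.
#'
#' @param structure a [dependency_structure()].
#' @param after element index; the boundary goes between `after` and
#'   `after + 1`.
#' @return A [dependency_structure()].
#' @export
add_chunk_boundary <- function(structure, after) {
  st <- structure
  stopifnot(after >= 1L, after < st$n)
  chunk_of <- st$chunk_of
  if (chunk_of[after] != chunk_of[after + 1L]) return(st)  # already a boundary
  chunk_of[(after + 1L):st$n] <- chunk_of[(after + 1L):st$n] + 1L
  dependency_structure(chunk_of, st$arcs)
}

#' Read a dependency structure from a tab-separated file
#'
#' Expected columns: `element` (1-based linear index), `chunk` (1-based
#' chunk index), `head` (1-based index of the element it attaches to, or 0
#' for none).  Each non-zero head row contributes an arc `(head, element)`.
#'
#' @param path file path.
#' @return A [dependency_structure()].
#' @export
read_structure <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  needed <- c("element", "chunk", "head")
  if (!all(needed %in% names(df)))
    stop("structure file needs columns element, chunk, head", call. = FALSE)
  df <- df[order(df$element), , drop = FALSE]
  if (!identical(as.integer(df$element), seq_len(nrow(df))))
    stop("element indices must be 1..n", call. = FALSE)
  keep <- df$head != 0L
  if (!any(keep)) stop("structure has no arcs", call. = FALSE)
  arcs <- cbind(df$head[keep], df$element[keep])
  dependency_structure(df$chunk, arcs)
}
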