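# Compatible-sequence machinery: the six admissible base pairs, uniform
# random compatible sequences, u-/p-neighborhoods and the compatible
# distance.  A sequence s is compatible with a structure S when every arc
# (i, j) of S carries one of the pairs A-U, U-A, G-C, C-G, G-U, U-G.
# Reorganizing s into (unpaired positions, base pairs) turns the set C[S]
# of compatible sequences into a product of formal cubes: each unpaired
# position has 3 one-step neighbors, each base pair 5 (exactly one of which
# is at Hamming distance one, e.g. G-C to G-U).

#' The six admissible ordered base pairs
#'
#' @return A 6 x 2 character matrix: A-U, U-A, G-C, C-G, G-U, U-G.
#' @export
allowed_pairs <- function() .ALLOWED_PAIRS

.check_rna <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  v <- strsplit(toupper(s), "")[[1]]
  bad <- which(!v %in% RNA_BASES)
  if (length(bad))
    stop(sprintf("illegal base '%s' at position %d (alphabet A,C,G,U)",
                 v[bad[1L]], bad[1L]))
  v
}

#' Is a sequence compatible with a structure?
#'
#' @param s RNA sequence (string over A,C,G,U) of length \code{S$n}.
#' @param S A consistent \code{rna_structure}.
#' @return TRUE iff every arc of \code{S} carries an admissible pair.
#' @export
is_compatible <- function(s, S) {
  stopifnot(.is_structure(S))
  v <- .check_rna(s)
  if (length(v) != S$n) stop("sequence length does not match structure")
  a <- S$arcs
  if (!nrow(a)) return(TRUE)
  all(.PAIR_OK[cbind(v[a[, 1L]], v[a[, 2L]])])
}

#' Random compatible start sequence
#'
#' Draws a sequence compatible with the target with uniform probability:
#' each unpaired position uniform over the four bases, each arc uniform
#' over the six admissible pairs, independently.
#'
#' @param S A consistent \code{rna_structure}.
#' @param seed Optional integer seed for reproducibility.
#' @return An RNA sequence string of length \code{S$n}.
#' @export
make_start <- function(S, seed = NULL) {
  stopifnot(.is_structure(S))
  if (!is.null(seed)) set.seed(seed)
  v <- character(S$n)
  pv <- pair_vector(S)
  unp <- which(pv == 0L)
  v[unp] <- sample(RNA_BASES, length(unp), replace = TRUE)
  a <- S$arcs
  if (nrow(a)) {
    pick <- sample.int(6L, nrow(a), replace = TRUE)
    v[a[, 1L]] <- .ALLOWED_PAIRS[pick, 1L]
    v[a[, 2L]] <- .ALLOWED_PAIRS[pick, 2L]
  }
  paste(v, collapse = "")
}

#' Compatible neighbors of a sequence
#'
#' All sequences one compatible move away from \code{s}: u-neighbors (a
#' point mutation at an unpaired position, 3 per position) and p-neighbors
#' (a compensatory replacement of the pair on an arc by one of the other
#' five admissible pairs; Hamming distance 1 or 2).
#'
#' @param s An RNA sequence compatible with \code{S}.
#' @param S A consistent \code{rna_structure}.
#' @return Character vector of \code{3 * n_unpaired + 5 * n_arcs} sequences.
#' @export
compatible_neighbors <- function(s, S) {
  stopifnot(.is_structure(S))
  v <- .check_rna(s)
  if (!is_compatible(s, S)) stop("sequence is not compatible with S")
  out <- character(0)
  pv <- pair_vector(S)
  for (w in which(pv == 0L)) {
    for (b in setdiff(RNA_BASES, v[w])) {
      t <- v; t[w] <- b
      out <- c(out, paste(t, collapse = ""))
    }
  }
  a <- S$arcs
  for (q in seq_len(nrow(a))) {
    cur <- c(v[a[q, 1L]], v[a[q, 2L]])
    for (p in seq_len(6L)) {
      np <- .ALLOWED_PAIRS[p, ]
      if (all(np == cur)) next
      t <- v; t[a[q, 1L]] <- np[1L]; t[a[q, 2L]] <- np[2L]
      out <- c(out, paste(t, collapse = ""))
    }
  }
  out
}

#' Compatible distance between two sequences
#'
#' Length of a shortest path between \code{s} and \code{t} in the
#' compatible-neighbor graph of \code{C[S]}: one step per differing
#' unpaired position plus one step per arc carrying different pairs (any
#' admissible pair reaches any other in a single compensatory move). Lower
#' bound for the neutral distance.
#'
#' @param s,t RNA sequences compatible with \code{S}.
#' @param S A consistent \code{rna_structure}.
#' @return Non-negative integer.
#' @export
compatible_distance <- function(s, t, S) {
  stopifnot(.is_structure(S))
  vs <- .check_rna(s); vt <- .check_rna(t)
  if (length(vs) != length(vt)) stop("sequences have different lengths")
  if (!is_compatible(s, S) || !is_compatible(t, S))
    stop("both sequences must be compatible with S")
  pv <- pair_vector(S)
  unp <- which(pv == 0L)
  d <- sum(vs[unp] != vt[unp])
  a <- S$arcs
  if (nrow(a))
    d <- d + sum(vs[a[, 1L]] != vt[a[, 1L]] | vs[a[, 2L]] != vt[a[, 2L]])
  as.integer(d)
}

#' Neutral distance (brute-force diagnostic)
#'
#' Shortest path between two sequences within the neutral network of
#' \code{S} (sequences whose mfe fold equals \code{S}), stepping through
#' compatible neighbors that are themselves neutral. Exhaustive
#' breadth-first search intended for tiny instances only; the compatible
#' distance is always a lower bound.
#'
#' @param s,t Sequences folding into \code{S} under the oracle.
#' @param S A valid \code{rna_structure} with \code{S$n <= max_n}.
#' @param oracle A folding oracle \code{function(s, N)}; default the
#'   reference oracle.
#' @param max_n Refuse lengths above this bound (default 12).
#' @return Integer path length, or NA if the two sequences lie in
#'   different components of the neutral network.
#' @export
neutral_distance <- function(s, t, S, oracle = NULL, max_n = 12L) {
  stopifnot(.is_structure(S))
  if (S$n > max_n) stop("neutral_distance is a brute-force diagnostic; n too large")
  if (is.null(oracle))
    oracle <- reference_oracle(min_arc_length = S$min_arc_length,
                               sigma = S$sigma, k = S$k)
  neutral <- function(x)
    structures_identical(mfe_structure(oracle(x, 1L)), S)
  if (!neutral(s) || !neutral(t))
    stop("both sequences must fold into S")
  if (s == t) return(0L)
  seen <- s
  frontier <- s
  d <- 0L
  repeat {
    d <- d + 1L
    nxt <- unique(unlist(lapply(frontier, compatible_neighbors, S = S)))
    nxt <- setdiff(nxt, seen)
    nxt <- nxt[vapply(nxt, neutral, logical(1))]
    if (t %in% nxt) return(d)
    if (!length(nxt)) return(NA_integer_)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
}
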