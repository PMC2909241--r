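# Test helpers: brute-force enumerators and oracles kept independent of the
# package's own algorithms.

# all diagrams over n positions with arc-length >= mal, degree <= 1,
# no (i, i+1) arc, and fewer than 3 mutually crossing arcs (brute force)
all_diagrams <- function(n, mal = 4L) {
  cand <- list()
  for (i in seq_len(max(n - mal, 0L))) {
    for (j in (i + mal):n) cand[[length(cand) + 1L]] <- c(i, j)
  }
  out <- list(rna_structure(n, NULL, validate = FALSE))
  nc <- length(cand)
  rec <- function(sel, used, from) {
    if (from > nc) return()
    for (p in from:nc) {
      a <- cand[[p]]
      if (used[a[1]] || used[a[2]]) next
      arcs <- do.call(rbind, c(sel, list(a)))
      if (brute_crossing(arcs) >= 3L) next
      u2 <- used; u2[a] <- TRUE
      out[[length(out) + 1L]] <<- rna_structure(n, arcs, validate = FALSE)
      rec(c(sel, list(a)), u2, p + 1L)
    }
  }
  if (nc) rec(list(), rep(FALSE, n), 1L)
  out
}

# brute-force crossing number: check all arc subsets for mutual crossing
brute_crossing <- function(arcs) {
  arcs <- if (inherits(arcs, "rna_structure")) arcs$arcs else as.matrix(arcs)
  m <- nrow(arcs)
  if (m == 0L) return(0L)
  best <- 1L
  if (m < 2L) return(best)
  for (size in 2:m) {
    for (sub in utils::combn(m, size, simplify = FALSE)) {
      a <- arcs[sub, , drop = FALSE]
      a <- a[order(a[, 1]), , drop = FALSE]
      if (all(diff(a[, 1]) > 0) && all(diff(a[, 2]) > 0) &&
          max(a[, 1]) < min(a[, 2]))
        best <- max(best, size)
    }
  }
  best
}

# breadth-first shortest path between two sequences in the
# compatible-neighbor graph of C[S] (tiny instances only)
bfs_compatible_distance <- function(s, t, S) {
  if (s == t) return(0L)
  seen <- s
  frontier <- s
  d <- 0L
  repeat {
    d <- d + 1L
    nxt <- unique(unlist(lapply(frontier, compatible_neighbors, S = S)))
    nxt <- setdiff(nxt, seen)
    if (t %in% nxt) return(d)
    if (!length(nxt)) return(NA_integer_)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
}

# random valid structure drawing used across test files
draw_structure <- function(n, seed, pk = TRUE) {
  random_structure(n, max_stems = 2L, allow_pseudoknot = pk, seed = seed)
}

# random compatible sequence of a given length (no structure)
random_seq <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")
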