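# Diagram data model for k-noncrossing RNA pseudoknot structures.
#
# A structure is a diagram over positions 1..n (1-based, closed intervals):
# vertices of degree <= 1 with arcs (i, j), i < j, drawn in the upper
# half-plane.  Arc-length is j - i.  The default validator accepts the class
# of 3-noncrossing, 3-canonical structures with minimum arc-length 4: no
# three mutually crossing arcs, every stack (run of exactly nested,
# endpoint-adjacent arcs) of size >= 3.

#' Construct an RNA structure (diagram)
#'
#' Creates an \code{rna_structure}: a diagram of length \code{n} with a set
#' of arcs (base pairs). Arcs are stored as a two-column integer matrix with
#' \code{l < r}, sorted by left endpoint.
#'
#' @param n Sequence length (non-negative integer).
#' @param arcs Two-column matrix (or data.frame) of arc endpoints, or NULL
#'   for the empty structure.
#' @param min_arc_length Minimum allowed arc-length \code{r - l} (default 4).
#' @param sigma Minimum stack size for canonicity (default 3).
#' @param k Crossing bound: no \code{k} mutually crossing arcs (default 3).
#' @param validate If TRUE, run the full validator (degree, adjacency,
#'   arc-length, crossing bound, canonicity). If FALSE only basic shape
#'   checks (integer endpoints, \code{1 <= l < r <= n}) are performed, so
#'   that illustrative sub-canonical diagrams remain constructible.
#' @return An object of class \code{rna_structure}.
#' @seealso [parse_structure()], [validate_structure()]
#' @export
rna_structure <- function(n, arcs = NULL, min_arc_length = 4L, sigma = 3L,
                          k = 3L, validate = TRUE) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 0L)
  if (is.null(arcs) || NROW(arcs) == 0L) {
    arcs <- matrix(integer(0), ncol = 2L)
  } else {
    arcs <- as.matrix(arcs)
    storage.mode(arcs) <- "integer"
    if (ncol(arcs) != 2L) stop("'arcs' must have two columns (l, r)")
    bad <- which(arcs[, 1L] >= arcs[, 2L] | arcs[, 1L] < 1L | arcs[, 2L] > n)
    if (length(bad)) {
      stop(sprintf("invalid arc (%d, %d): need 1 <= l < r <= n = %d",
                   arcs[bad[1L], 1L], arcs[bad[1L], 2L], n))
    }
    arcs <- arcs[order(arcs[, 1L], arcs[, 2L]), , drop = FALSE]
  }
  dimnames(arcs) <- list(NULL, c("l", "r"))
  S <- structure(list(n = n, arcs = arcs,
                      min_arc_length = as.integer(min_arc_length),
                      sigma = as.integer(sigma), k = as.integer(k)),
                 class = "rna_structure")
  if (validate) validate_structure(S)
  S
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA structure: n = %d, %d arc%s\n", x$n, nrow(x$arcs),
              if (nrow(x$arcs) == 1L) "" else "s"))
  if (nrow(x$arcs) && x$n <= 200L && is_consistent(x)) {
    db <- tryCatch(write_structure(x), error = function(e) NULL)
    if (!is.null(db)) cat(" ", db, "\n")
  } else if (nrow(x$arcs)) {
    cat("  arcs:", paste(sprintf("(%d,%d)", x$arcs[, 1L], x$arcs[, 2L]),
                         collapse = " "), "\n")
  }
  invisible(x)
}

.is_structure <- function(x) inherits(x, "rna_structure")

.as_arcs <- function(x) {
  if (.is_structure(x)) return(x$arcs)
  a <- as.matrix(x)
  storage.mode(a) <- "integer"
  a
}

#' Does every position carry at most one arc endpoint?
#'
#' Arc perturbations can produce diagrams in which a position is paired
#' twice; such diagrams are called inconsistent and are filtered out of
#' competitor sets.
#'
#' @param S An \code{rna_structure} (or arc matrix).
#' @return TRUE iff no position is an endpoint of more than one arc.
#' @export
is_consistent <- function(S) {
  a <- .as_arcs(S)
  ep <- c(a[, 1L], a[, 2L])
  !anyDuplicated(ep)
}

#' Validate a structure against the diagram invariants
#'
#' Checks, in order: vertex degree <= 1; no arc of the form (i, i+1);
#' minimum arc-length; the crossing bound (no \code{k} mutually crossing
#' arcs); sigma-canonicity (all stacks of size >= sigma). A violation
#' raises a classed error (\code{pkinv_invalid_structure}) naming the
#' invariant and the offending arcs.
#'
#' @param S An \code{rna_structure}.
#' @param degree,adjacent,arc_length,crossing,canonical Toggle individual
#'   checks.
#' @return Invisibly TRUE on success.
#' @export
validate_structure <- function(S, degree = TRUE, adjacent = TRUE,
                               arc_length = TRUE, crossing = TRUE,
                               canonical = TRUE) {
  stopifnot(.is_structure(S))
  a <- S$arcs
  fail <- function(what, arcs_txt) {
    stop(structure(class = c("pkinv_invalid_structure", "error", "condition"),
                   list(message = sprintf("invalid structure: %s (%s)",
                                          what, arcs_txt),
                        call = sys.call(-1L))))
  }
  arc_txt <- function(idx)
    paste(sprintf("(%d,%d)", a[idx, 1L], a[idx, 2L]), collapse = " ")
  if (degree) {
    ep <- c(a[, 1L], a[, 2L])
    dup <- ep[duplicated(ep)]
    if (length(dup))
      fail("position paired with more than one base",
           paste("position", dup[1L]))
  }
  if (adjacent && nrow(a)) {
    bad <- which(a[, 2L] - a[, 1L] == 1L)
    if (length(bad)) fail("arc of the form (i, i+1)", arc_txt(bad))
  }
  if (arc_length && nrow(a)) {
    bad <- which(a[, 2L] - a[, 1L] < S$min_arc_length)
    if (length(bad))
      fail(sprintf("arc-length below %d", S$min_arc_length), arc_txt(bad))
  }
  if (crossing && nrow(a) >= S$k) {
    cn <- crossing_number(a)
    if (cn >= S$k)
      fail(sprintf("%d mutually crossing arcs (bound k = %d)", cn, S$k), "")
  }
  if (canonical && nrow(a)) {
    st <- stacks_and_stems(S)
    sz <- vapply(st$stacks, nrow, integer(1))
    if (any(sz < S$sigma)) {
      i <- which(sz < S$sigma)[1L]
      fail(sprintf("stack of size %d below sigma = %d", sz[i], S$sigma),
           paste(sprintf("(%d,%d)", st$stacks[[i]][, 1L],
                         st$stacks[[i]][, 2L]), collapse = " "))
    }
  }
  invisible(TRUE)
}

#' Parse an extended dot-bracket string
#'
#' Reads a target structure written over the alphabet \code{":()[]{}"}
#' (\code{":"} or \code{"."} denotes an unpaired base; the three bracket
#' families are matched independently, each by LIFO nesting). Whitespace is
#' ignored.
#'
#' @param text A single string.
#' @inheritParams rna_structure
#' @return An \code{rna_structure}.
#' @examples
#' parse_structure("((((....))))")
#' parse_structure("(((..[[[..)))..]]]")  # a pseudoknot
#' @export
parse_structure <- function(text, min_arc_length = 4L, sigma = 3L, k = 3L,
                            validate = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(gsub("[[:space:]]", "", text), "")[[1]]
  n <- length(chars)
  open <- c("(" = 1L, "[" = 2L, "{" = 3L)
  close <- c(")" = 1L, "]" = 2L, "}" = 3L)
  stacks <- list(integer(0), integer(0), integer(0))
  arcs <- matrix(integer(0), ncol = 2L)
  for (p in seq_len(n)) {
    ch <- chars[p]
    if (ch %in% c(":", ".")) next
    if (ch %in% names(open)) {
      f <- open[[ch]]
      stacks[[f]] <- c(stacks[[f]], p)
    } else if (ch %in% names(close)) {
      f <- close[[ch]]
      if (!length(stacks[[f]]))
        stop(sprintf("unbalanced '%s' at position %d", ch, p))
      l <- stacks[[f]][length(stacks[[f]])]
      stacks[[f]] <- stacks[[f]][-length(stacks[[f]])]
      arcs <- rbind(arcs, c(l, p))
    } else {
      stop(sprintf("illegal character '%s' at position %d (expected :()[]{})",
                   ch, p))
    }
  }
  left <- vapply(stacks, length, integer(1))
  if (any(left > 0L)) {
    f <- which(left > 0L)[1L]
    stop(sprintf("unbalanced '%s' opened at position %d",
                 c("(", "[", "{")[f], stacks[[f]][1L]))
  }
  rna_structure(n, arcs, min_arc_length = min_arc_length, sigma = sigma,
                k = k, validate = validate)
}

#' Write a structure as an extended dot-bracket string
#'
#' Inverse of [parse_structure()]. Bracket families are assigned by greedy
#' coloring of the arc-crossing conflict graph: arcs ordered by left
#' endpoint each take the lowest-index family among \code{( ) [ ] \{ \}}
#' whose already-assigned arcs do not cross the new arc. Three families
#' suffice for 3-noncrossing inputs.
#'
#' @param S An \code{rna_structure} (consistent, 3-noncrossing).
#' @return A string over \code{":()[]{}"}.
#' @export
write_structure <- function(S) {
  stopifnot(.is_structure(S))
  if (!is_consistent(S)) stop("cannot write an inconsistent structure")
  a <- S$arcs
  out <- rep(":", S$n)
  if (nrow(a)) {
    fam <- integer(nrow(a))
    for (i in seq_len(nrow(a))) {
      used <- rep(FALSE, 3L)
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          if (.arcs_cross(a[j, ], a[i, ])) used[fam[j]] <- TRUE
        }
      }
      f <- which(!used)
      if (!length(f))
        stop("arc conflict graph needs more than 3 bracket families")
      fam[i] <- f[1L]
    }
    opens <- c("(", "[", "{")
    closes <- c(")", "]", "}")
    out[a[, 1L]] <- opens[fam]
    out[a[, 2L]] <- closes[fam]
  }
  paste(out, collapse = "")
}

# do two arcs (each c(l, r)) cross, i.e. l1 < l2 < r1 < r2 in some order?
.arcs_cross <- function(a, b) {
  (a[1L] < b[1L] & b[1L] < a[2L] & a[2L] < b[2L]) ||
    (b[1L] < a[1L] & a[1L] < b[2L] & b[2L] < a[2L])
}

# m x m logical crossing matrix for an arc matrix
.cross_matrix <- function(a) {
  m <- nrow(a)
  if (m == 0L) return(matrix(FALSE, 0L, 0L))
  l <- a[, 1L]; r <- a[, 2L]
  L1 <- matrix(l, m, m); R1 <- matrix(r, m, m)
  L2 <- t(L1); R2 <- t(R1)
  (L1 < L2 & L2 < R1 & R1 < R2) | (L2 < L1 & L1 < R2 & R2 < R1)
}

#' Crossing number of an arc set
#'
#' The largest \code{m} such that some \code{m} arcs are mutually crossing:
#' arcs \code{(i1,j1), ..., (im,jm)} with
#' \code{i1 < ... < im < j1 < ... < jm}. A structure is k-noncrossing iff
#' its crossing number is below \code{k}; RNA secondary structures have
#' crossing number <= 1. Mutually crossing sets are exactly the cliques of
#' the pairwise crossing graph, so this is a (branch-and-bound) maximum
#' clique computation.
#'
#' @param arcs An \code{rna_structure} or a two-column arc matrix.
#' @return A non-negative integer (0 for no arcs).
#' @examples
#' crossing_number(rbind(c(1, 7), c(4, 9), c(5, 11)))  # 3
#' @export
crossing_number <- function(arcs) {
  a <- .as_arcs(arcs)
  m <- nrow(a)
  if (m == 0L) return(0L)
  adj <- .cross_matrix(a)
  best <- 1L
  rec <- function(cand, size) {
    if (size + length(cand) <= best) return()
    if (!length(cand)) {
      if (size > best) best <<- size
      return()
    }
    for (ii in seq_along(cand)) {
      if (size + length(cand) - ii + 1L <= best) break
      v <- cand[ii]
      rest <- cand[-seq_len(ii)]
      rec(rest[adj[v, rest]], size + 1L)
    }
  }
  rec(seq_len(m), 0L)
  as.integer(best)
}

#' Pairing partner of a position
#'
#' Returns the position paired to \code{w} in \code{S}, or 0 if \code{w} is
#' unpaired.
#'
#' @param S A consistent \code{rna_structure}.
#' @param w A position in \code{1..n}.
#' @return Integer partner position, or 0.
#' @export
pairing_partner <- function(S, w) {
  stopifnot(.is_structure(S))
  w <- as.integer(w)
  if (any(w < 1L | w > S$n)) stop("position out of range 1..n")
  pair_vector(S)[w]
}

#' Pair vector of a structure
#'
#' Integer vector of length n: position of the partner, 0 when unpaired.
#'
#' @param S A consistent \code{rna_structure}.
#' @return Integer vector of length \code{S$n}.
#' @export
pair_vector <- function(S) {
  stopifnot(.is_structure(S))
  a <- S$arcs
  pv <- integer(S$n)
  if (nrow(a)) {
    ep <- c(a[, 1L], a[, 2L])
    if (anyDuplicated(ep))
      stop("structure is inconsistent (a position pairs with more than one base)")
    pv[a[, 1L]] <- a[, 2L]
    pv[a[, 2L]] <- a[, 1L]
  }
  pv
}

# inverse of pair_vector: arc matrix from a partner vector
.pv_to_arcs <- function(pv) {
  l <- which(pv > seq_along(pv))
  cbind(l = l, r = pv[l])
}

#' Structure distance between two diagrams
#'
#' Aligns the two diagrams position by position and counts positions paired
#' differently: a position scores 1 if it lies in different arcs in the two
#' structures, or is paired in exactly one of them, and 0 otherwise. This is
#' the base-pair-distance-style metric driving the local search.
#'
#' @param S1,S2 Consistent \code{rna_structure}s of equal length.
#' @return Non-negative integer; 0 iff the structures are identical.
#' @export
structure_distance <- function(S1, S2) {
  stopifnot(.is_structure(S1), .is_structure(S2))
  if (S1$n != S2$n) stop("structures have different lengths")
  sum(pair_vector(S1) != pair_vector(S2))
}

#' Are two structures identical (same length and arc set)?
#' @param S1,S2 \code{rna_structure}s.
#' @return TRUE or FALSE.
#' @export
structures_identical <- function(S1, S2) {
  S1$n == S2$n && nrow(S1$arcs) == nrow(S2$arcs) &&
    all(S1$arcs == S2$arcs)
}

#' Stacks and stems of a structure
#'
#' A stack is a maximal run of exactly nested arcs with both endpoints
#' adjacent: (i, j), (i+1, j-1), ..., (i+s-1, j-s+1). A stem is a maximal
#' chain of nested stacks in which consecutive stacks are separated by
#' isolated (unpaired) nucleotides on at least one side and by nothing else.
#'
#' @param S A consistent \code{rna_structure}.
#' @return A list with components \code{stacks} (list of arc matrices,
#'   outermost arc first), \code{stems} (list of integer vectors of stack
#'   indices, outermost stack first), \code{arc_stack} (stack index per arc
#'   of \code{S$arcs}) and \code{stem_span} (two-column matrix, one row per
#'   stem, the positions covered from the outermost arc).
#' @export
stacks_and_stems <- function(S) {
  stopifnot(.is_structure(S))
  a <- S$arcs
  m <- nrow(a)
  pv <- pair_vector(S)
  if (m == 0L)
    return(list(stacks = list(), stems = list(), arc_stack = integer(0),
                stem_span = matrix(integer(0), ncol = 2L)))
  key <- paste(a[, 1L], a[, 2L])
  idx <- stats::setNames(seq_len(m), key)
  # arc i starts a new stack unless (l-1, r+1) is also an arc
  starts <- which(is.na(idx[paste(a[, 1L] - 1L, a[, 2L] + 1L)]))
  arc_stack <- integer(m)
  stacks <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    i <- starts[s]
    run <- i
    repeat {
      nxt <- idx[paste(a[run[length(run)], 1L] + 1L,
                       a[run[length(run)], 2L] - 1L)]
      if (is.na(nxt)) break
      run <- c(run, nxt)
    }
    stacks[[s]] <- a[run, , drop = FALSE]
    arc_stack[run] <- s
  }
  # stem chaining: stack B continues stack A if B's outer arc is directly
  # nested under A's inner arc with only unpaired positions between.
  nst <- length(stacks)
  succ <- rep(NA_integer_, nst)
  has_pred <- rep(FALSE, nst)
  outer <- t(vapply(stacks, function(st) st[1L, ], integer(2)))
  inner <- t(vapply(stacks, function(st) st[nrow(st), ], integer(2)))
  for (sA in seq_len(nst)) {
    i1 <- inner[sA, 1L]; j1 <- inner[sA, 2L]
    for (sB in seq_len(nst)) {
      if (sB == sA) next
      i2 <- outer[sB, 1L]; j2 <- outer[sB, 2L]
      if (i1 < i2 && j2 < j1) {
        gap <- c(if (i2 - i1 > 1L) (i1 + 1L):(i2 - 1L),
                 if (j1 - j2 > 1L) (j2 + 1L):(j1 - 1L))
        if (all(pv[gap] == 0L)) {
          succ[sA] <- sB
          has_pred[sB] <- TRUE
          break
        }
      }
    }
  }
  stems <- list()
  for (s in which(!has_pred)) {
    chain <- s
    while (!is.na(succ[chain[length(chain)]]))
      chain <- c(chain, succ[chain[length(chain)]])
    stems[[length(stems) + 1L]] <- chain
  }
  stem_span <- t(vapply(stems, function(ch) outer[ch[1L], ], integer(2)))
  colnames(stem_span) <- c("l", "r")
  list(stacks = stacks, stems = stems, arc_stack = arc_stack,
       stem_span = stem_span)
}

#' Is a structure sigma-canonical?
#'
#' TRUE iff every stack has size at least \code{sigma} (default: the
#' structure's own \code{sigma} field).
#'
#' @param S A consistent \code{rna_structure}.
#' @param sigma Minimum stack size.
#' @return TRUE or FALSE.
#' @export
is_sigma_canonical <- function(S, sigma = S$sigma) {
  st <- stacks_and_stems(S)
  all(vapply(st$stacks, nrow, integer(1)) >= sigma)
}

#' Core and L-graph of a structure
#'
#' The core c(S) collapses each maximal stack to a single (outermost) arc.
#' The L-graph L(S) has one vertex per arc of the input with edges exactly
#' between crossing arcs; a structure is noncrossing iff its L-graph is
#' edgeless.
#'
#' @param S A consistent \code{rna_structure}.
#' @return List with \code{core} (an \code{rna_structure}, validation
#'   relaxed) and \code{lgraph} (logical adjacency matrix over the arcs of
#'   \code{S}, dimnames "l,r").
#' @export
core_and_lgraph <- function(S) {
  stopifnot(.is_structure(S))
  st <- stacks_and_stems(S)
  core_arcs <- if (length(st$stacks)) {
    t(vapply(st$stacks, function(x) x[1L, ], integer(2)))
  } else matrix(integer(0), ncol = 2L)
  core <- rna_structure(S$n, core_arcs, min_arc_length = S$min_arc_length,
                        sigma = S$sigma, k = S$k, validate = FALSE)
  adj <- .cross_matrix(S$arcs)
  lbl <- sprintf("%d,%d", S$arcs[, 1L], S$arcs[, 2L])
  dimnames(adj) <- list(lbl, lbl)
  list(core = core, lgraph = adj)
}
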