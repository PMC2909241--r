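# Unique loop decomposition of 3-noncrossing structures, and the interval
# sequence driving the local search.
#
# Every 3-noncrossing structure decomposes uniquely into hairpin, interior,
# multi- and pseudoknot loops.  Each hairpin/interior/multi loop is owned by
# its closing arc; the remaining arcs assemble into pseudoknot loops:
# irreducible sets of mutually crossing arcs (connected dependency graph) in
# which every member is a minimal beta-crossing arc for some arc beta.
# Unpaired positions inside a pseudoknot span that are not claimed by a
# hairpin/interior/multi loop belong to the pseudoknot loop.

#' Arcs crossing a given arc
#'
#' Returns the crossing set of \code{alpha} in \code{S}: all S-arcs
#' \code{beta} with interleaved endpoints.
#'
#' @param S An \code{rna_structure}.
#' @param alpha An arc \code{c(l, r)} that must be an arc of \code{S}.
#' @return Two-column matrix of crossing arcs (possibly 0 rows).
#' @export
crossing_set <- function(S, alpha) {
  stopifnot(.is_structure(S))
  alpha <- as.integer(alpha)
  a <- S$arcs
  ai <- which(a[, 1L] == alpha[1L] & a[, 2L] == alpha[2L])
  if (!length(ai)) stop("alpha is not an arc of S")
  cx <- .cross_matrix(a)[ai, ]
  a[cx, , drop = FALSE]
}

#' Is alpha a minimal beta-crossing arc?
#'
#' Among the arcs crossing \code{beta}, \code{alpha} is minimal when no
#' other member of the crossing set is nested inside it (the nesting
#' order: an arc precedes another iff it lies strictly inside it). Minimality is not
#' symmetric: \code{alpha} can be minimal beta-crossing while \code{beta} is
#' not minimal alpha-crossing.
#'
#' @param S An \code{rna_structure}.
#' @param alpha,beta Arcs \code{c(l, r)} of \code{S}; \code{alpha} must
#'   cross \code{beta}.
#' @return TRUE or FALSE.
#' @export
minimal_beta_crossing <- function(S, alpha, beta) {
  alpha <- as.integer(alpha); beta <- as.integer(beta)
  A <- crossing_set(S, beta)
  sel <- A[, 1L] == alpha[1L] & A[, 2L] == alpha[2L]
  if (!any(sel)) stop("alpha does not cross beta")
  others <- A[!sel, , drop = FALSE]
  !any(others[, 1L] > alpha[1L] & others[, 2L] < alpha[2L])
}

# indices (into S$arcs) of arcs that are minimal beta-crossing for some beta
.minimal_crossing_arcs <- function(arcs) {
  m <- nrow(arcs)
  if (m == 0L) return(integer(0))
  cx <- .cross_matrix(arcs)
  out <- logical(m)
  for (b in seq_len(m)) {
    A <- which(cx[b, ])
    if (!length(A)) next
    for (al in A) {
      others <- setdiff(A, al)
      if (!any(arcs[others, 1L] > arcs[al, 1L] &
               arcs[others, 2L] < arcs[al, 2L]))
        out[al] <- TRUE
    }
  }
  which(out)
}

.new_loop <- function(kind, arcs, unpaired, owner = NA_integer_) {
  arcs <- arcs[order(arcs[, 1L]), , drop = FALSE]
  list(kind = kind, arcs = arcs, unpaired = as.integer(unpaired),
       span = c(min(arcs[, 1L]), max(arcs[, 2L])), owner = owner)
}

#' Loop decomposition of a 3-noncrossing structure
#'
#' Computes the unique decomposition into hairpin, interior, multi- and
#' pseudoknot loops, ordered linearly (see [order_loops()]), together with
#' the induced interval sequence (see [interval_sequence()]).
#'
#' Ownership convention: each hairpin/interior/multi loop is attributed to
#' the arc closing it, each pseudoknot loop to its full arc set, so the
#' owned arcs partition the arcs of \code{S}.
#'
#' @param S A consistent, 3-noncrossing \code{rna_structure}.
#' @return Object of class \code{loop_decomposition}: list with
#'   \code{loops} (ordered list; each loop has \code{kind}, \code{arcs},
#'   \code{unpaired}, \code{span}, \code{span_wide}), \code{intervals}
#'   (two-column matrix) and \code{n}.
#' @examples
#' d <- decompose(parse_structure("(((..[[[..)))..]]]"))
#' vapply(d$loops, `[[`, "", "kind")
#' @export
decompose <- function(S) {
  stopifnot(.is_structure(S))
  if (!is_consistent(S)) stop("structure is inconsistent")
  if (crossing_number(S$arcs) >= 3L)
    stop("structure is not 3-noncrossing")
  a <- S$arcs
  m <- nrow(a)
  pv <- pair_vector(S)
  loops <- list()
  owner_kind <- rep(NA_character_, m)
  claimed <- logical(S$n)  # unpaired positions claimed by a loop
  if (m) {
    for (ai in seq_len(m)) {
      i <- a[ai, 1L]; j <- a[ai, 2L]
      inner <- if (j - i > 1L) (i + 1L):(j - 1L) else integer(0)
      paired_inner <- inner[pv[inner] != 0L]
      if (!length(paired_inner)) {
        loops[[length(loops) + 1L]] <-
          .new_loop("hairpin", a[ai, , drop = FALSE], inner, ai)
        owner_kind[ai] <- "hairpin"
        claimed[inner] <- TRUE
        next
      }
      nested <- which(a[, 1L] > i & a[, 2L] < j)
      cross_in <- any(pv[paired_inner] < i | pv[paired_inner] > j)
      maximal <- nested[vapply(nested, function(b) {
        !any(a[nested, 1L] < a[b, 1L] & a[b, 2L] < a[nested, 2L])
      }, logical(1))]
      if (length(maximal) == 1L) {
        l2 <- a[maximal, 1L]; r2 <- a[maximal, 2L]
        flank <- c(if (l2 - i > 1L) (i + 1L):(l2 - 1L),
                   if (j - r2 > 1L) (r2 + 1L):(j - 1L))
        if (all(pv[flank] == 0L)) {
          loops[[length(loops) + 1L]] <-
            .new_loop("interior", a[c(ai, maximal), , drop = FALSE],
                      flank, ai)
          owner_kind[ai] <- "interior"
          claimed[flank] <- TRUE
          next
        }
      }
      if (!cross_in) {
        spans <- a[maximal, , drop = FALSE]
        inside <- unlist(lapply(seq_len(nrow(spans)), function(q)
          spans[q, 1L]:spans[q, 2L]))
        unp <- setdiff(inner[pv[inner] == 0L], inside)
        loops[[length(loops) + 1L]] <-
          .new_loop("multi", a[c(ai, maximal), , drop = FALSE], unp, ai)
        owner_kind[ai] <- "multi"
        claimed[unp] <- TRUE
        next
      }
      # falls through to pseudoknot assembly
    }
    # pseudoknot loops: components of the dependency graph over the
    # unassigned arcs (each of which crosses some other arc)
    pk_arcs <- which(is.na(owner_kind))
    if (length(pk_arcs)) {
      cx <- .cross_matrix(a)
      comp <- .components(cx[pk_arcs, pk_arcs, drop = FALSE])
      comps <- split(pk_arcs, comp)
      spans <- vapply(comps, function(ix)
        c(min(a[ix, 1L]), max(a[ix, 2L])), integer(2))
      ord <- order(spans[2L, ] - spans[1L, ])  # innermost claims first
      for (q in ord) {
        ix <- comps[[q]]
        i1 <- spans[1L, q]; jt <- spans[2L, q]
        within <- (i1 + 1L):(jt - 1L)
        unp <- within[pv[within] == 0L & !claimed[within]]
        loops[[length(loops) + 1L]] <-
          .new_loop("pseudoknot", a[ix, , drop = FALSE], unp)
        owner_kind[ix] <- "pseudoknot"
        claimed[unp] <- TRUE
      }
    }
  }
  # widened spans: each loop arc extended to the span of its stem
  st <- stacks_and_stems(S)
  stack_stem <- integer(length(st$stacks))
  for (sm in seq_along(st$stems)) stack_stem[st$stems[[sm]]] <- sm
  arc_key <- if (m) paste(a[, 1L], a[, 2L]) else character(0)
  for (li in seq_along(loops)) {
    lp <- loops[[li]]
    ix <- match(paste(lp$arcs[, 1L], lp$arcs[, 2L]), arc_key)
    stems <- unique(stack_stem[st$arc_stack[ix]])
    sp <- st$stem_span[stems, , drop = FALSE]
    loops[[li]]$span_wide <- c(min(sp[, 1L], lp$span[1L], lp$unpaired),
                               max(sp[, 2L], lp$span[2L], lp$unpaired))
  }
  loops <- order_loops(loops)
  out <- structure(list(loops = loops, n = S$n), class = "loop_decomposition")
  out$intervals <- .interval_sequence_impl(S, loops)
  out
}

# connected components of a logical adjacency matrix; returns component id
.components <- function(adj) {
  m <- nrow(adj)
  comp <- integer(m)
  cur <- 0L
  for (v in seq_len(m)) {
    if (comp[v]) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.loop_decomposition <- function(x, ...) {
  cat(sprintf("Loop decomposition: %d loop%s\n", length(x$loops),
              if (length(x$loops) == 1L) "" else "s"))
  for (lp in x$loops) {
    cat(sprintf("  %-10s arcs: %-30s unpaired: %s\n", lp$kind,
                paste(sprintf("(%d,%d)", lp$arcs[, 1L], lp$arcs[, 2L]),
                      collapse = " "),
                if (length(lp$unpaired)) paste(lp$unpaired, collapse = ",")
                else "-"))
  }
  cat("  intervals:",
      paste(sprintf("[%d,%d]", x$intervals[, 1L], x$intervals[, 2L]),
            collapse = " "), "\n")
  invisible(x)
}

#' Linear ordering of loops
#'
#' Orders loops so that a loop nested in another precedes it and, among
#' non-nested loops, the one whose (stem-widened) span starts first comes
#' first. Implemented as ordering by (right end ascending, left end
#' descending), which is a linear extension of the nesting partial order;
#' loops sharing a widened span (stacked interior loops and their hairpin)
#' are ordered innermost first.
#'
#' @param loops List of loops as produced by [decompose()].
#' @return The reordered list.
#' @export
order_loops <- function(loops) {
  if (!length(loops)) return(loops)
  sp <- t(vapply(loops, function(lp)
    if (!is.null(lp$span_wide)) lp$span_wide else lp$span, integer(2)))
  innerkey <- vapply(loops, function(lp) max(lp$arcs[, 1L]), integer(1))
  loops[order(sp[, 2L], -sp[, 1L], -innerkey)]
}

.interval_sequence_impl <- function(S, loops) {
  n <- S$n
  pv <- pair_vector(S)
  ints <- list()
  for (lp in loops) {
    aw <- lp$span_wide
    bl <- aw[1L]; br <- aw[2L]
    while (bl > 1L && pv[bl - 1L] == 0L) bl <- bl - 1L
    while (br < n && pv[br + 1L] == 0L) br <- br + 1L
    ints[[length(ints) + 1L]] <- aw
    if (bl != aw[1L] || br != aw[2L])
      ints[[length(ints) + 1L]] <- c(bl, br)
  }
  if (!length(ints)) ints <- list(c(1L, max(n, 1L)))
  # repair: an interval must not cut any arc (whole loop groups only)
  a <- S$arcs
  ints <- lapply(ints, function(iv) {
    repeat {
      cut <- (a[, 1L] >= iv[1L] & a[, 1L] <= iv[2L]) !=
             (a[, 2L] >= iv[1L] & a[, 2L] <= iv[2L])
      if (!any(cut)) break
      iv <- c(min(iv[1L], a[cut, 1L]), max(iv[2L], a[cut, 2L]))
    }
    iv
  })
  keys <- vapply(ints, paste, "", collapse = ",")
  ints <- ints[!duplicated(keys)]
  ord <- order(vapply(ints, `[`, integer(1), 2L),
               -vapply(ints, `[`, integer(1), 1L))
  ints <- ints[ord]
  full <- c(1L, n)
  keys <- vapply(ints, paste, "", collapse = ",")
  ints <- ints[keys != paste(full, collapse = ",")]
  ints[[length(ints) + 1L]] <- full
  out <- do.call(rbind, ints)
  colnames(out) <- c("l", "r")
  out
}

#' Interval sequence of a structure
#'
#' For each loop, in linear order, emits its stem-widened span a_w and the
#' maximal extension b_w of a_w by adjacent consecutive unpaired
#' nucleotides (dropped when equal to a_w); duplicates are removed and the
#' final interval always covers the whole structure [1, n]. Intervals are
#' repaired (extended) so that no arc of the structure has exactly one
#' endpoint inside an interval, which keeps subsequence folding meaningful.
#'
#' @param S A consistent, 3-noncrossing \code{rna_structure}.
#' @return Two-column integer matrix of intervals.
#' @examples
#' interval_sequence(parse_structure(":((((....)))):"))  # [2,13], [1,14]
#' @export
interval_sequence <- function(S) {
  decompose(S)$intervals
}
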