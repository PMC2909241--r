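# Folding oracle: exhaustive enumeration of 3-noncrossing sigma-canonical
# structures under an additive loop-based energy.
#
# The oracle contract is a function (sequence, N) -> fold_result whose
# candidate list is sorted by energy with the mfe structure first.  The
# reference implementation enumerates every admissible structure for the
# sequence length (cached per length), filters by compatibility, scores
# with the loop-additive toy energy and sorts deterministically.  Any
# callable with the same contract (e.g. an adapter around an external
# folder) can be plugged into the inverse-folding search instead.

#' Additive loop-based energy model
#'
#' Dimensionless energy: each stacked adjacent arc pair (an interior loop
#' with no unpaired member) contributes -(w1 + w2)/2 where w is 3 for
#' G-C/C-G, 2 for A-U/U-A and 1 for G-U/U-G; an interior loop with unpaired
#' members costs \code{interior_unpaired} per member; hairpin, multi- and
#' pseudoknot loops cost flat penalties. The relative magnitudes mirror
#' nearest-neighbor stacking rules, with pseudoknots penalized so that they
#' only win when strongly supported by stacking.
#'
#' @param stack_gc,stack_au,stack_gu Pair weights for the stacking term.
#' @param hairpin,multi,pseudoknot Flat loop penalties.
#' @param interior_unpaired Cost per unpaired member of an interior loop.
#' @return Object of class \code{energy_model}.
#' @export
energy_model <- function(stack_gc = 3, stack_au = 2, stack_gu = 1,
                         hairpin = 3, interior_unpaired = 0.5, multi = 4,
                         pseudoknot = 7) {
  structure(list(stack_gc = stack_gc, stack_au = stack_au,
                 stack_gu = stack_gu, hairpin = hairpin,
                 interior_unpaired = interior_unpaired, multi = multi,
                 pseudoknot = pseudoknot),
            class = "energy_model")
}

# 4x4 matrix of pair weights under a model (0 = cannot pair)
.pair_weight_matrix <- function(model) {
  W <- matrix(0, 4L, 4L, dimnames = list(RNA_BASES, RNA_BASES))
  W["G", "C"] <- W["C", "G"] <- model$stack_gc
  W["A", "U"] <- W["U", "A"] <- model$stack_au
  W["G", "U"] <- W["U", "G"] <- model$stack_gu
  W
}

#' Loop-additive energy of a structure on a sequence
#'
#' Sums the per-loop terms of the unique loop decomposition; the empty
#' structure has energy 0. Deterministic; requires \code{s} compatible with
#' \code{S}.
#'
#' @param s RNA sequence.
#' @param S A consistent, 3-noncrossing \code{rna_structure}.
#' @param model An [energy_model()].
#' @return A real number (dimensionless units).
#' @export
energy <- function(s, S, model = energy_model()) {
  stopifnot(.is_structure(S), inherits(model, "energy_model"))
  if (!is_compatible(s, S)) stop("sequence is not compatible with S")
  if (!nrow(S$arcs)) return(0)
  v <- .check_rna(s)
  W <- .pair_weight_matrix(model)
  dec <- decompose(S)
  e <- 0
  for (lp in dec$loops) {
    e <- e + switch(lp$kind,
      hairpin = model$hairpin,
      interior = {
        if (length(lp$unpaired)) {
          model$interior_unpaired * length(lp$unpaired)
        } else {
          w1 <- W[v[lp$arcs[1L, 1L]], v[lp$arcs[1L, 2L]]]
          w2 <- W[v[lp$arcs[2L, 1L]], v[lp$arcs[2L, 2L]]]
          -(w1 + w2) / 2
        }
      },
      multi = model$multi,
      pseudoknot = model$pseudoknot)
  }
  e
}

#' Enumerate all admissible structures of a given length
#'
#' Exhaustively generates every k-noncrossing, sigma-canonical structure
#' with the given minimum arc-length over \code{n} positions (including the
#' empty structure), each exactly once. Structures are unions of maximal
#' stacks, so the enumeration places stacks of size >= sigma subject to
#' disjointness, non-merging, and the crossing bound.
#'
#' @param n Sequence length.
#' @param min_arc_length,sigma,k Structure-class parameters.
#' @param max_n Refuse lengths above this exhaustive limit (default 26).
#' @return List of \code{rna_structure}.
#' @export
enumerate_structures <- function(n, min_arc_length = 4L, sigma = 3L, k = 3L,
                                 max_n = 26L) {
  n <- as.integer(n)
  if (n > max_n)
    stop(sprintf(paste0("n = %d exceeds the exhaustive enumeration limit ",
                        "(%d); plug in a heuristic folding oracle for ",
                        "longer sequences"), n, max_n))
  tab <- .enum_table(n, min_arc_length, sigma, k)
  lapply(tab$structures, function(a)
    rna_structure(n, a, min_arc_length = min_arc_length, sigma = sigma,
                  k = k, validate = FALSE))
}

# ---- enumeration + per-structure tables, cached per (n, mal, sigma, k) ----

.pkinv_cache <- new.env(parent = emptyenv())

.enum_table <- function(n, mal, sigma, k) {
  key <- paste(n, mal, sigma, k, sep = "_")
  hit <- .pkinv_cache[[key]]
  if (!is.null(hit)) return(hit)
  enum <- .enumerate_arcsets(n, mal, sigma, k)
  structs <- enum$arcsets
  nS <- length(structs)
  # flat arc table for vectorized compatibility checks
  arc_cnt <- vapply(structs, nrow, integer(1))
  ac_sid <- rep.int(seq_len(nS), arc_cnt)
  ac_l <- unlist(lapply(structs, function(a) a[, 1L]), use.names = FALSE)
  ac_r <- unlist(lapply(structs, function(a) a[, 2L]), use.names = FALSE)
  if (is.null(ac_l)) { ac_l <- integer(0); ac_r <- integer(0) }
  # per-structure loop statistics (stack-level, see .loop_stats_stacks)
  # and stacked adjacent arc pairs (all within-stack adjacent pairs)
  n_hp <- integer(nS); n_mu <- integer(nS); n_pk <- integer(nS)
  n_int_unp <- integer(nS)
  sp_sid <- list(); sp <- list()
  keys <- character(nS)
  for (si in seq_len(nS)) {
    a <- structs[[si]]
    keys[si] <- paste(sprintf("%04d%04d", a[, 1L], a[, 2L]), collapse = "")
    if (!nrow(a)) next
    st <- .loop_stats_stacks(enum$cand[enum$sels[[si]], , drop = FALSE])
    n_hp[si] <- st$n_hp; n_mu[si] <- st$n_mu; n_pk[si] <- st$n_pk
    n_int_unp[si] <- st$n_int_unp
    if (nrow(st$sp)) {
      sp_sid[[length(sp_sid) + 1L]] <- rep.int(si, nrow(st$sp))
      sp[[length(sp) + 1L]] <- st$sp
    }
  }
  sp_sid <- if (length(sp_sid)) unlist(sp_sid) else integer(0)
  sp <- if (length(sp)) do.call(rbind, sp) else matrix(integer(0), ncol = 4L)
  out <- list(structures = structs, ac_sid = ac_sid, ac_l = ac_l,
              ac_r = ac_r, arc_cnt = arc_cnt, n_hp = n_hp, n_mu = n_mu,
              n_pk = n_pk, n_int_unp = n_int_unp, sp_sid = sp_sid,
              sp = sp, keys = keys, n = n)
  .pkinv_cache[[key]] <- out
  out
}

# loop statistics of a structure given as a set of stacks (rows i, j, s):
# counts of hairpin/multi/pseudoknot loops, total unpaired members of
# interior loops, and the stacked adjacent arc pairs (l1, r1, l2, r2).
# Within a stack of size s the s-1 adjacent pairs are the zero-unpaired
# interior loops; the loop closed by each stack's innermost arc is
# classified at stack granularity (stacks are position-disjoint, so any
# other stack is nested, disjoint, or crossing).
.loop_stats_stacks <- function(stk) {
  t <- nrow(stk)
  i <- stk[, 1L]; j <- stk[, 2L]; s <- stk[, 3L]
  a <- i + s - 1L; b <- j - s + 1L  # innermost arc of each stack
  sp <- do.call(rbind, lapply(seq_len(t), function(u) {
    if (s[u] == 1L) return(NULL)
    tt <- 0L:(s[u] - 2L)
    cbind(i[u] + tt, j[u] - tt, i[u] + tt + 1L, j[u] - tt - 1L)
  }))
  if (is.null(sp)) sp <- matrix(integer(0), ncol = 4L)
  n_hp <- 0L; n_mu <- 0L; n_int_unp <- 0L
  unassigned <- logical(t)
  nested <- outer(seq_len(t), seq_len(t), function(u, v)
    i[v] > a[u] & j[v] < b[u])           # [u, v]: v nested inside u
  crossing <- outer(seq_len(t), seq_len(t), function(u, v)
    i[v] > a[u] & i[v] + s[v] - 1L < b[u] & j[v] - s[v] + 1L > j[u])
  crossing <- crossing | t(crossing)     # [u, v]: u and v cross
  for (u in seq_len(t)) {
    kids <- which(nested[u, ])
    kids <- kids[!vapply(kids, function(v) any(nested[kids, v]), logical(1))]
    cr <- which(crossing[u, ])
    # runs of crossing stacks lying strictly inside (a_u, b_u)
    runs <- do.call(rbind, lapply(cr, function(v) {
      rbind(if (i[v] > a[u] && i[v] + s[v] - 1L < b[u])
              c(i[v], i[v] + s[v] - 1L),
            if (j[v] - s[v] + 1L > a[u] && j[v] < b[u])
              c(j[v] - s[v] + 1L, j[v]))
    }))
    in_kids <- function(runs) {
      if (is.null(runs) || !nrow(runs)) return(TRUE)
      all(vapply(seq_len(nrow(runs)), function(q)
        any(runs[q, 1L] >= i[kids] & runs[q, 2L] <= j[kids]), logical(1)))
    }
    if (!length(kids) && is.null(runs)) {
      n_hp <- n_hp + 1L
    } else if (length(kids) == 1L && in_kids(runs)) {
      n_int_unp <- n_int_unp + (i[kids] - a[u] - 1L) + (b[u] - j[kids] - 1L)
    } else if (length(kids) >= 2L && in_kids(runs)) {
      n_mu <- n_mu + 1L
    } else {
      unassigned[u] <- TRUE
    }
  }
  n_pk <- if (any(unassigned)) {
    max(.components(crossing[unassigned, unassigned, drop = FALSE]))
  } else 0L
  list(n_hp = n_hp, n_mu = n_mu, n_pk = n_pk, n_int_unp = n_int_unp,
       sp = sp)
}

# enumerate arc sets as a list of matrices (first element: empty
# structure), together with the stack selections that generated them
.enumerate_arcsets <- function(n, mal, sigma, k) {
  # candidate stacks (i, j, s): arcs (i+t, j-t), t = 0..s-1
  cand <- list()
  if (n >= mal + 2L * sigma - 1L) {
    for (i in seq_len(n)) {
      for (s in sigma:max(sigma, (n - mal) %/% 2L + 1L)) {
        jmin <- i + mal + 2L * (s - 1L)
        if (jmin > n) break
        for (j in jmin:n) cand[[length(cand) + 1L]] <- c(i, j, s)
      }
    }
  }
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand[, 1L], cand[, 2L], cand[, 3L]), , drop = FALSE]
  } else cand <- matrix(integer(0), ncol = 3L)
  nc <- nrow(cand)
  # precomputed pairwise relations between candidate stacks
  ok <- matrix(FALSE, nc, nc)     # may co-occur (disjoint, no merge)
  crossing <- matrix(FALSE, nc, nc)
  if (nc > 1L) {
    for (p in seq_len(nc - 1L)) {
      i1 <- cand[p, 1L]; j1 <- cand[p, 2L]; s1 <- cand[p, 3L]
      for (q in (p + 1L):nc) {
        i2 <- cand[q, 1L]; j2 <- cand[q, 2L]; s2 <- cand[q, 3L]
        # position runs of p: [i1, i1+s1-1], [j1-s1+1, j1]; q analogous
        iv <- function(a1, b1, a2, b2) b1 < a2 || b2 < a1
        disj <- iv(i1, i1 + s1 - 1L, i2, i2 + s2 - 1L) &&
                iv(i1, i1 + s1 - 1L, j2 - s2 + 1L, j2) &&
                iv(j1 - s1 + 1L, j1, i2, i2 + s2 - 1L) &&
                iv(j1 - s1 + 1L, j1, j2 - s2 + 1L, j2)
        merge <- (i2 == i1 + s1 && j2 == j1 - s1)
        ok[p, q] <- ok[q, p] <- disj && !merge
        cross_pq <- i1 < i2 && i2 + s2 - 1L < j1 - s1 + 1L &&
                    j2 - s2 + 1L > j1
        crossing[p, q] <- crossing[q, p] <- disj && cross_pq
      }
    }
  }
  out <- list(matrix(integer(0), ncol = 2L))
  sels <- list(integer(0))
  emit <- function(sel) {
    arcs <- do.call(rbind, lapply(sel, function(p) {
      i <- cand[p, 1L]; j <- cand[p, 2L]; s <- cand[p, 3L]
      t <- 0L:(s - 1L)
      cbind(i + t, j - t)
    }))
    arcs <- arcs[order(arcs[, 1L]), , drop = FALSE]
    out[[length(out) + 1L]] <<- arcs
    sels[[length(sels) + 1L]] <<- sel
  }
  rec <- function(sel, from) {
    if (from > nc) return()
    for (p in from:nc) {
      if (length(sel)) {
        if (!all(ok[sel, p])) next
        # crossing bound at stack level: adding p must not complete a
        # (k-1)-clique extension to k mutually crossing stacks
        cr <- sel[crossing[sel, p]]
        if (length(cr) >= k - 1L && .has_clique(crossing, cr, k - 1L)) next
      }
      nsel <- c(sel, p)
      emit(nsel)
      rec(nsel, p + 1L)
    }
  }
  if (nc) rec(integer(0), 1L)
  list(arcsets = out, sels = sels, cand = cand)
}

# does 'verts' contain a clique of size 'size' in adjacency 'adj'?
.has_clique <- function(adj, verts, size) {
  if (size <= 1L) return(length(verts) >= size)
  if (length(verts) < size) return(FALSE)
  for (ii in seq_along(verts)) {
    v <- verts[ii]
    rest <- verts[-seq_len(ii)]
    if (.has_clique(adj, rest[adj[v, rest]], size - 1L)) return(TRUE)
  }
  FALSE
}

#' Fold a sequence with the reference exhaustive oracle
#'
#' Enumerates every admissible structure for the sequence length, keeps
#' those compatible with \code{s}, scores them with the loop-additive
#' energy, sorts by energy (ties broken lexicographically on the sorted arc
#' list, so repeated calls are identical) and returns the best \code{N}.
#' The first candidate is the mfe structure.
#'
#' @param s RNA sequence (string over A,C,G,U).
#' @param N Number of suboptimal structures to return (default 1).
#' @param model An [energy_model()].
#' @param min_arc_length,sigma,k Structure-class parameters.
#' @param max_n Exhaustive enumeration limit.
#' @return Object of class \code{fold_result}: list with \code{sequence},
#'   \code{candidates} (list of \code{rna_structure}) and \code{energies}.
#' @examples
#' fold("GGGGAAAACCCC")$candidates[[1]]
#' @export
fold <- function(s, N = 1L, model = energy_model(), min_arc_length = 4L,
                 sigma = 3L, k = 3L, max_n = 26L) {
  if (N < 1L) stop("N must be >= 1")
  v <- .check_rna(s)
  n <- length(v)
  if (n > max_n)
    stop(sprintf("sequence length %d exceeds the exhaustive limit %d",
                 n, max_n))
  tab <- .enum_table(n, min_arc_length, sigma, k)
  W <- .pair_weight_matrix(model)
  vi <- match(v, RNA_BASES)
  nS <- length(tab$structures)
  # compatibility: a structure survives iff all its arcs can pair
  compat <- rep(TRUE, nS)
  if (length(tab$ac_sid)) {
    arc_ok <- W[cbind(vi[tab$ac_l], vi[tab$ac_r])] > 0
    compat[tab$ac_sid[!arc_ok]] <- FALSE
  }
  # energies: loop penalties + stacking over stacked adjacent pairs
  en <- model$hairpin * tab$n_hp + model$multi * tab$n_mu +
    model$pseudoknot * tab$n_pk + model$interior_unpaired * tab$n_int_unp
  if (length(tab$sp_sid)) {
    w1 <- W[cbind(vi[tab$sp[, 1L]], vi[tab$sp[, 2L]])]
    w2 <- W[cbind(vi[tab$sp[, 3L]], vi[tab$sp[, 4L]])]
    contr <- rowsum(-(w1 + w2) / 2, tab$sp_sid, reorder = FALSE)
    sid <- as.integer(rownames(contr))
    en[sid] <- en[sid] + contr[, 1L]
  }
  ix <- which(compat)
  if (N == 1L) {
    emin <- min(en[ix])
    cand <- ix[en[ix] == emin]
    top <- cand[which(tab$keys[cand] == min(tab$keys[cand]))[1L]]
  } else {
    ord <- ix[order(en[ix], tab$keys[ix], method = "radix")]
    top <- ord[seq_len(min(N, length(ord)))]
  }
  cands <- lapply(tab$structures[top], function(a)
    rna_structure(n, a, min_arc_length = min_arc_length, sigma = sigma,
                  k = k, validate = FALSE))
  structure(list(sequence = s, candidates = cands, energies = en[top]),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("Fold result for %s (%d candidate%s)\n", x$sequence,
              length(x$candidates),
              if (length(x$candidates) == 1L) "" else "s"))
  for (q in seq_along(x$candidates)) {
    cat(sprintf("  %8.2f  %s\n", x$energies[q],
                write_structure(x$candidates[[q]])))
  }
  invisible(x)
}

#' The mfe structure of a fold result
#' @param fr A \code{fold_result}.
#' @return An \code{rna_structure}.
#' @export
mfe_structure <- function(fr) {
  stopifnot(inherits(fr, "fold_result"))
  fr$candidates[[1L]]
}

#' Reference folding oracle as a pluggable callable
#'
#' Wraps [fold()] with fixed model and structure-class parameters into the
#' oracle contract \code{function(s, N) -> fold_result} used by the
#' inverse-folding search.
#'
#' @inheritParams fold
#' @return A function \code{(s, N)}.
#' @export
reference_oracle <- function(model = energy_model(), min_arc_length = 4L,
                             sigma = 3L, k = 3L, max_n = 26L) {
  force(model)
  function(s, N = 1L) fold(s, N, model = model,
                           min_arc_length = min_arc_length, sigma = sigma,
                           k = k, max_n = max_n)
}
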