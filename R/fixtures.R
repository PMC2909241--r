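# Deterministic generation of valid test inputs: random 3-noncrossing
# sigma-canonical structures (optionally with one crossing stem pair, i.e.
# an H-type pseudoknot) and reconstructible worked examples.

#' Random valid structure
#'
#' Draws a random k-noncrossing, sigma-canonical structure of length
#' \code{n} by placing hairpin stems (stack size >= sigma, minimum
#' arc-length respected) into free sequence intervals, occasionally nesting
#' one stem inside another, and - when \code{allow_pseudoknot} - sometimes
#' replacing two stems by a crossing stem pair. Rejection sampling with a
#' constructive fallback; the result always passes the full validator and
#' is reproducible under a fixed seed. Uniformity over the structure class
#' is not attempted.
#'
#' @param n Sequence length (>= 0).
#' @param max_stems Maximum number of stems to place (default 2).
#' @param allow_pseudoknot Allow a crossing stem pair (default FALSE).
#' @param sigma,min_arc_length Structure-class parameters.
#' @param seed Optional integer seed.
#' @param p_pseudoknot Probability of attempting a pseudoknot when allowed
#'   and the length permits (default 0.5).
#' @return An \code{rna_structure} passing [validate_structure()].
#' @export
random_structure <- function(n, max_stems = 2L, allow_pseudoknot = FALSE,
                             sigma = 3L, min_arc_length = 4L, seed = NULL,
                             p_pseudoknot = 0.5) {
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  if (n < 0L) stop("n must be non-negative")
  mk <- function(arcs) rna_structure(n, arcs, min_arc_length = min_arc_length,
                                     sigma = sigma, k = 3L, validate = FALSE)
  stem_min <- 2L * sigma + min_arc_length - 1L  # span of a minimal stem
  pk_min <- 4L * sigma  # minimal crossing stem pair span (gaps 0)
  for (attempt in seq_len(200L)) {
    arcs <- matrix(integer(0), ncol = 2L)
    if (allow_pseudoknot && n >= pk_min && stats::runif(1L) < p_pseudoknot) {
      arcs <- .place_pseudoknot(n, sigma, min_arc_length)
      if (is.null(arcs)) next
    } else {
      nstem <- sample.int(max(max_stems, 1L), 1L)
      free <- list(c(1L, n))
      for (q in seq_len(nstem)) {
        roomy <- which(vapply(free, function(f) f[2L] - f[1L] + 1L,
                              integer(1)) >= stem_min)
        if (!length(roomy)) break
        pick <- roomy[sample.int(length(roomy), 1L)]
        slot <- free[[pick]]
        st <- .place_stem(slot, sigma, min_arc_length)
        if (is.null(st)) next
        arcs <- rbind(arcs, st$arcs)
        # split the slot into the remaining free pieces (flanks + hairpin
        # interior, so a later stem may nest)
        free <- Filter(function(f) f[2L] >= f[1L],
                       c(free[-pick],
                         list(c(slot[1L], st$span[1L] - 1L),
                              c(st$span[2L] + 1L, slot[2L]),
                              st$inner)))
      }
    }
    S <- mk(arcs)
    ok <- tryCatch({ validate_structure(S); TRUE },
                   error = function(e) FALSE)
    if (ok) return(S)
  }
  # constructive fallback: one minimal stem at the left, else empty
  if (n >= stem_min) {
    t <- 0L:(sigma - 1L)
    S <- mk(cbind(1L + t, (2L * sigma + min_arc_length - 1L) - t))
    validate_structure(S)
    return(S)
  }
  mk(NULL)
}

# length-safe uniform pick from a vector
.pick <- function(x) x[sample.int(length(x), 1L)]

# place one stem inside slot [a, b]; returns arcs, outer span, free interior
.place_stem <- function(slot, sigma, mal) {
  a <- slot[1L]; b <- slot[2L]
  room <- b - a + 1L
  smax <- (room - mal + 1L) %/% 2L
  if (smax < sigma) return(NULL)
  s <- .pick(sigma:smax)
  span_min <- 2L * s + mal - 1L
  span <- .pick(span_min:room)
  off <- sample.int(room - span + 1L, 1L) - 1L
  i <- a + off
  j <- i + span - 1L
  t <- 0L:(s - 1L)
  list(arcs = cbind(i + t, j - t), span = c(i, j),
       inner = c(i + s, j - s))
}

# H-type pseudoknot: stem A left run, stem B left run, stem A right run,
# stem B right run, with random gaps
.place_pseudoknot <- function(n, sigma, mal) {
  s1 <- sigma; s2 <- sigma
  slack <- n - (2L * s1 + 2L * s2)
  if (slack < 0L) return(NULL)
  g <- c(0L, 0L, 0L, 0L, 0L)  # offset, g1, g2, g3, tail
  if (slack > 0L) {
    w <- stats::runif(5L)
    g <- floor(slack * w / sum(w))
  }
  x1 <- 1L + g[1L]
  bl <- x1 + s1 + g[2L]       # B left run start
  ar <- bl + s2 + g[3L]       # A right run start
  br <- ar + s1 + g[4L]       # B right run start
  if (br + s2 - 1L > n) return(NULL)
  tA <- 0L:(s1 - 1L)
  tB <- 0L:(s2 - 1L)
  arcsA <- cbind(x1 + tA, (ar + s1 - 1L) - tA)
  arcsB <- cbind(bl + tB, (br + s2 - 1L) - tB)
  arcs <- rbind(arcsA, arcsB)
  if (any(arcs[, 2L] - arcs[, 1L] < mal)) return(NULL)
  arcs
}

#' Reconstructible worked examples
#'
#' Small fixtures used throughout the tests: \code{crossing_triple}, three
#' mutually crossing arcs (1,7), (4,9), (5,11) over 11 positions (a
#' 4-noncrossing diagram, validation relaxed); \code{conflict_pair}, the
#' mutation scenario of a target arc (5,9) against a competitor arc (5,10);
#' and \code{pk18}, the 18-mer H-type pseudoknot
#' \code{"(((..[[[..)))..]]]"}.
#'
#' @return Named list.
#' @export
worked_examples <- function() {
  list(
    crossing_triple = rna_structure(11L,
      rbind(c(1L, 7L), c(4L, 9L), c(5L, 11L)), validate = FALSE),
    conflict_pair = list(
      target = rna_structure(10L, rbind(c(5L, 9L)), validate = FALSE),
      competitor = rna_structure(10L, rbind(c(5L, 10L)), validate = FALSE)),
    pk18 = parse_structure("(((..[[[..)))..]]]")
  )
}
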