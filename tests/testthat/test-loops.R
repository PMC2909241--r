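# Loop decomposition: crossing sets, minimality, the four loop types,
# linear ordering and the interval sequence.

pk18 <- parse_structure("(((..[[[..)))..]]]")

test_that("crossing sets are symmetric and match hand computation", {
  A <- crossing_set(pk18, c(1, 13))
  expect_equal(unname(A), rbind(c(6, 18), c(7, 17), c(8, 16)),
               ignore_attr = TRUE)
  S <- parse_structure("((((....))))")
  expect_equal(nrow(crossing_set(S, c(1, 12))), 0L)
  expect_error(crossing_set(S, c(1, 11)), "not an arc")

  # symmetry beta in A(alpha) <=> alpha in A(beta), exhaustively small n
  for (D in all_diagrams(9L)) {
    a <- D$arcs
    if (nrow(a) < 2) next
    for (x in seq_len(nrow(a))) {
      Ax <- crossing_set(D, a[x, ])
      for (q in seq_len(nrow(Ax))) {
        back <- crossing_set(D, Ax[q, ])
        expect_true(any(back[, 1] == a[x, 1] & back[, 2] == a[x, 2]))
      }
    }
  }
})

test_that("minimal beta-crossing selects innermost crossing arcs", {
  # singleton crossing set is always minimal
  S <- rna_structure(12, rbind(c(1, 7), c(4, 11)), validate = FALSE)
  expect_true(minimal_beta_crossing(S, c(4, 11), c(1, 7)))
  expect_true(minimal_beta_crossing(S, c(1, 7), c(4, 11)))

  # stem crossing a stem: only the innermost arc is minimal
  min_for <- function(beta) {
    A <- crossing_set(pk18, beta)
    A[vapply(seq_len(nrow(A)), function(q)
      minimal_beta_crossing(pk18, A[q, ], beta), logical(1)), , drop = FALSE]
  }
  expect_equal(unname(min_for(c(1, 13))), rbind(c(8L, 16L)),
               ignore_attr = TRUE)
  expect_equal(unname(min_for(c(8, 16))), rbind(c(3L, 11L)),
               ignore_attr = TRUE)
})

test_that("nested stack decomposes into stacked interiors plus a hairpin", {
  d <- decompose(parse_structure("((((....))))"))
  kinds <- vapply(d$loops, `[[`, "", "kind")
  expect_equal(sort(kinds), c("hairpin", rep("interior", 3)))
  hp <- d$loops[[which(kinds == "hairpin")]]
  expect_equal(unname(hp$arcs), rbind(c(4L, 9L)), ignore_attr = TRUE)
  expect_equal(hp$unpaired, 5:8)
})

test_that("the 18-mer pseudoknot decomposes per the loop-type rules", {
  d <- decompose(pk18)
  kinds <- vapply(d$loops, `[[`, "", "kind")
  expect_equal(sum(kinds == "interior"), 4L)
  expect_equal(sum(kinds == "pseudoknot"), 1L)
  pk <- d$loops[[which(kinds == "pseudoknot")]]
  expect_equal(unname(pk$arcs), rbind(c(3L, 11L), c(8L, 16L)),
               ignore_attr = TRUE)
  expect_equal(pk$unpaired, c(4L, 5L, 9L, 10L, 14L, 15L))
})

test_that("empty structures decompose to nothing", {
  d <- decompose(rna_structure(8, NULL))
  expect_length(d$loops, 0L)
  expect_equal(unname(d$intervals), rbind(c(1L, 8L)), ignore_attr = TRUE)
})

test_that("loops partition the arcs; pseudoknot loops satisfy P1", {
  for (seed in 1:100) {
    n <- 10L + (seed %% 31L)
    S <- draw_structure(n, seed)
    d <- decompose(S)
    owned <- 0L
    unp_all <- integer(0)
    for (lp in d$loops) {
      owned <- owned + if (lp$kind == "pseudoknot") nrow(lp$arcs) else 1L
      unp_all <- c(unp_all, lp$unpaired)
      if (lp$kind == "pseudoknot") {
        # dependency graph over the loop's arcs is connected
        adj <- pkinv:::.cross_matrix(lp$arcs)
        expect_equal(max(pkinv:::.components(adj)), 1L)
        # every member is a minimal beta-crossing arc for some beta
        for (q in seq_len(nrow(lp$arcs))) {
          alpha <- lp$arcs[q, ]
          betas <- crossing_set(S, alpha)
          ok <- any(vapply(seq_len(nrow(betas)), function(z)
            minimal_beta_crossing(S, alpha, betas[z, ]), logical(1)))
          expect_true(ok)
        }
      }
    }
    expect_equal(owned, nrow(S$arcs))
    expect_equal(anyDuplicated(unp_all), 0L)
  }
})

test_that("noncrossing structures contain no pseudoknot loops", {
  for (seed in 1:40) {
    S <- draw_structure(10L + (seed %% 31L), seed, pk = FALSE)
    kinds <- vapply(decompose(S)$loops, `[[`, "", "kind")
    expect_false(any(kinds == "pseudoknot"))
  }
})

test_that("loop order is a linear extension of nesting", {
  for (seed in 1:40) {
    S <- draw_structure(12L + (seed %% 29L), seed)
    loops <- decompose(S)$loops
    if (length(loops) < 2) next
    sp <- t(vapply(loops, `[[`, integer(2), "span_wide"))
    for (w in seq_len(length(loops) - 1L)) {
      for (h in (w + 1L):length(loops)) {
        # the later loop must not be strictly nested inside the earlier one
        strictly_nested <- sp[h, 1] >= sp[w, 1] && sp[h, 2] <= sp[w, 2] &&
          (sp[h, 1] > sp[w, 1] || sp[h, 2] < sp[w, 2])
        expect_false(strictly_nested)
      }
    }
  }
})

test_that("interval sequences end at [1, n] and never cut an arc", {
  expect_equal(unname(interval_sequence(parse_structure("((((....))))"))),
               rbind(c(1L, 12L)), ignore_attr = TRUE)
  expect_equal(unname(interval_sequence(parse_structure(":((((....)))):"))),
               rbind(c(2L, 13L), c(1L, 14L)), ignore_attr = TRUE)
  for (seed in 1:40) {
    n <- 12L + (seed %% 25L)
    S <- draw_structure(n, seed)
    iv <- interval_sequence(S)
    expect_equal(unname(iv[nrow(iv), ]), c(1L, n), ignore_attr = TRUE)
    a <- S$arcs
    for (q in seq_len(nrow(iv))) {
      inl <- a[, 1] >= iv[q, 1] & a[, 1] <= iv[q, 2]
      inr <- a[, 2] >= iv[q, 1] & a[, 2] <= iv[q, 2]
      expect_false(any(xor(inl, inr)))
    }
    # consecutive intervals grow: right ends are non-decreasing
    expect_true(all(diff(iv[, 2]) >= 0))
  }
})

test_that("two separated stems order by start point", {
  S <- parse_structure("::(((....)))::(((....))):")
  loops <- decompose(S)$loops
  sp <- t(vapply(loops, `[[`, integer(2), "span_wide"))
  expect_true(all(sp[which(sp[, 1] == 3)[1], 2] <=
                  sp[which(sp[, 1] == 15)[1], 2]))
  iv <- interval_sequence(S)
  expect_equal(unname(iv[1, ]), c(3L, 12L), ignore_attr = TRUE)
  expect_equal(unname(iv[nrow(iv), ]), c(1L, 25L), ignore_attr = TRUE)
})
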