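# Diagram model: parsing, writing, crossing analysis, stacks/stems,
# distance, pairing lookups, core and L-graph, file formats.

test_that("dot-bracket parsing matches hand bracket-matching", {
  S <- parse_structure("::::::")
  expect_equal(S$n, 6L)
  expect_equal(nrow(S$arcs), 0L)

  S <- parse_structure("((((....))))")
  expect_equal(unname(S$arcs),
               cbind(1:4, 12:9), ignore_attr = TRUE)

  S <- parse_structure("(((..[[[..)))..]]]")
  expect_equal(unname(S$arcs),
               rbind(c(1, 13), c(2, 12), c(3, 11),
                     c(6, 18), c(7, 17), c(8, 16)), ignore_attr = TRUE)
  expect_equal(crossing_number(S), 2L)
  st <- stacks_and_stems(S)
  expect_equal(vapply(st$stacks, nrow, integer(1)), c(3L, 3L))
})

test_that("parser reports unbalanced brackets and bad characters", {
  expect_error(parse_structure("(((..)"), "unbalanced")
  expect_error(parse_structure("..)..."), "unbalanced.*position 3")
  expect_error(parse_structure("..x..."), "illegal character")
  # whitespace is ignored on read
  expect_equal(parse_structure("(((( ....))))")$n, 12L)
})

test_that("validator names the violated invariant", {
  expect_error(rna_structure(10, rbind(c(1, 6), c(1, 8))),
               "more than one base", class = "pkinv_invalid_structure")
  expect_error(rna_structure(10, rbind(c(4, 5))), "i, i\\+1")
  expect_error(rna_structure(10, rbind(c(2, 5))), "arc-length")
  expect_error(rna_structure(12, rbind(c(1, 7), c(4, 9), c(5, 11)),
                             min_arc_length = 2),
               "mutually crossing")
  expect_error(rna_structure(12, rbind(c(1, 12), c(2, 11))),
               "stack of size 2")
  # empty structure is valid everywhere
  expect_silent(validate_structure(rna_structure(0, NULL)))
  expect_silent(validate_structure(rna_structure(7, NULL)))
})

test_that("write/parse round-trip is the identity on generated structures", {
  for (seed in 1:60) {
    n <- 9L + (seed %% 21L)
    S <- draw_structure(n, seed)
    txt <- write_structure(S)
    expect_equal(nchar(txt), n)
    S2 <- parse_structure(txt)
    expect_true(structures_identical(S, S2))
  }
})

test_that("crossing number matches the worked triple and brute force", {
  expect_equal(crossing_number(rbind(c(1, 7), c(4, 9), c(5, 11))), 3L)
  expect_equal(crossing_number(matrix(integer(0), ncol = 2)), 0L)
  expect_equal(crossing_number(rbind(c(1, 13), c(2, 12), c(3, 11),
                                     c(6, 18), c(7, 17), c(8, 16))), 2L)
})

test_that("crossing number agrees with independent maximum-clique search", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(8:14, 1)
    # random diagram with relaxed validation (degree <= 1 only)
    pos <- sample(n)
    m <- sample(0:(n %/% 2), 1)
    arcs <- NULL
    if (m > 0) {
      arcs <- t(apply(matrix(pos[seq_len(2 * m)], ncol = 2), 1, sort))
    }
    cn <- crossing_number(if (is.null(arcs)) matrix(integer(0), ncol = 2)
                          else arcs)
    if (is.null(arcs) || nrow(arcs) == 0) {
      expect_equal(cn, 0L)
    } else {
      adj <- pkinv:::.cross_matrix(arcs)
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      expect_equal(cn, igraph::clique_num(g))
      expect_equal(cn, brute_crossing(arcs))
    }
  }
})

test_that("stacks and stems follow the separation rule", {
  S <- parse_structure("((((....))))")
  st <- stacks_and_stems(S)
  expect_length(st$stacks, 1L)
  expect_equal(nrow(st$stacks[[1]]), 4L)
  expect_length(st$stems, 1L)

  # endpoints not adjacent on either side: two stacks of size 1, one stem
  S <- rna_structure(10, rbind(c(1, 10), c(3, 8)), validate = FALSE)
  st <- stacks_and_stems(S)
  expect_equal(vapply(st$stacks, nrow, integer(1)), c(1L, 1L))
  expect_false(is_sigma_canonical(S, sigma = 3))
  expect_length(st$stems, 1L)  # separated by unpaired on both sides

  # two crossing stems
  st <- stacks_and_stems(parse_structure("(((..[[[..)))..]]]"))
  expect_length(st$stems, 2L)
})

test_that("structure distance counts differently paired positions", {
  S <- parse_structure("((((....))))")
  expect_equal(structure_distance(S, S), 0L)
  S1 <- rna_structure(5, rbind(c(1, 5)), validate = FALSE)
  S2 <- rna_structure(5, NULL)
  expect_equal(structure_distance(S1, S2), 2L)
  S1 <- rna_structure(6, rbind(c(1, 5)), validate = FALSE)
  S3 <- rna_structure(6, rbind(c(1, 6)), validate = FALSE)
  expect_equal(structure_distance(S1, S3), 3L)
  expect_error(structure_distance(S1, S2), "different lengths")
})

test_that("structure distance is a metric (exhaustive for n <= 8)", {
  diags <- all_diagrams(8L)
  m <- length(diags)
  D <- matrix(0L, m, m)
  for (x in seq_len(m)) {
    for (y in seq_len(m)) D[x, y] <- structure_distance(diags[[x]],
                                                        diags[[y]])
  }
  expect_true(all(D >= 0))
  expect_equal(unname(diag(D)), rep(0L, m))
  # identity of indiscernibles
  expect_true(all((D == 0) == outer(seq_len(m), seq_len(m), function(x, y)
    mapply(function(a, b) structures_identical(diags[[a]], diags[[b]]),
           x, y))))
  expect_true(all(D == t(D)))
  # triangle inequality
  for (x in seq_len(m)) {
    expect_true(all(outer(D[x, ], D[x, ], `+`) >= D))
  }
})

test_that("pairing partner is an involution on paired positions", {
  S <- rna_structure(8, rbind(c(2, 7)), validate = FALSE)
  expect_equal(pairing_partner(S, 2), 7L)
  expect_equal(pairing_partner(S, 7), 2L)
  expect_equal(pairing_partner(S, 1), 0L)
  expect_error(pairing_partner(S, 9), "out of range")
  for (seed in 1:40) {
    S <- draw_structure(9L + (seed %% 16L), seed)
    pv <- pair_vector(S)
    paired <- which(pv != 0L)
    expect_equal(pv[pv[paired]], paired)
  }
})

test_that("core collapses stacks; L-graph records crossings", {
  S <- parse_structure("((((....))))")
  cl <- core_and_lgraph(S)
  expect_equal(nrow(cl$core$arcs), 1L)
  expect_false(any(cl$lgraph))

  S <- parse_structure("(((..[[[..)))..]]]")
  cl <- core_and_lgraph(S)
  expect_equal(nrow(cl$core$arcs), 2L)
  core_l <- core_and_lgraph(cl$core)$lgraph
  expect_equal(sum(core_l) / 2, 1)  # single edge: connected skeleton core

  # any noncrossing structure has an edgeless L-graph
  for (seed in 1:10) {
    S <- draw_structure(20L, seed, pk = FALSE)
    expect_false(any(core_and_lgraph(S)$lgraph))
  }
})

test_that("bpseq and CT files round-trip structures and sequences", {
  S <- parse_structure("(((..[[[..)))..]]]")
  s <- make_start(S, seed = 5)
  f1 <- tempfile(fileext = ".bpseq")
  write_bpseq(S, f1, sequence = s)
  got <- read_bpseq(f1)
  expect_true(structures_identical(got$structure, S))
  expect_equal(got$sequence, s)

  f2 <- tempfile(fileext = ".ct")
  write_ct(S, f2, sequence = s)
  got <- read_ct(f2)
  expect_true(structures_identical(got$structure, S))
  expect_equal(got$sequence, s)

  f3 <- tempfile(fileext = ".fasta")
  write_fasta_rna(c(one = s), f3)
  expect_equal(unname(read_fasta_rna(f3)), s)
})
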