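# Inverse-folding search: perturbation, competitor filtering, mutation,
# adjustment, local search, driver.

test_that("an interior arc has nine placements plus removal", {
  S <- parse_structure("((((....))))")
  out <- perturb_arc(S, c(2, 11))  # both endpoints away from the boundary
  expect_length(out, 10L)
  sizes <- vapply(out, function(x) nrow(x$arcs), integer(1))
  expect_equal(sum(sizes == nrow(S$arcs) - 1L), 1L)  # the removal
  expect_equal(sum(sizes == nrow(S$arcs)), 9L)

  # boundary clipping: arc (1, 5) in n = 5 keeps 2 x 2 placements + removal
  S5 <- rna_structure(5, rbind(c(1, 5)), validate = FALSE)
  out <- perturb_arc(S5, c(1, 5))
  expect_length(out, 5L)
  expect_error(perturb_arc(S5, c(2, 5)), "not an arc")
})

test_that("competitor sets drop inconsistent/incompatible/target members", {
  T <- parse_structure("((((....))))")
  s <- "GGGGAAAACCCC"
  fr <- fold(s, N = 10)
  C <- build_competitors(fr, s, T)
  expect_gt(C$size, 0L)
  tpv <- pair_vector(T)
  for (q in seq_len(C$size)) {
    pv <- C$pv[, q]
    # consistent by construction of the pair vector; not the target
    expect_false(identical(pv, tpv))
    arcs <- which(pv > seq_along(pv))
    # compatible with the current sequence
    v <- strsplit(s, "")[[1]]
    expect_true(all(mapply(function(l, r)
      pkinv:::.PAIR_OK[v[l], v[r]], arcs, pv[arcs])))
  }
  # no duplicates
  keys <- apply(C$pv, 2, paste, collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)

  # a perturbation creating a doubly paired position must be excluded:
  # candidate (1,12),(2,11) and shifting (2,11) to (1,11) collides with 1
  cand <- rna_structure(12, rbind(c(1, 12), c(2, 11)), validate = FALSE)
  C2 <- build_competitors(list(cand), "GGGGAAAACCCC", T)
  for (q in seq_len(C2$size)) {
    pv <- C2$pv[, q]
    arcs <- pkinv:::.pv_to_arcs(pv)
    expect_true(is_consistent(rna_structure(12, arcs, validate = FALSE)))
  }

  # a perturbation pairing A with G under the sequence is excluded
  s2 <- "GAAAAAAAAAAC"  # only (1, 12) can pair
  cand <- rna_structure(12, rbind(c(1, 12)), validate = FALSE)
  C3 <- build_competitors(list(cand), s2, rna_structure(12, NULL))
  v <- strsplit(s2, "")[[1]]
  for (q in seq_len(C3$size)) {
    arcs <- pkinv:::.pv_to_arcs(C3$pv[, q])
    if (nrow(arcs)) {
      expect_true(all(pkinv:::.PAIR_OK[cbind(v[arcs[, 1]], v[arcs[, 2]])]))
    }
  }
})

test_that("mutation leaves unconflicted sequences unchanged", {
  T <- parse_structure("((((....))))")
  C <- build_competitors(list(), "GGGGAAAACCCC", T)
  expect_equal(C$size, 0L)
  expect_equal(mutate_sequence("GGGGAAAACCCC", T, C), "GGGGAAAACCCC")
})

test_that("mutation breaks a competitor pairing while keeping the target", {
  # target arc (5, 9); a competitor pairs (5, 10) instead
  wx <- worked_examples()
  T <- wx$conflict_pair$target
  comp <- wx$conflict_pair$competitor
  s <- "AAAAAAAAUA"  # A-U on (5, 9), A at 10: competitor currently viable
  C <- structure(list(pv = matrix(pair_vector(comp), ncol = 1),
                      n = 10L, size = 1L,
                      provenance = data.frame()), class = "competitor_set")
  set.seed(4)
  for (rep in 1:20) {
    m <- mutate_sequence(s, T, C)
    expect_true(is_compatible(m, T))
    v <- strsplit(m, "")[[1]]
    # the redrawn pair differs from A-U and cannot bind the competitor's
    # partner base (the A at position 10 of the input sequence)
    expect_false(v[5] == "A" && v[9] == "U")
    expect_false(pkinv:::.PAIR_OK[v[5], "A"])
  }
})

test_that("a breaking choice exists for up to two competitor partners", {
  # competitors are compatible with the current sequence, so the partner
  # bases a position can face are limited to the (at most two) bases its
  # current base can pair; for every admissible current pair and every
  # such pair of partner bases, some admissible replacement pair breaks
  # both competitors
  pairs <- allowed_pairs()
  bases <- c("A", "C", "G", "U")
  for (q in seq_len(6)) {
    cur <- pairs[q, ]
    partners <- bases[pkinv:::.PAIR_OK[cur[1], ]]
    for (u1 in partners) {
      for (u2 in partners) {
        opts <- pairs[!(pairs[, 1] == cur[1] & pairs[, 2] == cur[2]), ,
                      drop = FALSE]
        breaking <- vapply(seq_len(nrow(opts)), function(z)
          !pkinv:::.PAIR_OK[opts[z, 1], u1] &&
          !pkinv:::.PAIR_OK[opts[z, 1], u2], logical(1))
        expect_true(any(breaking))
      }
    }
  }
})

test_that("sequence adjustment returns immediately on a solved start", {
  T <- parse_structure("((((....))))")
  s <- "GGGGAAAACCCC"
  expect_true(structures_identical(mfe_structure(fold(s)), T))
  got <- adjust_seq(s, T, search_config(seed = 1))
  expect_equal(got, s)
})

test_that("adjustment and local search conserve target compatibility", {
  for (seed in 1:6) {
    T <- draw_structure(14L + seed, seed)
    start <- make_start(T, seed = seed)
    adj <- adjust_seq(start, T, search_config(seed = seed))
    expect_true(is_compatible(adj, T))
    ls <- local_search(adj, T, cfg = search_config(seed = seed))
    expect_true(is_compatible(ls, T))
  }
})

test_that("with no uphill moves the local search never worsens the fold", {
  T <- parse_structure("(((:::[[[:::)))::]]]")
  cfg <- search_config(p_accept = 0, seed = 8, phase_max_factor = 3)
  start <- make_start(T, seed = 8)
  d0 <- structure_distance(mfe_structure(fold(start)), T)
  got <- local_search(start, T,
                      intervals = matrix(c(1L, T$n), ncol = 2), cfg = cfg)
  d1 <- structure_distance(mfe_structure(fold(got)), T)
  expect_lte(d1, d0)
})

test_that("local search returns solved sequences unchanged", {
  T <- parse_structure("((((....))))")
  s <- "GGGGAAAACCCC"
  expect_equal(local_search(s, T, cfg = search_config(seed = 2)), s)
})

test_that("inverse folding designs an empty target and a hairpin", {
  res <- inverse_fold(rna_structure(8, NULL), search_config(seed = 3))
  expect_true(res$success)
  expect_equal(nrow(mfe_structure(fold(res$sequence))$arcs), 0L)

  T <- parse_structure("((((....))))")
  res <- inverse_fold(T, search_config(seed = 1))
  expect_true(res$success)
  expect_true(structures_identical(mfe_structure(fold(res$sequence)), T))
})

test_that("success is certified by exhaustive re-enumeration", {
  T <- parse_structure("((((....))))")
  res <- inverse_fold(T, search_config(seed = 1))
  expect_true(res$success)
  s <- res$sequence
  es <- vapply(enumerate_structures(T$n), function(S)
    if (is_compatible(s, S)) energy(s, S) else Inf, numeric(1))
  expect_equal(energy(s, T), min(es))
})

test_that("a pseudoknotted target is designable", {
  T <- parse_structure("(((..[[[..)))..]]]")
  res <- inverse_fold(T, search_config(seed = 2))
  expect_true(res$success)
  kinds <- vapply(decompose(T)$loops, `[[`, "", "kind")
  expect_true("pseudoknot" %in% kinds)
})

test_that("identical target and seed reproduce the run exactly", {
  T <- parse_structure("(((..[[[..)))..]]]")
  r1 <- inverse_fold(T, search_config(seed = 7))
  r2 <- inverse_fold(T, search_config(seed = 7))
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$distance, r2$distance)
  expect_identical(r1$energy, r2$energy)
})

test_that("invalid targets are rejected before any search", {
  expect_error(inverse_fold("((..))"), class = "pkinv_invalid_structure")
})
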