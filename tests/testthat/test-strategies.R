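dm58 <- default_mixture("dm58")
bgd <- default_background()
tpr <- transition_priors()

test_that("cluster_sequences: duplicates, dissimilar sets, chaining", {
  set.seed(36)
  gen <- generate_planted_set(planted_spec(K = 4, dup = 3, flank_mean = 5))
  st <- state_from_msa(gen$truth, dm58, bgd, tpr)
  tightcl <- cluster_sequences(st, level = "tight")
  expect_equal(sort(lengths(lapply(tightcl, `[[`, "members"))), rep(3L, 4))
  expect_true(all(vapply(tightcl, `[[`, character(1), "kind") == "tight"))
  # every sequence in exactly one cluster at both levels
  for (lev in c("loose", "tight")) {
    cl <- cluster_sequences(st, level = lev)
    expect_equal(sort(unlist(lapply(cl, `[[`, "members"))), 1:st$K)
  }
  # all-dissimilar sequences -> singletons
  set.seed(37)
  rnd <- random_seq_set(6, 40)
  aln <- block_alignment(10L, matrix(5L, 6, 1), rep(40, 6))
  str <- block_to_hmm(aln, rnd, dm58, bgd, tpr)
  cl <- cluster_sequences(str, loose = 0.9)
  expect_equal(length(cl), 6L)
  # single-linkage chaining: a~b~c with a and c dissimilar
  seqs <- seq_set(c("a", "b", "c"), list(
    aa_encode("AAAAAAAAAA"), aa_encode("AAAAACCCCC"), aa_encode("CCCCCCCCCC")))
  stc <- msa_state(seqs, rep(list(1:10 * 1L), 3), 10L, dm58, bgd, tpr)
  cl2 <- cluster_sequences(stc, loose = 0.5)
  expect_equal(length(cl2), 1L)
  expect_equal(cl2[[1]]$members, 1:3)
})

test_that("consensus_sequence uses the weighted majority with ties to the
           alphabetically first residue", {
  seqs <- seq_set(c("a", "b", "c"),
                  list(aa_encode("ACD"), aa_encode("ACD"), aa_encode("CCD")))
  st <- msa_state(seqs, rep(list(c(1L, 2L, 3L)), 3), 3L, dm58, bgd, tpr)
  st$wstate$int <- rep(100L, 3)
  cons <- consensus_sequence(st, 1:3)
  expect_equal(cons$res, aa_encode("ACD"))
  # tie A vs C at equal weight -> 'A'
  seqs2 <- seq_set(c("a", "b"), list(aa_encode("AD"), aa_encode("CD")))
  st2 <- msa_state(seqs2, rep(list(c(1L, 2L)), 2), 2L, dm58, bgd, tpr)
  st2$wstate$int <- c(100L, 100L)
  expect_equal(consensus_sequence(st2, 1:2)$res, aa_encode("AD"))
  # loose cluster (different shapes) is rejected
  st3 <- st; st3$assigns[[2]] <- c(1L, 0L, 2L)
  expect_error(consensus_sequence(st3, 1:3), "tight")
})

test_that("consensus-template resampling aligns members identically and
           conserves residues", {
  set.seed(38)
  gen <- generate_planted_set(planted_spec(K = 5, dup = 4, flank_mean = 10))
  st <- state_from_msa(gen$truth, dm58, bgd, tpr)
  members <- which(startsWith(st$seqs$ids, "seq001"))
  expect_length(members, 4L)
  st2 <- resample_cluster_via_consensus(st, members, temperature = 0)
  expect_true(assert_state(st2))
  for (m in members[-1])
    expect_identical(st2$assigns[[m]], st2$assigns[[members[1]]])
  msa <- state_to_msa(st2)
  for (k in seq_len(st2$K))
    expect_identical(degap(msa$rows[k]), st2$seqs$seqs[[k]])
})

test_that("tandem group resampling: degenerate case, bookkeeping, guard", {
  set.seed(39)
  gen <- small_planted(seed = 39)
  st <- state_from_msa(gen$truth, dm58, bgd, tpr)
  expect_error(resample_group_tandem(st, seq_len(st$K)), "all sequences")
  # group of one at T=0 equals a deterministic single resample
  set.seed(5); a <- resample_group_tandem(st, 3L, temperature = 0)
  b <- gibbsmsa:::.realign_deterministic(st, 3L)
  expect_identical(a$assigns, b$assigns)
  st2 <- resample_group_tandem(st, c(2L, 4L, 7L), temperature = 0.5)
  expect_true(assert_state(st2))
})

test_that("group_by_shared_features finds congruent indels and minority
           residues", {
  set.seed(40)
  gen <- generate_planted_set(planted_spec(K = 50, ins_prob = 0,
                                           del_prob = 0, flank_mean = 20))
  st <- state_from_msa(gen$truth, dm58, bgd, tpr)
  # no indels, no minority residues in a fully conserved set: mostly empty;
  # plant a congruent insertion in 9 sequences at column 10
  assigns <- st$assigns
  seqs <- st$seqs
  newseqs <- seqs$seqs
  for (k in 1:9) {
    len <- sample(27:30, 1)
    p <- which(assigns[[k]] == 10L)
    newseqs[[k]] <- append(newseqs[[k]],
                           sample.int(20, len, TRUE), after = p)
    assigns[[k]] <- append(assigns[[k]], integer(len), after = p)
  }
  st2 <- msa_state(seq_set(seqs$ids, newseqs), assigns, st$w, dm58, bgd, tpr)
  groups <- group_by_shared_features(st2)
  expect_true(any(vapply(groups, function(g) setequal(g, 1:9), logical(1))))
  expect_true(all(lengths(groups) >= 2))
  expect_true(all(!vapply(groups, anyDuplicated, numeric(1))))
  # planted shared deletion run in 5 sequences (residues removed so the
  # paths stay legal: a stranded insert next to a deletion is forbidden)
  assigns3 <- st$assigns
  seqs3 <- st$seqs$seqs
  for (k in 11:15) {
    a <- assigns3[[k]]
    drop <- which(a %in% 20:22)
    seqs3[[k]] <- seqs3[[k]][-drop]
    assigns3[[k]] <- a[-drop]
  }
  st3 <- msa_state(seq_set(st$seqs$ids, seqs3), assigns3, st$w, dm58, bgd,
                   tpr)
  g3 <- group_by_shared_features(st3)
  expect_true(any(vapply(g3, function(g) setequal(g, 11:15), logical(1))))
})

test_that("purged_set_realign keeps membership and residue conservation", {
  set.seed(41)
  gen <- generate_planted_set(planted_spec(K = 6, dup = 3, flank_mean = 10))
  st <- state_from_msa(gen$truth, dm58, bgd, tpr)
  st2 <- purged_set_realign(st, temperature = 0)
  expect_true(assert_state(st2))
  expect_equal(st2$K, st$K)
  msa <- state_to_msa(st2)
  for (k in seq_len(st2$K))
    expect_identical(degap(msa$rows[k]), st2$seqs$seqs[[k]])
})

test_that("resample_worst_scoring ranks deterministically and tracks the
           emission decomposition", {
  set.seed(42)
  gen <- small_planted(seed = 42, K = 10)
  st <- state_from_msa(gen$truth, dm58, bgd, tpr)
  sc <- vapply(seq_len(st$K), function(k) seq_path_score(st, k), numeric(1))
  expect_true(all(is.finite(sc)))
  st2 <- resample_worst_scoring(st, fraction = 0.2, temperature = 0)
  expect_true(assert_state(st2))
  # fraction selecting one sequence resamples the argmin sequence
  worst <- which.min(sc)
  st3 <- resample_worst_scoring(st, fraction = 0.100001, temperature = 0)
  ref <- gibbsmsa:::.realign_deterministic(st, worst)
  expect_identical(st3$assigns[[worst]], ref$assigns[[worst]])
})

test_that("resample_random_subsets covers sequences and respects rounds", {
  set.seed(43)
  gen <- small_planted(seed = 43)
  st <- state_from_msa(gen$truth, dm58, bgd, tpr)
  expect_identical(resample_random_subsets(st, 2L, 0L)$assigns, st$assigns)
  seen <- integer(0)
  tracer <- st
  for (r in 1:60) {
    members <- sample.int(st$K, 2L)
    seen <- union(seen, members)
  }
  expect_setequal(seen, 1:st$K)            # coupon-collector style coverage
  st2 <- resample_random_subsets(st, 2L, 3L, temperature = 0.5)
  expect_true(assert_state(st2))
})

test_that("alignment_similarity: identity, disjoint, partial overlap", {
  m <- random_gapped_msa(4, 8, seed = 44)
  expect_equal(alignment_similarity(m, m), 1)
  # disjoint: no shared aligned pair
  a <- gapped_msa(c("x", "y"), c("ACd", "ACd"))
  b <- gapped_msa(c("x", "y"), c("acD", "acD"))
  expect_equal(alignment_similarity(a, b), 0)
  # hand-built 3-sequence case: benchmark has column pairs {ab, ac, bc};
  # test aligns only a-b
  bench <- gapped_msa(c("a", "b", "c"), c("A", "C", "D"))
  test <- gapped_msa(c("a", "b", "c"), c("A-", "C-", "-D"))
  expect_equal(sp_score(bench, test)$score, 1 / 3)
  expect_error(alignment_similarity(bench, gapped_msa("z", "A")),
               "different")
})

test_that("competitive selection degenerates to a single trajectory and
           conserves all sequences", {
  set.seed(45)
  gen <- generate_planted_set(planted_spec(K = 10, widths = c(10L, 8L),
                                           flank_mean = 12))
  msa <- competitive_selection(gen$seqs, pop = 1L, survivors = 1L,
                               p1 = phase1_config(patience = 2,
                                                  max_cycles = 8),
                               p2 = phase2_config(sweeps_per_temp = 1L,
                                                  patience = 2L,
                                                  max_final_sweeps = 5L))
  expect_setequal(msa$ids, gen$seqs$ids)
  ord <- match(gen$seqs$ids, msa$ids)
  for (k in seq_along(ord))
    expect_identical(degap(msa$rows[ord[k]]), gen$seqs$seqs[[k]])
})

test_that("population similarity ranking rejects a scrambled candidate", {
  set.seed(46)
  gen <- generate_planted_set(planted_spec(K = 5, ins_prob = 0,
                                           del_prob = 0, flank_mean = 10))
  base <- gen$truth
  # scrambled candidate: every sequence's alignment shifted two residues
  assigns <- msa_assignments(base)
  rows <- vapply(seq_along(assigns), function(k) {
    a <- assigns[[k]]
    a2 <- integer(length(a))
    nz <- which(a > 0)
    nz2 <- pmin(nz + 2L, length(a))
    keep <- !duplicated(nz2)
    a2[nz2[keep]] <- a[nz[keep]]
    gibbsmsa:::.state_row(gen$seqs$seqs[[k]], a2, base$w)
  }, character(1))
  scram <- gapped_msa(base$ids, rows)
  msas <- c(rep(list(base), 4), list(scram))
  sim <- gibbsmsa:::.population_similarity(msas)
  expect_equal(which.min(sim), 5L)
  expect_true(all(sim[1:4] > sim[5]))
})
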