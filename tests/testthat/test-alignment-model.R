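dm_unif <- dirichlet_mixture(1, matrix(1, 1, 20), "unif")

test_that("block_alignment enforces co-linearity", {
  expect_error(block_alignment(c(3, 2), cbind(c(1, 1), c(3, 2)), c(10, 10)),
               "overlap")
  expect_error(block_alignment(5, matrix(c(7, 1), 2), c(10, 10)), "past")
  a <- block_alignment(c(2, 2), cbind(c(1, 2), c(5, 6)), c(8, 8))
  expect_equal(aln_positions(a), cbind(c(1, 2), c(2, 3), c(5, 6), c(6, 7)))
})

test_that("integrated_block_llr: null, hand Gamma case, Polya oracle,
           permutation invariance", {
  bg <- default_background()
  s2 <- seq_set(c("a", "b"), list(aa_encode("A"), aa_encode("A")))
  a0 <- block_alignment(1, matrix(c(1, 1), 2), c(1, 1))
  expect_equal(integrated_block_llr(s2, a0, dm_unif, bg),
               log(1 / 210) - 2 * log(bg$theta0[1]))
  # random 5 x 8 single-block instances vs sequential predictive oracle
  set.seed(12)
  dm <- dirichlet_mixture(c(0.5, 0.5), rbind(rexp(20) + 0.3, rexp(20) + 0.3),
                          "t")
  for (rep in 1:5) {
    seqs <- random_seq_set(5, 8)
    aln <- block_alignment(8, matrix(1, 5), rep(8, 5))
    cm <- aln_col_matrix(aln, seqs)
    oracle <- sum(vapply(1:8, function(j) {
      log_polya_mix_oracle(cm[, j], dm) - sum(log(bg$theta0[cm[, j]]))
    }, numeric(1)))
    expect_equal(integrated_block_llr(seqs, aln, dm, bg), oracle,
                 tolerance = 1e-9)
    p <- sample.int(5)
    seqs_p <- seq_set(seqs$ids[p], seqs$seqs[p])
    expect_equal(integrated_block_llr(seqs_p, aln, dm, bg),
                 integrated_block_llr(seqs, aln, dm, bg))
  }
  expect_equal(integrated_block_llr(s2,
    structure(list(widths = integer(0), starts = matrix(0, 2, 0), w = 0L),
              class = "block_alignment"), dm_unif, bg), 0)
})

test_that("predictive placement: dominant residue, uniform model, forced", {
  bg <- default_background()
  # width-1 block, theta concentrated on C, sequence ACA
  th <- matrix((1 - 0.9) / 19, 20, 1); th[2, 1] <- 0.9
  pd <- predictive_placement_distribution(aa_encode("ACA"), 1L, th, bg)
  probs <- vapply(1:3, function(s) placement_prob(pd, s), numeric(1))
  expect_equal(which.max(probs), 2L)
  expect_equal(sum(probs), 1)
  # theta = theta0 -> uniform over feasible placements
  th0 <- matrix(bg$theta0, 20, 1)
  pd0 <- predictive_placement_distribution(aa_encode("ACAD"), 1L, th0, bg)
  expect_equal(vapply(1:4, function(s) placement_prob(pd0, s), numeric(1)),
               rep(0.25, 4))
  # two blocks 2+2 in length 4: exactly one placement, probability 1
  th4 <- matrix(bg$theta0, 20, 4)
  pd4 <- predictive_placement_distribution(aa_encode("ACDE"), c(2L, 2L),
                                           th4, bg)
  expect_equal(placement_prob(pd4, c(1, 3)), 1)
  expect_equal(sample_placement(pd4), c(1L, 3L))
  expect_error(predictive_placement_distribution(aa_encode("AC"), c(2L, 2L),
                                                 th4, bg), "shorter")
})

test_that("count_transitions matches hand traces and is weight-linear", {
  # K identical gapless paths
  assigns <- rep(list(c(1L, 2L, 3L)), 4)
  tc <- count_transitions(assigns, 3L)
  expect_equal(unname(tc["mm", ]), rep(4, 4))
  expect_equal(sum(tc) - sum(tc["mm", ]), 0)
  # length-2 insertion after column 1 (w = 2)
  tc2 <- count_transitions(list(c(1L, 0L, 0L, 2L)), 2L)
  expect_equal(unname(tc2[c("mi", "ii", "im"), 2]), c(1, 1, 1))
  expect_equal(unname(tc2["mm", c(1, 3)]), c(1, 1))
  # weights halve counts
  expect_equal(count_transitions(assigns, 3L, rep(50L, 4)), tc / 2)
  # deletions: columns 2 missing -> md then dm
  tc3 <- count_transitions(list(c(1L, 3L))  , 3L)
  expect_equal(unname(tc3["md", 2]), 1)
  expect_equal(unname(tc3["dm", 3]), 1)
  # illegal path: insert adjacent to deletion
  expect_error(count_transitions(list(c(1L, 0L, 3L)), 3L), "sequence 1")
})

test_that("transition point estimates are posterior means", {
  tc <- empty_tc(1)
  pe <- transition_point_estimates(tc, transition_priors(nmm = 8, nmi = 1,
                                                         nmd = 1))
  expect_equal(unname(pe["io", 1]), 0.1)
  expect_equal(unname(pe["do", 1]), 0.1)
  tc["mi", 1] <- 2; tc["mm", 1] <- 6
  pe2 <- transition_point_estimates(tc, transition_priors(1, 1, 1, 1, 1, 1, 1))
  expect_equal(unname(pe2["io", 1]), 3 / 11)
  expect_equal(unname(pe2["do", 1]), 1 / 11)
  # counts -> infinity: estimates approach empirical frequencies
  tc["mm", 1] <- 6e7; tc["mi", 1] <- 2e7; tc["md", 1] <- 2e7
  pe3 <- transition_point_estimates(tc, transition_priors())
  expect_equal(unname(pe3["io", 1]), 0.2, tolerance = 1e-6)
  expect_equal(unname(pe3["do", 1]), 0.2, tolerance = 1e-6)
  # open probabilities sum below 1 everywhere
  set.seed(14)
  tcr <- matrix(rexp(14), 7, 2, dimnames = list(TC_ROWS, NULL))
  per <- transition_point_estimates(tcr, transition_priors())
  expect_true(all(per["io", ] + per["do", ] < 1))
  expect_true(all(per > 0 & per < 1))
})

test_that("sampled transition probabilities match their Beta laws", {
  set.seed(15)
  tc <- empty_tc(0)
  tc["dd", 1] <- 3; tc["dm", 1] <- 5
  pr <- transition_priors(1, 1, 1, 1, 1, 1, 1)
  de <- replicate(1e5, sample_transition_probabilities(tc, pr)["de", 1])
  expect_lt(abs(mean(de) - 0.4), 3 * sd(de) / sqrt(1e5))
  # with zero counts the draws follow the prior (KS test)
  tc0 <- empty_tc(0)
  pr2 <- transition_priors(nmm = 18, nmi = 1, nmd = 1)
  do_ <- replicate(4e3, sample_transition_probabilities(tc0, pr2)["do", 1])
  ks <- suppressWarnings(stats::ks.test(do_, stats::pbeta, 1, 19))
  expect_gt(ks$p.value, 0.01)
  # io + do < 1 always; fixed seed reproducibility
  draws <- replicate(200, sample_transition_probabilities(tc, pr))
  expect_true(all(draws["io", , ] + draws["do", , ] < 1))
  set.seed(5); a <- sample_transition_probabilities(tc, pr)
  set.seed(5); b <- sample_transition_probabilities(tc, pr)
  expect_identical(a, b)
})

test_that("integrated transition loglike: zero, hand Gamma algebra, MC", {
  pr1 <- transition_priors(1, 1, 1, 1, 1, 1, 1)
  expect_equal(integrated_transition_loglike(empty_tc(2), pr1), 0)
  tc <- empty_tc(0); tc["mm", 1] <- 2; tc["mi", 1] <- 1
  expect_equal(integrated_transition_loglike(tc, pr1), log(1 / 30))
  # Monte-Carlo integration of h(Lambda | iota, delta) over the prior
  set.seed(16)
  n <- 4e5
  io_do <- matrix(rgamma(3 * n, 1), ncol = 3)       # Dirichlet(1,1,1)
  io_do <- io_do / rowSums(io_do)                   # (mi, md, mm)
  h <- io_do[, 1]^1 * io_do[, 3]^2                  # Nmi=1, Nmm=2
  mc <- log(mean(h))
  se_log <- sd(h) / mean(h) / sqrt(n)
  expect_lt(abs(integrated_transition_loglike(tc, pr1) - mc), 3 * se_log)
})

test_that("block_to_hmm builds insert runs, flanks and conserves residues", {
  set.seed(17)
  # 2 blocks (3+2), one sequence with 4 residues between blocks
  seqs <- seq_set(c("a", "b"),
                  list(sample.int(20, 12, TRUE), sample.int(20, 9, TRUE)))
  aln <- block_alignment(c(3, 2), cbind(c(2, 1), c(9, 5)), c(12, 9))
  st <- block_to_hmm(aln, seqs, dm_unif, default_background())
  # sequence a: M1 M2 M3, 4 inserts at column 3, M4 M5
  expect_equal(st$assigns[[1]], c(0L, 1L, 2L, 3L, 0L, 0L, 0L, 0L, 4L, 5L,
                                  0L, 0L))
  # both sequences open an insert at column 3 (a: run 4, b: run 1)
  wA <- st$wstate$int[1] / 100; wB <- st$wstate$int[2] / 100
  expect_equal(unname(st$tc[c("mi", "ii", "im"), 4]),
               c(wA + wB, 3 * wA, wA + wB))
  # no delete states in initial paths
  expect_equal(sum(st$tc[c("md", "dd", "dm"), ]), 0)
  # residue conservation through the gapped MSA
  msa <- state_to_msa(st)
  for (k in 1:2) expect_identical(degap(msa$rows[k]), seqs$seqs[[k]])
})

test_that("joint score decomposes and is additive over independent columns", {
  gen <- small_planted(seed = 18)
  st <- state_from_msa(gen$truth, default_mixture("dm20"),
                       default_background(), transition_priors())
  g <- joint_score(st)
  emis <- sum(gibbsmsa:::.bild_scores(st$h, st$dm, st$bg))
  trans <- integrated_transition_loglike(st$tc, st$tpriors)
  expect_equal(g, emis + trans)
  # emission term is the sum of independent per-column BILD scores
  expect_equal(emis, sum(vapply(seq_len(st$w), function(j)
    bild_score(st$h[, j], st$dm, st$bg), numeric(1))))
})
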