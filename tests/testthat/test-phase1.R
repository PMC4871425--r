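dm20 <- default_mixture("dm20")
bgd <- default_background()

test_that("init_random_blocks: forced placements and uniform start offsets", {
  set.seed(22)
  s10 <- random_seq_set(2, 10)
  cfg <- phase1_config(min_width = 10, max_width = 10)
  a <- init_random_blocks(s10, cfg)
  expect_equal(a$starts, matrix(1L, 2, 1))
  expect_equal(aln_positions(a)[1, ], 1:10)
  # widths summing to the shortest length -> single feasible placement
  expect_error(init_random_blocks(random_seq_set(2, 3), cfg), "minimum block")
  # one width-5 block in a length-20 sequence: 16 offsets, all hit,
  # frequencies uniform within 4 SD of binomial(8000, 1/16)
  hits <- replicate(8000, gibbsmsa:::.uniform_placement(20L, 5L))
  tab <- table(factor(hits, levels = 1:16))
  expect_true(all(tab > 0))
  expect_true(all(abs(tab - 500) < 4 * sqrt(8000 * (1 / 16) * (15 / 16))))
})

test_that("uniform placements of multiple blocks are feasible and uniform", {
  set.seed(23)
  for (i in 1:200) {
    widths <- sample(2:4, sample(1:3, 1), replace = TRUE)
    n <- sum(widths) + sample(0:5, 1)
    st <- gibbsmsa:::.uniform_placement(n, widths)
    expect_true(all(diff(c(st, n + 1)) >= c(widths)))
    expect_gte(st[1], 1)
  }
})

test_that("resample_sequence_blocks recovers a planted motif at T=0", {
  set.seed(24)
  gen <- generate_planted_set(planted_spec(K = 12, widths = 15L,
                                           ins_prob = 0, del_prob = 0,
                                           flank_mean = 20))
  truth_starts <- vapply(msa_assignments(gen$truth), function(a)
    which(a == 1L), integer(1))
  aln <- block_alignment(15L, matrix(truth_starts, ncol = 1),
                         lengths(gen$seqs$seqs))
  Wt <- rep(100L, 12)
  llr0 <- integrated_block_llr(gen$seqs, aln, dm20, bgd, Wt)
  for (k in 1:12) {
    a2 <- resample_sequence_blocks(aln, gen$seqs, k, dm20, bgd, Wt,
                                   temperature = 0)
    expect_equal(a2$starts[k, 1], truth_starts[k])
  }
  # resampling into the same position leaves the LLR unchanged
  expect_equal(integrated_block_llr(gen$seqs, aln, dm20, bgd, Wt), llr0)
  # T=1 with a flat model: placements uniform (chi-squared)
  s1 <- random_seq_set(3, 24)
  fa <- block_alignment(5L, matrix(10L, 3, 1), rep(24, 3))
  th0 <- matrix(bgd$theta0, 20, 5)
  pd <- predictive_placement_distribution(s1$seqs[[1]], 5L, th0, bgd, 1)
  draws <- replicate(5000, sample_placement(pd)[1])
  tab <- table(factor(draws, levels = 1:20))
  chi <- sum((tab - 250)^2 / 250)
  expect_gt(stats::pchisq(chi, df = 19, lower.tail = FALSE), 0.01)
})

test_that("edge-column moves respect preconditions and the LLR delta", {
  set.seed(25)
  # conserved flanking column: all sequences share 'W' next to the block
  K <- 10
  seqs <- seq_set(paste0("s", 1:K), lapply(1:K, function(k) {
    c(sample.int(20, 5, TRUE), aa_encode("W"),
      sample.int(20, 3, TRUE) , sample.int(20, 5, TRUE))
  }))
  aln <- block_alignment(3L, matrix(7L, K, 1), lengths(seqs$seqs))
  grown <- sample_edge_column(aln, seqs, 1, "left", dm20, bgd,
                              temperature = 0, action = "add")
  expect_equal(grown$widths, 4L)           # pure-W column accepted at T=0
  expect_equal(grown$w, 4L)
  # at T=0 removing the conserved column is refused (delta < 0)
  keep <- sample_edge_column(grown, seqs, 1, "left", dm20, bgd,
                             temperature = 0, action = "remove")
  expect_equal(keep$widths, grown$widths)
  # removing (at high temperature every delta is accepted) and re-adding
  # the same column restores the identical alignment
  removed <- sample_edge_column(grown, seqs, 1, "left", dm20, bgd,
                                temperature = 1e9, action = "remove")
  expect_equal(removed$starts, aln$starts)
  expect_equal(removed$widths, aln$widths)
  back <- sample_edge_column(removed, seqs, 1, "left", dm20, bgd,
                             temperature = 0, action = "add")
  expect_equal(back$starts, grown$starts)
  expect_equal(back$widths, grown$widths)
  # add blocked at the sequence boundary
  atedge <- block_alignment(3L, matrix(1L, K, 1), lengths(seqs$seqs))
  expect_identical(sample_edge_column(atedge, seqs, 1, "left", dm20, bgd,
                                      temperature = 0, action = "add"),
                   atedge)
  # remove refused for width-1 blocks
  w1 <- block_alignment(1L, matrix(7L, K, 1), lengths(seqs$seqs))
  expect_identical(sample_edge_column(w1, seqs, 1, "right", dm20, bgd,
                                      temperature = 0, action = "remove"), w1)
})

test_that("block in/out moves follow the integrated-LLR delta at T=0", {
  set.seed(26)
  gen <- generate_planted_set(planted_spec(K = 10, widths = 10L,
                                           ins_prob = 0, del_prob = 0,
                                           flank_mean = 30))
  truth_starts <- vapply(msa_assignments(gen$truth), function(a)
    which(a == 1L), integer(1))
  # extend every sequence with background residues so a decoy block fits
  seqs <- seq_set(gen$seqs$ids, lapply(gen$seqs$seqs, function(r)
    c(r, sample.int(20, 15, TRUE, prob = bgd$theta0))))
  gen$seqs <- seqs
  nk <- lengths(gen$seqs$seqs)
  # conserved block + a pure-background block: background block removed
  bg_starts <- nk - 8L
  aln2 <- block_alignment(c(10L, 5L), cbind(truth_starts, bg_starts), nk)
  out <- sample_block_in_out(aln2, gen$seqs, dm20, bgd, temperature = 0,
                             action = "remove")
  done <- FALSE
  for (i in 1:20) {           # removal picks a block uniformly; iterate
    out <- sample_block_in_out(out, gen$seqs, dm20, bgd, temperature = 0,
                               action = "remove")
    if (length(out$widths) == 1L) { done <- TRUE; break }
  }
  expect_true(done)
  expect_equal(out$widths, 10L)            # the conserved block survives
  expect_equal(out$starts[, 1], truth_starts)
})

test_that("run_phase1 improves monotonically and stops on patience", {
  set.seed(27)
  gen <- generate_planted_set(planted_spec(K = 15, widths = 20L,
                                           ins_prob = 0, del_prob = 0,
                                           flank_mean = 25))
  aln <- run_phase1(gen$seqs, phase1_config(patience = 3, max_cycles = 25),
                    dm20, bgd)
  tr <- attr(aln, "trace")
  expect_true(all(diff(tr) >= 0))          # best-LLR trace non-decreasing
  expect_gt(attr(aln, "llr"), 0)
  # strong planted signal: recovered columns overlap the truth
  truth_pos <- lapply(msa_assignments(gen$truth), function(a) which(a > 0))
  rec_pos <- aln_positions(aln)
  overlap <- mean(vapply(1:15, function(k)
    mean(rec_pos[k, ] %in% truth_pos[[k]]), numeric(1)))
  expect_gt(overlap, 0.6)
})

test_that("edge-column moves satisfy detailed balance on a two-state toy", {
  set.seed(55)
  # toy: one block whose left neighbour column has a fixed LLR delta;
  # at T=1 the chain over {in, out} must reach occupancy e^d / (1 + e^d)
  K <- 6
  seqs <- seq_set(paste0("s", 1:K), lapply(1:K, function(k)
    c(aa_encode("L"), sample.int(20, 4, TRUE))))
  aln_out <- block_alignment(3L, matrix(2L, K, 1), lengths(seqs$seqs))
  d <- bild_score(count_residues(rep(aa_encode("L"), K)),
                  default_mixture("dm20"), bgd)
  cur <- aln_out
  inside <- logical(3000)
  for (i in seq_along(inside)) {
    cur <- sample_edge_column(cur, seqs, 1, "left", default_mixture("dm20"),
                              bgd, temperature = 1)
    inside[i] <- cur$widths[1] == 4L
  }
  target <- exp(d) / (1 + exp(d))
  expect_lt(abs(mean(inside[-(1:200)]) - target), 0.05)
})
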