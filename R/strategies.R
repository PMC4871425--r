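# ---------------------------------------------------------------------------
# Correlated-sequence escape strategies.  Clusters of similar sequences
# bias single-sequence Gibbs moves toward recurring misalignment; these
# moves remove and resample whole groups in tandem.

# sampled (T > 0) or posterior-mean (T = 0) HMM parameters of a state
.hmm_params <- function(state, temperature) {
  h <- pmax(state$h, 0)
  theta <- if (temperature > 0) .sample_emission_matrix(h, state$dm)
  else .posterior_mean_matrix(h, state$dm)
  tpe <- transition_point_estimates(pmax(state$tc, 0), state$tpriors)
  list(theta = theta, tpe = tpe)
}

# pairwise percent identity over the current match columns
.pairwise_identity <- function(state) {
  cm <- state_col_matrix(state)
  K <- state$K
  id <- matrix(1, K, K)
  for (k in seq_len(K - 1L)) for (l in (k + 1L):K) {
    both <- !is.na(cm[k, ]) & !is.na(cm[l, ])
    id[k, l] <- id[l, k] <- if (any(both))
      sum(cm[k, both] == cm[l, both]) / sum(both) else 0
  }
  id
}

#' Cluster sequences by alignment identity
#'
#' Single-linkage clustering on percent identity measured over the
#' current alignment's match columns.  At `level = "loose"` clusters
#' chain at the `loose` threshold (used for purged-set realignment and
#' representative picking); a loose cluster is flagged `tight` when its
#' members also share identical gap patterns (their mutual alignment
#' lacks indels) and chain at the `tight` threshold.  At
#' `level = "tight"` the partition is into tight clusters directly:
#' sequences are first grouped by identical alignment shape, then
#' single-linked at the `tight` threshold (used for consensus-template
#' moves).
#'
#' @param state an `msa_state`.
#' @param tight,loose identity thresholds in (0, 1], `tight >= loose`.
#' @param level `"loose"` or `"tight"`.
#' @return list of clusters, each `list(members, kind)`; every sequence
#'   is in exactly one cluster.
#' @export
cluster_sequences <- function(state, tight = 0.95, loose = 0.40,
                              level = c("loose", "tight")) {
  stopifnot(tight >= loose, loose > 0, tight <= 1)
  level <- match.arg(level)
  K <- state$K
  if (K == 1L) return(list(list(members = 1L, kind = "tight")))
  id <- .pairwise_identity(state)
  if (level == "loose") {
    hc <- hclust(as.dist(1 - id), method = "single")
    grp <- cutree(hc, h = 1 - loose + 1e-9)
    return(lapply(unique(grp), function(g) {
      members <- which(grp == g)
      kind <- "loose"
      if (length(members) == 1L) kind <- "tight"
      else {
        shapes <- vapply(members, function(k)
          paste(state$assigns[[k]], collapse = ","), character(1L))
        if (length(unique(shapes)) == 1L &&
            min(id[members, members]) >= tight)
          kind <- "tight"
      }
      list(members = members, kind = kind)
    }))
  }
  # tight partition: identical shapes, then single linkage at `tight`
  shapes <- vapply(seq_len(K), function(k)
    paste(length(state$seqs$seqs[[k]]), paste(state$assigns[[k]],
                                              collapse = ","), sep = ";"),
    character(1L))
  out <- list()
  for (sh in unique(shapes)) {
    members <- which(shapes == sh)
    if (length(members) == 1L) {
      out <- c(out, list(list(members = members, kind = "tight")))
    } else {
      sub <- id[members, members, drop = FALSE]
      hc <- hclust(as.dist(1 - sub), method = "single")
      grp <- cutree(hc, h = 1 - tight + 1e-9)
      for (g in unique(grp))
        out <- c(out, list(list(members = members[grp == g],
                                kind = "tight")))
    }
  }
  out
}

#' Consensus sequence of a tight cluster
#'
#' Members of a tight cluster share one alignment shape; the consensus
#' carries, at every residue position, the weighted-majority residue
#' (ties resolved to the alphabetically first residue).
#'
#' @param state an `msa_state`.
#' @param members indices of a tight cluster.
#' @return list with `res` (integer codes) and `assign` (shared shape).
#' @export
consensus_sequence <- function(state, members) {
  shapes <- vapply(members, function(k)
    paste(state$assigns[[k]], collapse = ","), character(1L))
  if (length(unique(shapes)) != 1L)
    stop("consensus requires a tight cluster (identical gap patterns)")
  wt <- state$wstate$int[members] / 100
  n <- length(state$seqs$seqs[[members[1L]]])
  res <- integer(n)
  for (i in seq_len(n)) {
    counts <- numeric(20L)
    for (m in seq_along(members)) {
      r <- state$seqs$seqs[[members[m]]][i]
      if (!is.na(r)) counts[r] <- counts[r] + wt[m]
    }
    res[i] <- if (all(counts == 0)) NA_integer_ else which.max(counts)
  }
  list(res = res, assign = state$assigns[[members[1L]]])
}

# remove a set of sequences from the counts
.remove_group <- function(state, members) {
  for (k in members) state <- .state_remove_seq(state, k)
  state
}

#' Resample a tight cluster through its consensus template
#'
#' Removes all cluster members from the counts, aligns the cluster
#' consensus sequence to the sampled HMM, and places every member back
#' with the consensus path (members share the consensus gap pattern).
#'
#' @param state an `msa_state`.
#' @param members tight-cluster member indices.
#' @param temperature sampling temperature.
#' @return updated state.
#' @export
resample_cluster_via_consensus <- function(state, members, temperature = 0) {
  if (state$w == 0L || length(members) >= state$K) return(state)
  cons <- consensus_sequence(state, members)
  st <- .remove_group(state, members)
  par <- .hmm_params(st, temperature)
  a <- align_sequence_to_hmm(cons$res, par$theta, par$tpe, st$bg, temperature)
  for (k in members) st <- .state_add_seq(st, k, a)
  st
}

#' Remove and resample a group of sequences in tandem
#'
#' All members are removed from the counts first (so the model is free
#' of the group's joint bias), then realigned one at a time, each
#' realignment updating the counts before the next.
#'
#' @param state an `msa_state`.
#' @param members group indices (`length(members) < K`).
#' @param temperature sampling temperature.
#' @return updated state.
#' @export
resample_group_tandem <- function(state, members, temperature = 0) {
  if (length(members) >= state$K)
    stop("cannot remove all sequences from the model")
  if (state$w == 0L) return(state)
  st <- .remove_group(state, members)
  for (k in members) {
    par <- .hmm_params(st, temperature)
    a <- align_sequence_to_hmm(st$seqs$seqs[[k]], par$theta, par$tpe, st$bg,
                               temperature)
    st <- .state_add_seq(st, k, a)
  }
  st
}

#' Groups of sequences sharing indel or residue features
#'
#' Candidate escape groups: (a) sequences sharing an insertion of
#' similar length (within 20%) at the same position; (b) sequences
#' sharing an identical deletion run; (c) sequences sharing the same
#' minority residue (weighted frequency < 25%) in a positively scoring
#' (BILD > 0) column.  Groups have at least two members.
#'
#' @param state an `msa_state`.
#' @return list of integer member vectors (deduplicated).
#' @export
group_by_shared_features <- function(state) {
  groups <- list()
  if (state$w == 0L) return(groups)
  ir <- .insert_runs(state)
  # (a) congruent insertions
  for (j in seq_len(max(state$w - 1L, 0L))) {
    have <- which(ir$runs[, j + 1L] > 0L)
    if (length(have) < 2L) next
    len <- ir$runs[have, j + 1L]
    ord <- order(len)
    cur <- have[ord[1L]]; curmin <- len[ord[1L]]
    for (t in seq_along(ord)[-1L]) {
      if (len[ord[t]] <= 1.2 * curmin) cur <- c(cur, have[ord[t]])
      else {
        if (length(cur) >= 2L) groups <- c(groups, list(sort(cur)))
        cur <- have[ord[t]]; curmin <- len[ord[t]]
      }
    }
    if (length(cur) >= 2L) groups <- c(groups, list(sort(cur)))
  }
  # (b) shared deletion runs
  delkey <- lapply(seq_len(state$K), function(k) {
    cols <- sort(state$assigns[[k]][state$assigns[[k]] > 0L])
    if (length(cols) < 2L) return(character(0))
    missing <- setdiff(seq(cols[1L], cols[length(cols)]), cols)
    if (!length(missing)) return(character(0))
    br <- c(0L, which(diff(missing) > 1L), length(missing))
    vapply(seq_len(length(br) - 1L), function(i) {
      run <- missing[(br[i] + 1L):br[i + 1L]]
      paste0(run[1L], "-", run[length(run)])
    }, character(1L))
  })
  allkeys <- unique(unlist(delkey))
  for (key in allkeys) {
    members <- which(vapply(delkey, function(x) key %in% x, logical(1L)))
    if (length(members) >= 2L) groups <- c(groups, list(sort(members)))
  }
  # (c) shared minority residues in supported columns
  bs <- .bild_scores(state$h, state$dm, state$bg)
  cm <- state_col_matrix(state)
  wt <- state$wstate$int / 100
  for (j in which(bs > 0)) {
    cj <- cm[, j]
    tot <- sum(wt[!is.na(cj)])
    if (tot == 0) next
    for (a in unique(cj[!is.na(cj)])) {
      members <- which(!is.na(cj) & cj == a)
      if (length(members) >= 2L && sum(wt[members]) / tot < 0.25)
        groups <- c(groups, list(sort(members)))
    }
  }
  unique(groups[lengths(groups) < state$K])
}

# weighted per-column majority consensus over match columns
.cluster_column_consensus <- function(state, members) {
  cm <- state_col_matrix(state)[members, , drop = FALSE]
  wt <- state$wstate$int[members] / 100
  vapply(seq_len(state$w), function(j) {
    counts <- numeric(20L)
    for (m in seq_along(members)) {
      r <- cm[m, j]
      if (!is.na(r)) counts[r] <- counts[r] + wt[m]
    }
    if (all(counts == 0)) NA_integer_ else which.max(counts)
  }, integer(1L))
}

#' Realign using a purged (representative) sequence set
#'
#' Groups all sequences into loose clusters, retains only the one
#' sequence per cluster closest to the cluster's column consensus
#' (fewest mismatches over match columns, ties to the lowest index),
#' realigns the retained representatives by sampling, then resamples
#' the originally excluded sequences back into the alignment.
#'
#' @param state an `msa_state`.
#' @param temperature sampling temperature.
#' @param tight,loose clustering thresholds.
#' @return updated state.
#' @export
purged_set_realign <- function(state, temperature = 0, tight = 0.95,
                               loose = 0.40) {
  if (state$w == 0L) return(state)
  clusters <- cluster_sequences(state, tight, loose)
  reps <- vapply(clusters, function(cl) {
    if (length(cl$members) == 1L) return(cl$members)
    cons <- .cluster_column_consensus(state, cl$members)
    cm <- state_col_matrix(state)[cl$members, , drop = FALSE]
    mism <- vapply(seq_along(cl$members), function(m) {
      sum(is.na(cm[m, ]) | is.na(cons) | cm[m, ] != cons)
    }, numeric(1L))
    cl$members[which.min(mism)]
  }, integer(1L))
  excluded <- setdiff(seq_len(state$K), reps)
  if (!length(excluded)) {
    for (k in reps[sample.int(length(reps))]) state <- resample_sequence(state, k, temperature)
    return(state)
  }
  st <- .remove_group(state, excluded)
  for (k in reps[sample.int(length(reps))]) {
    st <- .state_remove_seq(st, k)
    par <- .hmm_params(st, temperature)
    a <- align_sequence_to_hmm(st$seqs$seqs[[k]], par$theta, par$tpe, st$bg,
                               temperature)
    st <- .state_add_seq(st, k, a)
  }
  for (k in excluded) {
    par <- .hmm_params(st, temperature)
    a <- align_sequence_to_hmm(st$seqs$seqs[[k]], par$theta, par$tpe, st$bg,
                               temperature)
    st <- .state_add_seq(st, k, a)
  }
  st
}

#' Resample the worst-scoring sequences in tandem
#'
#' Ranks sequences by their per-sequence log-odds contribution (path
#' emission log-odds plus path transition log-probability) and applies
#' [resample_group_tandem()] to the bottom fraction; ties rank the
#' lowest index first.
#'
#' @param state an `msa_state`.
#' @param fraction fraction of sequences to resample, in (0, 1).
#' @param temperature sampling temperature.
#' @return updated state.
#' @export
resample_worst_scoring <- function(state, fraction = 0.1, temperature = 0) {
  stopifnot(fraction > 0, fraction < 1)
  if (state$w == 0L) return(state)
  theta <- .posterior_mean_matrix(pmax(state$h, 0), state$dm)
  tpe <- transition_point_estimates(pmax(state$tc, 0), state$tpriors)
  sc <- vapply(seq_len(state$K), function(k)
    .seq_path_score(state, k, theta, tpe), numeric(1L))
  nsel <- max(1L, min(state$K - 1L, floor(fraction * state$K)))
  worst <- order(sc, seq_len(state$K))[seq_len(nsel)]
  resample_group_tandem(state, worst, temperature)
}

#' Resample random sequence subsets in tandem
#'
#' @param state an `msa_state`.
#' @param subset_size subset size (`< K`).
#' @param rounds number of tandem rounds.
#' @param temperature sampling temperature.
#' @return updated state.
#' @export
resample_random_subsets <- function(state, subset_size = NULL, rounds = 5L,
                                    temperature = 0) {
  if (is.null(subset_size)) subset_size <- max(1L, ceiling(state$K / 10))
  stopifnot(subset_size < state$K)
  if (state$w == 0L) return(state)
  for (r in seq_len(rounds)) {
    members <- sample.int(state$K, subset_size)
    state <- resample_group_tandem(state, members, temperature)
  }
  state
}

#' Symmetric sum-of-pairs similarity between two alignments
#'
#' Fraction of residue pairs aligned in `a` that are also aligned in
#' `b`, averaged with the reverse direction; 1 for identical
#' alignments, 0 when no aligned pair is shared.
#'
#' @param a,b `gapped_msa` objects over the same sequences.
#' @return similarity in `[0, 1]`.
#' @export
alignment_similarity <- function(a, b) {
  if (!identical(sort(a$ids), sort(b$ids)))
    stop("alignments are over different sequence sets")
  sab <- sp_score(a, b)$score
  sba <- sp_score(b, a)$score
  (sab + sba) / 2
}

# round-robin strategy dispatcher used by run_phase2
.apply_strategy <- function(state, i, temperature, opts = list()) {
  tight <- opts$tight %||% 0.95
  loose <- opts$loose %||% 0.40
  frac <- opts$worst_fraction %||% 0.1
  rounds <- opts$subset_rounds %||% 5L
  max_groups <- opts$max_groups %||% 5L
  switch(((i - 1L) %% 5L) + 1L,
    { # 1: tight-cluster consensus-template moves
      for (cl in cluster_sequences(state, tight, loose, level = "tight")) {
        if (cl$kind == "tight" && length(cl$members) >= 2L &&
            length(cl$members) < state$K)
          state <- resample_cluster_via_consensus(state, cl$members,
                                                  temperature)
      }
      state
    },
    { # 2: shared-feature group tandem resampling
      groups <- group_by_shared_features(state)
      if (length(groups) > max_groups)
        groups <- groups[sample.int(length(groups), max_groups)]
      for (g in groups) state <- resample_group_tandem(state, g, temperature)
      state
    },
    purged_set_realign(state, temperature, tight, loose),      # 3
    resample_worst_scoring(state, frac, temperature),          # 4
    resample_random_subsets(state, NULL, rounds, temperature)  # 5
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Competitive selection over a population of candidate alignments
#'
#' (i) Builds a rough block alignment of all sequences and clusters
#' them, keeping one representative per cluster; (ii) generates
#' `pop` independent phase-1 block alignments of the representatives;
#' (iii) converts each to an HMM state and briefly refines it;
#' (iv) scores each candidate by its mean sum-of-pairs similarity to
#' the other candidates (the best alignments agree most with the
#' rest); (v) refines the top `survivors` further and keeps the best by
#' the same criterion; (vi) samples the remaining sequences back in,
#' performs final refinement, and returns the full alignment.  With
#' fewer than 3 representatives or `pop = 1`, competition degenerates
#' to a single phase-1 + phase-2 trajectory.
#'
#' @param seqs a `seq_set`.
#' @param pop population size (default 10).
#' @param survivors refinement survivors (default 5).
#' @param p1 phase-1 configuration.
#' @param p2 final phase-2 configuration.
#' @param dm20,dm58 compact and full emission mixtures.
#' @param bg background.
#' @param tpriors transition priors.
#' @param tight,loose clustering thresholds for representative picking.
#' @param verbose log progress.
#' @return a [gapped_msa()] of all input sequences (attributes as
#'   [run_phase2()]).
#' @export
competitive_selection <- function(seqs, pop = 10L, survivors = 5L,
                                  p1 = phase1_config(),
                                  p2 = phase2_config(),
                                  dm20 = default_mixture("dm20"),
                                  dm58 = default_mixture("dm58"),
                                  bg = default_background(),
                                  tpriors = transition_priors(),
                                  tight = 0.95, loose = 0.40,
                                  verbose = FALSE) {
  stopifnot(pop >= survivors, survivors >= 1L)
  K <- n_seq(seqs)
  # (i) rough block alignment -> clusters -> representatives
  rough_cfg <- phase1_config(patience = 2L, max_cycles = 8L)
  rough <- run_phase1(seqs, rough_cfg, dm20, bg)
  rough_state <- block_to_hmm(rough, seqs, dm20, bg, tpriors)
  clusters <- cluster_sequences(rough_state, tight, loose)
  reps <- vapply(clusters, function(cl) cl$members[1L], integer(1L))
  single <- pop == 1L || length(reps) < 3L
  if (single && verbose)
    message("competition skipped (", length(reps),
            " representatives); single trajectory")
  if (single || length(reps) == K) {
    run_seqs <- seqs
    reps <- seq_len(K)
  } else {
    run_seqs <- seq_set(seqs$ids[reps], seqs$seqs[reps], seqs$desc[reps])
  }
  if (single) {
    aln <- run_phase1(run_seqs, p1, dm20, bg)
    best_state <- attr(run_phase2(run_seqs, aln, p2, dm58, bg, tpriors,
                                  verbose = verbose), "state")
  } else {
    brief <- phase2_config(sweeps_per_temp = 1L, patience = 2L,
                           max_final_sweeps = 4L, use_strategies = FALSE)
    cand <- vector("list", pop)
    for (p in seq_len(pop)) {
      aln <- run_phase1(run_seqs, p1, dm20, bg)
      cand[[p]] <- attr(run_phase2(run_seqs, aln, brief, dm58, bg, tpriors),
                        "state")
      if (verbose) message("candidate ", p, ": g=",
                           round(joint_score(cand[[p]]), 1))
    }
    msas <- lapply(cand, state_to_msa)
    sim <- .population_similarity(msas)
    keep <- order(-sim)[seq_len(survivors)]
    more <- phase2_config(sweeps_per_temp = 1L, patience = 3L,
                          max_final_sweeps = 6L, use_strategies = TRUE)
    cand <- lapply(cand[keep], function(st)
      attr(run_phase2(st$seqs, st, more, dm58, bg, tpriors), "state"))
    msas <- lapply(cand, state_to_msa)
    sim <- .population_similarity(msas)
    best_state <- cand[[which.max(sim)]]
  }
  # (vi) sample back the remaining sequences and refine on the full set
  remaining <- setdiff(seq_len(K), reps)
  if (length(remaining)) {
    full_assigns <- vector("list", K)
    for (i in seq_along(reps))
      full_assigns[[reps[i]]] <- best_state$assigns[[i]]
    for (k in remaining)
      full_assigns[[k]] <- integer(length(seqs$seqs[[k]]))
    state <- msa_state(seqs, full_assigns, best_state$w, dm58, bg, tpriors)
    for (k in remaining[sample.int(length(remaining))]) state <- .realign_deterministic(state, k)
  } else {
    state <- best_state
  }
  run_phase2(seqs, state, p2, dm58, bg, tpriors, verbose = verbose)
}

# mean pairwise similarity of each candidate to the others
.population_similarity <- function(msas) {
  P <- length(msas)
  sim <- numeric(P)
  s <- matrix(0, P, P)
  for (p in seq_len(P - 1L)) for (q in (p + 1L):P)
    s[p, q] <- s[q, p] <- alignment_similarity(msas[[p]], msas[[q]])
  for (p in seq_len(P)) sim[p] <- mean(s[p, -p])
  sim
}
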