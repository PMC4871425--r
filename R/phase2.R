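# ---------------------------------------------------------------------------
# Phase 2: annealed Gibbs sampling of the gapped alignment against the
# profile HMM, with BILD-driven column add/remove/shift moves and
# (optionally) the correlated-sequence strategy moves.

#' Phase-2 configuration (annealing schedule and column-move options)
#'
#' The annealing schedule visits temperatures `1.0, 0.9, ..., 0.1, 0.0`
#' (`dt = 0.1`), running `sweeps_per_temp` full sequence sweeps at each;
#' at T = 0 sweeps continue until `patience` sweeps produce no new best
#' joint score.  `early_slack` is the BILD slack (nats) by which columns
#' that fail marginally to be statistically supported are retained
#' before the final stage.
#'
#' @param t_start,t_end,dt annealing schedule (defaults 1, 0, 0.1).
#' @param sweeps_per_temp sweeps per temperature.
#' @param patience T=0 sweeps without a new best before stopping.
#' @param max_final_sweeps hard cap on T=0 sweeps.
#' @param early_slack BILD retention slack in nats during annealing.
#' @param use_strategies run the correlated-sequence strategy moves.
#' @param final_filter apply [model_significance_filter()] to the
#'   returned best state.
#' @param strategy_every plain sweeps between strategy invocations.
#' @param strategy_opts options passed to the strategy moves.
#' @return list of class `phase2_config`.
#' @export
phase2_config <- function(t_start = 1, t_end = 0, dt = 0.1,
                          sweeps_per_temp = 2L, patience = 10L,
                          max_final_sweeps = 40L, early_slack = 2,
                          use_strategies = TRUE, strategy_every = 2L,
                          final_filter = TRUE, strategy_opts = list()) {
  temps <- seq(t_start, t_end, by = -dt)
  if (abs(temps[length(temps)] - t_end) > 1e-9) temps <- c(temps, t_end)
  temps <- round(temps, 10)
  structure(list(temps = temps, sweeps_per_temp = as.integer(sweeps_per_temp),
                 patience = as.integer(patience),
                 max_final_sweeps = as.integer(max_final_sweeps),
                 early_slack = early_slack,
                 use_strategies = isTRUE(use_strategies),
                 strategy_every = as.integer(strategy_every),
                 final_filter = isTRUE(final_filter),
                 strategy_opts = strategy_opts),
            class = "phase2_config")
}

# deterministic realignment of one sequence (posterior-mean emissions,
# point-estimate transitions, T = 0); used for greedy steps and repairs
.realign_deterministic <- function(state, k) {
  if (state$w == 0L) return(state)
  st <- .state_remove_seq(state, k)
  theta <- .posterior_mean_matrix(pmax(st$h, 0), st$dm)
  tpe <- transition_point_estimates(pmax(st$tc, 0), st$tpriors)
  a <- align_sequence_to_hmm(st$seqs$seqs[[k]], theta, tpe, st$bg, 0)
  .state_add_seq(st, k, a)
}

# rebuild a state after structural column changes, repairing sequences
# whose paths became illegal (insert run stranded next to a deletion)
.state_rebuild <- function(state, assigns, w) {
  broken <- integer(0)
  for (k in seq_len(state$K)) {
    ok <- tryCatch({ .path_events(assigns[[k]], w); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      broken <- c(broken, k)
      assigns[[k]] <- integer(length(assigns[[k]]))  # all-delete, legal
    }
  }
  st <- msa_state(state$seqs, assigns, w, state$dm, state$bg, state$tpriors,
                  wstate = state$wstate)
  for (k in broken) st <- .realign_deterministic(st, k)
  st
}

# insert-run length after column j (j = 1..w-1) for every sequence,
# plus the position of the first/last residue of each run
.insert_runs <- function(state) {
  w <- state$w
  runs <- matrix(0L, state$K, w + 1L)   # column j+1 = run after column j
  first <- matrix(NA_integer_, state$K, w + 1L)
  last <- matrix(NA_integer_, state$K, w + 1L)
  for (k in seq_len(state$K)) {
    a <- state$assigns[[k]]
    nz <- which(a > 0L)
    if (length(nz) < 2L) next
    gaps <- diff(nz) - 1L
    at <- which(gaps > 0L)
    for (t in at) {
      j <- a[nz[t]]
      runs[k, j + 1L] <- gaps[t]
      first[k, j + 1L] <- nz[t] + 1L
      last[k, j + 1L] <- nz[t + 1L] - 1L
    }
  }
  list(runs = runs, first = first, last = last)
}

#' Add and remove model columns by their BILD scores
#'
#' A match column is kept only if its weighted BILD score exceeds the
#' phase threshold (0 nats in the final phase, `-early_slack` during
#' annealing, so marginal columns get time to converge).  Candidate new
#' columns are insert positions (and the two flank edges) where at
#' least half the weighted sequences have an adjacent residue; a
#' candidate is added when its BILD score exceeds the same threshold.
#' Removed columns' residues become insertions; sequences whose path
#' would become illegal are realigned deterministically.
#'
#' @param state an `msa_state`.
#' @param phase `"early"` or `"final"`.
#' @param early_slack retention slack in nats for the early phase.
#' @return updated state.
#' @export
column_add_remove <- function(state, phase = c("early", "final"),
                              early_slack = 2) {
  phase <- match.arg(phase)
  tau <- if (phase == "final") 0 else -early_slack
  # --- removals
  if (state$w > 0L) {
    bs <- .bild_scores(state$h, state$dm, state$bg)
    drop <- which(bs <= tau)
    if (length(drop)) state <- .remove_columns(state, drop)
  }
  # --- additions
  repeat {
    added <- FALSE
    if (state$w == 0L) break
    cand <- .addition_candidates(state)
    if (length(cand$j)) {
      sc <- vapply(seq_along(cand$j), function(i) {
        bild_score(count_residues(cand$res[[i]], cand$wt[[i]]),
                   state$dm, state$bg)
      }, numeric(1L))
      best <- which.max(sc)
      if (sc[best] > tau) {
        state <- .add_column(state, cand$j[best], cand$pos[[best]])
        added <- TRUE
      }
    }
    if (!added) break
  }
  state
}

# candidate column additions: for each insert position j = 0..w, the
# adjacent residue available in each sequence (NA if none)
.addition_candidates <- function(state) {
  ir <- .insert_runs(state)
  K <- state$K; w <- state$w
  wt <- state$wstate$int / 100
  pos_js <- list(); js <- integer(0)
  # interior insert positions: leftmost residue of each run
  for (j in seq_len(max(w - 1L, 0L))) {
    have <- which(ir$runs[, j + 1L] > 0L)
    if (sum(wt[have]) < sum(wt) / 2) next
    pos <- rep(NA_integer_, K)
    pos[have] <- ir$first[have, j + 1L]
    js <- c(js, j)
    pos_js <- c(pos_js, list(pos))
  }
  # flank edges: residue immediately before the first / after the last
  # match-emitted residue
  firstm <- vapply(state$assigns, function(a) {
    nz <- which(a > 0L); if (length(nz)) nz[1L] else NA_integer_
  }, integer(1L))
  lastm <- vapply(state$assigns, function(a) {
    nz <- which(a > 0L); if (length(nz)) nz[length(nz)] else NA_integer_
  }, integer(1L))
  pre <- ifelse(!is.na(firstm) & firstm > 1L, firstm - 1L, NA_integer_)
  if (sum(wt[!is.na(pre)]) >= sum(wt) / 2) {
    js <- c(js, 0L); pos_js <- c(pos_js, list(pre))
  }
  nk <- lengths(state$seqs$seqs)
  post <- ifelse(!is.na(lastm) & lastm < nk, lastm + 1L, NA_integer_)
  if (sum(wt[!is.na(post)]) >= sum(wt) / 2) {
    js <- c(js, w); pos_js <- c(pos_js, list(post))
  }
  res <- lapply(pos_js, function(p) {
    vapply(seq_len(K), function(k)
      if (is.na(p[k])) NA_integer_ else state$seqs$seqs[[k]][p[k]],
      integer(1L))
  })
  wts <- lapply(pos_js, function(p) wt)
  list(j = js, pos = pos_js, res = res, wt = wts)
}

# add a new match column after column j (j = 0..w), taking residue
# `pos[k]` for each sequence (NA -> deletion at the new column)
.add_column <- function(state, j, pos) {
  w2 <- state$w + 1L
  assigns <- state$assigns
  for (k in seq_len(state$K)) {
    a <- assigns[[k]]
    a[a > j] <- a[a > j] + 1L
    if (!is.na(pos[k])) a[pos[k]] <- j + 1L
    assigns[[k]] <- a
  }
  .state_rebuild(state, assigns, w2)
}

# remove the given match columns; their residues become insertions
.remove_columns <- function(state, cols) {
  cols <- sort(unique(cols))
  w2 <- state$w - length(cols)
  newcol <- integer(state$w)
  keep <- setdiff(seq_len(state$w), cols)
  newcol[keep] <- seq_along(keep)
  assigns <- lapply(state$assigns, function(a) {
    nz <- a > 0L
    a[nz] <- newcol[a[nz]]
    a
  })
  .state_rebuild(state, assigns, w2)
}

#' Shift edge match columns across insert regions
#'
#' For every insert region, evaluates transferring the downstream
#' block's first column to the upstream side of the insertions (each
#' sequence's column residue becomes the first residue of its insert
#' run) and vice versa, and applies the variant with the best aggregate
#' weighted BILD score; ties keep the current configuration.  Residue
#' content is conserved; only column assignment changes.
#'
#' @param state an `msa_state`.
#' @return updated state.
#' @export
shift_columns_across_insertions <- function(state) {
  if (state$w < 2L) return(state)
  changed <- TRUE
  guard <- 0L
  while (changed && guard < 4L * state$w) {
    changed <- FALSE
    guard <- guard + 1L
    ir <- .insert_runs(state)
    for (j in seq_len(state$w - 1L)) {
      have <- which(ir$runs[, j + 1L] > 0L)
      if (!length(have)) next
      wt <- state$wstate$int / 100
      cm <- state_col_matrix(state)
      # variant A: column j+1 takes the first run residue
      okA <- j + 1L == state$w ||
        all(vapply(have, function(k) (j + 2L) %in% state$assigns[[k]],
                   logical(1L)))
      dA <- -Inf
      if (okA) {
        resA <- cm[, j + 1L]
        resA[have] <- vapply(have, function(k)
          state$seqs$seqs[[k]][ir$first[k, j + 1L]], integer(1L))
        dA <- bild_score(count_residues(resA, wt), state$dm, state$bg) -
          bild_score(count_residues(cm[, j + 1L], wt), state$dm, state$bg)
      }
      # variant B: column j takes the last run residue
      okB <- j == 1L ||
        all(vapply(have, function(k) (j - 1L) %in% state$assigns[[k]],
                   logical(1L)))
      dB <- -Inf
      if (okB) {
        resB <- cm[, j]
        resB[have] <- vapply(have, function(k)
          state$seqs$seqs[[k]][ir$last[k, j + 1L]], integer(1L))
        dB <- bild_score(count_residues(resB, wt), state$dm, state$bg) -
          bild_score(count_residues(cm[, j], wt), state$dm, state$bg)
      }
      if (max(dA, dB) <= 0) next
      assigns <- state$assigns
      if (dA >= dB) {
        for (k in have) {
          a <- assigns[[k]]
          old <- which(a == j + 1L)
          a[old] <- 0L
          a[ir$first[k, j + 1L]] <- j + 1L
          assigns[[k]] <- a
        }
      } else {
        for (k in have) {
          a <- assigns[[k]]
          old <- which(a == j)
          a[old] <- 0L
          a[ir$last[k, j + 1L]] <- j
          assigns[[k]] <- a
        }
      }
      state$assigns <- assigns
      state <- state_refresh(state)
      changed <- TRUE
    }
  }
  state
}

#' Minimum-description-length significance test of the whole model
#'
#' The per-column BILD threshold cannot see placement selection bias: a
#' sampler optimizing over all co-linear placements will concentrate a
#' few spuriously positive columns even on unrelated random sequences.
#' Under the minimum description length principle the alignment must
#' also pay for describing where the model sits within each sequence,
#' about `log(n_k)` nats per sequence (weighted like all other counts;
#' within-model indel placement is already charged through the
#' integrated transition likelihood).  The model is retained only when
#' its joint posterior score exceeds this description cost; otherwise
#' all columns are removed and the sequences are reported unaligned,
#' so unrelated sequences yield an empty model rather than a forced
#' alignment.
#'
#' @param state an `msa_state`.
#' @return the state, with all columns removed if not significant.
#' @export
model_significance_filter <- function(state) {
  if (state$w == 0L) return(state)
  cost <- sum((state$wstate$int / 100) * log(lengths(state$seqs$seqs)))
  if (joint_score(state) > cost) return(state)
  assigns <- lapply(state$assigns, function(a) integer(length(a)))
  msa_state(state$seqs, assigns, 0L, state$dm, state$bg, state$tpriors,
            wstate = state$wstate)
}

#' Run the phase-2 annealed Gibbs sampler
#'
#' Converts the phase-1 block alignment into the gapped profile-HMM
#' state, then for each temperature of the schedule runs sweeps of
#' single-sequence Gibbs resampling interleaved with BILD column
#' add/remove/shift moves, weight updates (frozen once T drops below
#' 1), and the correlated-sequence strategy moves.  Tracks the maximum
#' joint posterior score and, at T = 0, stops once `patience` sweeps
#' yield no new maximum.
#'
#' @param seqs a `seq_set`.
#' @param init a `block_alignment` from [run_phase1()] (or an
#'   `msa_state` to continue from).
#' @param cfg a [phase2_config()].
#' @param dm emission mixture (default: packaged 58-component stand-in).
#' @param bg background.
#' @param tpriors transition priors.
#' @param verbose print one line per sweep.
#' @return the best-scoring alignment as a [gapped_msa()], with
#'   attributes `state`, `score` and `trace` (best-score trace).
#' @export
run_phase2 <- function(seqs, init, cfg = phase2_config(),
                       dm = default_mixture("dm58"),
                       bg = default_background(),
                       tpriors = transition_priors(), verbose = FALSE) {
  state <- if (inherits(init, "msa_state")) init
  else block_to_hmm(init, seqs, dm, bg, tpriors)
  best <- state
  best_score <- joint_score(state)
  trace <- best_score
  strat_i <- 0L
  sweep_i <- 0L
  track <- function(st) {
    sc <- joint_score(st)
    if (sc > best_score) {
      best_score <<- sc; best <<- st
      TRUE
    } else FALSE
  }
  do_sweep <- function(state, temp) {
    sweep_i <<- sweep_i + 1L
    for (k in sample.int(state$K)) {
      state <- if (temp <= 0) .realign_deterministic(state, k)
      else resample_sequence(state, k, temp)
    }
    phase <- if (temp <= 0) "final" else "early"
    state <- column_add_remove(state, phase, cfg$early_slack)
    state <- shift_columns_across_insertions(state)
    if (!state$wstate$frozen && state$w > 0L) {
      ws <- update_weights(state$wstate, state_col_matrix(state))
      if (!identical(ws$int, state$wstate$int)) {
        state$wstate <- ws
        state <- state_refresh(state)
      }
    }
    if (cfg$use_strategies && sweep_i %% cfg$strategy_every == 0L &&
        state$w > 0L) {
      strat_i <<- strat_i + 1L
      state <- .apply_strategy(state, strat_i, temp, cfg$strategy_opts)
    }
    improved <- track(state)
    trace <<- c(trace, best_score)
    if (verbose)
      message(sprintf("phase2 sweep %d (T=%.1f): g=%.1f best=%.1f w=%d",
                      sweep_i, temp, joint_score(state), best_score, state$w))
    list(state = state, improved = improved)
  }
  for (temp in cfg$temps) {
    if (temp <= 0) break
    if (temp < 1) state$wstate$frozen <- TRUE  # freeze below T = 1
    for (s in seq_len(cfg$sweeps_per_temp)) {
      state <- do_sweep(state, temp)$state
    }
  }
  state$wstate$frozen <- TRUE
  stale <- 0L
  for (s in seq_len(cfg$max_final_sweeps)) {
    out <- do_sweep(state, 0)
    state <- out$state
    stale <- if (out$improved) 0L else stale + 1L
    if (stale >= cfg$patience) break
  }
  if (isTRUE(cfg$final_filter)) {
    filtered <- model_significance_filter(best)
    if (filtered$w == 0L) {
      best <- filtered
      best_score <- joint_score(best)
    }
  }
  msa <- state_to_msa(best)
  attr(msa, "state") <- best
  attr(msa, "score") <- best_score
  attr(msa, "trace") <- trace
  msa
}
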