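# ---------------------------------------------------------------------------
# msa_state: the phase-2 container.  Holds the sequences, each sequence's
# assignment of residues to match columns (0 = flank/insert), the Henikoff
# weight state, the emission/transition priors, and incrementally
# maintained weighted emission counts (20 x w) and transition counts
# (7 x (w+1)).  The joint posterior score decomposes as
#   g = sum_j BILD(h_j) + log h(Lambda)
# and is recomputable from scratch via state_refresh for bookkeeping checks.

.FLANK_SELF <- 0.99  # fixed N/C flank self-transition probability

#' Construct a phase-2 alignment state
#'
#' @param seqs a `seq_set`.
#' @param assigns list of per-sequence integer assignment vectors
#'   (residue position -> match column, 0 = flank/insert).
#' @param w number of match columns.
#' @param dm emission Dirichlet mixture.
#' @param bg background distribution.
#' @param tpriors transition priors.
#' @param wstate optional precomputed `weight_state` (else computed).
#' @return object of class `msa_state`.
#' @export
msa_state <- function(seqs, assigns, w, dm, bg, tpriors,
                      wstate = NULL) {
  st <- structure(list(seqs = seqs, K = n_seq(seqs), w = as.integer(w),
                       assigns = assigns, dm = dm, bg = bg,
                       tpriors = tpriors, wstate = NULL,
                       h = NULL, tc = NULL),
                  class = "msa_state")
  st$wstate <- if (!is.null(wstate)) {
    wstate
  } else if (st$w == 0L) {
    # no columns: weights undefined, fall back to uniform full weight
    structure(list(raw = rep(1, st$K), int = rep(100L, st$K),
                   frozen = FALSE), class = "weight_state")
  } else {
    weight_state(state_col_matrix(st))
  }
  state_refresh(st)
}

#' @export
print.msa_state <- function(x, ...) {
  cat(sprintf("msa_state: K=%d, w=%d, joint score %.2f nats\n",
              x$K, x$w, joint_score(x)))
  invisible(x)
}

#' Residue codes at the match columns of the current state
#' @param state an `msa_state`.
#' @return K x w integer matrix (`NA` where a sequence has a deletion).
#' @export
state_col_matrix <- function(state) {
  out <- matrix(NA_integer_, state$K, state$w)
  if (state$w == 0L) return(out)
  for (k in seq_len(state$K)) {
    a <- state$assigns[[k]]
    nz <- which(a > 0L)
    out[k, a[nz]] <- state$seqs$seqs[[k]][nz]
  }
  out
}

# one sequence's weighted emission count contribution (20 x w)
.seq_emission_counts <- function(state, k) {
  out <- matrix(0, 20L, state$w)
  a <- state$assigns[[k]]
  nz <- which(a > 0L)
  res <- state$seqs$seqs[[k]][nz]
  keep <- !is.na(res)
  wt <- state$wstate$int[k] / 100
  for (i in which(keep)) out[res[i], a[nz[i]]] <- out[res[i], a[nz[i]]] + wt
  out
}

# one sequence's weighted transition count contribution
.seq_transition_counts <- function(state, k) {
  ev <- .path_events(state$assigns[[k]], state$w)
  .path_transition_counts(ev, state$w) * (state$wstate$int[k] / 100)
}

#' Recompute all counts of a state from scratch
#' @param state an `msa_state`.
#' @return the state with `h` and `tc` rebuilt from the assignments.
#' @export
state_refresh <- function(state) {
  h <- matrix(0, 20L, state$w)
  tc <- matrix(0, 7L, state$w + 1L, dimnames = list(.TC_ROWS, NULL))
  for (k in seq_len(state$K)) {
    h <- h + .seq_emission_counts(state, k)
    tc <- tc + .seq_transition_counts(state, k)
  }
  state$h <- h
  state$tc <- tc
  state
}

# remove / restore one sequence's contribution to the counts
.state_remove_seq <- function(state, k) {
  state$h <- state$h - .seq_emission_counts(state, k)
  state$tc <- state$tc - .seq_transition_counts(state, k)
  state
}
.state_add_seq <- function(state, k, assign = NULL) {
  if (!is.null(assign)) state$assigns[[k]] <- assign
  state$h <- state$h + .seq_emission_counts(state, k)
  state$tc <- state$tc + .seq_transition_counts(state, k)
  state
}

#' Joint posterior score g of the current state
#'
#' Emission log-likelihood ratio (sum of weighted per-column BILD
#' scores) plus the integrated transition log-likelihood log h(Lambda).
#'
#' @param state an `msa_state`.
#' @return score in nats.
#' @export
joint_score <- function(state) {
  emis <- if (state$w == 0L) 0 else sum(.bild_scores(state$h, state$dm,
                                                     state$bg))
  emis + integrated_transition_loglike(state$tc, state$tpriors)
}

#' Per-sequence log-odds contribution
#'
#' Emission log-odds of the sequence's match residues under the current
#' posterior-mean column emissions, plus its path's transition
#' log-probability under the point estimates, plus the flank
#' self-transition terms.  Used to rank sequences for worst-scorer
#' resampling.
#'
#' @param state an `msa_state`.
#' @param k sequence index.
#' @return score in nats.
#' @export
seq_path_score <- function(state, k) {
  theta <- .posterior_mean_matrix(state$h, state$dm)
  tpe <- transition_point_estimates(state$tc, state$tpriors)
  .seq_path_score(state, k, theta, tpe)
}

.seq_path_score <- function(state, k, theta, tpe) {
  a <- state$assigns[[k]]
  res <- state$seqs$seqs[[k]]
  nz <- which(a > 0L)
  emis <- 0
  for (i in nz) {
    if (!is.na(res[i]))
      emis <- emis + log(theta[res[i], a[i]] / state$bg$theta0[res[i]])
  }
  ev <- .path_events(a, state$w)
  tcp <- .path_transition_counts(ev, state$w)
  ltr <- .log_transition_matrix(tpe)
  trans <- sum(tcp * ltr)
  nflank <- length(res) - length(nz) - sum(ev$runs)
  emis + trans + nflank * log(.FLANK_SELF)
}

# 7 x (w+1) log transition matrix from point estimates
.log_transition_matrix <- function(tpe) {
  rbind(mm = log(pmax(1 - tpe["io", ] - tpe["do", ], 1e-300)),
        mi = log(tpe["io", ]),
        md = log(tpe["do", ]),
        im = log(1 - tpe["ie", ]),
        ii = log(tpe["ie", ]),
        dm = log(1 - tpe["de", ]),
        dd = log(tpe["de", ]))
}

#' Convert an alignment state to a gapped MSA
#' @param state an `msa_state`.
#' @return a [gapped_msa()].
#' @export
state_to_msa <- function(state) {
  rows <- vapply(seq_len(state$K), function(k) {
    .state_row(state$seqs$seqs[[k]], state$assigns[[k]], state$w)
  }, character(1L))
  gapped_msa(state$seqs$ids, rows)
}

.state_row <- function(res, assign, w) {
  chars <- ifelse(is.na(res), "X", AA_ALPHABET[res])
  nz <- which(assign > 0L)
  if (!length(nz)) return(paste0(paste(tolower(chars), collapse = ""),
                                 strrep("-", w)))
  cols <- assign[nz]
  out <- character(0)
  out <- c(out, tolower(chars[seq_len(nz[1L] - 1L)]))
  prev_col <- 0L; prev_pos <- nz[1L] - 1L
  for (t in seq_along(nz)) {
    j <- cols[t]; p <- nz[t]
    if (t > 1L && p - prev_pos > 1L)           # insert run (before this match)
      out <- c(out, tolower(chars[(prev_pos + 1L):(p - 1L)]))
    if (j - prev_col > 1L)                     # deleted columns
      out <- c(out, rep("-", j - prev_col - 1L))
    out <- c(out, toupper(chars[p]))
    prev_col <- j; prev_pos <- p
  }
  if (prev_col < w) out <- c(out, rep("-", w - prev_col))
  if (prev_pos < length(res))
    out <- c(out, tolower(chars[(prev_pos + 1L):length(res)]))
  paste(out, collapse = "")
}

#' Build a state from a gapped MSA
#' @param msa a `gapped_msa`.
#' @param dm,bg,tpriors model priors.
#' @return an `msa_state`.
#' @export
state_from_msa <- function(msa, dm, bg, tpriors) {
  assigns <- msa_assignments(msa)
  seqs <- seq_set(msa$ids, lapply(msa$rows, degap))
  msa_state(seqs, assigns, msa$w, dm, bg, tpriors)
}

#' Convert a phase-1 block alignment into the phase-2 HMM state
#'
#' One match state per block column; inter-block unaligned residues
#' become insert-state emissions at the preceding column; flanking
#' residues become N/C flank emissions.  Initial paths contain no
#' delete states.
#'
#' @param aln a `block_alignment`.
#' @param seqs a `seq_set`.
#' @param dm,bg,tpriors model priors.
#' @return an `msa_state`.
#' @export
block_to_hmm <- function(aln, seqs, dm, bg, tpriors = transition_priors()) {
  pos <- aln_positions(aln)
  assigns <- lapply(seq_len(n_seq(seqs)), function(k) {
    a <- integer(length(seqs$seqs[[k]]))
    a[pos[k, ]] <- seq_len(aln$w)
    a
  })
  msa_state(seqs, assigns, aln$w, dm, bg, tpriors)
}

#' Check all structural invariants of a state
#'
#' Verifies strictly increasing match columns, the legality of every
#' insert run (never adjacent to a deletion), and that the incremental
#' counts agree with a from-scratch recomputation.
#'
#' @param state an `msa_state`.
#' @param tol tolerance for count agreement.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
assert_state <- function(state, tol = 1e-6) {
  for (k in seq_len(state$K)) .path_events(state$assigns[[k]], state$w)
  fresh <- state_refresh(state)
  stopifnot(max(abs(fresh$h - state$h)) < tol,
            max(abs(fresh$tc - state$tc)) < tol)
  invisible(TRUE)
}

#' Align one sequence to the profile HMM by dynamic programming
#'
#' Runs the match/insert/delete dynamic program over the model columns
#' with background-emitting flanks.  Every model column is consumed by
#' M or D.  At `temperature = 0` the maximum-probability path is
#' returned with deterministic tie-breaking (prefer M over D over I,
#' leftmost); at `temperature > 0` the path is drawn from the globally
#' tempered path distribution `p^(1/T)` by stochastic traceback.
#'
#' @param res integer residue codes of the sequence.
#' @param theta 20 x w emission probability matrix (typically sampled
#'   from the column posteriors).
#' @param tpe 4 x (w+1) transition point estimates
#'   (see [transition_point_estimates()]).
#' @param bg background.
#' @param temperature annealing temperature in `[0, 1]`.
#' @return integer assignment vector (residue -> column, 0 = unaligned).
#' @export
align_sequence_to_hmm <- function(res, theta, tpe, bg, temperature = 0) {
  stopifnot(ncol(theta) >= 1L)
  elo <- log(theta / bg$theta0)
  ltr <- .log_transition_matrix(tpe)
  .dp_align_cpp(as.integer(res), elo, ltr, log(.FLANK_SELF), temperature)
}

#' Gibbs-resample one sequence against the evolving HMM
#'
#' Removes sequence k's path from the counts, recomputes the posterior
#' HMM from the remaining sequences, samples column emission
#' probabilities from their posteriors (point estimates are used for the
#' transitions), realigns the sequence to the sampled HMM by dynamic
#' programming, and restores the counts with the new path.
#'
#' @param state an `msa_state` with `K >= 3`.
#' @param k sequence index.
#' @param temperature annealing temperature.
#' @return updated state.
#' @export
resample_sequence <- function(state, k, temperature = 0) {
  if (state$w == 0L) return(state)
  st <- .state_remove_seq(state, k)
  theta <- .sample_emission_matrix(pmax(st$h, 0), st$dm)
  tpe <- transition_point_estimates(pmax(st$tc, 0), st$tpriors)
  a <- align_sequence_to_hmm(st$seqs$seqs[[k]], theta, tpe, st$bg,
                             temperature)
  .state_add_seq(st, k, a)
}
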