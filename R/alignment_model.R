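#' Construct a co-linear block alignment (phase 1)
#'
#' The phase-1 alignment is a set of ungapped blocks occurring co-linearly
#' in every sequence: `widths` gives the number of columns of each block
#' and `starts[k, b]` the 1-based position of block b in sequence k.
#' Within a block, column positions advance by one residue per column;
#' blocks may not overlap and must appear in order.
#'
#' @param widths integer vector of block widths (all >= 1).
#' @param starts K x B integer matrix of block start positions.
#' @param seq_lengths integer vector of sequence lengths (for validation).
#' @return object of class `block_alignment` with `widths`, `starts`, `w`.
#' @export
block_alignment <- function(widths, starts, seq_lengths) {
  widths <- as.integer(widths)
  starts <- matrix(as.integer(starts), ncol = length(widths))
  if (any(widths < 1L)) stop("block widths must be >= 1")
  B <- length(widths); K <- nrow(starts)
  if (any(starts < 1L)) stop("block start < 1")
  if (B > 1L) {
    for (b in seq_len(B - 1L))
      if (any(starts[, b] + widths[b] > starts[, b + 1L]))
        stop("blocks overlap or are out of order (co-linearity violated)")
  }
  if (any(starts[, B] + widths[B] - 1L > seq_lengths))
    stop("block extends past sequence end")
  structure(list(widths = widths, starts = starts, w = sum(widths)),
            class = "block_alignment")
}

#' @export
print.block_alignment <- function(x, ...) {
  cat(sprintf("block_alignment: %d block(s) (widths %s), w=%d, K=%d\n",
              length(x$widths), paste(x$widths, collapse = "+"), x$w,
              nrow(x$starts)))
  invisible(x)
}

# column j -> (block, offset) lookup
.col_block <- function(widths) {
  rep(seq_along(widths), widths)
}
.col_offset <- function(widths) {
  unlist(lapply(widths, function(wb) seq_len(wb) - 1L), use.names = FALSE)
}

#' Residue positions a_{k,j} of every match column
#' @param aln a `block_alignment`.
#' @return K x w integer matrix of residue indices.
#' @export
aln_positions <- function(aln) {
  b <- .col_block(aln$widths); off <- .col_offset(aln$widths)
  out <- apply(aln$starts, 1L, function(s) s[b] + off)
  if (is.null(dim(out))) matrix(out, ncol = 1L) else t(out)
}

#' Residue codes at every match column
#' @param aln a `block_alignment`.
#' @param seqs a `seq_set`.
#' @return K x w integer residue-code matrix.
#' @export
aln_col_matrix <- function(aln, seqs) {
  pos <- aln_positions(aln)
  K <- nrow(pos)
  out <- matrix(NA_integer_, K, aln$w)
  for (k in seq_len(K)) out[k, ] <- seqs$seqs[[k]][pos[k, ]]
  out
}

# weighted 20 x w emission count matrix for a block alignment
.aln_counts <- function(aln, seqs, Wt = NULL) {
  cm <- aln_col_matrix(aln, seqs)
  K <- nrow(cm)
  wts <- if (is.null(Wt)) rep(1, K) else Wt / 100
  out <- matrix(0, 20L, aln$w)
  for (j in seq_len(aln$w))
    out[, j] <- count_residues(cm[, j], wts)
  out
}

#' Integrated log-likelihood ratio of a block alignment
#'
#' The log marginal likelihood of the aligned columns (per-column Polya
#' prior-predictive under the Dirichlet-mixture prior, with the column
#' multinomial parameters integrated out) minus the background
#' log-likelihood of the same residues, so the empty alignment scores 0.
#' Equals the sum of the per-column BILD scores; uses weighted counts.
#'
#' @param seqs a `seq_set`.
#' @param aln a `block_alignment`.
#' @param dm Dirichlet-mixture column prior (a single-component mixture
#'   reproduces a plain Dirichlet prior `beta`).
#' @param bg an `aa_background`.
#' @param Wt optional integer weights (1..100); default unweighted.
#' @return log-likelihood ratio in nats.
#' @export
integrated_block_llr <- function(seqs, aln, dm, bg, Wt = NULL) {
  if (aln$w == 0L) return(0)
  sum(.bild_scores(.aln_counts(aln, seqs, Wt), dm, bg))
}

# ---------------------------------------------------------------------------
# Predictive placement of one sequence's blocks

# per-column log-odds of every residue of sequence k: w x n matrix
.seq_logodds <- function(res, theta_hat, bg) {
  lo <- log(theta_hat / bg$theta0)          # 20 x w
  n <- length(res)
  out <- matrix(0, ncol(theta_hat), n)
  known <- !is.na(res)
  out[, known] <- t(lo)[, res[known], drop = FALSE]
  out
}

# sliding-window block scores: list over blocks of vectors over feasible-ish
# start positions 1..n-wb+1
.block_scores <- function(elo, widths) {
  n <- ncol(elo)
  j0 <- cumsum(c(0L, widths[-length(widths)]))
  lapply(seq_along(widths), function(b) {
    wb <- widths[b]
    if (n < wb) return(numeric(0))
    s <- numeric(n - wb + 1L)
    for (c in seq_len(wb))
      s <- s + elo[j0[b] + c, c:(n - wb + c)]
    s
  })
}

#' Predictive placement distribution of one sequence's blocks
#'
#' Conditional predictive distribution of the conserved region's location
#' in sequence k, proportional to the product over columns of
#' `(theta_hat_j / theta0)^(residue at a_{k,j})`, normalized by dynamic
#' programming over all feasible co-linear placements of all blocks.
#'
#' @param res integer residue codes of the sequence being placed.
#' @param widths block widths.
#' @param theta_hat 20 x w matrix of posterior-mean column emissions
#'   (computed from the alignment with this sequence removed).
#' @param bg an `aa_background`.
#' @param temperature sampling temperature T; scores are divided by T
#'   (`T = 0` marks the distribution degenerate at the argmax).
#' @return object of class `placement_dist`: per-block score vectors,
#'   forward log-sums, total `logZ`.
#' @export
predictive_placement_distribution <- function(res, widths, theta_hat, bg,
                                              temperature = 1) {
  n <- length(res)
  if (n < sum(widths)) stop("sequence shorter than total block width")
  elo <- .seq_logodds(res, theta_hat, bg)
  S <- .block_scores(elo, widths)
  if (temperature > 0) S <- lapply(S, function(x) x / temperature)
  B <- length(widths)
  Fw <- vector("list", B)
  Fw[[1L]] <- S[[1L]]
  if (B > 1L) for (b in 2:B) {
    prev <- Fw[[b - 1L]]
    # prefix logsumexp of prev, shifted so block b at s requires
    # prev start s' <= s - widths[b-1]
    pl <- .prefix_lse(prev)
    nb <- length(S[[b]])
    idx <- seq_len(nb) - widths[b - 1L]   # latest admissible prev index
    val <- rep(-Inf, nb)
    ok <- idx >= 1L
    val[ok] <- pl[pmin(idx[ok], length(pl))]
    Fw[[b]] <- S[[b]] + val
  }
  logZ <- .logsumexp(Fw[[B]])
  structure(list(S = S, Fw = Fw, widths = widths, n = n,
                 temperature = temperature, logZ = logZ),
            class = "placement_dist")
}

.prefix_lse <- function(x) {
  out <- numeric(length(x))
  acc <- -Inf
  for (i in seq_along(x)) {
    xi <- x[i]
    acc <- if (acc > xi) acc + log1p(exp(xi - acc))
    else if (is.finite(xi)) xi + log1p(exp(acc - xi)) else acc
    out[i] <- acc
  }
  out
}

#' Probability of a specific placement under a placement distribution
#' @param pd a `placement_dist`.
#' @param starts integer vector of block starts.
#' @return probability (temperature-tempered, normalized).
#' @export
placement_prob <- function(pd, starts) {
  B <- length(pd$widths)
  tot <- sum(vapply(seq_len(B), function(b) pd$S[[b]][starts[b]], numeric(1L)))
  exp(tot - pd$logZ)
}

#' Sample (or maximize) a co-linear placement
#'
#' Draws block starts from a [predictive_placement_distribution()]; at
#' `temperature = 0` returns the argmax placement with ties broken
#' toward the smallest start positions.
#'
#' @param pd a `placement_dist`.
#' @return integer vector of block starts.
#' @export
sample_placement <- function(pd) {
  B <- length(pd$widths)
  starts <- integer(B)
  greedy <- pd$temperature == 0
  hi <- length(pd$Fw[[B]])
  for (b in rev(seq_len(B))) {
    val <- pd$Fw[[b]][seq_len(hi)]
    starts[b] <- if (greedy) which.max(val) else .sample_log(val)
    hi <- starts[b] - pd$widths[max(b - 1L, 1L)]
  }
  starts
}

.sample_log <- function(logw) {
  w <- exp(logw - max(logw))
  sample.int(length(w), 1L, prob = w)
}

# ---------------------------------------------------------------------------
# HMM transition counts, priors, estimates

.TC_ROWS <- c("mm", "mi", "md", "im", "ii", "dm", "dd")

#' Transition prior pseudocounts
#'
#' Positive pseudocounts for the position-specific transition rows:
#' match row (Dirichlet over M->M, M->I, M->D), insert row (Beta over
#' I->I vs I->M) and delete row (Beta over D->D vs D->M).  The default
#' strong match-continuation prior concentrates indels where other
#' sequences already have them.
#'
#' @param nmm,nmi,nmd,nii,nim,ndd,ndm positive pseudocounts.
#' @return object of class `transition_priors`.
#' @export
transition_priors <- function(nmm = 18, nmi = 1, nmd = 1,
                              nii = 1, nim = 1, ndd = 1, ndm = 1) {
  p <- c(mm = nmm, mi = nmi, md = nmd, im = nim, ii = nii, dm = ndm, dd = ndd)
  if (any(p <= 0)) stop("transition pseudocounts must be strictly positive")
  structure(as.list(p), class = "transition_priors")
}

# path events for one sequence: match/delete status per column and insert
# run lengths; errors on architecture violations (I adjacent to D)
.path_events <- function(assign, w) {
  nz <- which(assign > 0L)
  cols <- assign[nz]
  if (is.unsorted(cols, strictly = TRUE))
    stop("match columns not strictly increasing along the sequence")
  if (length(cols) && (any(cols < 1L) | any(cols > w)))
    stop("column index out of range")
  state <- rep(FALSE, w)       # TRUE = M
  state[cols] <- TRUE
  runs <- integer(w + 1L)      # runs[j+1] = insert run after column j (j=0..w)
  if (length(nz)) {
    gaps <- diff(nz) - 1L              # unassigned residues between matches
    if (any(gaps > 0L)) {
      at <- which(gaps > 0L)
      if (any(cols[at + 1L] != cols[at] + 1L))
        stop("insert run adjacent to a deletion (illegal path)")
      runs[cols[at] + 1L] <- gaps[at]
    }
  }
  list(mstate = state, runs = runs, nmatch = length(nz))
}

#' Count HMM transitions over all sequence paths
#'
#' Walks each sequence's state path through the model (N flank, M/I/D
#' per column, C flank) and adds `Wt(k)/100` to each traversed arc's
#' positional counter.  Start-state arcs accumulate at j = 0; arcs out
#' of column w (into the end state) accumulate at j = w, treating the
#' end symmetrically to the start.
#'
#' @param assigns list of per-sequence assignment vectors (residue ->
#'   match column, 0 = insert/flank).
#' @param w number of match columns.
#' @param Wt integer sequence weights in 1..100 (default all 100).
#' @return 7 x (w+1) numeric matrix, rows `mm,mi,md,im,ii,dm,dd`,
#'   column `j+1` holding position-j counts.
#' @export
count_transitions <- function(assigns, w, Wt = NULL) {
  K <- length(assigns)
  if (is.null(Wt)) Wt <- rep(100L, K)
  tc <- matrix(0, 7L, w + 1L, dimnames = list(.TC_ROWS, NULL))
  for (k in seq_len(K)) {
    ev <- tryCatch(.path_events(assigns[[k]], w), error = function(e)
      stop("sequence ", k, ": ", conditionMessage(e)))
    tc <- tc + .path_transition_counts(ev, w) * (Wt[k] / 100)
  }
  tc
}

# unweighted transition counts of one path
.path_transition_counts <- function(ev, w) {
  tc <- matrix(0, 7L, w + 1L, dimnames = list(.TC_ROWS, NULL))
  s <- c(TRUE, ev$mstate, TRUE)  # virtual M at start (j=0) and end (j=w+1)
  for (j in 0:w) {
    r <- ev$runs[j + 1L]
    if (r > 0L) {
      tc["mi", j + 1L] <- tc["mi", j + 1L] + 1
      tc["ii", j + 1L] <- tc["ii", j + 1L] + (r - 1L)
      tc["im", j + 1L] <- tc["im", j + 1L] + 1
    } else {
      type <- paste0(if (s[j + 1L]) "m" else "d", if (s[j + 2L]) "m" else "d")
      tc[type, j + 1L] <- tc[type, j + 1L] + 1
    }
  }
  tc
}

#' Posterior point estimates of the transition probabilities
#'
#' Posterior means of the per-position insertion-open, insertion-extend,
#' deletion-open and deletion-extend probabilities given observed
#' weighted counts and the prior pseudocounts, e.g.
#' `delta_e[j] = (N_dd[j] + n_dd) / (N_dd[j] + N_dm[j] + n_d.)`.
#' These are the position-specific gap penalties.  (The paper-style MAP
#' estimates are taken as posterior means: with pseudocounts of 1 the
#' posterior mode is degenerate at the boundary.)
#'
#' @param tc 7 x (w+1) transition count matrix (see [count_transitions()]).
#' @param priors a [transition_priors()].
#' @return 4 x (w+1) matrix with rows `io`, `ie`, `do`, `de`.
#' @export
transition_point_estimates <- function(tc, priors) {
  if (is.null(dim(tc))) tc <- matrix(tc, nrow = 7L,
                                     dimnames = list(.TC_ROWS, NULL))
  m_tot <- tc["mm", ] + tc["mi", ] + tc["md", ] +
    priors$mm + priors$mi + priors$md
  io <- (tc["mi", ] + priors$mi) / m_tot
  do_ <- (tc["md", ] + priors$md) / m_tot
  ie <- (tc["ii", ] + priors$ii) / (tc["ii", ] + tc["im", ] +
                                      priors$ii + priors$im)
  de <- (tc["dd", ] + priors$dd) / (tc["dd", ] + tc["dm", ] +
                                      priors$dd + priors$dm)
  rbind(io = io, ie = ie, do = do_, de = de)
}

#' Sample transition probabilities from their posterior
#'
#' Factorized posterior draws per position:
#' `delta_o ~ Beta(N_md+n_md, N_mm+N_mi+n_mm+n_mi)`,
#' `delta_e ~ Beta(N_dd+n_dd, N_dm+n_dm)`,
#' `iota_o = (1-delta_o) * iota*_o` with
#' `iota*_o ~ Beta(N_mi+n_mi, N_mm+n_mm)`, and
#' `iota_e ~ Beta(N_ii+n_ii, N_im+n_im)`; `iota_o + delta_o < 1` almost
#' surely.  Uses R's RNG.
#'
#' @inheritParams transition_point_estimates
#' @return 4 x (w+1) matrix with rows `io`, `ie`, `do`, `de`.
#' @export
sample_transition_probabilities <- function(tc, priors) {
  if (is.null(dim(tc))) tc <- matrix(tc, nrow = 7L,
                                     dimnames = list(.TC_ROWS, NULL))
  m <- ncol(tc)
  do_ <- rbeta(m, tc["md", ] + priors$md,
               tc["mm", ] + tc["mi", ] + priors$mm + priors$mi)
  de <- rbeta(m, tc["dd", ] + priors$dd, tc["dm", ] + priors$dm)
  iostar <- rbeta(m, tc["mi", ] + priors$mi, tc["mm", ] + priors$mm)
  io <- (1 - do_) * iostar
  ie <- rbeta(m, tc["ii", ] + priors$ii, tc["im", ] + priors$im)
  rbind(io = io, ie = ie, do = do_, de = de)
}

#' Integrated transition log-likelihood log h(Lambda)
#'
#' The transition probabilities integrated out against their priors: a
#' product over positions of Gamma-function ratios for the match
#' (trinomial), insert and delete rows, in log space, summed over
#' j = 0..w (start position included).  Zero when all counts are zero.
#'
#' @inheritParams transition_point_estimates
#' @return log h(Lambda) in nats.
#' @export
integrated_transition_loglike <- function(tc, priors) {
  if (is.null(dim(tc))) tc <- matrix(tc, nrow = 7L,
                                     dimnames = list(.TC_ROWS, NULL))
  nm <- priors$mm + priors$mi + priors$md
  ni <- priors$ii + priors$im
  nd <- priors$dd + priors$dm
  mrow <- lgamma(tc["mi", ] + priors$mi) + lgamma(tc["md", ] + priors$md) +
    lgamma(tc["mm", ] + priors$mm) + lgamma(nm) -
    lgamma(tc["mm", ] + tc["mi", ] + tc["md", ] + nm) -
    lgamma(priors$mi) - lgamma(priors$md) - lgamma(priors$mm)
  irow <- lgamma(tc["ii", ] + priors$ii) + lgamma(tc["im", ] + priors$im) +
    lgamma(ni) - lgamma(tc["ii", ] + tc["im", ] + ni) -
    lgamma(priors$ii) - lgamma(priors$im)
  drow <- lgamma(tc["dd", ] + priors$dd) + lgamma(tc["dm", ] + priors$dm) +
    lgamma(nd) - lgamma(tc["dd", ] + tc["dm", ] + nd) -
    lgamma(priors$dd) - lgamma(priors$dm)
  sum(mrow + irow + drow)
}
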