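# ---------------------------------------------------------------------------
# Phase 1: top-down block sampling.  A crude alignment of short ungapped
# co-linear blocks is Gibbs-sampled: sequences' block placements are drawn
# from their predictive distributions, and edge columns / whole blocks are
# Metropolis-sampled in or out of the alignment on the integrated
# block-alignment LLR (= sum of column BILD scores).

#' Phase-1 configuration
#'
#' @param min_width,max_width initial block width range (columns).
#' @param patience cycles without a new best LLR before stopping.
#' @param max_cycles hard cap on sampling cycles.
#' @param temperature sampling temperature for phase-1 moves.
#' @return list of class `phase1_config`.
#' @export
phase1_config <- function(min_width = 5L, max_width = 15L, patience = 5L,
                          max_cycles = 60L, temperature = 1) {
  stopifnot(min_width >= 1L, min_width <= max_width, patience >= 1L)
  structure(list(min_width = as.integer(min_width),
                 max_width = as.integer(max_width),
                 patience = as.integer(patience),
                 max_cycles = as.integer(max_cycles),
                 temperature = temperature),
            class = "phase1_config")
}

# uniform draw of a feasible co-linear placement of blocks `widths`
# in a sequence of length n (all placements equiprobable)
.uniform_placement <- function(n, widths) {
  B <- length(widths)
  W <- sum(widths)
  if (n < W) stop("sequence shorter than total block width")
  v <- sort(sample.int(n - W + B, B))
  u <- v - seq_len(B) + 1L                      # nondecreasing in 1..n-W+1
  u + cumsum(c(0L, widths[-B]))
}

#' Initialize a random co-linear block alignment
#'
#' The number of blocks is drawn uniformly on `1..floor(L_min /
#' max_width)` (at least 1) and block widths uniformly on
#' `[min_width, max_width]`, truncated so the total width fits the
#' shortest sequence; each sequence's placement is drawn uniformly among
#' its feasible co-linear placements, independently.
#'
#' @param seqs a `seq_set`.
#' @param cfg a [phase1_config()].
#' @return a [block_alignment()].
#' @export
init_random_blocks <- function(seqs, cfg = phase1_config()) {
  nk <- lengths(seqs$seqs)
  lmin <- min(nk)
  if (lmin < cfg$min_width)
    stop("shortest sequence (", lmin, ") is below the minimum block width; ",
         "offending sequence: ", seqs$ids[which.min(nk)])
  bmax <- max(1L, lmin %/% cfg$max_width)
  B <- sample.int(bmax, 1L)
  widths <- sample.int(cfg$max_width - cfg$min_width + 1L, B,
                       replace = TRUE) + cfg$min_width - 1L
  while (sum(widths) > lmin && length(widths) > 1L)
    widths <- widths[-length(widths)]
  if (sum(widths) > lmin) widths <- min(widths, lmin)
  starts <- t(vapply(nk, .uniform_placement, integer(length(widths)),
                     widths = widths))
  if (length(widths) == 1L) starts <- matrix(starts, ncol = 1L)
  block_alignment(widths, starts, nk)
}

# weighted emission count matrix excluding sequence k
.aln_counts_minus <- function(aln, seqs, Wt, k) {
  cnt <- .aln_counts(aln, seqs, Wt)
  pos <- aln_positions(aln)[k, ]
  res <- seqs$seqs[[k]][pos]
  wt <- Wt[k] / 100
  for (j in seq_len(aln$w))
    if (!is.na(res[j])) cnt[res[j], j] <- cnt[res[j], j] - wt
  pmax(cnt, 0)
}

#' Resample one sequence's block placements
#'
#' Removes sequence k, computes posterior-mean column emissions from the
#' remaining sequences, and draws a new co-linear placement of all
#' blocks from the tempered predictive placement distribution
#' (`temperature = 0` takes the argmax, ties toward smallest starts).
#'
#' @param aln a `block_alignment`.
#' @param seqs a `seq_set`.
#' @param k sequence index.
#' @param dm,bg priors.
#' @param Wt integer weights.
#' @param temperature sampling temperature.
#' @return updated `block_alignment`.
#' @export
resample_sequence_blocks <- function(aln, seqs, k, dm, bg, Wt = NULL,
                                     temperature = 1) {
  if (is.null(Wt)) Wt <- rep(100L, n_seq(seqs))
  cnt <- .aln_counts_minus(aln, seqs, Wt, k)
  theta <- .posterior_mean_matrix(cnt, dm)
  pd <- predictive_placement_distribution(seqs$seqs[[k]], aln$widths, theta,
                                          bg, temperature)
  aln$starts[k, ] <- sample_placement(pd)
  aln
}

# counts of a prospective column at per-sequence positions `pos`
.column_counts <- function(seqs, pos, Wt) {
  res <- vapply(seq_along(pos), function(k) seqs$seqs[[k]][pos[k]],
                integer(1L))
  count_residues(res, Wt / 100)
}

# Metropolis acceptance on a tempered LLR delta
.accept_delta <- function(delta, temperature) {
  if (temperature <= 0) return(delta > 0)
  delta >= 0 || runif(1L) < exp(delta / temperature)
}

#' Sample an edge column of a block in or out of the alignment
#'
#' Proposes adding an adjacent column on the given side (only if every
#' sequence has an unaligned residue there) or removing the edge column
#' (only if the block is wider than one column), and accepts with
#' tempered probability on the change in the integrated block LLR.
#'
#' @param aln a `block_alignment`.
#' @param seqs a `seq_set`.
#' @param block block index.
#' @param side `"left"` or `"right"`.
#' @param dm,bg priors.
#' @param Wt integer weights.
#' @param temperature sampling temperature.
#' @param action `"add"`, `"remove"`, or `"random"`.
#' @return updated `block_alignment`.
#' @export
sample_edge_column <- function(aln, seqs, block, side = c("left", "right"),
                               dm, bg, Wt = NULL, temperature = 1,
                               action = c("random", "add", "remove")) {
  side <- match.arg(side)
  action <- match.arg(action)
  if (is.null(Wt)) Wt <- rep(100L, n_seq(seqs))
  if (action == "random") action <- if (runif(1L) < 0.5) "add" else "remove"
  b <- block
  nk <- lengths(seqs$seqs)
  if (action == "add") {
    pos <- if (side == "left") aln$starts[, b] - 1L
    else aln$starts[, b] + aln$widths[b]
    lo_ok <- if (b == 1L) pos >= 1L
    else pos >= aln$starts[, b - 1L] + aln$widths[b - 1L]
    hi_ok <- if (b == length(aln$widths)) pos <= nk
    else pos < aln$starts[, b + 1L]
    if (!all(lo_ok & hi_ok)) return(aln)      # blocked: no free residue
    delta <- bild_score(.column_counts(seqs, pos, Wt), dm, bg)
    if (.accept_delta(delta, temperature)) {
      if (side == "left") aln$starts[, b] <- aln$starts[, b] - 1L
      aln$widths[b] <- aln$widths[b] + 1L
      aln$w <- sum(aln$widths)
    }
  } else {
    if (aln$widths[b] <= 1L) return(aln)
    pos <- if (side == "left") aln$starts[, b]
    else aln$starts[, b] + aln$widths[b] - 1L
    delta <- -bild_score(.column_counts(seqs, pos, Wt), dm, bg)
    if (.accept_delta(delta, temperature)) {
      if (side == "left") aln$starts[, b] <- aln$starts[, b] + 1L
      aln$widths[b] <- aln$widths[b] - 1L
      aln$w <- sum(aln$widths)
    }
  }
  aln
}

#' Sample a whole block in or out of the alignment
#'
#' With equal probability proposes removing a uniformly chosen block
#' (never the last one) or inserting a new minimum-width block into a
#' uniformly chosen inter-block gap (skipped when some sequence has no
#' room there); accepts on the tempered integrated-LLR change.
#'
#' @inheritParams sample_edge_column
#' @param cfg a [phase1_config()] (for the minimum block width).
#' @return updated `block_alignment`.
#' @export
sample_block_in_out <- function(aln, seqs, dm, bg, Wt = NULL,
                                temperature = 1, cfg = phase1_config(),
                                action = c("random", "insert", "remove")) {
  action <- match.arg(action)
  if (is.null(Wt)) Wt <- rep(100L, n_seq(seqs))
  if (action == "random") action <- if (runif(1L) < 0.5) "insert" else "remove"
  B <- length(aln$widths)
  nk <- lengths(seqs$seqs)
  if (action == "remove") {
    if (B <= 1L) return(aln)
    b <- sample.int(B, 1L)
    cnt <- .aln_counts(aln, seqs, Wt)
    jset <- which(.col_block(aln$widths) == b)
    delta <- -sum(.bild_scores(cnt[, jset, drop = FALSE], dm, bg))
    if (.accept_delta(delta, temperature)) {
      aln$widths <- aln$widths[-b]
      aln$starts <- aln$starts[, -b, drop = FALSE]
      aln$w <- sum(aln$widths)
    }
  } else {
    wb <- cfg$min_width
    g <- sample.int(B + 1L, 1L) - 1L           # insert after block g (0=front)
    lo <- if (g == 0L) rep(1L, length(nk))
    else aln$starts[, g] + aln$widths[g]
    hi <- if (g == B) nk else aln$starts[, g + 1L] - 1L
    if (any(hi - lo + 1L < wb)) return(aln)    # no feasible co-linear slot
    newstart <- vapply(seq_along(nk), function(k) {
      lo[k] + sample.int(hi[k] - lo[k] + 1L - wb + 1L, 1L) - 1L
    }, integer(1L))
    pos0 <- newstart
    delta <- sum(vapply(seq_len(wb) - 1L, function(off) {
      bild_score(.column_counts(seqs, pos0 + off, Wt), dm, bg)
    }, numeric(1L)))
    if (.accept_delta(delta, temperature)) {
      aln$widths <- append(aln$widths, wb, after = g)
      aln$starts <- cbind(aln$starts[, seq_len(g), drop = FALSE],
                          newstart,
                          if (g < B) aln$starts[, (g + 1L):B, drop = FALSE])
      colnames(aln$starts) <- NULL
      aln$w <- sum(aln$widths)
    }
  }
  aln
}

#' Run the phase-1 block sampler
#'
#' Cycles of: a fresh random sequence order; a predictive-placement
#' Gibbs resampling of every sequence's blocks; edge-column moves on
#' both sides of every block; one block in/out move; a Henikoff weight
#' update.  Tracks the best integrated LLR seen and stops after
#' `patience` cycles without a new best (or at `max_cycles`).
#'
#' @param seqs a `seq_set` (K >= 2).
#' @param cfg a [phase1_config()].
#' @param dm,bg priors (defaults: packaged compact mixture, standard
#'   background).
#' @param aln optional starting `block_alignment` (else random init).
#' @param verbose print one line per cycle.
#' @return the best-scoring `block_alignment`, with attributes
#'   `llr` (its LLR) and `trace` (best-LLR trace, non-decreasing).
#' @export
run_phase1 <- function(seqs, cfg = phase1_config(),
                       dm = default_mixture("dm20"),
                       bg = default_background(),
                       aln = NULL, verbose = FALSE) {
  if (n_seq(seqs) < 2L) stop("need at least two sequences")
  if (is.null(aln)) aln <- init_random_blocks(seqs, cfg)
  Wt <- integerize_weights(henikoff_weights(aln_col_matrix(aln, seqs)))
  best <- aln
  best_llr <- integrated_block_llr(seqs, aln, dm, bg, Wt)
  trace <- best_llr
  stale <- 0L
  for (cycle in seq_len(cfg$max_cycles)) {
    for (k in sample.int(n_seq(seqs))) {
      aln <- resample_sequence_blocks(aln, seqs, k, dm, bg, Wt,
                                      cfg$temperature)
    }
    for (b in seq_along(aln$widths)) {
      for (side in c("left", "right")) {
        aln <- sample_edge_column(aln, seqs, b, side, dm, bg, Wt,
                                  cfg$temperature)
      }
    }
    aln <- sample_block_in_out(aln, seqs, dm, bg, Wt, cfg$temperature, cfg)
    Wt <- integerize_weights(henikoff_weights(aln_col_matrix(aln, seqs)))
    llr <- integrated_block_llr(seqs, aln, dm, bg, Wt)
    if (llr > best_llr) {
      best_llr <- llr; best <- aln; stale <- 0L
    } else stale <- stale + 1L
    trace <- c(trace, best_llr)
    if (verbose)
      message(sprintf("phase1 cycle %d: LLR %.1f (best %.1f), w=%d",
                      cycle, llr, best_llr, aln$w))
    if (stale >= cfg$patience) break
  }
  attr(best, "llr") <- best_llr
  attr(best, "trace") <- trace
  best
}
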