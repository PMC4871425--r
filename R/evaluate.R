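# ---------------------------------------------------------------------------
# SP-score benchmark evaluation, column diagnostics, and the planted-domain
# generator that makes the whole sampler testable without external data.

#' Sum-of-pairs accuracy of a test alignment against a benchmark
#'
#' The SP-score is the proportion of aligned residue pairs of the
#' benchmark MSA (two residues of different sequences in the same match
#' column) that are similarly aligned (share a match column) in the
#' test MSA.  Residues the benchmark leaves unaligned are ignored
#' entirely, so a test alignment is neither penalized nor advantaged
#' for aligning them.
#'
#' @param benchmark,test `gapped_msa` objects over the same sequences.
#' @return list of class `sp_result`: `score` in `[0,1]`, `counted`
#'   benchmark pairs, `matched` pairs (score 0 with a warning when the
#'   benchmark has no aligned pair).
#' @export
sp_score <- function(benchmark, test) {
  ord <- match(benchmark$ids, test$ids)
  if (anyNA(ord)) stop("sequence ids differ between benchmark and test")
  ba <- msa_assignments(benchmark)
  ta <- msa_assignments(test)[ord]
  for (k in seq_along(ba))
    if (length(ba[[k]]) != length(ta[[k]]))
      stop("residues differ between benchmark and test for '",
           benchmark$ids[k], "'")
  counted <- 0; matched <- 0
  # per benchmark column: test columns of the residues aligned there
  K <- length(ba)
  bcol <- vector("list", benchmark$w)
  for (j in seq_len(benchmark$w)) bcol[[j]] <- integer(0)
  for (k in seq_len(K)) {
    nz <- which(ba[[k]] > 0L)
    for (i in nz) bcol[[ba[[k]][i]]] <- c(bcol[[ba[[k]][i]]], ta[[k]][i])
  }
  for (j in seq_len(benchmark$w)) {
    tcols <- bcol[[j]]
    m <- length(tcols)
    if (m < 2L) next
    counted <- counted + m * (m - 1) / 2
    tc <- tcols[tcols > 0L]
    if (length(tc)) {
      tab <- table(tc)
      matched <- matched + sum(tab * (tab - 1) / 2)
    }
  }
  if (counted == 0) {
    warning("benchmark has no aligned residue pairs; SP-score undefined (0)")
    score <- 0
  } else score <- matched / counted
  structure(list(score = score, counted = counted, matched = matched),
            class = "sp_result")
}

#' @export
print.sp_result <- function(x, ...) {
  cat(sprintf("SP-score %.4f (%d / %d benchmark pairs matched)\n",
              x$score, x$matched, x$counted))
  invisible(x)
}

#' Relative entropy of a column against the background
#'
#' `sum_a f_a log(f_a / theta0_a)` in nats, with `f` the normalized
#' (weighted) column counts; nonnegative, zero iff `f = theta0`, and
#' invariant to scaling the counts.
#'
#' @param counts weighted length-20 counts (sum > 0).
#' @param bg an `aa_background`.
#' @return relative entropy in nats.
#' @export
column_relative_entropy <- function(counts, bg) {
  n <- sum(counts)
  if (n <= 0) stop("relative entropy undefined for empty counts")
  f <- counts / n
  pos <- f > 0
  sum(f[pos] * log(f[pos] / bg$theta0[pos]))
}

#' Specification of a planted-domain synthetic sequence set
#'
#' Describes the regime the sampler targets: K full-length sequences
#' sharing one co-linear multi-block domain, with position-clustered
#' indels at the inter-block hotspots and unrelated background flanks.
#' The `"cdd_like"` preset is the package's desk-scale stand-in for a
#' curated-domain benchmark set: K = 50, blocks of 12/18/10 columns,
#' per-column Dirichlet conservation concentration 20 around a
#' background-drawn consensus residue, insertions at inter-block
#' hotspots in 30% of sequences with geometric(mean 8) lengths,
#' deletions in 10% with geometric(mean 2) column runs, and
#' geometric(mean 60) flanks.
#'
#' @param preset `"cdd_like"` or `"none"`.
#' @param ... overrides of individual fields: `K`, `widths`,
#'   `conservation`, `ins_prob`, `ins_mean`, `del_prob`, `del_mean`,
#'   `flank_mean`, `dup` (tight-cluster duplication factor), `bg`.
#' @return list of class `planted_spec`.
#' @export
planted_spec <- function(preset = c("cdd_like", "none"), ...) {
  preset <- match.arg(preset)
  spec <- list(K = 50L, widths = c(12L, 18L, 10L), conservation = 20,
               ins_prob = 0.3, ins_mean = 8, del_prob = 0.1, del_mean = 2,
               flank_mean = 60, dup = 1L, bg = default_background())
  over <- list(...)
  for (nm in names(over)) spec[[nm]] <- over[[nm]]
  stopifnot(spec$K >= 2L, all(spec$widths >= 1L),
            spec$ins_prob >= 0, spec$ins_prob <= 1,
            spec$del_prob >= 0, spec$del_prob <= 1, spec$dup >= 1L)
  structure(spec, class = "planted_spec")
}

#' Generate a planted-domain sequence set with its truth alignment
#'
#' For each sequence: background flanks drawn from theta0, domain block
#' columns emitted from per-column Dirichlet-concentrated residue
#' distributions, insertions of background residues at the inter-block
#' hotspots, and column-run deletions at block starts.  The exact truth
#' alignment is recorded as a `gapped_msa`.  Deterministic under
#' `set.seed`; a duplication factor d yields d exact copies of every
#' base sequence (for tight-cluster tests).
#'
#' @param spec a [planted_spec()].
#' @return list with `seqs` (a `seq_set`), `truth` (a `gapped_msa`),
#'   `theta` (the 20 x w column distributions used).
#' @export
generate_planted_set <- function(spec = planted_spec()) {
  bg <- spec$bg
  w <- sum(spec$widths)
  B <- length(spec$widths)
  block_of <- rep(seq_len(B), spec$widths)
  # per-column emission distributions
  theta <- matrix(0, 20L, w)
  for (j in seq_len(w)) {
    if (spec$conservation <= 0) theta[, j] <- bg$theta0
    else {
      cons <- sample.int(20L, 1L, prob = bg$theta0)
      a <- spec$conservation * (seq_len(20L) == cons) + bg$theta0
      g <- rgamma(20L, shape = a, rate = 1)
      theta[, j] <- g / sum(g)
    }
  }
  rbg <- function(n) if (n <= 0) integer(0) else
    sample.int(20L, n, replace = TRUE, prob = bg$theta0)
  ids <- character(0); seqs <- list(); assigns <- list()
  for (k in seq_len(spec$K)) {
    # deletions: per interior hotspot, a run of columns at the next
    # block's start
    deleted <- rep(FALSE, w)
    if (B > 1L && spec$del_prob > 0) {
      for (b in seq_len(B - 1L)) {
        if (runif(1L) < spec$del_prob) {
          len <- min(1L + rgeom(1L, 1 / spec$del_mean),
                     spec$widths[b + 1L] - 1L)
          if (len > 0L) {
            start <- sum(spec$widths[seq_len(b)]) + 1L
            deleted[start:(start + len - 1L)] <- TRUE
          }
        }
      }
    }
    res <- integer(0); assign <- integer(0)
    lead <- rbg(rgeom(1L, 1 / (spec$flank_mean + 1)))
    res <- c(res, lead); assign <- c(assign, integer(length(lead)))
    for (j in seq_len(w)) {
      # an insert run may not abut a deleted column (the HMM architecture
      # forbids I next to D), so hotspots with a deletion get no insertion
      if (j > 1L && block_of[j] != block_of[j - 1L] && !deleted[j] &&
          spec$ins_prob > 0 && runif(1L) < spec$ins_prob) {
        ins <- rbg(1L + rgeom(1L, 1 / spec$ins_mean))
        res <- c(res, ins); assign <- c(assign, integer(length(ins)))
      }
      if (!deleted[j]) {
        res <- c(res, sample.int(20L, 1L, prob = theta[, j]))
        assign <- c(assign, j)
      }
    }
    trail <- rbg(rgeom(1L, 1 / (spec$flank_mean + 1)))
    res <- c(res, trail); assign <- c(assign, integer(length(trail)))
    ids <- c(ids, sprintf("seq%03d", k))
    seqs <- c(seqs, list(res)); assigns <- c(assigns, list(assign))
  }
  if (spec$dup > 1L) {
    ids <- unlist(lapply(seq_len(spec$K), function(k) {
      c(ids[k], paste0(ids[k], ".", seq_len(spec$dup - 1L) + 1L))
    }))
    seqs <- rep(seqs, each = spec$dup)
    assigns <- rep(assigns, each = spec$dup)
  }
  sset <- seq_set(ids, seqs)
  rows <- vapply(seq_along(seqs), function(k)
    .state_row(seqs[[k]], assigns[[k]], w), character(1L))
  list(seqs = sset, truth = gapped_msa(ids, rows), theta = theta)
}

#' Generate unrelated background sequences
#'
#' I.i.d. residues from the background distribution: the null regime in
#' which no alignment is statistically supported.
#'
#' @param K number of sequences.
#' @param len sequence length (recycled).
#' @param bg an `aa_background`.
#' @return a `seq_set`.
#' @export
random_seq_set <- function(K, len = 300L, bg = default_background()) {
  len <- rep_len(len, K)
  seq_set(sprintf("rnd%03d", seq_len(K)),
          lapply(len, function(n)
            sample.int(20L, n, replace = TRUE, prob = bg$theta0)))
}
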