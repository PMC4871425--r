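# Shared fixtures and independent oracles.  Oracles are deliberately
# naive (enumeration / sequential predictive products / hand recursion)
# and never call the code paths they check.

TC_ROWS <- c("mm", "mi", "md", "im", "ii", "dm", "dd")

empty_tc <- function(w) {
  matrix(0, 7L, w + 1L, dimnames = list(TC_ROWS, NULL))
}

# sequential predictive product: log P(residue sequence) under a Dirichlet
# mixture, tracking per-component posterior weights residue by residue
log_polya_mix_oracle <- function(res, dm) {
  lw <- log(dm$rho)          # running log component weights (unnormalized)
  counts <- numeric(20L)
  total <- 0
  for (r in res) {
    wnorm <- exp(lw - max(lw)); wnorm <- wnorm / sum(wnorm)
    pred <- sum(vapply(seq_len(dm$L), function(l) {
      a <- dm$alpha[l, ]
      wnorm[l] * (a[r] + counts[r]) / (sum(a) + sum(counts))
    }, numeric(1L)))
    total <- total + log(pred)
    # update component weights with this observation
    lw <- lw + vapply(seq_len(dm$L), function(l) {
      a <- dm$alpha[l, ]
      log((a[r] + counts[r]) / (sum(a) + sum(counts)))
    }, numeric(1L))
    counts[r] <- counts[r] + 1
  }
  total
}

# all legal assignment vectors of an n-residue sequence against w columns
enumerate_assignments <- function(n, w) {
  out <- list()
  valid_prefix <- function(a, i) {
    nz <- which(a[1:i] > 0)
    cols <- a[nz]
    if (length(cols) > 1 && any(diff(cols) <= 0)) return(FALSE)
    if (length(nz) >= 2) {
      gaps <- diff(nz) - 1
      if (any(gaps > 0 & diff(cols) != 1)) return(FALSE)
    }
    TRUE
  }
  rec <- function(a, i) {
    if (i > n) { out[[length(out) + 1]] <<- a; return(invisible()) }
    for (v in 0:w) {
      a[i] <- v
      if (valid_prefix(a, i)) rec(a, i + 1)
    }
  }
  rec(integer(n), 1L)
  out
}

# independent path score under the phase-2 state graph
path_score_oracle <- function(a, res, elo, ltr, lfl = log(0.99)) {
  w <- ncol(elo); n <- length(res)
  nz <- which(a > 0); cols <- a[nz]
  sc <- 0
  for (t in seq_along(nz)) {
    r <- res[nz[t]]
    if (!is.na(r)) sc <- sc + elo[r, cols[t]]
  }
  mstate <- logical(w); mstate[cols] <- TRUE
  runs <- integer(w + 1)
  if (length(nz) >= 2) {
    gaps <- diff(nz) - 1
    for (t in which(gaps > 0)) runs[cols[t] + 1] <- gaps[t]
  }
  s <- c(TRUE, mstate, TRUE)
  for (j in 0:w) {
    r <- runs[j + 1]
    if (r > 0) {
      sc <- sc + ltr["mi", j + 1] + (r - 1) * ltr["ii", j + 1] +
        ltr["im", j + 1]
    } else {
      type <- paste0(if (s[j + 1]) "m" else "d", if (s[j + 2]) "m" else "d")
      sc <- sc + ltr[type, j + 1]
    }
  }
  unname(sc + (n - length(nz) - sum(runs)) * lfl)
}

# brute-force SP-score: enumerate all benchmark residue pairs directly
sp_score_oracle <- function(benchmark, test) {
  ba <- msa_assignments(benchmark)
  ta <- msa_assignments(test)[match(benchmark$ids, test$ids)]
  K <- length(ba)
  counted <- 0; matched <- 0
  for (k1 in seq_len(K - 1)) for (k2 in (k1 + 1):K) {
    for (i1 in which(ba[[k1]] > 0)) for (i2 in which(ba[[k2]] > 0)) {
      if (ba[[k1]][i1] == ba[[k2]][i2]) {
        counted <- counted + 1
        if (ta[[k1]][i1] > 0 && ta[[k1]][i1] == ta[[k2]][i2])
          matched <- matched + 1
      }
    }
  }
  list(counted = counted, matched = matched,
       score = if (counted) matched / counted else 0)
}

# random gapped MSA over random sequences (for round-trip properties)
random_gapped_msa <- function(K = 5, w = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- vapply(seq_len(K), function(k) {
    parts <- character(0)
    lead <- sample(0:3, 1)
    if (lead) parts <- c(parts, tolower(aa_decode(sample.int(20, lead, TRUE))))
    for (j in seq_len(w)) {
      if (runif(1) < 0.15) parts <- c(parts, "-")
      else parts <- c(parts, aa_decode(sample.int(20, 1)))
      nins <- sample(0:2, 1, prob = c(0.7, 0.2, 0.1))
      if (nins && j < w)
        parts <- c(parts, tolower(aa_decode(sample.int(20, nins, TRUE))))
    }
    trail <- sample(0:3, 1)
    if (trail) parts <- c(parts, tolower(aa_decode(sample.int(20, trail, TRUE))))
    paste(parts, collapse = "")
  }, character(1))
  gapped_msa(paste0("s", seq_len(K)), rows)
}

# small planted set shared by several tests
small_planted <- function(seed = 11, K = 8, flank = 10) {
  set.seed(seed)
  generate_planted_set(planted_spec(K = K, flank_mean = flank))
}

# tight-cluster insertion-boundary trap: `n_other` diverse domain
# sequences without hotspot insertions plus `dup` exact copies of one
# more sequence carrying a long insertion whose boundary is planted
# three columns early.  The learned insert-extension probabilities at
# the wrong position self-reinforce the cluster's misalignment.
make_trap_instance <- function(n_other = 40, dup = 10, ins_len = 27,
                               dm = default_mixture("dm58"),
                               bg = default_background(),
                               tp = transition_priors()) {
  gen <- generate_planted_set(planted_spec(K = n_other + 1, ins_prob = 0,
                                           del_prob = 0, flank_mean = 40))
  w <- gen$truth$w
  base_assign <- msa_assignments(gen$truth)
  k0 <- n_other + 1
  a0 <- base_assign[[k0]]; r0 <- gen$seqs$seqs[[k0]]
  cut <- which(a0 == 12)
  ins <- sample.int(20, ins_len, replace = TRUE, prob = bg$theta0)
  r1 <- c(r0[1:cut], ins, r0[(cut + 1):length(r0)])
  a_true <- c(a0[1:cut], integer(ins_len), a0[(cut + 1):length(a0)])
  a_trap <- a_true
  a_trap[vapply(10:12, function(j) which(a_true == j), integer(1))] <- 0L
  ins_pos <- cut + seq_len(ins_len)
  a_trap[ins_pos[(ins_len - 2):ins_len]] <- c(10L, 11L, 12L)
  ids <- c(gen$seqs$ids[1:n_other], paste0("dup", seq_len(dup)))
  seqs <- c(gen$seqs$seqs[1:n_other], rep(list(r1), dup))
  sset <- seq_set(ids, seqs)
  state <- msa_state(sset,
                     c(base_assign[1:n_other], rep(list(a_trap), dup)),
                     w, dm, bg, tp)
  list(state = state, members = n_other + seq_len(dup),
       truth = c(base_assign[1:n_other], rep(list(a_true), dup)))
}

trap_mismatch <- function(state, trap) {
  sum(vapply(trap$members, function(k)
    sum(state$assigns[[k]] != trap$truth[[k]]), numeric(1)))
}
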