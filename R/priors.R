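#' Construct a Dirichlet mixture prior over amino-acid frequencies
#'
#' A mixture of L Dirichlet components: mixture coefficients `rho`
#' (positive, summing to 1) and a 20-column matrix of positive
#' concentration parameters `alpha` (one row per component, residues in
#' `ACDEFGHIKLMNPQRSTVWY` order).  The single-component case doubles as
#' the plain per-column Dirichlet prior of the block model.
#'
#' @param rho numeric vector of mixture coefficients.
#' @param alpha L x 20 matrix of concentrations.
#' @param name provenance string.
#' @return object of class `dirichlet_mixture`.
#' @export
dirichlet_mixture <- function(rho, alpha, name = "unnamed") {
  alpha <- matrix(as.numeric(alpha), nrow = length(rho))
  stopifnot(ncol(alpha) == 20L)
  if (any(rho <= 0)) stop("mixture coefficients must be positive")
  if (abs(sum(rho) - 1) > 1e-8) stop("mixture coefficients must sum to 1")
  if (any(alpha <= 0)) stop("Dirichlet parameters must be positive")
  structure(list(rho = as.numeric(rho) / sum(rho), alpha = alpha,
                 name = name, L = length(rho)),
            class = "dirichlet_mixture")
}

#' @export
print.dirichlet_mixture <- function(x, ...) {
  cat(sprintf("dirichlet_mixture '%s': L=%d components, |alpha| %.2f..%.2f\n",
              x$name, x$L, min(rowSums(x$alpha)), max(rowSums(x$alpha))))
  invisible(x)
}

#' Background residue distribution
#'
#' `theta0` is the background amino-acid distribution used in every
#' log-odds denominator; `alpha` is its Dirichlet parameter vector
#' (`conc * theta0`).
#'
#' @param theta0 length-20 positive probabilities summing to 1.
#' @param conc total concentration for the Dirichlet parameterization.
#' @return object of class `aa_background`.
#' @export
background <- function(theta0, conc = 20) {
  theta0 <- as.numeric(theta0)
  stopifnot(length(theta0) == 20L)
  if (any(theta0 <= 0)) stop("background must be strictly positive")
  if (abs(sum(theta0) - 1) > 1e-12) theta0 <- theta0 / sum(theta0)
  structure(list(theta0 = theta0, alpha = conc * theta0),
            class = "aa_background")
}

#' Default background: Robinson-Robinson amino-acid frequencies
#' @return an [background()] object.
#' @export
default_background <- function() {
  # Robinson & Robinson (1991) frequencies, ACDEFGHIKLMNPQRSTVWY order
  f <- c(0.07805, 0.01925, 0.05364, 0.06295, 0.03856, 0.07377, 0.02199,
         0.05142, 0.05744, 0.09019, 0.02243, 0.04487, 0.05203, 0.04264,
         0.05129, 0.07120, 0.05841, 0.06441, 0.01330, 0.03216)
  background(f / sum(f))
}

#' Mean distribution of a Dirichlet mixture
#' @param dm a `dirichlet_mixture`.
#' @return length-20 probability vector: rho-weighted component means.
#' @export
mixture_mean <- function(dm) {
  m <- sweep(dm$alpha, 1L, rowSums(dm$alpha), "/")
  drop(dm$rho %*% m)
}

#' Read a Dirichlet mixture text file
#'
#' Format: optional `#` comment lines, then a line with the component
#' count L, then one line per component `rho alpha_1 ... alpha_20`
#' (residues in alphabetical one-letter order `ACDEFGHIKLMNPQRSTVWY`).
#'
#' @param path file path.
#' @param quiet suppress the component-count message.
#' @return a [dirichlet_mixture()].
#' @export
read_dirichlet_mixture <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  name <- sub("^#\\s*", "", lines[grepl("^#", lines)][1])
  if (is.na(name)) name <- basename(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  L <- suppressWarnings(as.integer(lines[1L]))
  if (is.na(L) || L < 1L) stop("malformed mixture file: bad component count")
  if (length(lines) != L + 1L)
    stop("malformed mixture file: expected ", L, " component lines")
  mat <- t(vapply(lines[-1L], function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
    if (length(v) != 21L || anyNA(v))
      stop("malformed mixture component line: '", l, "'")
    v
  }, numeric(21L), USE.NAMES = FALSE))
  if (any(mat <= 0)) stop("non-positive mixture parameter")
  dm <- dirichlet_mixture(mat[, 1L] / sum(mat[, 1L]), mat[, -1L], name = name)
  if (!quiet) message("loaded Dirichlet mixture '", name, "' with L=", dm$L,
                      " components")
  dm
}

#' Write a Dirichlet mixture text file
#' @param dm a `dirichlet_mixture`.
#' @param path output path.
#' @export
write_dirichlet_mixture <- function(dm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", dm$name), con)
  writeLines(paste0("# one line per component: rho alpha_A..alpha_Y (",
                    paste(AA_ALPHABET, collapse = ""), ")"), con)
  writeLines(as.character(dm$L), con)
  for (l in seq_len(dm$L))
    writeLines(paste(format(c(dm$rho[l], dm$alpha[l, ]), digits = 8,
                            scientific = FALSE, trim = TRUE),
                     collapse = " "), con)
  invisible(NULL)
}

#' Packaged default mixtures (synthetic stand-ins)
#'
#' The compact (20-component) mixture used during the competitive phase-1
#' stage and the larger (58-component) mixture used afterwards.  These
#' are *synthetic* stand-ins constructed from the background
#' distribution, single-residue components and chemically similar residue
#' groups; any published amino-acid Dirichlet mixture file in the same
#' format may be substituted.
#'
#' @param which `"dm20"` or `"dm58"`.
#' @return a [dirichlet_mixture()].
#' @export
default_mixture <- function(which = c("dm20", "dm58")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("synthetic-", which, ".txt"),
                      package = "gibbsmsa")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", paste0("synthetic-", which, ".txt"))
  read_dirichlet_mixture(path, quiet = TRUE)
}

# ---------------------------------------------------------------------------
# Polya (Dirichlet-multinomial) machinery

#' Log Polya (Dirichlet-multinomial) marginal of a count vector
#'
#' `log P(counts | alpha)` with the multinomial parameter integrated
#' against `Dirichlet(alpha)`, omitting the multinomial coefficient
#' (counts are treated as an ordered sequence of residues, as in
#' sequential predictive products).  Accepts fractional (weighted)
#' counts via the log-Gamma function.
#'
#' @param counts nonnegative length-20 numeric.
#' @param alpha positive length-20 numeric.
#' @return log marginal likelihood in nats.
#' @export
log_polya <- function(counts, alpha) {
  sum(lgamma(counts + alpha) - lgamma(alpha)) +
    lgamma(sum(alpha)) - lgamma(sum(counts) + sum(alpha))
}

# componentwise log Polya for a counts vector under every component of dm
.log_polya_mix_components <- function(counts, dm) {
  n <- sum(counts)
  vapply(seq_len(dm$L), function(l) {
    a <- dm$alpha[l, ]
    sum(lgamma(counts + a) - lgamma(a)) + lgamma(sum(a)) - lgamma(n + sum(a))
  }, numeric(1L))
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log prior-predictive (mixture Polya) of a column's counts
#' @param counts weighted length-20 counts.
#' @param dm a `dirichlet_mixture`.
#' @return `log sum_l rho_l Polya(counts; alpha_l)` in nats.
#' @export
log_polya_mixture <- function(counts, dm) {
  .logsumexp(log(dm$rho) + .log_polya_mix_components(counts, dm))
}

# posterior component responsibilities rho'_l given counts
.component_posterior <- function(counts, dm) {
  lw <- log(dm$rho) + .log_polya_mix_components(counts, dm)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Posterior-mean emission probabilities for a column
#'
#' The posterior mean of the column's multinomial parameter theta under
#' the Dirichlet-mixture prior, given (weighted) observed counts:
#' `sum_l rho'_l (counts + alpha_l)/|counts + alpha_l|` with
#' `rho'_l` proportional to `rho_l * Polya(counts; alpha_l)`.
#'
#' @param counts weighted length-20 counts.
#' @param dm a `dirichlet_mixture`.
#' @return length-20 probability vector.
#' @export
posterior_mean_emissions <- function(counts, dm) {
  rp <- .component_posterior(counts, dm)
  post <- sweep(dm$alpha, 2L, counts, "+")
  drop(rp %*% sweep(post, 1L, rowSums(post), "/"))
}

#' Sample an emission probability vector from the column posterior
#'
#' Draws a mixture component with its posterior responsibility, then a
#' Dirichlet variate with parameters `counts + alpha_l`.  Uses R's RNG:
#' reproducible under `set.seed`.
#'
#' @inheritParams posterior_mean_emissions
#' @return length-20 probability vector.
#' @export
sample_emission_vector <- function(counts, dm) {
  rp <- .component_posterior(counts, dm)
  l <- sample.int(dm$L, 1L, prob = rp)
  g <- rgamma(20L, shape = counts + dm$alpha[l, ], rate = 1)
  g / sum(g)
}

# L x w matrix of per-column log(rho_l) + log Polya(counts_j; alpha_l)
.component_logpost_matrix <- function(counts_mat, dm) {
  w <- ncol(counts_mat)
  n <- colSums(counts_mat)
  lp <- matrix(0, dm$L, w)
  for (l in seq_len(dm$L)) {
    a <- dm$alpha[l, ]
    lp[l, ] <- colSums(lgamma(counts_mat + a)) - sum(lgamma(a)) +
      lgamma(sum(a)) - lgamma(n + sum(a))
  }
  lp + log(dm$rho)
}

# per-column posterior component responsibilities (L x w)
.responsibility_matrix <- function(counts_mat, dm) {
  lp <- .component_logpost_matrix(counts_mat, dm)
  m <- apply(lp, 2L, max)
  e <- exp(sweep(lp, 2L, m, "-"))
  sweep(e, 2L, colSums(e), "/")
}

# sample emissions for all columns of a counts matrix (20 x w) at once
.sample_emission_matrix <- function(counts_mat, dm) {
  w <- ncol(counts_mat)
  if (w == 0L) return(matrix(0, 20L, 0L))
  rp <- .responsibility_matrix(counts_mat, dm)
  comp <- vapply(seq_len(w), function(j)
    sample.int(dm$L, 1L, prob = rp[, j]), integer(1L))
  shape <- counts_mat + t(dm$alpha[comp, , drop = FALSE])
  g <- matrix(rgamma(20L * w, shape = as.vector(shape), rate = 1), 20L, w)
  sweep(g, 2L, colSums(g), "/")
}

#' Bayesian integral log-odds (BILD) score of a column
#'
#' The prior-predictive log-odds of the column's (weighted) residue
#' counts under the Dirichlet-mixture model versus the fixed background:
#' `ln[ sum_l rho_l Polya(counts; alpha_l) / prod_a theta0_a^counts_a ]`,
#' in nats.  Additive over columns; zero for an empty column.  A positive
#' score means the column is statistically supported.
#'
#' @param counts weighted length-20 counts.
#' @param dm a `dirichlet_mixture`.
#' @param bg an `aa_background`.
#' @return score in nats.
#' @export
bild_score <- function(counts, dm, bg) {
  if (sum(counts) == 0) return(0)
  log_polya_mixture(counts, dm) - sum(counts * log(bg$theta0))
}

# vectorized over the columns of a 20 x w counts matrix
.bild_scores <- function(counts_mat, dm, bg) {
  if (is.null(dim(counts_mat))) counts_mat <- matrix(counts_mat, nrow = 20L)
  w <- ncol(counts_mat)
  if (w == 0L) return(numeric(0))
  n <- colSums(counts_mat)
  lp <- .component_logpost_matrix(counts_mat, dm)
  m <- apply(lp, 2L, max)
  mix <- m + log(colSums(exp(sweep(lp, 2L, m, "-"))))
  out <- mix - colSums(counts_mat * log(bg$theta0))
  out[n == 0] <- 0
  out
}

# posterior-mean emissions for all columns of a 20 x w counts matrix
.posterior_mean_matrix <- function(counts_mat, dm) {
  w <- ncol(counts_mat)
  if (w == 0L) return(matrix(0, 20L, 0L))
  rp <- .responsibility_matrix(counts_mat, dm)
  out <- matrix(0, 20L, w)
  n <- colSums(counts_mat)
  for (l in seq_len(dm$L)) {
    a <- dm$alpha[l, ]
    out <- out + sweep(counts_mat + a, 2L,
                       rp[l, ] / (n + sum(a)), "*")
  }
  out
}
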