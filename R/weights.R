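#' Henikoff position-based sequence weights
#'
#' Raw weight of sequence k over the current match columns:
#' `wt(k) = sum_j 1 / (Nt_j * Nr_{k,j})`, where `Nt_j` is the number of
#' residue types present in column j and `Nr_{k,j}` the number of
#' sequences carrying the same residue as k there.  In a gapped
#' alignment, columns where a sequence has a deletion are skipped for
#' that sequence (and its cell does not enter `Nt`/`Nr`).  Redundant
#' sequences share column credit and end up down-weighted.
#'
#' @param col_mat K x w integer matrix of residue codes at the aligned
#'   match columns (`NA` = deletion/unknown cell, skipped).
#' @return numeric raw weight per sequence (> 0 where defined; sequences
#'   with no aligned cell get the minimum positive weight).
#' @export
henikoff_weights <- function(col_mat) {
  col_mat <- as.matrix(col_mat)
  K <- nrow(col_mat); w <- ncol(col_mat)
  if (w == 0L) stop("weights undefined: alignment has no match columns")
  wt <- numeric(K)
  for (j in seq_len(w)) {
    cj <- col_mat[, j]
    keep <- !is.na(cj)
    if (!any(keep)) next
    tab <- table(cj[keep])
    nt <- length(tab)
    nr <- as.integer(tab[as.character(cj[keep])])
    wt[keep] <- wt[keep] + 1 / (nt * nr)
  }
  if (any(wt == 0)) {
    pos <- wt[wt > 0]
    wt[wt == 0] <- if (length(pos)) min(pos) else 1
  }
  wt
}

#' Normalize and integerize raw weights
#'
#' `Wt(k) = ceiling(100 * wt(k) / wt_max)`: integers in 1..100 with at
#' least one sequence at 100.  Downstream, weighted counts use
#' `Wt(k)/100` so one unique sequence contributes about one count.
#'
#' @param raw positive raw weight vector.
#' @return integer weights in 1..100.
#' @export
integerize_weights <- function(raw) {
  if (any(raw <= 0)) stop("raw weights must be positive")
  # epsilon guards the ratio 1 case against floating-point overshoot
  as.integer(ceiling(100 * raw / max(raw) - 1e-9))
}

#' Weight state for the evolving alignment
#'
#' Holds raw and integerized weights plus the frozen flag: weights are
#' updated after each sampling cycle while the alignment evolves and are
#' frozen for the final stage of sampling (here: when the annealing
#' temperature first drops below 1).
#'
#' @param col_mat K x w residue-code matrix of the current match columns.
#' @param frozen logical.
#' @return object of class `weight_state` with `raw`, `int`, `frozen`.
#' @export
weight_state <- function(col_mat, frozen = FALSE) {
  raw <- henikoff_weights(col_mat)
  structure(list(raw = raw, int = integerize_weights(raw), frozen = frozen),
            class = "weight_state")
}

#' Update weights from the current alignment
#'
#' Recomputes Henikoff weights unless the state is frozen, in which case
#' the input is returned unchanged.
#'
#' @param state a `weight_state`.
#' @param col_mat K x w residue-code matrix of the current match columns.
#' @return updated `weight_state`.
#' @export
update_weights <- function(state, col_mat) {
  if (isTRUE(state$frozen)) return(state)
  weight_state(col_mat, frozen = FALSE)
}
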