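#' Scaled confusion matrix from a prediction list and a confirmed subset
#'
#' Wet-lab confirmation covers only a sample of the real mutations, so raw
#' overlap counts must be scaled. Assuming the confirmed set is a uniform
#' sample of the \code{M} real mutations, the true positives are estimated
#' as \code{overlap * M / n_confirmed} (rounded, then capped at \code{pred}
#' so false positives stay non-negative). Specificity counts positions, not
#' position-change combinations: its denominator is
#' \code{n_positions - M}.
#'
#' @param pred Number of predictions emitted.
#' @param overlap Predictions that match the confirmed set.
#' @param n_confirmed Size of the confirmed set.
#' @param M Expected total number of real mutations.
#' @param n_positions Total sequenced reference positions.
#' @return List with \code{TP}, \code{FP}, \code{FN}, \code{sensitivity}
#'   and \code{specificity} (percentages, rounded to 2 decimals).
#' @examples
#' scaled_confusion(107, 36, 39, 107, 4670)  # TP 99, FP 8, FN 8
#' @export
scaled_confusion <- function(pred, overlap, n_confirmed, M, n_positions) {
  stopifnot(overlap <= pred, overlap <= n_confirmed, n_confirmed >= 1,
            M >= 1, n_positions > M, pred >= 0)
  TP <- min(pred, round(overlap * M / n_confirmed))
  FP <- pred - TP
  FN <- M - TP
  list(TP = TP, FP = FP, FN = FN,
       sensitivity = round(100 * TP / M, 2),
       specificity = round(100 * (n_positions - M - FP) / (n_positions - M), 2))
}

#' Count predictions matching a truth table
#'
#' @param calls Data frame of calls with \code{seqid}, \code{pos},
#'   \code{alt} and (when \code{require_carrier}) \code{well}.
#' @param truth Data frame of true mutations with the same columns.
#' @param require_carrier Must the carrier well also match (default TRUE)?
#'   Position + change matching only (as granted to methods that do not
#'   identify carriers) when FALSE.
#' @return Number of calls matching truth entries; each truth entry matches
#'   at most once.
#' @export
match_calls <- function(calls, truth, require_carrier = TRUE) {
  if (nrow(calls) == 0L || nrow(truth) == 0L) return(0L)
  keyf <- function(d) {
    if (require_carrier) paste(d$seqid, d$pos, d$alt, d$well, sep = "\r")
    else paste(d$seqid, d$pos, d$alt, sep = "\r")
  }
  sum(!is.na(match(unique(keyf(truth)), keyf(calls))))
}

#' Evaluate a call set against a confirmed subset at several budgets
#'
#' Convenience wrapper reproducing the threshold-sweep evaluation layout:
#' for each budget, predictions are the top calls, overlap is computed
#' against the confirmed set, and the scaled confusion matrix is derived.
#'
#' @param calls Ranked calls data frame (from \code{\link{select_calls}}).
#' @param confirmed Truth data frame of confirmed mutations.
#' @param M,n_positions See \code{\link{scaled_confusion}}.
#' @param budgets Integer vector of prediction counts to evaluate.
#' @param require_carrier See \code{\link{match_calls}}.
#' @return Data frame with one row per budget: \code{pred}, \code{conf},
#'   \code{FP}, \code{FN}, \code{sens}, \code{spec}.
#' @export
evaluate_budgets <- function(calls, confirmed, M, n_positions, budgets,
                             require_carrier = TRUE) {
  rows <- lapply(budgets, function(b) {
    sub <- utils::head(calls, b)
    ov <- match_calls(sub, confirmed, require_carrier)
    sc <- scaled_confusion(nrow(sub), ov, nrow(confirmed), M, n_positions)
    data.frame(pred = nrow(sub), conf = ov, FP = sc$FP, FN = sc$FN,
               sens = sc$sensitivity, spec = sc$specificity)
  })
  do.call(rbind, rows)
}
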