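#' Run the full caller over a set of positions
#'
#' preprocess -> model -> threshold: applies the coverage gate and
#' strand/count exclusions at every position, computes configuration
#' posteriors where the gate passes, and selects the final ranked call set.
#'
#' @param positions List of \code{\link{position_data}} (from
#'   \code{\link{assemble_positions}} or \code{\link{generate_counts}}).
#' @param design The \code{pool_design}.
#' @param params \code{\link{experiment_params}}.
#' @param n_predictions,f_cutoff Selection mode passed to
#'   \code{\link{select_calls}}; default emits every candidate, ranked.
#' @param min_total,alpha,hi,lo Preprocessing thresholds (see
#'   \code{\link{position_exclusions}}).
#' @param i_well,f_max Passed to \code{\link{position_posteriors}}.
#' @return List with \code{calls} (ranked data frame), \code{tables}
#'   (per-position \code{posterior_table}s of searched positions), and
#'   \code{stats} (counts of positions, gated, uncallable, vetoes).
#' @export
camba_call <- function(positions, design, params, n_predictions = NULL,
                       f_cutoff = NULL, min_total = 10000, alpha = 0.01,
                       hi = 10, lo = 0.1, i_well = design$i_well,
                       f_max = 700) {
  if (is.null(n_predictions) && is.null(f_cutoff)) f_cutoff <- -Inf
  tables <- list()
  n_gated <- 0L; n_uncallable <- 0L; n_vetoes <- 0L
  for (p in positions) {
    if (!p$ref %in% BASES) { n_uncallable <- n_uncallable + 1L; next }
    excl <- position_exclusions(p, min_total, alpha, hi, lo)
    if (excl$gated) { n_gated <- n_gated + 1L; next }
    n_vetoes <- n_vetoes + nrow(excl$reasons)
    tables[[length(tables) + 1L]] <-
      position_posteriors(p, design, params, excl, i_well = i_well,
                          f_max = f_max)
  }
  calls <- select_calls(tables, n_predictions, f_cutoff)
  list(calls = calls, tables = tables,
       stats = list(n_positions = length(positions), n_gated = n_gated,
                    n_uncallable = n_uncallable, n_vetoes = n_vetoes,
                    n_calls = nrow(calls)))
}

#' Empirical prediction budget via the split-pool procedure
#'
#' Convenience wrapper: splits one pool axis of the data into a pseudo
#' design (\code{\link{split_pool_axis}}), runs the caller on both the real
#' and pseudo designs, and applies
#' \code{\link{split_design_fp_threshold}}.
#'
#' @inheritParams camba_call
#' @param axis Which axis to split ("col" or "row").
#' @param target_fp_rate See \code{\link{split_design_fp_threshold}}.
#' @param ... Further arguments to \code{\link{camba_call}}.
#' @return List with \code{budget} and the two call sets (\code{full},
#'   \code{pseudo}).
#' @export
camba_split_budget <- function(positions, design, params, axis = "col",
                               target_fp_rate = 0.05, ...) {
  sp <- split_pool_axis(positions, design, axis)
  full <- camba_call(positions, design, params, ...)
  pseudo <- camba_call(sp$positions, sp$design, params,
                       i_well = design$i_well, ...)
  budget <- split_design_fp_threshold(full$calls$F, pseudo$calls$F, design,
                                      sp$g, target_fp_rate)
  list(budget = budget, full = full$calls, pseudo = pseudo$calls)
}
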