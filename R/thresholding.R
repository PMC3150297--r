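#' Expected number of induced mutations in an experiment
#'
#' Sums the induction probability of every possible base change at every
#' reference position over all individuals. A G or C site offers one
#' canonical change (G->A or C->T) and two non-canonical ones; an A or T
#' site offers three non-canonical changes, giving
#' \code{n_ind * (n_GC * (p_c + 2 p_nc) + n_AT * 3 p_nc)}.
#'
#' @param references A \code{Biostrings::DNAStringSet}, a character vector of
#'   sequences, or a list with per-base counts \code{n_GC} and \code{n_AT}.
#' @param params \code{\link{experiment_params}}.
#' @param n_individuals Individuals screened.
#' @return Expected mutation count (not rounded).
#' @export
expected_mutations <- function(references, params, n_individuals) {
  comp <- base_composition(references)
  n_individuals *
    (comp$n_GC * (params$p_c + 2 * params$p_nc) + comp$n_AT * 3 * params$p_nc)
}

base_composition <- function(references) {
  if (is.list(references) && !is.null(references$n_GC))
    return(references[c("n_GC", "n_AT")])
  seqs <- as.character(references)   # works for DNAStringSet and character
  if (length(seqs) == 0L) stop("no reference sequences")
  tab <- table(factor(unlist(strsplit(toupper(paste(seqs, collapse = "")),
                                      "")), levels = BASES))
  list(n_GC = sum(tab[c("G", "C")]), n_AT = sum(tab[c("A", "T")]))
}

#' Derive per-change induction probabilities from whole-sequence rates
#'
#' CEL I screens report induced mutation rates per sequenced base,
#' \code{i_c} (canonical) and \code{i_nc} (non-canonical). Dividing by the
#' number of opportunities per base gives the per-change probabilities:
#' \code{p_c = i_c / p_til(G,C)} (only G/C sites offer a canonical change)
#' and \code{p_nc = i_nc / (2 p_til(G,C) + 3 p_til(A,T))}.
#'
#' @param i_c,i_nc Induced mutation rates for canonical / non-canonical
#'   changes.
#' @param p_til_gc Fraction of TILLING reference bases that are G or C.
#' @param p_til_at Fraction that are A or T (default the complement).
#' @return List with \code{p_c} and \code{p_nc}.
#' @export
derive_rates <- function(i_c, i_nc, p_til_gc, p_til_at = 1 - p_til_gc) {
  stopifnot(abs(p_til_gc + p_til_at - 1) < 1e-9)
  denom_nc <- 2 * p_til_gc + 3 * p_til_at
  if (i_c > 0 && p_til_gc == 0) stop("rate underivable: no G/C content")
  if (i_nc > 0 && denom_nc == 0) stop("rate underivable")
  list(p_c = if (i_c == 0) 0 else i_c / p_til_gc,
       p_nc = if (i_nc == 0) 0 else i_nc / denom_nc)
}

#' Scale the expected mutation count into a prediction budget
#'
#' CEL I screening misses real mutations, so the expectation derived from it
#' underestimates the truth. A validated correction factor of 1.55 (107
#' wet-lab-supported wheat mutations over an initial estimate of 69) scales
#' the initial estimate into the number of calls to emit.
#'
#' @param initial Initial expected mutation count.
#' @param scaling Correction factor (default 1.55).
#' @return Integer prediction budget, rounded to nearest.
#' @export
scale_estimate <- function(initial, scaling = 1.55) {
  stopifnot(initial >= 0, scaling > 0)
  as.integer(round(initial * scaling))
}

#' Select final mutation calls from scored positions
#'
#' Each position contributes at most one candidate: its best
#' zygosity-collapsed (well, change) entry, provided that entry beats the
#' null configuration at that position. Candidates are ranked by descending
#' \code{F} score and cut either to a fixed budget (\code{n_predictions}) or
#' at a score cutoff (\code{f_cutoff}). Ties are broken by (sequence,
#' position) order for determinism.
#'
#' @param tables A list of \code{posterior_table}s
#'   (see \code{\link{position_posteriors}}).
#' @param n_predictions Call budget, or \code{NULL}.
#' @param f_cutoff Minimal \code{F} score, or \code{NULL}. Exactly one of
#'   the two modes must be given.
#' @return A data frame of calls: \code{seqid}, \code{pos}, \code{ref},
#'   \code{alt}, \code{row_library}, \code{column_library}, \code{well},
#'   \code{t}, \code{F}, \code{rank}.
#' @export
select_calls <- function(tables, n_predictions = NULL, f_cutoff = NULL) {
  if (is.null(n_predictions) == is.null(f_cutoff))
    stop("give exactly one of n_predictions or f_cutoff")
  cand <- candidate_table(tables)
  if (nrow(cand) == 0L) return(cand_with_rank(cand))
  ord <- order(-cand$F, cand$seqid, cand$pos)
  cand <- cand[ord, , drop = FALSE]
  if (!is.null(n_predictions)) {
    stopifnot(n_predictions >= 0)
    cand <- utils::head(cand, n_predictions)
  } else {
    cand <- cand[cand$F >= f_cutoff, , drop = FALSE]
  }
  cand_with_rank(cand)
}

candidate_table <- function(tables) {
  rows <- lapply(tables, function(tb) {
    b <- tb$best
    # positions where the null wins (or that have no mutant configuration)
    # are never emitted
    if (is.null(b) || b$t <= tb$null_posterior) return(NULL)
    data.frame(seqid = tb$seqid, pos = tb$pos, ref = tb$ref, alt = b$alt,
               row_library = b$row, column_library = b$col, well = b$well,
               t = b$t, F = b$F, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(seqid = character(), pos = integer(), ref = character(),
                      alt = character(), row_library = character(),
                      column_library = character(), well = character(),
                      t = numeric(), F = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

cand_with_rank <- function(cand) {
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand
}

#' Split-design empirical false-positive threshold
#'
#' Without a prior CEL I screen the budget can be set empirically: split one
#' pool axis (say the 12 column pools) into two halves and treat them as the
#' rows and columns of a pseudo bi-dimensional design. A real mutation
#' virtually never recurs in two independent pools of the same axis, so
#' every call on the pseudo design is a false positive; scaled up by the
#' ratio of well-pair counts (\code{n_rows*n_cols / g^2} for halves of size
#' \code{g}), the pseudo-call count at a score cutoff estimates the false
#' positives among the real design's candidates at that cutoff. The budget
#' returned is the largest candidate count whose estimated FP rate is
#' nearest the target.
#'
#' @param full_scores Descending-sorted \code{F} scores of the real design's
#'   candidate calls (from \code{\link{select_calls}} with a large budget).
#' @param pseudo_scores \code{F} scores of the pseudo design's calls.
#' @param design The real \code{pool_design}.
#' @param g Pools per half in the split.
#' @param target_fp_rate Acceptable estimated FP fraction among emitted
#'   calls (default 0.05).
#' @param max_budget Budget returned when the pseudo design yields no calls
#'   at all (FP estimate 0 everywhere); defaults to all candidates.
#' @return Integer budget.
#' @export
split_design_fp_threshold <- function(full_scores, pseudo_scores, design, g,
                                      target_fp_rate = 0.05,
                                      max_budget = length(full_scores)) {
  stopifnot(g >= 1)
  scale <- (design$n_rows * design$n_cols) / (g * g)
  full_scores <- sort(full_scores, decreasing = TRUE)
  if (length(full_scores) == 0L) return(0L)
  budgets <- seq_along(full_scores)
  est_fp <- vapply(budgets, function(b) {
    sum(pseudo_scores >= full_scores[b]) * scale
  }, numeric(1))
  if (all(est_fp == 0)) return(as.integer(max_budget))
  rate <- est_fp / budgets
  dev <- abs(rate - target_fp_rate)
  # largest budget among those with minimal deviation from the target
  as.integer(max(budgets[dev == min(dev)]))
}

#' Split one pool axis into a pseudo bi-dimensional design
#'
#' Reassigns the chosen axis's libraries into two halves forming a pseudo
#' design (first half = pseudo rows, second half = pseudo columns), and
#' projects every position's counts onto those libraries. Library individual
#' counts are carried over from the originals.
#'
#' @param positions List of \code{\link{position_data}} on the full design.
#' @param design The full \code{pool_design}.
#' @param axis "col" (default) or "row": which axis to split.
#' @return List with \code{design} (the pseudo \code{pool_design}),
#'   \code{positions} (projected), \code{g} (pools per half) and
#'   \code{i_well} (the original design's, for priors).
#' @export
split_pool_axis <- function(positions, design, axis = c("col", "row")) {
  axis <- match.arg(axis)
  libs <- if (axis == "col") design$cols else design$rows
  if (length(libs) %% 2L != 0L)
    stop("cannot split an odd number of ", axis, " pools")
  g <- length(libs) %/% 2L
  half1 <- libs[seq_len(g)]
  half2 <- libs[g + seq_len(g)]
  sel <- match(c(half1, half2), design$libraries$library)
  pd <- pseudo_design(half1, half2, i_l = design$libraries$i_l[sel])
  proj <- lapply(positions, function(p) {
    new_position_data(p$seqid, p$pos, p$ref, p$n[sel],
                      p$k[sel, , drop = FALSE], p$fwd[sel, , drop = FALSE])
  })
  list(design = pd, positions = proj, g = g, i_well = design$i_well)
}
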