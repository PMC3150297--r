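#' Z-score outlier statistic for one well and base change
#'
#' The naive competitor to the Bayesian caller: a real mutation in well
#' \code{w} should make the frequency of its base change stand out in both
#' of the well's libraries. For each axis the z-score of the library's
#' change frequency is taken against the frequencies of the remaining
#' libraries (mean and sample sd, with 0.0001 added to the sd to avoid
#' division by zero); the well's score is the lower of its row and column
#' z-scores. Zero-coverage libraries have no defined frequency and are
#' dropped from the background.
#'
#' @param position A \code{\link{position_data}}.
#' @param well Well id.
#' @param alt Base change to score.
#' @param design The \code{pool_design}.
#' @param sd_guard Additive guard on the standard deviation (default 1e-4).
#' @return The score, or \code{NA} if either axis's z-score is undefined
#'   (library without coverage, or fewer than 2 background libraries).
#' @export
outlier_score <- function(position, well, alt, design, sd_guard = 1e-4) {
  i <- match(well, design$wells$well)
  if (is.na(i)) stop("unknown well: ", well)
  f <- ifelse(position$n > 0, position$k[, alt] / position$n, NA_real_)
  z_for <- function(l) {
    if (is.na(f[l])) return(NA_real_)
    bg <- f[-l]
    bg <- bg[!is.na(bg)]
    if (length(bg) < 2L) return(NA_real_)
    (f[l] - mean(bg)) / (stats::sd(bg) + sd_guard)
  }
  zr <- z_for(design$wells$row_idx[i])
  zc <- z_for(design$wells$col_idx[i])
  if (is.na(zr) || is.na(zc)) return(NA_real_)
  min(zr, zc)
}

# Vectorized scores for all wells x alts at one position.
# Leave-one-out background mean/sd over the defined frequencies.
outlier_scores_all <- function(position, design, params, sd_guard = 1e-4) {
  ref <- position$ref
  alts <- setdiff(BASES, ref)
  alts <- alts[change_prob(ref, alts, params) > 0]
  if (length(alts) == 0L) return(NULL)
  wells <- design$wells
  res <- matrix(NA_real_, nrow(wells), length(alts),
                dimnames = list(wells$well, alts))
  n <- position$n
  ok <- n > 0
  for (mi in seq_along(alts)) {
    f <- ifelse(ok, position$k[, alts[mi]] / n, NA_real_)
    v <- f[ok]
    S1 <- sum(v); S2 <- sum(v * v); nn <- length(v)
    if (nn < 3L) next   # background after leave-one-out needs >= 2
    z <- rep(NA_real_, length(f))
    loo_mean <- (S1 - f) / (nn - 1)
    loo_var <- pmax((S2 - f^2 - (nn - 1) * loo_mean^2) / (nn - 2), 0)
    z[ok] <- ((f - loo_mean) / (sqrt(loo_var) + sd_guard))[ok]
    zr <- z[wells$row_idx]
    zc <- z[wells$col_idx]
    res[, mi] <- pmin(zr, zc)
  }
  res
}

#' Outlier method call at a position
#'
#' Emits the single best-scoring (well, change) combination if its score
#' exceeds the threshold. When the mutagen induces no non-canonical changes
#' (\code{p_nc = 0}) only canonical changes are considered, mirroring the
#' main caller. Ties take the first well in design order.
#'
#' @param position A \code{\link{position_data}}.
#' @param design The \code{pool_design}.
#' @param params \code{\link{experiment_params}} (used only to restrict the
#'   change set).
#' @param threshold Score threshold; with \code{threshold = -Inf} the best
#'   candidate is always returned (useful for rank-based evaluation).
#' @param sd_guard See \code{\link{outlier_score}}.
#' @return A one-row data frame (\code{seqid}, \code{pos}, \code{ref},
#'   \code{alt}, \code{row_library}, \code{column_library}, \code{well},
#'   \code{score}) or \code{NULL} if no score exceeds the threshold.
#' @export
outlier_call <- function(position, design, params, threshold,
                         sd_guard = 1e-4) {
  sc <- outlier_scores_all(position, design, params, sd_guard)
  if (is.null(sc) || all(is.na(sc))) return(NULL)
  best <- which(sc == max(sc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  s <- sc[best[1], best[2]]
  if (!(s > threshold)) return(NULL)
  i <- best[1]
  data.frame(seqid = position$seqid, pos = position$pos, ref = position$ref,
             alt = colnames(sc)[best[2]],
             row_library = design$wells$row[i],
             column_library = design$wells$col[i],
             well = design$wells$well[i], score = s,
             stringsAsFactors = FALSE)
}

#' Run the Outlier method over a set of positions
#'
#' Applies the same preprocessing gate as the main caller, scores every
#' position, and keeps the top \code{n_predictions} calls by score (or all
#' calls above \code{threshold}).
#'
#' @param positions List of \code{\link{position_data}}.
#' @param design,params As elsewhere.
#' @param n_predictions Budget (used with \code{threshold = -Inf}), or NULL.
#' @param threshold Score cutoff when no budget is given.
#' @param min_total Coverage gate (see \code{\link{coverage_gate}}).
#' @param sd_guard See \code{\link{outlier_score}}.
#' @return Data frame of ranked calls.
#' @export
outlier_caller <- function(positions, design, params, n_predictions = NULL,
                           threshold = -Inf, min_total = 10000,
                           sd_guard = 1e-4) {
  calls <- lapply(positions, function(p) {
    if (!p$ref %in% BASES || !coverage_gate(p, min_total)) return(NULL)
    outlier_call(p, design, params, threshold = -Inf, sd_guard = sd_guard)
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (length(calls) == 0L)
    return(data.frame(seqid = character(), pos = integer(), ref = character(),
                      alt = character(), row_library = character(),
                      column_library = character(), well = character(),
                      score = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  calls <- do.call(rbind, calls)
  calls <- calls[order(-calls$score, calls$seqid, calls$pos), , drop = FALSE]
  if (!is.null(n_predictions)) calls <- utils::head(calls, n_predictions)
  else calls <- calls[calls$score > threshold, , drop = FALSE]
  calls$rank <- seq_len(nrow(calls))
  rownames(calls) <- NULL
  calls
}
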