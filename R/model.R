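#' Enumerate candidate configurations at a position
#'
#' A configuration is a single hypothesis about one position: either no
#' mutation anywhere (the null), or exactly one mutant individual in well
#' \code{w}, carrying base change \code{ref -> m} with zygosity \code{z}.
#' Changes whose per-individual induction probability is zero (e.g. all
#' non-canonical changes when \code{p_nc = 0}) are omitted: their prior is
#' zero so they can never acquire posterior mass.
#'
#' @param design A \code{\link{build_design}} object.
#' @param params An \code{\link{experiment_params}} object.
#' @param ref Reference base at the position.
#' @return A data frame with one row per configuration: \code{kind}
#'   ("null"/"mutant"), \code{well}, \code{row_idx}, \code{col_idx},
#'   \code{alt}, \code{zyg}. The null row comes first.
#' @examples
#' d <- build_design(8, 12, 8)
#' p <- experiment_params(p_c = 3.88e-6, p_nc = 0)
#' nrow(enumerate_configurations(d, p, "G"))  # 96 wells * 2 zygosities + null
#' @export
enumerate_configurations <- function(design, params, ref) {
  stopifnot(ref %in% BASES)
  alts <- setdiff(BASES, ref)
  alts <- alts[change_prob(ref, alts, params) > 0]
  null_row <- data.frame(kind = "null", well = NA_character_,
                         row_idx = NA_integer_, col_idx = NA_integer_,
                         alt = NA_character_, zyg = NA_character_,
                         stringsAsFactors = FALSE)
  if (length(alts) == 0L) return(null_row)
  w <- design$wells
  grid <- expand.grid(zyg = c("het", "hom"), alt = alts,
                      wi = seq_len(nrow(w)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mut <- data.frame(kind = "mutant", well = w$well[grid$wi],
                    row_idx = w$row_idx[grid$wi], col_idx = w$col_idx[grid$wi],
                    alt = grid$alt, zyg = grid$zyg, stringsAsFactors = FALSE)
  rbind(null_row, mut)
}

#' Position-specific sequencing error rate for a base change
#'
#' Pooled estimate of the rate at which the reference base is read as
#' \code{alt}: total \code{alt} calls over total coverage, summed over the
#' libraries that cannot contain the hypothesised mutation. Under the null
#' that is every library; under a mutant configuration the two libraries
#' containing the candidate well are excluded.
#'
#' @param position A \code{\link{position_data}}.
#' @param alt Alternate base.
#' @param design The \code{pool_design}.
#' @param well Candidate mutant well id, or \code{NULL} for the null
#'   configuration.
#' @return The pooled error rate (a fraction).
#' @export
error_rate <- function(position, alt, design, well = NULL) {
  keep <- rep(TRUE, length(position$n))
  if (!is.null(well)) {
    i <- match(well, design$wells$well)
    if (is.na(i)) stop("unknown well: ", well)
    keep[c(design$wells$row_idx[i], design$wells$col_idx[i])] <- FALSE
  }
  denom <- sum(position$n[keep])
  if (denom <= 0) stop("error rate undefined: no coverage in reference libraries")
  sum(position$k[keep, alt]) / denom
}

#' Expected mutant allele fraction in a library
#'
#' For diploid individuals, one heterozygous mutant contributes 1 allele and
#' one homozygous mutant 2 alleles out of the \code{2 * i_l} alleles pooled
#' in a library of \code{i_l} individuals; a library not containing the
#' mutant well contributes none.
#'
#' @param zyg "het" or "hom".
#' @param i_l Individuals in the library.
#' @param contains Does the library contain the mutant well?
#' @return The expected fraction of mutant alleles.
#' @export
mutant_allele_fraction <- function(zyg, i_l, contains = TRUE) {
  if (!contains) return(0)
  n_alleles <- switch(zyg, het = 1, hom = 2, stop("zygosity must be het or hom"))
  n_alleles / (2 * i_l)
}

#' Expected rate of reading a base change
#'
#' Mixture of sequencing error on wild-type alleles and faithful reads of
#' mutant alleles: \code{(1 - m_frac) * e + m_frac}.
#'
#' @param e Sequencing error rate for the change.
#' @param m_frac Mutant allele fraction in the library.
#' @return A rate in \code{[e, 1]}.
#' @export
expected_change_rate <- function(e, m_frac) {
  stopifnot(e >= 0, e <= 1, m_frac >= 0, m_frac <= 1)
  (1 - m_frac) * e + m_frac
}

#' Log likelihood of the data at a position under one configuration
#'
#' Under configuration \code{c}, each non-reference base count in each
#' library is modelled as Binomial(\code{n_l}, \code{r_lmc}) where
#' \code{r_lmc} is the expected change-read rate (pure error everywhere
#' except the hypothesised change in the two libraries holding the mutant
#' well), and counts are taken independent across libraries and changes.
#'
#' This is the transparent per-configuration form used for small cases and
#' cross-checks; the pipeline uses an equivalent vectorized path
#' (\code{\link{position_posteriors}}).
#'
#' @param position A \code{\link{position_data}}.
#' @param config One row of \code{\link{enumerate_configurations}} (or a list
#'   with the same fields).
#' @param design The \code{pool_design}.
#' @param exclusions Optional \code{\link{position_exclusions}} result; a
#'   vetoed configuration gets \code{-Inf}.
#' @return The log likelihood (\code{-Inf} if vetoed or impossible).
#' @export
log_likelihood <- function(position, config, design, exclusions = NULL) {
  alts <- setdiff(BASES, position$ref)
  nl <- position$n
  i_l <- design$libraries$i_l
  is_mut <- !is.null(config$kind) && config$kind == "mutant"
  if (is_mut && !is.null(exclusions) &&
      config_vetoed(exclusions, config$row_idx, config$col_idx, config$alt))
    return(-Inf)
  ll <- 0
  for (m in alts) {
    keep <- rep(TRUE, length(nl))
    if (is_mut) keep[c(config$row_idx, config$col_idx)] <- FALSE
    # no remaining coverage: every count is zero and the likelihood term is
    # an empty product (rate taken as 0)
    e <- if (sum(nl[keep]) == 0) 0 else
      error_rate(position, m, design, well = if (is_mut) config$well else NULL)
    for (l in seq_along(nl)) {
      mf <- 0
      if (is_mut && m == config$alt && l %in% c(config$row_idx, config$col_idx))
        mf <- mutant_allele_fraction(config$zyg, i_l[l])
      r <- expected_change_rate(e, mf)
      ll <- ll + stats::dbinom(position$k[l, m], nl[l], r, log = TRUE)
    }
  }
  unname(ll)
}

#' Log prior ratio of a mutant configuration to the null
#'
#' Per-well priors come from a Binomial over the \code{i_well} individuals of
#' a well: \code{p1m = B(1 | i_well, p_m)} for carrying the change in exactly
#' one individual and \code{p0m = B(0 | i_well, p_m)} for none. The prior of
#' a full configuration is a product over every (well, change) pair, so all
#' factors cancel between a mutant configuration and the null except the
#' mutant well's own change, leaving \code{t_z * p1m / p0m}. Working with
#' this ratio keeps the arithmetic stable; the common product never needs to
#' be formed.
#'
#' @param ref,alt The base change.
#' @param zyg "het" or "hom".
#' @param params \code{\link{experiment_params}}.
#' @param i_well Individuals per well.
#' @return \code{log(prior(c) / prior(null))}.
#' @export
config_log_prior_ratio <- function(ref, alt, zyg, params, i_well) {
  p_m <- change_prob(ref, alt, params)
  t_z <- switch(zyg, het = params$t_het, hom = params$t_hom,
                stop("zygosity must be het or hom"))
  if (p_m == 0 || t_z == 0) return(-Inf)
  log(t_z) + stats::dbinom(1, i_well, p_m, log = TRUE) -
    stats::dbinom(0, i_well, p_m, log = TRUE)
}

#' Monotone score transform of a posterior
#'
#' Posteriors cluster hard against 0 and 1, which makes thresholds on the
#' raw probability scale uninformative; the natural log-odds
#' \code{F(t) = log(t / (1 - t))} spreads both tails (effectively a log
#' posterior for small \code{t}), clamped to \code{[-f_max, f_max]} so the
#' endpoints stay finite and comparable.
#'
#' @param t Posterior probability (vectorized).
#' @param f_max Clamp magnitude (default 700, about the largest log-odds
#'   representable from double-precision posteriors).
#' @return \code{F(t)}.
#' @export
transform_score <- function(t, f_max = 700) {
  stopifnot(all(t >= 0 & t <= 1))
  pmin(pmax(log(t) - log1p(-t), -f_max), f_max)
}

# Row sum that tolerates -Inf entries being excluded: recompute sum of x
# without the columns in drop (used where subtracting a -Inf term would
# produce NaN).
sum_excluding <- function(x_row, drop) sum(x_row[-drop])

#' Posterior probabilities of all configurations at a position
#'
#' Applies Bayes' theorem over the full configuration set: the unnormalized
#' log posterior of each configuration is its binomial log likelihood plus
#' its log prior (as a ratio to the null), normalized by max-subtraction.
#' Zygosities are then collapsed, \code{t(w, m) = p(het) + p(hom)}, and the
#' best mutant entry is reported with its log-odds score.
#'
#' @param position A \code{\link{position_data}}.
#' @param design The \code{pool_design}.
#' @param params \code{\link{experiment_params}}.
#' @param exclusions Optional \code{\link{position_exclusions}} result;
#'   vetoed configurations get zero posterior mass. The null is never vetoed.
#' @param i_well Override for individuals per well (needed for pseudo
#'   designs whose wells are not physical); defaults to \code{design$i_well}.
#' @param f_max Score clamp, see \code{\link{transform_score}}.
#' @return A \code{posterior_table}: list with \code{seqid}, \code{pos},
#'   \code{ref}, \code{configs} (configuration data frame with a
#'   \code{posterior} column), \code{collapsed} (per (well, change):
#'   \code{well}, \code{row}, \code{col}, \code{alt}, \code{t}, \code{F}),
#'   \code{null_posterior}, and \code{best} (the top collapsed row, or NULL
#'   when only the null configuration exists).
#' @export
position_posteriors <- function(position, design, params, exclusions = NULL,
                                i_well = design$i_well, f_max = 700) {
  ref <- position$ref
  if (!ref %in% BASES) stop("uncallable reference base: ", ref)
  alts <- setdiff(BASES, ref)
  alts <- alts[change_prob(ref, alts, params) > 0]
  nl <- position$n
  L <- length(nl)
  N <- sum(nl)
  if (N <= 0) stop("error rate undefined: position has no coverage")

  null_only <- data.frame(kind = "null", well = NA_character_,
                          row_idx = NA_integer_, col_idx = NA_integer_,
                          alt = NA_character_, zyg = NA_character_,
                          posterior = 1, stringsAsFactors = FALSE)
  empty <- structure(list(seqid = position$seqid, pos = position$pos,
                          ref = ref, configs = null_only,
                          collapsed = NULL, null_posterior = 1, best = NULL),
                     class = "posterior_table")
  if (length(alts) == 0L) return(empty)

  Kalt <- position$k[, alts, drop = FALSE]        # L x M
  M <- length(alts)
  Ktot <- colSums(Kalt)
  wells <- design$wells
  W <- nrow(wells)
  ri <- wells$row_idx
  ci <- wells$col_idx

  # Null log likelihood: error rates pooled over all libraries.
  e0 <- Ktot / N
  ll_null <- sum(stats::dbinom(as.vector(Kalt), rep(nl, M),
                               rep(e0, each = L), log = TRUE))

  # Per-well error rates excluding the well's two libraries (W x M).
  denom <- N - nl[ri] - nl[ci]
  E <- (matrix(Ktot, W, M, byrow = TRUE) - Kalt[ri, , drop = FALSE] -
          Kalt[ci, , drop = FALSE]) / denom
  E[denom <= 0, ] <- 0

  # Full per-(well, library, change) log binomial terms: W x (L*M), column
  # block m' holding libraries 1..L at rate E[, m'].
  k_rep <- matrix(as.vector(Kalt), W, L * M, byrow = TRUE)
  n_rep <- matrix(rep(nl, M), W, L * M, byrow = TRUE)
  p_rep <- E[, rep(seq_len(M), each = L), drop = FALSE]
  Tmat <- stats::dbinom(k_rep, n_rep, p_rep, log = TRUE)
  B <- rowSums(Tmat)

  i_l <- design$libraries$i_l

  # Per-(well, change) base term with the well's two (library, change m)
  # entries removed: indices into Tmat's column blocks.
  widx <- rep(seq_len(W), M)
  tR <- cbind(widx, rep((seq_len(M) - 1L) * L, each = W) + ri)
  tC <- cbind(widx, rep((seq_len(M) - 1L) * L, each = W) + ci)
  termR <- matrix(Tmat[tR], W, M)
  termC <- matrix(Tmat[tC], W, M)
  base_excl <- B - termR - termC
  bad <- which(!is.finite(base_excl), arr.ind = TRUE)
  for (j in seq_len(nrow(bad))) {
    w <- bad[j, 1]; mi <- bad[j, 2]
    base_excl[w, mi] <- sum_excluding(Tmat[w, ], (mi - 1L) * L + c(ri[w], ci[w]))
  }

  kR <- Kalt[ri, , drop = FALSE]; kC <- Kalt[ci, , drop = FALSE]
  nR <- nl[ri]; nC <- nl[ci]
  lpr <- vapply(alts, function(m) c(
    config_log_prior_ratio(ref, m, "het", params, i_well),
    config_log_prior_ratio(ref, m, "hom", params, i_well)), numeric(2))

  ll_z <- lapply(1:2, function(zi) {       # W x M log likelihoods per zygosity
    mfR <- zi / (2 * i_l[ri]); mfC <- zi / (2 * i_l[ci])
    rR <- (1 - mfR) * E + mfR              # mf vectors recycle down columns
    rC <- (1 - mfC) * E + mfC
    base_excl + stats::dbinom(kR, nR, rR, log = TRUE) +
      stats::dbinom(kC, nC, rC, log = TRUE)
  })
  lp_het <- ll_z[[1]] + matrix(lpr[1, ], W, M, byrow = TRUE)
  lp_hom <- ll_z[[2]] + matrix(lpr[2, ], W, M, byrow = TRUE)

  if (!is.null(exclusions)) {
    V <- exclusions$lib_veto[ri] | exclusions$lib_veto[ci] |
      exclusions$change_veto[ri, alts, drop = FALSE] |
      exclusions$change_veto[ci, alts, drop = FALSE]
    lp_het[V] <- -Inf
    lp_hom[V] <- -Inf
  }

  # Configuration order: null first, then wells (outer) x alts x zygosity
  # (inner) -- t() puts alts inner within each well, rbind interleaves zyg.
  n_mut <- W * M * 2L
  lp <- c(ll_null,
          as.vector(rbind(as.vector(t(lp_het)), as.vector(t(lp_hom)))))

  mx <- max(lp)
  if (!is.finite(mx)) stop("degenerate position: all configurations have zero mass")
  post <- exp(lp - mx)
  post <- post / sum(post)

  cfg_wi <- rep(seq_len(W), each = M * 2L)
  configs <- data.frame(
    kind = c("null", rep("mutant", n_mut)),
    well = c(NA_character_, wells$well[cfg_wi]),
    row_idx = c(NA_integer_, ri[cfg_wi]),
    col_idx = c(NA_integer_, ci[cfg_wi]),
    alt = c(NA_character_, rep(rep(alts, each = 2L), W)),
    zyg = c(NA_character_, rep(c("het", "hom"), W * M)),
    posterior = post, stringsAsFactors = FALSE)

  # Collapse zygosity: posterior vector after null is (het, hom) adjacent.
  pm <- matrix(post[-1], nrow = 2L)              # 2 x (W*M)
  t_wm <- colSums(pm)
  coll_w <- rep(seq_len(W), each = M)
  coll_m <- rep(seq_len(M), W)
  # order above is wells outer, alts inner, zyg innermost
  collapsed <- data.frame(
    well = wells$well[coll_w],
    row = wells$row[coll_w], col = wells$col[coll_w],
    alt = alts[coll_m],
    t = t_wm, stringsAsFactors = FALSE)
  collapsed$F <- transform_score(pmin(pmax(collapsed$t, 0), 1), f_max)
  best_i <- which.max(collapsed$t)   # ties: first in (well, change) order
  structure(list(seqid = position$seqid, pos = position$pos, ref = ref,
                 configs = configs, collapsed = collapsed,
                 null_posterior = post[1], best = collapsed[best_i, ]),
            class = "posterior_table")
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf("posterior_table %s:%d ref=%s null=%.4g\n",
              x$seqid, x$pos, x$ref, x$null_posterior))
  if (!is.null(x$best))
    cat(sprintf("  best: %s %s->%s t=%.4g F=%.3f\n", x$best$well, x$ref,
                x$best$alt, x$best$t, x$best$F))
  invisible(x)
}
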