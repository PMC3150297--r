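#' Per-library base-quality cutoff
#'
#' For each library, base calls are screened against a cutoff set one sample
#' standard deviation below the mean Phred quality of that library's
#' reference-matching calls (over the whole gene); calls strictly below the
#' cutoff are discarded before counting. With a single reference call the
#' standard deviation is taken as 0.
#'
#' @param ref_qualities Numeric vector of qualities of reference-matching
#'   calls in the library.
#' @return The quality threshold.
#' @export
library_quality_cutoff <- function(ref_qualities) {
  if (length(ref_qualities) == 0L)
    stop("quality cutoff undefined: library has no reference-matching calls")
  s <- if (length(ref_qualities) == 1L) 0 else stats::sd(ref_qualities)
  mean(ref_qualities) - s
}

#' Coverage gate for a position
#'
#' Candidate mutations are only searched where the error rate can be
#' estimated accurately. The gate requires the expected total coverage over
#' all but two libraries -- i.e. total coverage scaled by
#' \code{(|L| - 2) / |L|}, the expectation over which row/column pair a
#' candidate well would exclude -- to reach \code{min_total}. The default
#' 10,000 corresponds, for the 20-library 768-individual screen, to a
#' minimum per-individual coverage of 7.23.
#'
#' @param position A \code{\link{position_data}}, or a numeric vector of
#'   per-library coverages.
#' @param min_total Gate threshold on the expected remaining coverage.
#' @return TRUE if the position passes (is searched), FALSE if gated.
#' @export
coverage_gate <- function(position, min_total = 10000) {
  n <- if (inherits(position, "position_data")) position$n else position
  L <- length(n)
  if (L < 3L) return(FALSE)
  sum(n) * (L - 2) / L >= min_total
}

#' Strand orientation bias of a base
#'
#' @param fwd,rev Forward- and reverse-strand call counts.
#' @return \code{fwd / rev}; \code{Inf} when only forward calls exist,
#'   \code{NaN} when there are no calls at all.
#' @export
orientation_bias <- function(fwd, rev) {
  stopifnot(all(fwd >= 0), all(rev >= 0))
  ifelse(fwd == 0 & rev == 0, NaN, fwd / rev)
}

# Fast two-sided Fisher exact p for the 2x2 table
#   ref: (a fwd, b rev)
#   alt: (c fwd, d rev)
# Oriented so the hypergeometric support runs over the (small) alt row:
# x = c, col1 total m = a + c, col2 total n = b + d, row total k = c + d.
# Sums all tables whose density does not exceed the observed one (the
# convention of stats::fisher.test, against which this is unit-tested);
# written out because the pipeline runs one test per library per change per
# position and fisher.test is too slow for that loop.
fisher2x2_p <- function(a, b, c, d) {
  if (c + d == 0 || a + b == 0 || a + c == 0 || b + d == 0) return(1)
  m <- a + c; n <- b + d; k <- c + d
  xs <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(xs, m, n, k)
  dobs <- stats::dhyper(c, m, n, k)
  sum(dens[dens <= dobs * (1 + 1e-7)])
}

#' Strand-orientation exclusions at a position
#'
#' Two vetoes guard against strand artifacts. (a) If, in some library, the
#' orientation bias of base change \code{m} differs from that of the
#' reference base with Fisher exact p below \code{alpha}, every
#' configuration whose mutant well lies in that library is vetoed for change
#' \code{m}. (b) If the reference base's own orientation bias is above
#' \code{hi} or below \code{lo}, the bias of a change cannot be assessed
#' against it and the library is vetoed for all changes.
#'
#' @param position A \code{\link{position_data}}.
#' @param alpha Significance cutoff for the exact test (default 0.01; no
#'   multiple-testing correction is applied, by design).
#' @param hi,lo Reference-bias bounds (defaults 10 and 0.1).
#' @return List with \code{lib_veto} (logical per library) and
#'   \code{change_veto} (library x base logical matrix), plus a
#'   \code{reasons} data frame (library index, base or NA, reason code).
#' @export
strand_exclusions <- function(position, alpha = 0.01, hi = 10, lo = 0.1) {
  L <- length(position$n)
  lib_veto <- logical(L)
  change_veto <- matrix(FALSE, L, 4, dimnames = list(NULL, BASES))
  reasons <- list()
  ref <- position$ref
  if (!ref %in% BASES)
    return(list(lib_veto = lib_veto, change_veto = change_veto,
                reasons = empty_reasons()))
  alts <- setdiff(BASES, ref)
  rf <- position$fwd[, ref]
  rr <- position$k[, ref] - rf
  bias <- orientation_bias(rf, rr)
  for (l in seq_len(L)) {
    if (is.finite(bias[l]) && (bias[l] > hi || bias[l] < lo) ||
        is.infinite(bias[l])) {
      lib_veto[l] <- TRUE
      reasons[[length(reasons) + 1L]] <-
        data.frame(lib = l, base = NA_character_, reason = "ref_strand_bias")
      next
    }
    for (m in alts) {
      mf <- position$fwd[l, m]
      mr <- position$k[l, m] - mf
      if (mf + mr == 0) next
      p <- fisher2x2_p(rf[l], rr[l], mf, mr)
      if (p < alpha) {
        change_veto[l, m] <- TRUE
        reasons[[length(reasons) + 1L]] <-
          data.frame(lib = l, base = m, reason = "strand_bias_test")
      }
    }
  }
  list(lib_veto = lib_veto, change_veto = change_veto,
       reasons = bind_reasons(reasons))
}

#' Mutant-exceeds-reference exclusions at a position
#'
#' A library showing strictly more reads of some candidate change than of
#' the reference base is treated as unreliable at this position: every
#' configuration whose mutant well lies in it is vetoed, for any change.
#'
#' @param position A \code{\link{position_data}}.
#' @return Same shape as \code{\link{strand_exclusions}}.
#' @export
mutant_exceeds_ref_exclusions <- function(position) {
  L <- length(position$n)
  lib_veto <- logical(L)
  change_veto <- matrix(FALSE, L, 4, dimnames = list(NULL, BASES))
  reasons <- list()
  ref <- position$ref
  if (ref %in% BASES) {
    alts <- setdiff(BASES, ref)
    kr <- position$k[, ref]
    over <- apply(position$k[, alts, drop = FALSE] >
                    matrix(kr, L, 3), 1, any)
    for (l in which(over)) {
      lib_veto[l] <- TRUE
      reasons[[length(reasons) + 1L]] <-
        data.frame(lib = l, base = NA_character_, reason = "mutant_gt_ref")
    }
  }
  list(lib_veto = lib_veto, change_veto = change_veto,
       reasons = bind_reasons(reasons))
}

empty_reasons <- function() {
  data.frame(lib = integer(), base = character(), reason = character(),
             stringsAsFactors = FALSE)
}

bind_reasons <- function(reasons) {
  if (length(reasons) == 0L) empty_reasons() else do.call(rbind, reasons)
}

#' Combined exclusion set for a position
#'
#' Unions the coverage gate, strand-orientation vetoes and
#' mutant-exceeds-reference vetoes. The union is order-independent, so the
#' filters may be evaluated in any order.
#'
#' @param position A \code{\link{position_data}}.
#' @param min_total Coverage-gate threshold (see \code{\link{coverage_gate}}).
#' @param alpha,hi,lo Strand-filter parameters
#'   (see \code{\link{strand_exclusions}}).
#' @return An \code{exclusion_set}: list with \code{gated} (logical),
#'   \code{lib_veto}, \code{change_veto}, \code{reasons}.
#' @export
position_exclusions <- function(position, min_total = 10000, alpha = 0.01,
                                hi = 10, lo = 0.1) {
  gated <- !coverage_gate(position, min_total)
  s <- strand_exclusions(position, alpha, hi, lo)
  x <- mutant_exceeds_ref_exclusions(position)
  structure(list(
    gated = gated,
    lib_veto = s$lib_veto | x$lib_veto,
    change_veto = s$change_veto | x$change_veto,
    reasons = rbind(s$reasons, x$reasons)
  ), class = "exclusion_set")
}

# Is configuration (well with libraries ri, ci; change m) vetoed?
config_vetoed <- function(excl, ri, ci, m) {
  excl$lib_veto[ri] || excl$lib_veto[ci] ||
    excl$change_veto[ri, m] || excl$change_veto[ci, m]
}
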