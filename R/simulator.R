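#' Specify a synthetic pooled TILLING experiment
#'
#' Describes the world the generator emulates: the pool design, reference
#' sequences, mutagenesis parameters, a scalar per-change base-miscall rate,
#' a negative-binomial per-library coverage model (mean per individual
#' coverage times library size; dispersion controls the across-library
#' variability that separates wheat-like from rice-like data), a
#' forward-strand fraction, and a constant Phred quality for emitted calls.
#'
#' @param design A \code{\link{build_design}} object.
#' @param references Named character vector (or \code{DNAStringSet}) of
#'   reference sequences.
#' @param params \code{\link{experiment_params}}.
#' @param error_rate Per-change miscall rate (default 1e-3, i.e. each
#'   specific wrong base read at rate 0.1%).
#' @param coverage Mean per-individual coverage (default 270, wheat-like;
#'   rice-like data averaged 140).
#' @param dispersion Negative-binomial size parameter for per-library
#'   coverage (default 20; \code{Inf} gives Poisson).
#' @param fwd_fraction Forward-strand probability per call (default 0.5).
#' @param quality Constant Phred score of emitted calls (default 31,
#'   wheat-like; rice-like data averaged 13).
#' @return A \code{simulation_spec} object.
#' @export
simulation_spec <- function(design, references, params, error_rate = 1e-3,
                            coverage = 270, dispersion = 20,
                            fwd_fraction = 0.5, quality = 31) {
  refs <- stats::setNames(toupper(as.character(references)), names(references))
  if (is.null(names(refs))) names(refs) <- paste0("gene", seq_along(refs))
  stopifnot(error_rate >= 0, error_rate <= 1, coverage > 0,
            fwd_fraction >= 0, fwd_fraction <= 1, dispersion > 0)
  structure(list(design = design, references = refs, params = params,
                 error_rate = error_rate, coverage = coverage,
                 dispersion = dispersion, fwd_fraction = fwd_fraction,
                 quality = quality),
            class = "simulation_spec")
}

#' Random reference sequence
#'
#' @param length Sequence length in bp.
#' @param gc GC fraction (default 0.5).
#' @return A character string of A/C/G/T.
#' @export
random_reference <- function(length, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

#' Plant mutations into a simulated population
#'
#' In the default (rate-driven) mode every individual, position and possible
#' base change receives an independent Bernoulli draw at the mutagen's
#' per-change probability, so the expected planted count equals
#' \code{\link{expected_mutations}}; positions hit in more than one
#' individual are re-drawn (the caller's model assumes at most one mutant
#' individual per position). With \code{n_fixed}, exactly that many
#' mutations are planted at distinct random positions, with changes sampled
#' proportionally to their induction probabilities. Zygosity is heterozygous
#' with probability \code{t_het}.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @param n_fixed Plant exactly this many mutations (default NULL:
#'   rate-driven).
#' @return Truth table data frame: \code{seqid}, \code{pos}, \code{ref},
#'   \code{alt}, \code{well}, \code{zyg}.
#' @export
plant_mutations <- function(spec, n_fixed = NULL) {
  design <- spec$design
  params <- spec$params
  n_ind <- design$n_w * design$i_well
  out <- list()
  for (sq in names(spec$references)) {
    ref <- strsplit(spec$references[[sq]], "")[[1]]
    P <- length(ref)
    alt_mat <- vapply(ref, function(r) setdiff(BASES, r), character(3))  # 3 x P
    pr_mat <- matrix(change_prob(rep(ref, each = 3), as.vector(alt_mat),
                                 params), nrow = 3)
    if (is.null(n_fixed)) {
      cnt <- matrix(stats::rbinom(3 * P, n_ind, as.vector(pr_mat)), nrow = 3)
      bad <- which(colSums(cnt) > 1L)
      while (length(bad) > 0L) {
        cnt[, bad] <- stats::rbinom(3 * length(bad), n_ind,
                                    as.vector(pr_mat[, bad, drop = FALSE]))
        bad <- bad[colSums(cnt[, bad, drop = FALSE]) > 1L]
      }
      hits <- which(cnt == 1L, arr.ind = TRUE)
      if (nrow(hits) == 0L) next
      pos <- hits[, 2]
      alt <- alt_mat[hits]
    } else {
      site_w <- colSums(pr_mat)
      if (all(site_w == 0)) next
      pos <- sample.int(P, n_fixed, replace = FALSE, prob = site_w)
      alt <- vapply(pos, function(p) {
        sample(alt_mat[, p], 1L, prob = pr_mat[, p])
      }, character(1))
    }
    if (length(pos) == 0L) next
    wells <- sample(design$wells$well, length(pos), replace = TRUE)
    zyg <- ifelse(stats::runif(length(pos)) < params$t_het, "het", "hom")
    out[[sq]] <- data.frame(seqid = sq, pos = as.integer(pos),
                            ref = ref[pos], alt = alt, well = wells,
                            zyg = zyg, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(seqid = character(), pos = integer(), ref = character(),
                      alt = character(), well = character(), zyg = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$seqid, res$pos), , drop = FALSE]
}

#' Generate per-library counts for a simulated experiment
#'
#' Runs the caller's own observation model generatively. Per library and
#' gene, a mean coverage is drawn from the negative-binomial coverage model
#' and shared across the gene's positions via Poisson draws; each
#' non-reference base count is Binomial(\code{n_l}, rate), where the rate is
#' the miscall rate except in the two libraries holding a planted mutation's
#' well, where it is lifted by the mutant allele fraction. Forward-strand
#' counts are Binomial(\code{k}, \code{fwd_fraction}).
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @param truth Truth table from \code{\link{plant_mutations}}.
#' @return List of \code{\link{position_data}} in (sequence, position)
#'   order, with attribute \code{"lib_coverage"} (gene x library mean
#'   coverage matrix, used by \code{\link{variance_perturbation}}).
#' @export
generate_counts <- function(spec, truth) {
  design <- spec$design
  libs <- design$libraries
  L <- nrow(libs)
  e <- spec$error_rate
  positions <- list()
  covmat <- matrix(NA_real_, length(spec$references), L,
                   dimnames = list(names(spec$references), libs$library))
  for (sq in names(spec$references)) {
    ref <- strsplit(spec$references[[sq]], "")[[1]]
    P <- length(ref)
    mu <- spec$coverage * libs$i_l
    lib_mean <- if (is.finite(spec$dispersion))
      stats::rnbinom(L, size = spec$dispersion, mu = mu)
    else stats::rpois(L, mu)
    lib_mean <- pmax(lib_mean, 1)
    covmat[sq, ] <- lib_mean
    n <- matrix(stats::rpois(P * L, rep(lib_mean, each = P)), P, L)
    K <- array(0, c(P, L, 4), dimnames = list(NULL, NULL, BASES))
    for (b in BASES) {
      notref <- ref != b
      draws <- matrix(0, P, L)
      draws[notref, ] <- stats::rbinom(sum(notref) * L, n[notref, ], e)
      K[, , b] <- draws
    }
    tt <- truth[truth$seqid == sq, , drop = FALSE]
    if (nrow(tt) > 0L) {
      wi <- match(tt$well, design$wells$well)
      for (j in seq_len(nrow(tt))) {
        p <- tt$pos[j]
        for (li in c(design$wells$row_idx[wi[j]], design$wells$col_idx[wi[j]])) {
          mf <- mutant_allele_fraction(tt$zyg[j], libs$i_l[li])
          r <- expected_change_rate(e, mf)
          K[p, li, tt$alt[j]] <- stats::rbinom(1L, n[p, li], r)
        }
      }
    }
    # total alternate calls may not exceed coverage; resample rare excesses
    # (the reference slice of K is all zero, so the full sum is the alt total)
    alt_tot <- matrix(K[, , 1] + K[, , 2] + K[, , 3] + K[, , 4], P, L)
    over <- which(alt_tot > n, arr.ind = TRUE)
    for (r_i in seq_len(nrow(over))) {
      p <- over[r_i, 1]; li <- over[r_i, 2]
      repeat {
        for (b in setdiff(BASES, ref[p]))
          K[p, li, b] <- stats::rbinom(1L, n[p, li], e)
        if (sum(K[p, li, setdiff(BASES, ref[p])]) <= n[p, li]) break
      }
    }
    for (p in seq_len(P)) {
      k <- matrix(K[p, , ], L, 4, dimnames = list(NULL, BASES))
      k[, ref[p]] <- n[p, ] - rowSums(k[, setdiff(BASES, ref[p]), drop = FALSE])
      fwd <- matrix(stats::rbinom(L * 4, k, spec$fwd_fraction), L, 4,
                    dimnames = list(NULL, BASES))
      positions[[length(positions) + 1L]] <-
        new_position_data(sq, p, ref[p], as.numeric(n[p, ]), k, fwd)
    }
  }
  attr(positions, "lib_coverage") <- covmat
  positions
}

#' Coverage-variance perturbation by read thinning
#'
#' Stress-tests callers against uneven sequencing: per gene, each library's
#' coverage is driven to \code{(cov_l / cov_max)^s * cov_max} -- the
#' library's coverage ratio to the best-covered library raised to the
#' scaling factor \code{s}, times that maximum -- by discarding each base
#' call independently with the matching probability. \code{s = 1} leaves
#' coverage unchanged in expectation; \code{s = 5} emulates the most
#' variable real genes. The highest-coverage library is never thinned.
#'
#' @param positions List of \code{\link{position_data}} from
#'   \code{\link{generate_counts}} (its \code{lib_coverage} attribute
#'   supplies per-gene library coverages; otherwise they are estimated from
#'   the data).
#' @param s Scaling factor (>= 1).
#' @return The thinned position list.
#' @export
variance_perturbation <- function(positions, s) {
  stopifnot(s >= 1)
  covmat <- attr(positions, "lib_coverage")
  seqids <- vapply(positions, function(p) p$seqid, character(1))
  if (is.null(covmat)) {
    genes <- unique(seqids)
    L <- length(positions[[1]]$n)
    covmat <- t(vapply(genes, function(g) {
      rowMeans(vapply(positions[seqids == g], function(p) p$n,
                      numeric(L)))
    }, numeric(L)))
    rownames(covmat) <- genes
  }
  out <- lapply(seq_along(positions), function(i) {
    p <- positions[[i]]
    cov <- covmat[p$seqid, ]
    keep <- (cov / max(cov))^(s - 1)
    fwd_new <- matrix(stats::rbinom(length(p$fwd), p$fwd, keep), nrow(p$fwd),
                      4, dimnames = list(NULL, BASES))
    rev_new <- matrix(stats::rbinom(length(p$k), p$k - p$fwd, keep),
                      nrow(p$k), 4, dimnames = list(NULL, BASES))
    k_new <- fwd_new + rev_new
    new_position_data(p$seqid, p$pos, p$ref, rowSums(k_new), k_new, fwd_new)
  })
  attr(out, "lib_coverage") <- covmat * ((covmat / apply(covmat, 1, max))^(s - 1))
  out
}
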