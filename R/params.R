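BASES <- c("A", "C", "G", "T")

#' Mutagenesis experiment parameters
#'
#' Per-individual, per-position probabilities that the mutagen induces a
#' specific base change. EMS (and Az-MNU, to a good approximation) strongly
#' favours the canonical transitions G->A and C->T; every other substitution
#' is non-canonical. Selfed M2 material carries mutations that are
#' heterozygous in 2/3 of cases and homozygous in the remaining 1/3.
#'
#' Published per-experiment values: rice \code{p_c = 5.6e-6},
#' \code{p_nc = 4.93e-7}; wheat \code{p_c = 3.88e-6}, \code{p_nc = 0}.
#'
#' @param p_c Probability of a specific canonical change (G->A or C->T) in
#'   one individual at one position.
#' @param p_nc Same for a specific non-canonical change.
#' @param t_het,t_hom Fractions of induced mutations that are heterozygous /
#'   homozygous; must sum to 1.
#' @return An \code{experiment_params} object.
#' @seealso \code{\link{derive_rates}} to obtain \code{p_c}, \code{p_nc} from
#'   whole-sequence induced mutation rates and base composition.
#' @export
experiment_params <- function(p_c, p_nc = 0, t_het = 2 / 3, t_hom = 1 / 3) {
  stopifnot(p_c >= 0, p_c <= 1, p_nc >= 0, p_nc <= 1,
            t_het >= 0, t_hom >= 0, abs(t_het + t_hom - 1) < 1e-12)
  structure(list(p_c = p_c, p_nc = p_nc, t_het = t_het, t_hom = t_hom),
            class = "experiment_params")
}

#' Is a base change canonical?
#'
#' @param ref,alt Reference and alternate bases.
#' @return Logical: TRUE for G->A and C->T, the mutagen's preferred
#'   transitions, FALSE for all other substitutions.
#' @export
is_canonical <- function(ref, alt) {
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

# Per-change induction probability (p_c if canonical else p_nc), vectorized.
change_prob <- function(ref, alt, params) {
  ifelse(is_canonical(ref, alt), params$p_c, params$p_nc)
}
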