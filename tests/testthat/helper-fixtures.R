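# Shared fixtures: tiny designs and hand-built positions.

toy_design <- function() build_design(2, 2, 8)

wheat_params <- function() experiment_params(p_c = 3.88e-6, p_nc = 0)
rice_params <- function() experiment_params(p_c = 5.6e-6, p_nc = 4.93e-7)

# A position on an arbitrary design with given per-library coverage and a
# named list of count overrides, e.g. list("1.A" = 5) sets k[1, "A"] = 5.
make_position <- function(design, ref = "G", n = 1000, overrides = list(),
                          seqid = "g1", pos = 1L) {
  L <- nrow(design$libraries)
  n <- rep_len(n, L)
  k <- matrix(0, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    k[as.integer(parts[1]), parts[2]] <- overrides[[key]]
  }
  k[, ref] <- n - rowSums(k)
  stopifnot(all(k[, ref] >= 0))
  position_data(seqid, pos, ref, n, k)
}

# Independent brute-force posterior oracle: enumerates every configuration
# and evaluates prior x likelihood in direct (non-log) arithmetic with
# explicitly formed full priors (the product over all wells and changes),
# sharing no code path with position_posteriors beyond base dbinom.
brute_force_posteriors <- function(position, design, params,
                                   i_well = design$i_well) {
  ref <- position$ref
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  alts <- alts[ifelse((ref == "G" & alts == "A") | (ref == "C" & alts == "T"),
                      params$p_c, params$p_nc) > 0]
  nl <- position$n
  W <- nrow(design$wells)
  p_of <- function(m) if ((ref == "G" && m == "A") || (ref == "C" && m == "T"))
    params$p_c else params$p_nc
  all_alts <- setdiff(c("A", "C", "G", "T"), ref)
  p0 <- vapply(all_alts, function(m) (1 - p_of(m))^i_well, numeric(1))
  p1 <- vapply(all_alts, function(m) {
    i_well * p_of(m) * (1 - p_of(m))^(i_well - 1)
  }, numeric(1))
  names(p0) <- names(p1) <- all_alts
  prior_null <- prod(p0)^W
  lik <- function(well_i, alt, zyg) {
    val <- 1
    for (m in all_alts) {
      excl <- if (!is.null(well_i))
        c(design$wells$row_idx[well_i], design$wells$col_idx[well_i])
      else integer(0)
      keep <- setdiff(seq_along(nl), excl)
      e <- sum(position$k[keep, m]) / sum(nl[keep])
      for (l in seq_along(nl)) {
        mf <- 0
        if (!is.null(well_i) && m == alt &&
            l %in% c(design$wells$row_idx[well_i], design$wells$col_idx[well_i]))
          mf <- (if (zyg == "het") 1 else 2) / (2 * design$libraries$i_l[l])
        r <- (1 - mf) * e + mf
        kk <- position$k[l, m]
        val <- val * choose(nl[l], kk) * r^kk * (1 - r)^(nl[l] - kk)
      }
    }
    val
  }
  num <- prior_null * lik(NULL, NULL, NULL)
  labels <- "null"
  for (w in seq_len(W)) for (m in alts) for (z in c("het", "hom")) {
    t_z <- if (z == "het") params$t_het else params$t_hom
    prior <- t_z * p1[m] * p0[m]^(W - 1) *
      prod(p0[setdiff(all_alts, m)])^W
    num <- c(num, prior * lik(w, m, z))
    labels <- c(labels, paste(design$wells$well[w], m, z))
  }
  stats::setNames(num / sum(num), labels)
}

# Small simulated experiment used across tests.
small_sim <- function(seed, n_rows = 8, n_cols = 12, i_well = 8, len = 120,
                      gc = 0.5, params = rice_params(), coverage = 100,
                      dispersion = 20, error_rate = 1e-3, n_planted = 3) {
  set.seed(seed)
  d <- build_design(n_rows, n_cols, i_well)
  refs <- stats::setNames(random_reference(len, gc), "g1")
  sp <- simulation_spec(d, refs, params, error_rate = error_rate,
                        coverage = coverage, dispersion = dispersion)
  truth <- plant_mutations(sp, n_fixed = n_planted)
  list(design = d, params = params, spec = sp, truth = truth,
       positions = generate_counts(sp, truth))
}
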