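test_that("expected mutations sum change probabilities over sites", {
  wp <- wheat_params()
  refs <- list(n_GC = 40, n_AT = 60)
  expect_equal(expected_mutations(refs, wp, 768), 768 * 40 * 3.88e-6)
  expect_equal(expected_mutations(refs, experiment_params(0, 0), 768), 0)
  # linearity in individuals
  expect_equal(expected_mutations(refs, wp, 1536),
               2 * expected_mutations(refs, wp, 768))
  # string input equals a per-site brute-force sum
  set.seed(9)
  seqs <- stats::setNames(random_reference(300, 0.41), "g")
  rp <- rice_params()
  brute <- 0
  for (b in strsplit(seqs[[1]], "")[[1]]) {
    for (m in setdiff(c("A", "C", "G", "T"), b)) {
      brute <- brute + ifelse((b == "G" & m == "A") | (b == "C" & m == "T"),
                              rp$p_c, rp$p_nc)
    }
  }
  expect_equal(expected_mutations(seqs, rp, 768), 768 * brute)
})

test_that("per-change rates derive from whole-sequence rates and composition", {
  expect_equal(derive_rates(2.8e-6, 0, 0.5)$p_c, 5.6e-6)
  expect_equal(derive_rates(0, 1e-6, 0.5)$p_c, 0)
  expect_equal(derive_rates(1e-6, 0, 0.5)$p_nc, 0)
  expect_equal(derive_rates(0, 1e-6, 0.4)$p_nc, 1e-6 / (2 * 0.4 + 3 * 0.6))
  expect_error(derive_rates(1e-6, 0, 0), "underivable")
})

test_that("budget scaling rounds the corrected estimate", {
  expect_equal(scale_estimate(69, 1.55), 107L)
  expect_equal(scale_estimate(0), 0L)
  expect_equal(scale_estimate(100, 1.55), 155L)
  expect_equal(round(107 / 69, 2), 1.55)
})

test_that("call selection ranks by F, caps budget, and nests", {
  mk_table <- function(pos, t_best, null_post = 1 - t_best - 0.001) {
    structure(list(seqid = "g", pos = pos, ref = "G",
                   collapsed = NULL, null_posterior = null_post,
                   best = data.frame(well = "(R1,C1)", row = "R1", col = "C1",
                                     alt = "A", t = t_best,
                                     F = transform_score(t_best))),
              class = "posterior_table")
  }
  tabs <- list(mk_table(1, 0.95), mk_table(2, 0.4, 0.6), mk_table(3, 0.999))
  # position 2's best is null-dominated and never emitted
  all_calls <- select_calls(tabs, f_cutoff = -Inf)
  expect_equal(all_calls$pos, c(3, 1))
  top1 <- select_calls(tabs, n_predictions = 1)
  expect_equal(top1$pos, 3)
  expect_equal(top1$rank, 1L)
  # budget monotonicity: top-k nests
  for (k in 0:2) {
    expect_equal(select_calls(tabs, n_predictions = k)$pos,
                 utils::head(all_calls$pos, k))
  }
  expect_equal(nrow(select_calls(list(), n_predictions = 5)), 0)
  expect_error(select_calls(tabs), "exactly one")
  expect_error(select_calls(tabs, n_predictions = 1, f_cutoff = 0),
               "exactly one")
})

test_that("split-design FP estimation scales by well-pair counts", {
  d <- build_design(8, 12, 8)
  # scale factor for a 6+6 column split: 96 / 36
  expect_equal((d$n_rows * d$n_cols) / 36, 96 / 36)
  full <- c(10, 8, 6, 5, 4, 3, 2, 1)
  # pseudo calls above F=5 -> at budget 4 est FP = 1 * 96/36 = 2.67
  pseudo <- c(9, 5.5)
  b <- split_design_fp_threshold(full, pseudo, d, g = 6,
                                 target_fp_rate = 0.05)
  rates <- vapply(seq_along(full), function(k)
    sum(pseudo >= sort(full, decreasing = TRUE)[k]) * (96 / 36) / k,
    numeric(1))
  expect_equal(b, max(which(abs(rates - 0.05) == min(abs(rates - 0.05)))))
  # no pseudo calls at all: budget unbounded -> configured maximum
  expect_equal(split_design_fp_threshold(full, numeric(0), d, 6,
                                         max_budget = 8), 8L)
  expect_equal(split_design_fp_threshold(numeric(0), pseudo, d, 6), 0L)
})

test_that("split projection builds a consistent pseudo design", {
  sim <- small_sim(5, len = 10)
  sp <- split_pool_axis(sim$positions, sim$design, "col")
  expect_equal(sp$g, 6)
  expect_equal(sp$design$n_w, 36)
  expect_equal(sp$design$libraries$library, paste0("C", 1:12))
  expect_equal(sp$design$libraries$i_l, rep(64, 12))
  sel <- match(paste0("C", 1:12), sim$design$libraries$library)
  for (i in c(1, 5)) {
    expect_equal(sp$positions[[i]]$k, sim$positions[[i]]$k[sel, ])
    expect_equal(sp$positions[[i]]$n, sim$positions[[i]]$n[sel])
  }
  d3 <- build_design(3, 3, 2)
  expect_error(split_pool_axis(list(), d3, "col"), "odd number")
})

test_that("same-axis pseudo designs bound the false positives of real designs", {
  # A real mutation carries signal in only one pool of each axis, so a
  # same-axis pseudo design can never score it as highly as the real design
  # does: pseudo calls (signal leaking from single carrier pools) rank
  # strictly below the real calls, the estimated FP count at the real calls'
  # score levels is zero, and the procedure returns the full budget.
  recovered <- 0; planted <- 0
  for (seed in 1:6) {
    sim <- small_sim(seed + 100, len = 60, coverage = 100, n_planted = 3,
                     dispersion = 30)
    res <- camba_split_budget(sim$positions, sim$design, sim$params,
                              f_cutoff = 0, min_total = 1000)
    ov <- match_calls(res$full, sim$truth)
    recovered <- recovered + ov
    planted <- planted + nrow(sim$truth)
    true_F <- res$full$F[paste(res$full$pos, res$full$alt, res$full$well) %in%
                           paste(sim$truth$pos, sim$truth$alt, sim$truth$well)]
    if (nrow(res$pseudo) > 0 && length(true_F) > 0) {
      expect_lt(max(res$pseudo$F), min(true_F))
      expect_equal(sum(res$pseudo$F >= min(true_F)) * 96 / 36, 0)
    }
    expect_equal(res$budget, nrow(res$full))  # FP estimate 0 -> max budget
  }
  expect_gte(recovered / planted, 0.9)
})
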