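test_that("configuration enumeration counts wells x changes x zygosities", {
  d <- build_design(8, 12, 8)
  expect_equal(nrow(enumerate_configurations(d, rice_params(), "G")),
               96 * 3 * 2 + 1)   # 577
  expect_equal(nrow(enumerate_configurations(d, wheat_params(), "G")),
               96 * 2 + 1)       # canonical only: 193
  expect_equal(nrow(enumerate_configurations(d, wheat_params(), "A")), 1)
  cfg <- enumerate_configurations(d, wheat_params(), "C")
  expect_equal(cfg$kind[1], "null")
  expect_true(all(cfg$alt[-1] == "T"))
})

test_that("error rate pools counts over non-mutant libraries", {
  d <- build_design(1, 1, 8)   # two libraries around a single well
  p <- position_data("g", 1, "G", n = c(100, 300),
                     k = rbind(c(1, 0, 99, 0), c(3, 0, 297, 0)))
  expect_equal(error_rate(p, "A", d), 4 / 400)   # 0.01
  expect_equal(error_rate(p, "C", d), 0)
  # mutant configuration on a 2x2 design excludes the well's two libraries
  d2 <- toy_design()
  p2 <- make_position(d2, ref = "G", n = c(100, 100, 200, 200),
                      overrides = list("1.A" = 2, "3.A" = 4, "4.A" = 6))
  w <- d2$wells$well[d2$wells$row_idx == 1 & d2$wells$col_idx == 3]
  expect_equal(error_rate(p2, "A", d2, well = w), 6 / 300)  # libs 2 and 4 only
  expect_equal(error_rate(p2, "A", d2), 12 / 600)
})

test_that("allele fraction and expected change rate follow diploid mixing", {
  expect_equal(mutant_allele_fraction("het", 96), 1 / 192)
  expect_equal(mutant_allele_fraction("hom", 64), 1 / 64)
  expect_equal(mutant_allele_fraction("het", 96, contains = FALSE), 0)
  expect_equal(expected_change_rate(0.05, 0), 0.05)
  expect_equal(expected_change_rate(0.05, 1), 1)
  expect_equal(expected_change_rate(0.001, 1 / 192),
               (1 - 1 / 192) * 0.001 + 1 / 192)   # 0.0062031...
})

test_that("binomial log likelihood matches hand arithmetic", {
  # single well, single library pair; k = 2 of n = 10 at rate 0.1
  d <- build_design(1, 1, 1)
  p <- position_data("g", 1, "G", n = c(10, 0),
                     k = rbind(c(2, 0, 8, 0), c(0, 0, 0, 0)))
  cfg <- list(kind = "null")
  # null: e = 2/10 = 0.2 pooled; direct check of the dbinom sum instead:
  ll <- log_likelihood(p, cfg, d)
  e <- 2 / 10
  expect_equal(ll, dbinom(2, 10, e, log = TRUE) + dbinom(0, 0, e, log = TRUE))
  expect_equal(dbinom(2, 10, 0.1), 45 * 0.01 * 0.9^8)   # 0.1937102
})

test_that("zero-coverage positions contribute empty-product likelihoods", {
  d <- toy_design()
  p <- make_position(d, ref = "G", n = 0)
  cfg <- enumerate_configurations(d, rice_params(), "G")
  expect_error(position_posteriors(p, d, rice_params()), "no coverage")
  # but a configuration's likelihood over zero-coverage libraries is 1
  expect_equal(log_likelihood(p, as.list(cfg[2, ]), d), 0)
  expect_equal(log_likelihood(p, list(kind = "null"), d), 0)
})

test_that("prior ratio uses the per-well binomial and zygosity fractions", {
  pr <- experiment_params(1e-6, 0)
  expect_equal(exp(config_log_prior_ratio("G", "A", "het", pr, 8) -
                     log(2 / 3) - log(dbinom(1, 8, 1e-6) / dbinom(0, 8, 1e-6))),
               1)
  expect_equal(dbinom(1, 8, 1e-6), 8 * 1e-6 * (1 - 1e-6)^7)
  expect_equal(config_log_prior_ratio("G", "C", "het", pr, 8), -Inf)  # p_nc = 0
})

test_that("posteriors match the brute-force enumeration oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    d <- if (seed %% 2) toy_design() else build_design(3, 3, 4)
    L <- nrow(d$libraries)
    ref <- sample(c("G", "C"), 1)
    ov <- list()
    for (l in sample(L, 3)) {
      b <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      ov[[paste0(l, ".", b)]] <- sample(0:8, 1)
    }
    p <- make_position(d, ref = ref, n = sample(200:1500, L), overrides = ov)
    got <- position_posteriors(p, d, rice_params())
    want <- brute_force_posteriors(p, d, rice_params())
    expect_equal(unname(got$configs$posterior), unname(want),
                 tolerance = 1e-12)
    expect_equal(sum(got$configs$posterior), 1, tolerance = 1e-9)
    # zygosity collapse equals het + hom sums
    mut <- got$configs[-1, ]
    agg <- aggregate(mut$posterior, by = list(well = mut$well, alt = mut$alt),
                     FUN = sum)
    m <- merge(got$collapsed, agg, by.x = c("well", "alt"),
               by.y = c("well", "alt"))
    expect_equal(m$t, m$x, tolerance = 1e-12)
  }
})

test_that("vetoed configurations get zero mass; the null is never vetoed", {
  d <- toy_design()
  p <- make_position(d, ref = "G", n = 1000,
                     overrides = list("1.A" = 12, "3.A" = 9))
  excl <- position_exclusions(p, min_total = 100)
  excl$lib_veto[1] <- TRUE   # veto everything in library 1
  got <- position_posteriors(p, d, rice_params(), excl)
  in_lib1 <- !is.na(got$configs$row_idx) & got$configs$row_idx == 1
  expect_true(all(got$configs$posterior[in_lib1] == 0))
  expect_gt(got$configs$posterior[1], 0)
  expect_equal(sum(got$configs$posterior), 1, tolerance = 1e-9)
})

test_that("score transform is log-odds, symmetric and monotone", {
  expect_equal(transform_score(0.5), 0)
  expect_equal(transform_score(0.9), log(9))
  expect_equal(transform_score(0), -700)
  expect_equal(transform_score(1), 700)
  t <- seq(0.001, 0.999, by = 0.007)
  expect_true(all(diff(transform_score(t)) > 0))
  expect_equal(transform_score(t), -transform_score(1 - t), tolerance = 1e-9)
})

test_that("doubling evidence never weakens a clear mutant call", {
  d <- build_design(4, 4, 8)
  pr <- rice_params()
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(600:1200, nrow(d$libraries))
    p <- make_position(d, ref = "G", n = n,
                       overrides = list("1.A" = round(n[1] * 0.006),
                                        "5.A" = round(n[5] * 0.008)))
    p2 <- position_data("g1", 1, "G", n * 2, p$k * 2)
    t1 <- position_posteriors(p, d, pr)$best$t
    t2 <- position_posteriors(p2, d, pr)$best$t
    expect_gte(t2, t1)
  }
})
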