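test_that("percentile interval uses interpolated order statistics", {
  expect_equal(percentile_ci(1:1000), c(low = 25.975, high = 975.025))
  expect_equal(unname(diff(percentile_ci(rep(3.2, 50)))), 0)
  expect_error(percentile_ci(1:10), "at least 20")
  expect_error(percentile_ci(1:100, level = 0), "between 0 and 1")
  expect_error(percentile_ci(1:100, level = 1), "between 0 and 1")
})

test_that("two-sided bootstrap p doubles the smaller tail fraction", {
  expect_equal(two_sided_bootstrap_p(c(rep(2, 975), rep(0.5, 25)), 1), 0.05)
  expect_equal(two_sided_bootstrap_p(c(rep(2, 500), rep(0.5, 500)), 1), 1)
  expect_equal(two_sided_bootstrap_p(rep(2, 1000), 1), 0)
  # ties at the reference are excluded from both counts
  expect_equal(two_sided_bootstrap_p(c(rep(1, 100), rep(2, 880), rep(0.5, 20)),
                                     1), 0.04)
  # a degenerate distribution at the reference carries no evidence
  expect_equal(two_sided_bootstrap_p(rep(1, 100), 1), 1)
  expect_error(two_sided_bootstrap_p(numeric(0), 1), "no samples")
})

test_that("p-value matches a hand-counted fraction on random draws", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(500, mean = runif(1, -0.5, 0.5))
    hand <- 0L
    for (v in x) if (v > 0) hand <- hand + 1L
    expect_equal(two_sided_bootstrap_p(x, 0),
                 min(1, 2 * min(hand, 500 - sum(x == 0) - hand) / 500))
  }
})

test_that("zero synthesis noise collapses the bootstrap to the point estimate", {
  fit <- clonofit(sf ~ dose, lq_points(0.45, 0.05))
  expect_lt(fit$sigma, 1e-8)  # noiseless triplicates: all SDs ~ 0
  b <- boot_params(fit, n_boot = 30, seed = 1)
  expect_lt(max(abs(b$draws$alpha - 0.45)), 1e-6)
  expect_lt(unname(diff(b$ci["alpha", ])), 1e-6)

  bs <- boot_ser(fit, fit, n_boot = 30, seed = 1)
  expect_equal(bs$point, 1)
  expect_equal(bs$ci_low, 1, tolerance = 1e-6)
  expect_equal(bs$ci_high, 1, tolerance = 1e-6)
  expect_equal(bs$p_value, 1)
})

test_that("bootstraps are bit-identical under a fixed seed", {
  pair <- fit_pair(c(alpha = 0.45, beta = 0.05),
                   c(alpha = 0.5686, beta = 0.06), seed = 101)
  b1 <- boot_params(pair$ctrl, n_boot = 25, seed = 7)
  b2 <- boot_params(pair$ctrl, n_boot = 25, seed = 7)
  expect_identical(b1$draws, b2$draws)
  b3 <- boot_params(pair$ctrl, n_boot = 25, seed = 8)
  expect_false(identical(b1$draws, b3$draws))

  s1 <- boot_ser(pair$ctrl, pair$treat, n_boot = 25, seed = 7)
  s2 <- boot_ser(pair$ctrl, pair$treat, n_boot = 25, seed = 7)
  expect_identical(s1$draws, s2$draws)
})

test_that("the SER point estimate comes from the measured fits, not draw means", {
  pair <- fit_pair(c(alpha = 0.45, beta = 0.05),
                   c(alpha = 0.5686, beta = 0.06), seed = 103)
  b <- boot_ser(pair$ctrl, pair$treat, n_boot = 60, seed = 5)
  expect_equal(b$point, ser(pair$ctrl, pair$treat))
  expect_false(isTRUE(all.equal(b$point, mean(b$draws))))
})

test_that("bootstrap SER draws centre on the measured-truth SER", {
  # measured curves fixed at the generating truths (noiseless points), with
  # a representative synthesis SD, so the draw median must sit near the
  # analytic D10 ratio 1.19
  fc <- clonofit(sf ~ dose, lq_points(0.45, 0.05))
  ft <- clonofit(sf ~ dose, lq_points(0.5686, 0.06))
  designs <- list(transform(boot_design(fc), sd = 0.015),
                  transform(boot_design(ft), sd = 0.015))
  b <- boot_ser(fc, ft, n_boot = 400, seed = 9, designs = designs)
  expect_equal(median(b$draws, na.rm = TRUE), 1.19, tolerance = 0.03)
})

test_that("paired comparison is antisymmetric under mirrored arm streams", {
  pa <- fit_pair(c(alpha = 0.45, beta = 0.05),
                 c(alpha = 0.5686, beta = 0.06), seed = 107)
  pb <- fit_pair(c(alpha = 0.45, beta = 0.05),
                 c(alpha = 0.45, beta = 0.05), seed = 109)
  d1 <- boot_compare_ser(list(pa$ctrl, pa$treat), list(pb$ctrl, pb$treat),
                         n_boot = 30, seed = 11, arm_ids = 1:4)
  d2 <- boot_compare_ser(list(pb$ctrl, pb$treat), list(pa$ctrl, pa$treat),
                         n_boot = 30, seed = 11, arm_ids = c(3, 4, 1, 2))
  expect_equal(d1$draws, -d2$draws)
  expect_equal(d1$point, -d2$point)
  expect_equal(d1$p_value, d2$p_value)
})

test_that("a paired comparison reproduces each arm pair's standalone draws", {
  pa <- fit_pair(c(alpha = 0.45, beta = 0.05),
                 c(alpha = 0.5686, beta = 0.06), seed = 113)
  pb <- fit_pair(c(alpha = 0.45, beta = 0.05),
                 c(alpha = 0.45, beta = 0.05), seed = 115)
  sa <- boot_ser(pa$ctrl, pa$treat, n_boot = 30, seed = 13,
                 arm_ids = c(1L, 2L))
  sb <- boot_ser(pb$ctrl, pb$treat, n_boot = 30, seed = 13,
                 arm_ids = c(3L, 4L))
  d <- boot_compare_ser(list(pa$ctrl, pa$treat), list(pb$ctrl, pb$treat),
                        n_boot = 30, seed = 13)
  expect_equal(d$draws, sa$draws - sb$draws)
})

test_that("mechanistic binomial synthesis re-draws plates and the PE", {
  rec <- simulate_clonogenic(c(alpha = 0.45, beta = 0.05), seed = 121)
  fit <- clonofit(survival_curve(rec))
  des <- binomial_design(rec)
  expect_named(des, c("dose", "n", "sd", "n_seeded", "pe"))
  expect_equal(des$dose, 0:6)  # fit range excludes 8 Gy
  expect_equal(des$n, rep(3L, 7))
  expect_equal(des$pe, rep(plating_efficiency(rec), 7))

  b1 <- boot_params(fit, n_boot = 25, seed = 3, noise = "binomial",
                    design = des)
  b2 <- boot_params(fit, n_boot = 25, seed = 3, noise = "binomial",
                    design = des)
  expect_identical(b1$draws, b2$draws)
  # binomial draws must differ from the Gaussian stream under the same seed
  bg <- boot_params(fit, n_boot = 25, seed = 3)
  expect_false(identical(b1$draws, bg$draws))
  # and must reflect extra spread from the re-estimated plating efficiency
  expect_gt(sd(b1$draws$alpha), 0)
  expect_error(boot_params(fit, n_boot = 5, seed = 1, noise = "binomial",
                           design = boot_design(fit)),
               "n_seeded")
})

test_that("significance by CI containment matches the p-value rule", {
  set.seed(17)
  checked <- 0
  for (i in 1:40) {
    draws <- rnorm(500, mean = 1 + runif(1, -0.1, 0.1), sd = 0.05)
    p <- two_sided_bootstrap_p(draws, 1)
    ci <- percentile_ci(draws)
    if (abs(p - 0.05) > 2 / 500) {  # away from the percentile-tie edge
      expect_equal(p < 0.05, 1 < ci[["low"]] || 1 > ci[["high"]])
      checked <- checked + 1
    }
  }
  expect_gt(checked, 20)
})

test_that("identical-truth arms give a null Delta SER", {
  pa <- fit_pair(c(alpha = 0.45, beta = 0.05),
                 c(alpha = 0.45, beta = 0.05), seed = 211)
  d <- boot_compare_ser(list(pa$ctrl, pa$ctrl), list(pa$ctrl, pa$ctrl),
                        n_boot = 40, seed = 19)
  expect_equal(d$point, 0)
  expect_gt(d$p_value, 0.5)
})

test_that("bootstrap reports serialize seed, CI and p with the floor note", {
  pair <- fit_pair(c(alpha = 0.45, beta = 0.05),
                   c(alpha = 0.5686, beta = 0.06), seed = 117)
  b <- boot_ser(pair$ctrl, pair$treat, n_boot = 40, seed = 23)
  f <- tempfile(); fd <- tempfile()
  write_boot_report(b, f, draws_file = fd)
  txt <- readLines(f)
  expect_true(any(grepl("^rng_seed: 23$", txt)))
  expect_true(any(grepl("^n_boot: 40$", txt)))
  if (b$p_value == 0) expect_true(any(grepl("p_floor", txt)))
  expect_equal(nrow(read.csv(fd)), 40)
  expect_output(print(b), "SER")
})
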