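test_that("configuration validates frequencies, deltas and rates", {
  expect_error(sim_config(data.frame(label = "A", n_female = 10, n_male = 10,
                                     p_f = 0.1, p_m = 0.1, delta_f = 0.5)),
               "infeasible")
  expect_error(sim_config(data.frame(label = "A", n_female = 10, n_male = 10,
                                     p_f = 1.2, p_m = 0.1)), "out of")
  expect_error(sim_config(missing_male = 1.5), "rates")
  # defaults: five populations, equal sex ratio, stratified null
  cfg <- sim_config()
  expect_equal(nrow(cfg$populations), 5)
  expect_true(all(cfg$populations$p_f == cfg$populations$p_m))
  expect_equal(cfg$male_layout, "hemizygous")
})

test_that("draws are reproducible and variant-order invariant", {
  cfg <- sim_config(seed = 99)
  a <- simulate_counts(cfg, 4)
  b <- simulate_counts(cfg, 4)
  expect_identical(a, b)
  # the first variants of a longer run coincide with a shorter run
  c8 <- simulate_counts(cfg, 8)
  expect_identical(c8[1:4], a)
})

test_that("genotype-class frequencies converge to the configured trinomial", {
  n <- 2e5
  cfg <- sim_config(data.frame(label = "P", n_female = n, n_male = n,
                               p_f = 0.3, p_m = 0.3, delta_f = 0.05),
                    seed = 17)
  x <- simulate_counts(cfg, 1)[[1]]$P
  pr <- c(0.7^2 + 0.05, 2 * 0.3 * 0.7 - 0.1, 0.3^2 + 0.05)
  for (k in 1:3) {
    se <- sqrt(pr[k] * (1 - pr[k]) / n)
    expect_lt(abs(x$female[k] / n - pr[k]), 4 * se)
  }
  se_m <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(x$male[2] / n - 0.3), 4 * se_m)
})

test_that("error model: identity at zero rates, correct rates otherwise", {
  sex <- setNames(rep(c("female", "male"), each = 3),
                  c("f1", "f2", "f3", "m1", "m2", "m3"))
  gt <- c(f1 = "0/0", f2 = "0/1", f3 = "1/1", m1 = "0", m2 = "1", m3 = "0")
  expect_identical(apply_error_model(gt, sex), gt)

  # male missingness ~ 20%: measured on a large simulated panel
  big_sex <- setNames(rep(c("female", "male"), each = 5000),
                      c(sprintf("f%d", 1:5000), sprintf("m%d", 1:5000)))
  big_gt <- setNames(rep(c("0/1", "1"), each = 5000), names(big_sex))
  out <- apply_error_model(big_gt, big_sex, missing_male = 0.2, seed = 3)
  male_rate <- mean(out[5001:10000] == ".")
  expect_lt(abs(male_rate - 0.2), 4 * sqrt(0.2 * 0.8 / 5000))
  expect_true(all(out[1:5000] == "0/1"))

  # hemizygote miscalls become diploid heterozygote strings
  out2 <- apply_error_model(big_gt, big_sex, male_het_error = 0.1, seed = 4)
  expect_gt(sum(out2[5001:10000] == "0/1"), 0)
})

test_that("simulated VCF round-trips through tally_variant exactly", {
  cfg <- sim_config(
    data.frame(label = c("P1", "P2"), n_female = c(60, 40),
               n_male = c(50, 50), p_f = c(0.2, 0.4), p_m = c(0.25, 0.4)),
    region = "NPR", missing_female = 0.05, missing_male = 0.1,
    male_het_error = 0.05, seed = 21
  )
  sim <- simulate_vcf(cfg, 6, dir = tempfile())
  vcf <- read_vcf_genotypes(sim$vcf)
  sex <- read_sex_map(sim$sex_map)
  drawn <- simulate_counts(cfg, 6)
  expect_equal(nrow(vcf$sites), 6)
  # sex map lists exactly the VCF samples
  expect_setequal(names(sex), colnames(vcf$gt))
  # NPR males are written haploid (or 0/1 only for miscalls)
  male_ids <- names(sex)[sex == "male"]
  male_calls <- vcf$gt[, male_ids]
  expect_true(all(male_calls %in% c("0", "1", ".", "0/1")))
  expect_true(any(nchar(male_calls) == 1))
  for (i in 1:6) {
    tv <- suppressWarnings(tally_variant(vcf$gt[i, ], sex, "NPR"))
    pooled <- pool_counts(drawn[[i]])
    expect_equal(tv$female, pooled$female)
    expect_equal(tv$male, pooled$male)
    expect_equal(tv$missing_female, pooled$missing_female)
    expect_equal(tv$missing_male, pooled$missing_male)
  }
  # truth table covers every variant/population pair
  truth <- data.table::fread(sim$truth)
  expect_equal(nrow(truth), 12)

  # positions must match the configured region
  expect_error(simulate_vcf(cfg, 2, positions = c(100000, 155000000),
                            dir = tempfile()),
               "outside the configured region")
})

test_that("pooling HWE populations with unequal MAFs inflates delta", {
  # Wahlund: two HWE populations at p = 0.1 and 0.5; the pooled female HWD
  # estimate is positive in expectation (analytic value
  # mean(p^2) - mean(p)^2 = 0.04)
  cfg <- sim_config(
    data.frame(label = c("A", "B"), n_female = 500, n_male = 500,
               p_f = c(0.1, 0.5), p_m = c(0.1, 0.5)),
    seed = 77
  )
  draws <- simulate_counts(cfg, 400)
  deltas <- vapply(draws, function(d) {
    hwd_delta(pool_counts(d)$female)
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_equal(mean(deltas), 0.04, tolerance = 0.25)
})

test_that("power grows along a sample-size doubling ladder", {
  sizes <- c(125, 250, 500, 1000)
  power <- vapply(sizes, function(n) {
    cfg <- sim_config(
      data.frame(label = "P", n_female = n, n_male = n,
                 p_f = 0.35, p_m = 0.25),
      seed = 1234
    )
    null_typeI_experiment(cfg, n_reps = 400, alpha = 0.05)$reject_rate
  }, numeric(1))
  expect_true(all(diff(power) > 0))
  expect_gt(power[length(power)], 0.95)
})
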