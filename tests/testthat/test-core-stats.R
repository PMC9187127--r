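test_that("frequency and HWD estimates match their definitions", {
  x <- toy_npr_counts()
  fe <- estimate_freqs(x)
  expect_equal(fe$p_f, 0.2)
  expect_equal(fe$delta_f, 0)
  expect_equal(fe$p_m, 0.5)
  expect_true(is.na(fe$delta_m))
  expect_equal(fe$var_f, 0.16 / 2000)
  expect_equal(fe$var_m, 0.25 / 1000)

  nfe <- table1_counts("X-2779827-G-A", "NFE")
  fe2 <- estimate_freqs(nfe)
  expect_equal(fe2$p_f, 196 / 39262, tolerance = 1e-12)
  expect_equal(round(fe2$delta_m, 3), -0.226)

  expect_error(estimate_freqs(ss_counts(c(0, 0, 0), c(1, 1), "hemizygous")),
               "empty sex stratum")
})

test_that("hwd_delta matches its definition and feasible bounds", {
  expect_equal(hwd_delta(c(640, 320, 40)), 0)
  expect_equal(round(hwd_delta(c(626, 13577, 67)), 3), -0.226)
  expect_equal(hwd_delta(c(0, 100, 0)), -0.25)
  expect_error(hwd_delta(c(0, 0, 0)), "empty")

  set.seed(11)
  for (i in 1:200) {
    tr <- random_triple()
    d <- hwd_delta(tr)
    p <- (2 * tr[3] + tr[2]) / (2 * sum(tr))
    expect_gte(d, max(-p^2, -(1 - p)^2) - 1e-12)
    expect_lte(d, p * (1 - p) + 1e-12)
  }
})

test_that("sdMAF tests reproduce worked examples", {
  # toy NPR variant: T = 0.09 / 3.3e-4; p frozen from an
  # arbitrary-precision erfc oracle
  r <- sdmaf_test_npr(toy_npr_counts())
  expect_equal(r$statistic, 272.7272727, tolerance = 1e-9)
  expect_equal(r$neg_log10_p, 60.53947710, tolerance = 1e-8)
  expect_equal(signif(10^-r$neg_log10_p, 3), 2.89e-61)
  expect_equal(r$statistic_type, "T_X")

  # equal frequencies, HWE females: null at exactly 0
  eq <- ss_counts(c(360, 480, 160), c(600, 400), "hemizygous")
  r0 <- sdmaf_test_npr(eq)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$neg_log10_p, 0)

  # identical female/male triples in PAR
  same <- ss_counts(c(30, 20, 50), c(30, 20, 50), "diploid")
  rs <- sdmaf_test_par(same)
  expect_equal(rs$statistic, 0)
  expect_equal(rs$sdmaf, 0)

  # layout guards
  expect_error(sdmaf_test_npr(same), "hemizygous")
  expect_error(sdmaf_test_par(toy_npr_counts()), "diploid")

  # degenerate sex-fixed variant: infinite statistic, flagged
  fixed <- ss_counts(c(0, 0, 100), c(100, 0), "hemizygous")
  rf <- sdmaf_test(fixed)
  expect_true(rf$degenerate)
  expect_identical(rf$statistic, Inf)
  expect_identical(rf$neg_log10_p, Inf)
})

test_that("allele-swap antisymmetry holds for both tests", {
  set.seed(23)
  for (i in 1:50) {
    f <- random_triple(500)
    layout <- if (i %% 2) "hemizygous" else "diploid"
    m <- if (layout == "hemizygous") {
      c(sample.int(300, 1), sample.int(300, 1))
    } else random_triple(500)
    x <- ss_counts(f, m, layout)
    a <- sdmaf_test(x)
    b <- sdmaf_test(swap_alleles(x))
    expect_equal(b$sdmaf, -a$sdmaf, tolerance = 1e-12)
    expect_equal(b$statistic, a$statistic, tolerance = 1e-9)
    expect_equal(b$neg_log10_p, a$neg_log10_p, tolerance = 1e-9)
  }
})

test_that("T_A with zero HWD reduces to the two-sample proportion Wald test", {
  # integer triples in exact HWE proportions (n q^2, 2 n p q, n p^2),
  # so both deltas are identically zero
  hwe_triple <- function(n, p) round(n * c((1 - p)^2, 2 * p * (1 - p), p^2))
  grid <- expand.grid(p1 = c(0.1, 0.3, 0.5), p2 = c(0.2, 0.4, 0.7))
  for (i in seq_len(nrow(grid))) {
    f <- 100; m <- 100
    ft <- hwe_triple(f, grid$p1[i]); mt <- hwe_triple(m, grid$p2[i])
    x <- ss_counts(ft, mt, "diploid")
    fe <- estimate_freqs(x)
    expect_equal(fe$delta_f, 0, tolerance = 1e-14)
    expect_equal(fe$delta_m, 0, tolerance = 1e-14)
    wald <- (fe$p_f - fe$p_m)^2 /
      (fe$p_f * (1 - fe$p_f) / (2 * f) + fe$p_m * (1 - fe$p_m) / (2 * m))
    expect_equal(sdmaf_test_par(x)$statistic, wald, tolerance = 1e-12)
  }
})

test_that("HWE chi-square forms agree and reproduce packaged examples", {
  nfe <- table1_counts("X-52861869-T-C", "NFE")
  h <- hwe_chisq(nfe, "female")
  expect_equal(signif(10^-h$neg_log10_p, 3), 1.45e-103)

  # HWE-exact proportions give statistic 0
  x <- ss_counts(c(640, 320, 40), c(10, 10, 10), "diploid")
  expect_equal(hwe_chisq(x, "female")$statistic, 0)

  # delta form vs expected-count form on a fixed triple and random ones
  tri <- ss_counts(c(30, 20, 50), c(1, 1, 1), "diploid")
  expect_equal(hwe_chisq(tri, "female", form = "delta")$statistic,
               hwe_chisq(tri, "female", form = "expected")$statistic,
               tolerance = 1e-10)

  # scopes: male and combined need diploid layout
  expect_error(hwe_chisq(toy_npr_counts(), "male"), "diploid")
  comb <- hwe_chisq(x, "sex_combined")
  expect_equal(comb$n, 1030)
  expect_equal(comb$n1, 1000)
  expect_equal(comb$n2, 30)

  # monomorphic stratum reports NA p
  mono <- ss_counts(c(100, 0, 0), c(50, 0, 0), "diploid")
  hm <- hwe_chisq(mono, "female")
  expect_true(is.na(hm$statistic) && is.na(hm$neg_log10_p))
  expect_equal(hm$delta, 0)
})

test_that("within-sex exact test agrees with the normalized-weight oracle", {
  expect_equal(hwe_exact_within_sex(c(57, 0, 0))$p, 1)
  expect_equal(hwe_exact_within_sex(c(1, 0, 1))$p,
               oracle_exact_within(c(1, 0, 1)))

  # spot-check larger random triples (exhaustive n <= 25 runs in the
  # acceptance suite)
  set.seed(41)
  for (i in 1:40) {
    tr <- random_triple(60)
    expect_equal(hwe_exact_within_sex(tr)$p, oracle_exact_within(tr),
                 tolerance = 1e-9, info = paste(tr, collapse = ","))
  }
})

test_that("joint X-linked exact test matches oracles and reduces cleanly", {
  # tool-exact reference value for the toy variant (see acceptance suite)
  r <- hwe_exact_x_joint(c(640, 320, 40), c(500, 500))
  expect_equal(r$p, 6.418765e-61, tolerance = 1e-6)

  # m = 0 reduces to the within-sex exact test
  for (tr in list(c(5, 2, 3), c(10, 1, 0), c(2, 8, 2))) {
    expect_equal(hwe_exact_x_joint(tr, c(0, 0))$p,
                 hwe_exact_within_sex(tr)$p)
  }

  # brute-force allele-subset enumeration for tiny samples
  cases <- list(
    list(f = c(1, 2, 1), m = c(2, 2)),
    list(f = c(2, 1, 0), m = c(1, 3)),
    list(f = c(0, 3, 1), m = c(4, 0)),
    list(f = c(3, 0, 2), m = c(0, 2))
  )
  for (cs in cases) {
    expect_equal(hwe_exact_x_joint(cs$f, cs$m)$p,
                 oracle_exact_x_bruteforce(cs$f, cs$m),
                 tolerance = 1e-9,
                 info = paste(c(cs$f, cs$m), collapse = ","))
  }

  # normalized-weight oracle on moderate sizes
  set.seed(43)
  for (i in 1:30) {
    f <- as.vector(rmultinom(1, sample.int(12, 1), c(0.4, 0.4, 0.2)))
    m <- c(sample.int(8, 1), sample.int(8, 1) - 1L)
    expect_equal(hwe_exact_x_joint(f, m)$p, oracle_exact_x_joint(f, m),
                 tolerance = 1e-9, info = paste(c(f, m), collapse = ","))
  }
})

test_that("log-space chi-square p-values survive extreme statistics", {
  expect_equal(chisq1_neg_log10_sf(0), 0)
  expect_equal(chisq1_neg_log10_sf(3.841459), 1.30103004, tolerance = 1e-7)
  # frozen from an arbitrary-precision complementary-error-function oracle
  expect_equal(chisq1_neg_log10_sf(1600), 349.1359765, tolerance = 1e-7)
  expect_identical(chisq1_neg_log10_sf(Inf), Inf)
  expect_error(chisq1_neg_log10_sf(-1), ">= 0")
  # no underflow: monotone far beyond the double-precision p floor
  v <- chisq1_neg_log10_sf(c(2000, 4000, 8000))
  expect_true(all(diff(v) > 0) && all(is.finite(v)))
})

test_that("p-value rendering floors at the 1e-300 convention", {
  expect_equal(format_pvalue(c(0, 83.84466, 310)),
               c("1", "1.43E-84", "<1E-300"))
  expect_equal(format_pvalue(NA_real_), "NA")
})
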