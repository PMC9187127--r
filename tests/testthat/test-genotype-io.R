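test_that("sex maps are normalized and validated", {
  p <- write_sex_map_file(c("s1", "s2", "s3", "s4"), c("F", "M", "2", "1"))
  sm <- read_sex_map(p)
  expect_equal(unname(sm), c("female", "male", "female", "male"))
  expect_equal(names(sm), c("s1", "s2", "s3", "s4"))

  dup <- write_sex_map_file(c("s1", "s1"), c("F", "M"))
  expect_error(read_sex_map(dup), "duplicate")

  bad <- write_sex_map_file(c("s1", "s2"), c("F", "U"))
  expect_error(read_sex_map(bad), "unknown sex code")
})

test_that("tally_variant applies region-specific male ploidy and policy", {
  sex <- c(f1 = "female", f2 = "female", f3 = "female",
           m1 = "male", m2 = "male")
  gt <- c(f1 = "0/0", f2 = "0/0", f3 = "0/1", m1 = "0", m2 = "1")
  x <- tally_variant(gt, sex, "NPR")
  expect_equal(x$female, c(2, 1, 0))
  expect_equal(x$male, c(1, 1))
  expect_equal(x$male_layout, "hemizygous")

  # diploid-homozygous male calls in NPR contribute one allele
  gt2 <- c(f1 = "0/0", f2 = "0/0", f3 = "0/1", m1 = "1/1", m2 = "0/0")
  x2 <- tally_variant(gt2, sex, "NPR")
  expect_equal(x2$male, c(1, 1))

  # heterozygous male in NPR: policy-dependent
  gt3 <- c(f1 = "0/0", f2 = "0/0", f3 = "0/1", m1 = "0/1", m2 = "1")
  expect_warning(x3 <- tally_variant(gt3, sex, "NPR"), "heterozygous male")
  expect_equal(x3$missing_male, 1)
  expect_equal(x3$male, c(0, 1))
  expect_error(tally_variant(gt3, sex, "NPR", male_het_policy = "error"),
               "heterozygous male")

  # PAR1: males diploid, heterozygote slot real
  x4 <- tally_variant(gt3, sex, "PAR1")
  expect_equal(x4$male_layout, "diploid")
  expect_equal(x4$male[2], 1)
  expect_equal(x4$missing_male, 1)  # the haploid call cannot be diploid-tallied

  # missing calls increment per-sex counters
  gt5 <- c(f1 = "./.", f2 = "0/0", f3 = "0/1", m1 = ".", m2 = "1")
  x5 <- tally_variant(gt5, sex, "NPR")
  expect_equal(x5$missing_female, 1)
  expect_equal(x5$missing_male, 1)
})

test_that("global MAF pools allele counts with region-appropriate ploidy", {
  x <- toy_npr_counts()
  gm <- compute_global_maf(x)
  expect_equal(gm$maf, 0.3)
  expect_equal(gm$minor_allele, "A")
  expect_false(gm$tie)
  # pooled count equals the per-sex sum (module invariant)
  ac <- allele_counts(x)
  expect_equal(unname(ac["A"]), (2 * 40 + 320) + 500)
  expect_equal(unname(ac["total"]), 2 * 1000 + 1000)

  # exact 0.5 is a tie resolved toward the designated (ALT) allele
  tie <- ss_counts(c(10, 0, 10), c(5, 5), "hemizygous")
  gm2 <- compute_global_maf(tie)
  expect_true(gm2$tie)
  expect_equal(gm2$minor_allele, "A")

  mono <- ss_counts(c(0, 0, 10), c(0, 0, 10), "diploid")
  gm3 <- compute_global_maf(mono)
  expect_true(gm3$monomorphic)
  expect_equal(gm3$maf, 0)
  expect_equal(gm3$minor_allele, "a")
})

test_that("filter_variants implements the selection pipeline stages", {
  fx <- write_filter_fixture_vcf()
  vcf <- read_vcf_genotypes(fx$path)
  sex <- read_sex_map(fx$sex_map)
  map <- load_region_map("GRCh37")
  fl <- filter_variants(vcf, sex, map, maf_threshold = 0.05)
  s <- fl$summary
  expect_equal(sum(s$multiallelic), 2)
  expect_equal(sum(s$indel), 2)
  expect_equal(sum(s$low_maf), 2)
  expect_equal(sum(s$monomorphic), 1)
  expect_equal(sum(s$retained), 3)
  expect_equal(length(fl$records), 3)
  # conservation: removed + retained = input
  expect_equal(sum(s$multiallelic + s$indel + s$low_maf + s$monomorphic +
                     s$retained), sum(s$input))
  expect_equal(sum(s$input), 10)

  # threshold 0 keeps everything polymorphic and biallelic
  fl0 <- filter_variants(vcf, sex, map, maf_threshold = 0)
  expect_equal(length(fl0$records), 5)
})

test_that("count tables read gnomAD-style summary rows and round-trip", {
  recs <- read_count_table(table1_fixture())
  expect_length(recs, 16)

  x <- table1_counts("X-2779827-G-A", "NFE")
  expect_equal(x$female, c(19436, 194, 1))
  expect_equal(x$male, c(626, 13577, 67))
  expect_equal(x$male_layout, "diploid")

  # male RA = NA denotes hemizygous layout
  xh <- table1_counts("X-52861869-T-C", "AFR")
  expect_equal(xh$male_layout, "hemizygous")
  expect_equal(xh$male, c(8552, 175))

  out <- tempfile(fileext = ".tsv")
  write_count_table(recs, out)
  recs2 <- read_count_table(out)
  expect_equal(length(recs2), length(recs))
  for (i in seq_along(recs)) {
    expect_equal(recs2[[i]]$counts$female, recs[[i]]$counts$female)
    expect_equal(recs2[[i]]$counts$male, recs[[i]]$counts$male)
    expect_equal(recs2[[i]]$population, recs[[i]]$population)
  }

  # a SNP with a single sex row is rejected
  bad <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Region\tSNP\tPopulation\tSex\tCallRate\tRR\tRA\tAA\tMinorAllele",
    "NPR\tX-1-A-G\tP1\tF\tNA\t10\t5\t1\tG"), bad)
  expect_error(read_count_table(bad), "exactly one female and one male")
})

test_that("call rate is percent non-missing", {
  x <- ss_counts(c(50, 40, 9), c(70, 30), "hemizygous",
                 missing_female = 1, missing_male = 0)
  expect_equal(call_rate(x, "female"), 99)
  expect_equal(call_rate(x, "male"), 100)
  allmiss <- ss_counts(c(0, 0, 0), c(0, 0), "hemizygous",
                       missing_female = 0, missing_male = 5)
  expect_error(call_rate(allmiss, "female"), "no individuals")
  expect_error(call_rate(allmiss, "male"), "all genotypes missing")
})
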