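# small in-code fixtures shared across test files

table1_fixture <- function() {
  system.file("extdata", "gnomad_top8_counts.tsv", package = "sdmafx")
}

table1_counts <- function(snp, pop) {
  recs <- read_count_table(table1_fixture())
  hit <- vapply(recs, function(r) r$id == snp && r$population == pop,
                logical(1))
  recs[[which(hit)]]$counts
}

# a toy NPR variant: HWE females at p = 0.2, males at 0.5
toy_npr_counts <- function() {
  ss_counts(c(640, 320, 40), c(500, 500), "hemizygous")
}

write_sex_map_file <- function(ids, codes, path = tempfile(fileext = ".tsv")) {
  writeLines(paste(ids, codes, sep = "\t"), path)
  path
}

# hand-built 10-record VCF for the filter pipeline: 2 multiallelic,
# 2 indels, 3 biallelic SNPs with low global MAF, 3 retainable SNPs
write_filter_fixture_vcf <- function(path = tempfile(fileext = ".vcf")) {
  samples <- c(sprintf("f%d", 1:10), sprintf("m%d", 1:10))
  gt_common  <- c(rep("0/1", 10), rep("1", 5), rep("0", 5))   # MAF ~ 0.5
  gt_rare    <- c("0/1", rep("0/0", 9), rep("0", 10))         # MAF = 1/30
  gt_mono    <- c(rep("0/0", 10), rep("0", 10))
  rows <- c(
    paste(c("X", 10e6, "multi1", "A", "G,T", ".", "PASS", ".", "GT",
            gt_common), collapse = "\t"),
    paste(c("X", 11e6, "multi2", "C", "A,T", ".", "PASS", ".", "GT",
            gt_common), collapse = "\t"),
    paste(c("X", 12e6, "indel1", "AT", "A", ".", "PASS", ".", "GT",
            gt_common), collapse = "\t"),
    paste(c("X", 13e6, "indel2", "G", "GAA", ".", "PASS", ".", "GT",
            gt_common), collapse = "\t"),
    paste(c("X", 14e6, "rare1", "A", "G", ".", "PASS", ".", "GT",
            gt_rare), collapse = "\t"),
    paste(c("X", 15e6, "rare2", "T", "C", ".", "PASS", ".", "GT",
            gt_rare), collapse = "\t"),
    paste(c("X", 16e6, "mono1", "G", "A", ".", "PASS", ".", "GT",
            gt_mono), collapse = "\t"),
    paste(c("X", 17e6, "keep1", "A", "G", ".", "PASS", ".", "GT",
            gt_common), collapse = "\t"),
    paste(c("X", 18e6, "keep2", "C", "T", ".", "PASS", ".", "GT",
            gt_common), collapse = "\t"),
    paste(c("X", 19e6, "keep3", "G", "C", ".", "PASS", ".", "GT",
            gt_common), collapse = "\t")
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=X,length=155270560>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  list(path = path,
       sex_map = write_sex_map_file(samples, rep(c("F", "M"), each = 10)))
}

random_triple <- function(max_n = 2000) {
  n <- sample.int(max_n, 1)
  p <- runif(1, 0.02, 0.98)
  d <- runif(1, max(-p^2, -(1 - p)^2), p * (1 - p))
  pr <- pmax(c((1 - p)^2 + d, 2 * p * (1 - p) - 2 * d, p^2 + d), 0)
  as.vector(rmultinom(1, n, pr / sum(pr)))
}
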