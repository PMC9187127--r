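#' Pipeline run configuration
#'
#' Bundles everything [run_pipeline()] needs. Mode `"vcf"` reads
#' individual-level genotypes plus a sample sex map and applies the
#' variant-selection pipeline; mode `"count_table"` reads an aggregated
#' sex-stratified count table (one female and one male row per SNP and
#' population) and tests each row pair directly.
#'
#' @param input Path to the VCF or count table.
#' @param mode `"vcf"` or `"count_table"`.
#' @param sex_map Path to the sample sex map TSV (vcf mode only).
#' @param build Genome build for the region map.
#' @param region_override Optional BED path overriding PAR intervals.
#' @param maf_threshold Global-MAF retention threshold (vcf mode).
#' @param sig_threshold Genome-wide significance threshold on p.
#' @param male_het_policy Policy for heterozygous male calls at hemizygous
#'   sites.
#' @param window_size,window_step Sliding-window parameters.
#' @param out_dir Output directory for the TSV reports.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, mode = c("vcf", "count_table"),
                       sex_map = NULL, build = "GRCh37",
                       region_override = NULL, maf_threshold = 0.05,
                       sig_threshold = 5e-8,
                       male_het_policy = "set_missing",
                       window_size = 50, window_step = 25,
                       out_dir = "sdmaf_out") {
  mode <- match.arg(mode)
  if (mode == "vcf" && is.null(sex_map)) {
    stop("vcf mode requires a sex map", call. = FALSE)
  }
  if (maf_threshold < 0 || maf_threshold >= 1 ||
      sig_threshold <= 0 || sig_threshold >= 1) {
    stop("thresholds must lie in (0,1)", call. = FALSE)
  }
  structure(
    list(input = input, mode = mode, sex_map = sex_map, build = build,
         region_override = region_override, maf_threshold = maf_threshold,
         sig_threshold = sig_threshold, male_het_policy = male_het_policy,
         window_size = window_size, window_step = window_step,
         out_dir = out_dir),
    class = "run_config"
  )
}

# one results row per variant record (designated allele already minor)
.variant_row <- function(rec, sig_nlp) {
  x <- rec$counts
  r <- sdmaf_test(x)
  hemi <- x$male_layout == "hemizygous"
  gm <- compute_global_maf(x)
  hwe_f <- hwe_chisq(x, "female")
  ex_f <- hwe_exact_within_sex(x$female)
  if (hemi) {
    hwe_m_delta <- NA_real_; hwe_m_nlp <- NA_real_
    hwe_c_nlp <- NA_real_; ex_m_nlp <- NA_real_
  } else {
    hwe_m <- hwe_chisq(x, "male")
    hwe_c <- hwe_chisq(x, "sex_combined")
    ex_m <- hwe_exact_within_sex(x$male)
    hwe_m_delta <- hwe_m$delta; hwe_m_nlp <- hwe_m$neg_log10_p
    hwe_c_nlp <- hwe_c$neg_log10_p; ex_m_nlp <- ex_m$neg_log10_p
  }
  data.table::data.table(
    CHR = rec$chrom, POS = rec$pos, ID = rec$id,
    REF = rec$ref, ALT = rec$alt, REGION = rec$region,
    POPULATION = if (is.null(rec$population)) NA_character_
                 else rec$population,
    MINOR_ALLELE = x$allele_A,
    STAT_TYPE = r$statistic_type,
    F0 = x$female[1], F1 = x$female[2], F2 = x$female[3],
    M0 = x$male[1],
    M1 = if (hemi) NA_real_ else x$male[2],
    M2 = if (hemi) x$male[2] else x$male[3],
    MAF_F = r$p_f, MAF_M = r$p_m, MAF = gm$freq_A,
    sdMAF = r$sdmaf,
    STATISTIC = r$statistic,
    NEG_LOG10_P = r$neg_log10_p,
    P = format_pvalue(r$neg_log10_p),
    SIGNIFICANT = r$neg_log10_p > sig_nlp,
    DEGENERATE = r$degenerate, FLIP = r$flip, TIE = r$tie,
    HWD_DELTA_F = hwe_f$delta, HWE_P_F = format_pvalue(hwe_f$neg_log10_p),
    HWE_NEG_LOG10_P_F = hwe_f$neg_log10_p,
    HWD_DELTA_M = hwe_m_delta,
    HWE_NEG_LOG10_P_M = hwe_m_nlp,
    HWE_NEG_LOG10_P_COMBINED = hwe_c_nlp,
    HWE_EXACT_NEG_LOG10_P_F = ex_f$neg_log10_p,
    HWE_EXACT_NEG_LOG10_P_M = ex_m_nlp
  )
}

#' Run the end-to-end sdMAF pipeline
#'
#' Reads the input, selects biallelic SNPs (vcf mode), designates the
#' pooled-sample minor allele per variant, dispatches the region-
#' appropriate sdMAF test (T_X in NPR/PAR3, T_A in PAR1/PAR2), computes the
#' region-appropriate HWE columns, detects minor-allele flips, smooths
#' -log10 p with sliding windows, and writes TSV reports to
#' `config$out_dir`: `results.tsv`, `region_summary.tsv`, `flips.tsv`,
#' `windows.tsv`, and (vcf mode) `filter_summary.tsv`. Reruns with an
#' identical configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the results `data.table`, the filter
#'   summary (or NULL), the window table, the region summary, and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  map <- load_region_map(config$build, override = config$region_override)
  sig_nlp <- -log10(config$sig_threshold)

  filter_summary <- NULL
  if (config$mode == "vcf") {
    sex <- read_sex_map(config$sex_map)
    vcf <- read_vcf_genotypes(config$input)
    fl <- filter_variants(vcf, sex, map,
                          maf_threshold = config$maf_threshold,
                          male_het_policy = config$male_het_policy)
    records <- fl$records
    filter_summary <- fl$summary
    # designate the pooled minor allele
    records <- lapply(records, function(rec) {
      if (rec$minor_allele != rec$counts$allele_A) {
        rec$counts <- swap_alleles(rec$counts)
      }
      rec
    })
  } else {
    records <- read_count_table(config$input)
    records <- lapply(records, function(rec) {
      if (!is.na(rec$minor_allele) &&
          rec$minor_allele == rec$counts$allele_a) {
        rec$counts <- swap_alleles(rec$counts)
      }
      rec$region <- assign_region(map, rec$pos)
      rec
    })
  }

  if (!length(records)) {
    warning("no variants retained; writing empty outputs", call. = FALSE)
    results <- data.table::data.table()
  } else {
    results <- data.table::rbindlist(lapply(records, .variant_row,
                                            sig_nlp = sig_nlp))
    data.table::setorder(results, POS, ID)
  }

  windows <- if (nrow(results) >= config$window_size) {
    sliding_mean_neglog10(results$POS, results$NEG_LOG10_P,
                          config$window_size, config$window_step)
  } else {
    data.frame(start_index = integer(0), pos = numeric(0),
               mean_neg_log10_p = numeric(0), n_snps = integer(0),
               n_infinite = integer(0))
  }
  summary <- region_summary(results, config$sig_threshold)
  flips <- if (nrow(results)) results[results$FLIP, ] else results

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    results = file.path(config$out_dir, "results.tsv"),
    region_summary = file.path(config$out_dir, "region_summary.tsv"),
    flips = file.path(config$out_dir, "flips.tsv"),
    windows = file.path(config$out_dir, "windows.tsv")
  )
  data.table::fwrite(results, paths$results, sep = "\t", na = "NA",
                     quote = FALSE)
  data.table::fwrite(summary, paths$region_summary, sep = "\t", na = "NA",
                     quote = FALSE)
  data.table::fwrite(flips, paths$flips, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(windows, paths$windows, sep = "\t", na = "NA",
                     quote = FALSE)
  if (!is.null(filter_summary)) {
    paths$filter_summary <- file.path(config$out_dir, "filter_summary.tsv")
    data.table::fwrite(filter_summary, paths$filter_summary, sep = "\t",
                       na = "NA", quote = FALSE)
  }
  invisible(list(results = results, filter_summary = filter_summary,
                 windows = windows, region_summary = summary,
                 paths = paths))
}

#' Per-region significance summary
#'
#' Tallies, per region, the number of variants tested, the number and
#' percentage with p below `threshold`, and -- among the significant ones
#' only -- the percentage whose MAF is higher in females (sdMAF > 0).
#' Percentages are `NA` where no variant qualifies.
#'
#' @param results Results table from [run_pipeline()] (needs `REGION`,
#'   `NEG_LOG10_P`, `sdMAF`).
#' @param threshold Significance threshold on the p-value scale.
#' @return data.frame with one row per region.
#' @export
region_summary <- function(results, threshold = 5e-8) {
  dt <- data.table::as.data.table(results)
  if (!nrow(dt)) {
    return(data.frame(region = character(0), n = integer(0),
                      n_significant = integer(0), pct_significant = numeric(0),
                      pct_female_higher = numeric(0)))
  }
  crit <- -log10(threshold)
  out <- dt[, {
    sig <- NEG_LOG10_P > crit
    nsig <- sum(sig)
    list(
      n = .N,
      n_significant = nsig,
      pct_significant = 100 * nsig / .N,
      pct_female_higher = if (nsig) 100 * sum(sdMAF[sig] > 0) / nsig
                          else NA_real_
    )
  }, by = .(region = REGION)][order(region)]
  as.data.frame(out)
}
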