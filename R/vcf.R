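#' Read genotype calls for a chromosome-X VCF
#'
#' Thin wrapper around `VariantAnnotation::readVcf()` that keeps what the
#' sdMAF pipeline needs: site fields and the raw GT strings (which on the
#' X chromosome may be haploid `"1"`, diploid `"0/1"` or phased `"0|1"`,
#' and `"."`/`"./."` for missing). No record is dropped here; filtering is
#' the job of [filter_variants()].
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @return List with `sites` (data.frame: `chrom`, `pos`, `id`, `ref`,
#'   `alt` -- comma-joined for multiallelics -- and `n_alt`) and `gt`
#'   (character matrix, variants x samples).
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  alt_chr <- vapply(seq_along(alt),
                    function(i) paste(as.character(alt[[i]]), collapse = ","),
                    character(1))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  ids <- names(rr)
  if (is.null(ids)) ids <- rep(".", length(rr))
  list(
    sites = data.frame(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      id = ids,
      ref = as.character(rr$REF),
      alt = alt_chr,
      n_alt = n_alt,
      stringsAsFactors = FALSE
    ),
    gt = gt
  )
}

# split GT strings into allele-code vectors; "." and "./." are missing
.parse_gt <- function(gt) strsplit(gt, "[/|]", perl = FALSE)

#' Tally one biallelic site into sex-stratified counts
#'
#' In NPR/PAR3 the male layout is hemizygous: haploid male calls count
#' directly; diploid-homozygous male calls (phase-3-style `"1/1"`)
#' contribute one allele; heterozygous male calls are a data inconsistency
#' handled per `male_het_policy`. In PAR1/PAR2 males are tallied as
#' diploid. Missing calls (any `.` allele) increment the per-sex missing
#' counters.
#'
#' @param genotypes Named character vector of GT strings for one site
#'   (names are sample ids), or one row of the `gt` matrix from
#'   [read_vcf_genotypes()].
#' @param sex Sex map from [read_sex_map()] covering every sample.
#' @param region Region label; determines male layout via
#'   [region_male_layout()].
#' @param male_het_policy `"set_missing"` (default: count the male as
#'   missing, with a warning the first time) or `"error"`.
#' @param ref,alt Allele symbols recorded on the result.
#' @return An [ss_counts()] object whose designated allele A is `alt`.
#' @export
tally_variant <- function(genotypes, sex, region,
                          male_het_policy = c("set_missing", "error"),
                          ref = "REF", alt = "ALT") {
  male_het_policy <- match.arg(male_het_policy)
  layout <- region_male_layout(region)
  ids <- names(genotypes)
  if (is.null(ids)) stop("genotypes must be named by sample id", call. = FALSE)
  unknown <- setdiff(ids, names(sex))
  if (length(unknown)) {
    stop("samples absent from sex map: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  sx <- sex[ids]
  alleles <- .parse_gt(genotypes)
  ploidy <- lengths(alleles)
  dose <- vapply(alleles, function(a) {
    if (any(a == "." | a == "")) return(NA_real_)
    sum(a == "1")
  }, numeric(1))

  fsel <- sx == "female"
  f_dose <- dose[fsel]
  female <- c(sum(f_dose == 0, na.rm = TRUE),
              sum(f_dose == 1, na.rm = TRUE),
              sum(f_dose == 2, na.rm = TRUE))
  missing_female <- sum(is.na(f_dose))
  # haploid female calls would be malformed; treat as missing
  bad_f <- !is.na(f_dose) & ploidy[fsel] != 2
  if (any(bad_f)) {
    d <- f_dose[bad_f]
    female[1] <- female[1] - sum(d == 0); female[3] <- female[3] - sum(d == 1)
    missing_female <- missing_female + sum(bad_f)
  }

  m_dose <- dose[!fsel]
  m_ploidy <- ploidy[!fsel]
  missing_male <- sum(is.na(m_dose))
  if (layout == "hemizygous") {
    # heterozygous diploid male calls are impossible in NPR/PAR3
    het <- !is.na(m_dose) & m_ploidy == 2 & m_dose == 1
    if (any(het)) {
      if (male_het_policy == "error") {
        stop("heterozygous male call(s) at a hemizygous site: ",
             paste(head(ids[!fsel][het], 5), collapse = ", "), call. = FALSE)
      }
      warning(sum(het), " heterozygous male call(s) at a hemizygous site ",
              "set to missing", call. = FALSE)
      missing_male <- missing_male + sum(het)
      m_dose[het] <- NA
    }
    # haploid calls count directly; diploid homozygotes contribute 1 allele
    carrier <- !is.na(m_dose) & m_dose > 0
    male <- c(sum(!is.na(m_dose) & m_dose == 0), sum(carrier))
  } else {
    # PAR: males diploid; a haploid call cannot be tallied as two alleles
    bad_m <- !is.na(m_dose) & m_ploidy != 2
    if (any(bad_m)) {
      missing_male <- missing_male + sum(bad_m)
      m_dose[bad_m] <- NA
    }
    male <- c(sum(m_dose == 0, na.rm = TRUE),
              sum(m_dose == 1, na.rm = TRUE),
              sum(m_dose == 2, na.rm = TRUE))
  }
  ss_counts(female, male, layout,
            missing_female = missing_female, missing_male = missing_male,
            allele_a = ref, allele_A = alt)
}

#' Variant-selection pipeline for a set of raw VCF records
#'
#' Applies the standard high-quality biallelic-SNP selection: drop
#' multiallelic records (>1 ALT; not decomposed), drop indels (REF or ALT
#' longer than one nucleotide, or symbolic), then tally the rest and drop
#' variants whose sex-pooled global MAF is below `maf_threshold`
#' (inclusive comparison: MAF >= threshold is retained). Monomorphic
#' variants are counted separately from other low-MAF removals.
#'
#' @param vcf_data List from [read_vcf_genotypes()].
#' @param sex Sex map from [read_sex_map()].
#' @param region_map A [load_region_map()] result.
#' @param maf_threshold Global MAF retention threshold (default 0.05).
#' @param male_het_policy Passed to [tally_variant()].
#' @return List with `records` (list of `variant_record`: `chrom`, `pos`,
#'   `id`, `ref`, `alt`, `region`, `counts`, `maf`, `minor_allele`, `tie`)
#'   and `summary` (per-region data.frame of stage removals; removed +
#'   retained = input).
#' @export
filter_variants <- function(vcf_data, sex, region_map, maf_threshold = 0.05,
                            male_het_policy = "set_missing") {
  sites <- vcf_data$sites
  n <- nrow(sites)
  region <- assign_region(region_map, sites$pos)
  is_multi <- sites$n_alt > 1L
  is_indel <- !is_multi &
    (nchar(sites$ref) != 1L | nchar(sites$alt) != 1L |
       !grepl("^[ACGTacgt]$", sites$ref) |
       !(grepl("^[ACGTacgt]$", sites$alt) | sites$alt == ""))
  stage <- rep("retained", n)
  stage[is_indel] <- "indel"
  stage[is_multi] <- "multiallelic"

  records <- vector("list", n)
  for (i in seq_len(n)) {
    if (stage[i] != "retained") next
    counts <- tally_variant(vcf_data$gt[i, ], sex, region[i],
                            male_het_policy = male_het_policy,
                            ref = sites$ref[i], alt = sites$alt[i])
    gm <- compute_global_maf(counts)
    if (gm$monomorphic) {
      stage[i] <- "monomorphic"
      next
    }
    if (gm$maf < maf_threshold) {
      stage[i] <- "low_maf"
      next
    }
    records[[i]] <- structure(
      list(chrom = sites$chrom[i], pos = sites$pos[i], id = sites$id[i],
           ref = sites$ref[i], alt = sites$alt[i], region = region[i],
           counts = counts, maf = gm$maf, minor_allele = gm$minor_allele,
           tie = gm$tie),
      class = "variant_record"
    )
  }
  summary <- data.table::data.table(region = region, stage = stage)[
    , .(input = .N,
        multiallelic = sum(stage == "multiallelic"),
        indel = sum(stage == "indel"),
        low_maf = sum(stage == "low_maf"),
        monomorphic = sum(stage == "monomorphic"),
        retained = sum(stage == "retained")),
    by = region][order(region)]
  list(records = Filter(Negate(is.null), records),
       summary = as.data.frame(summary))
}
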