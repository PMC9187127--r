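#' Simulation configuration for synthetic sex-stratified genotypes
#'
#' Describes the generative world the sdMAF tests assume: independent
#' biallelic variants; per population, female genotypes drawn from the
#' HWD-parameterized trinomial
#' `((1-p_f)^2 + delta_f, 2 p_f (1-p_f) - 2 delta_f, p_f^2 + delta_f)`
#' (ordered aa/Aa/AA), males Bernoulli(`p_m`) when hemizygous or the
#' analogous trinomial with `delta_m` when diploid. Missingness and a
#' hemizygote-miscall error (a hemizygous male erroneously called as a
#' diploid heterozygote, emulating the mapping artefacts of low-coverage
#' X-chromosome data) are applied per sex.
#'
#' The default population panel mimics a 1000-Genomes-style cohort: five
#' super-populations of 500 individuals each with an equal sex ratio and
#' allele frequencies spread over 0.1-0.5, in Hardy-Weinberg equilibrium
#' and with no sex difference (a stratified null).
#'
#' @param populations data.frame with columns `label`, `n_female`,
#'   `n_male`, `p_f`, `p_m` and optionally `delta_f`, `delta_m`
#'   (defaulting to 0).
#' @param region Region label; controls the male layout.
#' @param missing_female,missing_male Per-individual missingness rates.
#' @param male_het_error Probability a called hemizygous male is miscalled
#'   as a heterozygote (hemizygous layouts only).
#' @param seed Integer seed; one seeded stream per run, with per-variant
#'   substreams derived deterministically so variant order does not change
#'   draws.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(populations = NULL, region = "NPR",
                       missing_female = 0, missing_male = 0,
                       male_het_error = 0, seed = 1L) {
  if (is.null(populations)) {
    populations <- data.frame(
      label = c("AFR", "AMR", "EAS", "EUR", "SAS"),
      n_female = 250L, n_male = 250L,
      p_f = c(0.1, 0.2, 0.3, 0.4, 0.5),
      p_m = c(0.1, 0.2, 0.3, 0.4, 0.5)
    )
  }
  pops <- as.data.frame(populations)
  need <- c("label", "n_female", "n_male", "p_f", "p_m")
  miss <- setdiff(need, names(pops))
  if (length(miss)) stop("populations missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"delta_f" %in% names(pops)) pops$delta_f <- 0
  if (!"delta_m" %in% names(pops)) pops$delta_m <- 0
  layout <- region_male_layout(region)
  if (any(pops$n_female < 0 | pops$n_male < 0)) {
    stop("sample sizes must be >= 0", call. = FALSE)
  }
  rates <- c(missing_female, missing_male, male_het_error)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]", call. = FALSE)
  for (i in seq_len(nrow(pops))) {
    .check_freq_delta(pops$p_f[i], pops$delta_f[i], "female",
                      pops$label[i])
    if (layout == "diploid") {
      .check_freq_delta(pops$p_m[i], pops$delta_m[i], "male", pops$label[i])
    } else if (pops$p_m[i] < 0 || pops$p_m[i] > 1) {
      stop("male frequency out of [0,1] in ", pops$label[i], call. = FALSE)
    }
  }
  structure(
    list(populations = pops, region = region, male_layout = layout,
         missing_female = missing_female, missing_male = missing_male,
         male_het_error = male_het_error, seed = as.integer(seed)),
    class = "sim_config"
  )
}

.check_freq_delta <- function(p, delta, sex, label) {
  if (p < 0 || p > 1) {
    stop(sex, " frequency out of [0,1] in ", label, call. = FALSE)
  }
  lo <- max(-p^2, -(1 - p)^2)
  hi <- p * (1 - p)
  if (delta < lo - 1e-12 || delta > hi + 1e-12) {
    stop("infeasible ", sex, " HWD delta ", delta, " in ", label,
         " (feasible range [", signif(lo, 6), ", ", signif(hi, 6), "])",
         call. = FALSE)
  }
}

.geno_probs <- function(p, delta) {
  pr <- c((1 - p)^2 + delta, 2 * p * (1 - p) - 2 * delta, p^2 + delta)
  pmax(pr, 0) / sum(pmax(pr, 0))  # guard tiny negative rounding
}

# deterministic per-variant substream seeds (variant order never matters)
.variant_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Draw sex-stratified genotype counts
#'
#' @param config A [sim_config()].
#' @param n_variants Number of independent variants to draw.
#' @return List of length `n_variants`; each element is a named list (one
#'   [ss_counts()] per population). Miscalled hemizygous males are moved to
#'   the missing counter (what a set-missing tally policy would produce)
#'   and their number is recorded in attribute `n_male_het_miscall`.
#' @export
simulate_counts <- function(config, n_variants) {
  stopifnot(inherits(config, "sim_config"), n_variants >= 1)
  vseeds <- .variant_seeds(config$seed, n_variants)
  pops <- config$populations
  hemi <- config$male_layout == "hemizygous"
  lapply(seq_len(n_variants), function(v) {
    set.seed(vseeds[v])
    out <- vector("list", nrow(pops))
    names(out) <- pops$label
    for (k in seq_len(nrow(pops))) {
      nf <- pops$n_female[k]; nm <- pops$n_male[k]
      miss_f <- rbinom(1, nf, config$missing_female)
      fg <- if (nf - miss_f > 0) {
        as.vector(rmultinom(1, nf - miss_f,
                            .geno_probs(pops$p_f[k], pops$delta_f[k])))
      } else c(0, 0, 0)
      miss_m <- rbinom(1, nm, config$missing_male)
      nm_called <- nm - miss_m
      n_miscall <- 0L
      if (hemi) {
        mA <- if (nm_called > 0) rbinom(1, nm_called, pops$p_m[k]) else 0L
        male <- c(nm_called - mA, mA)
        if (config$male_het_error > 0 && nm_called > 0) {
          mis <- c(rbinom(1, male[1], config$male_het_error),
                   rbinom(1, male[2], config$male_het_error))
          male <- male - mis
          n_miscall <- sum(mis)
          miss_m <- miss_m + n_miscall
        }
      } else {
        male <- if (nm_called > 0) {
          as.vector(rmultinom(1, nm_called,
                              .geno_probs(pops$p_m[k], pops$delta_m[k])))
        } else c(0, 0, 0)
      }
      x <- ss_counts(fg, male, config$male_layout,
                     missing_female = miss_f, missing_male = miss_m,
                     allele_a = "A", allele_A = "G")
      attr(x, "n_male_het_miscall") <- n_miscall
      out[[k]] <- x
    }
    out
  })
}

#' Pool counts across strata
#'
#' Sums genotype counts (and missing counters) over a list of compatible
#' [ss_counts()] objects, e.g. the populations of one simulated variant.
#'
#' @param counts_list List of `ss_counts` sharing a male layout.
#' @return One pooled `ss_counts`.
#' @export
pool_counts <- function(counts_list) {
  stopifnot(length(counts_list) >= 1)
  layouts <- vapply(counts_list, `[[`, character(1), "male_layout")
  if (length(unique(layouts)) != 1L) {
    stop("cannot pool mixed male layouts", call. = FALSE)
  }
  x <- counts_list[[1]]
  for (y in counts_list[-1]) {
    x$female <- x$female + y$female
    x$male <- x$male + y$male
    x$missing_female <- x$missing_female + y$missing_female
    x$missing_male <- x$missing_male + y$missing_male
  }
  attr(x, "n_male_het_miscall") <- NULL
  x
}

#' Apply a sex-differential error model to genotype calls
#'
#' Corrupts a vector/matrix of GT strings: each female call is set missing
#' with probability `missing_female`, each male call with
#' `missing_male`, and each surviving haploid male call is rewritten as a
#' diploid heterozygote (`"0/1"`) with probability `male_het_error`. With
#' all rates zero the input is returned unchanged.
#'
#' @param gt Character vector (one site) or matrix (sites x samples) of GT
#'   strings; columns/names are sample ids.
#' @param sex Sex map covering the samples.
#' @param missing_female,missing_male,male_het_error Rates in `[0, 1]`.
#' @param seed Optional seed for reproducibility.
#' @return Corrupted object of the same shape.
#' @export
apply_error_model <- function(gt, sex, missing_female = 0, missing_male = 0,
                              male_het_error = 0, seed = NULL) {
  rates <- c(missing_female, missing_male, male_het_error)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]", call. = FALSE)
  if (all(rates == 0)) return(gt)
  if (!is.null(seed)) set.seed(seed)
  mat <- is.matrix(gt)
  ids <- if (mat) colnames(gt) else names(gt)
  if (is.null(ids)) stop("gt must carry sample ids", call. = FALSE)
  sx <- sex[ids]
  corrupt <- function(calls) {
    f <- sx == "female"
    drop_f <- f & runif(length(calls)) < missing_female
    drop_m <- !f & runif(length(calls)) < missing_male
    calls[drop_f | drop_m] <- ifelse(grepl("[/|]", calls[drop_f | drop_m]),
                                     "./.", ".")
    hap <- !f & !grepl("[/|]", calls) & calls %in% c("0", "1")
    mis <- hap & runif(length(calls)) < male_het_error
    calls[mis] <- "0/1"
    calls
  }
  if (mat) t(apply(gt, 1, corrupt)) else corrupt(gt)
}

#' Write a synthetic VCF with matching sex map and truth table
#'
#' Expands counts drawn by [simulate_counts()] (same seed, hence identical
#' draws) into individual-level genotypes: NPR/PAR3 males are written
#' haploid (`0`/`1`), miscalled hemizygous males as `0/1`, missing calls as
#' `.` or `./.`. Tallying the written VCF with a set-missing male-het
#' policy therefore reproduces the drawn count matrices exactly.
#'
#' @param config A [sim_config()].
#' @param n_variants Number of variants.
#' @param positions Optional 1-based positions (sorted); defaults to evenly
#'   spaced positions inside the configured region of `build`'s map.
#' @param dir Output directory (created if needed).
#' @param build Genome build for the region map and contig length.
#' @return List with paths `vcf`, `sex_map`, `truth` and the `positions`
#'   used.
#' @export
simulate_vcf <- function(config, n_variants, positions = NULL,
                         dir = tempdir(), build = "GRCh37") {
  stopifnot(inherits(config, "sim_config"))
  map <- load_region_map(build)
  if (is.null(positions)) {
    if (config$region == "NPR") {
      lo <- 10e6; hi <- 80e6
    } else {
      iv <- map$intervals[map$intervals$label == config$region, ]
      lo <- iv$start; hi <- iv$end
    }
    positions <- floor(seq(lo, hi, length.out = n_variants + 2))[
      seq_len(n_variants) + 1L]
  }
  if (length(positions) != n_variants) {
    stop("need one position per variant", call. = FALSE)
  }
  reg <- assign_region(map, positions)
  if (any(reg != config$region)) {
    stop("position(s) fall outside the configured region ", config$region,
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  pops <- config$populations
  sample_ids <- unlist(lapply(seq_len(nrow(pops)), function(k) {
    c(sprintf("%s_F%04d", pops$label[k], seq_len(pops$n_female[k])),
      sprintf("%s_M%04d", pops$label[k], seq_len(pops$n_male[k])))
  }))
  sample_sex <- unlist(lapply(seq_len(nrow(pops)), function(k) {
    c(rep("F", pops$n_female[k]), rep("M", pops$n_male[k]))
  }))

  counts <- simulate_counts(config, n_variants)
  # independent substream for the genotype-to-individual shuffle
  sseeds <- .variant_seeds(config$seed + 1L, n_variants)
  hemi <- config$male_layout == "hemizygous"

  lines <- character(n_variants)
  truth <- vector("list", n_variants)
  for (v in seq_len(n_variants)) {
    set.seed(sseeds[v])
    gts <- character(0)
    for (k in seq_len(nrow(pops))) {
      x <- counts[[v]][[k]]
      fg <- c(rep("0/0", x$female[1]), rep("0/1", x$female[2]),
              rep("1/1", x$female[3]),
              rep("./.", pops$n_female[k] - sum(x$female)))
      n_mis <- attr(x, "n_male_het_miscall")
      if (hemi) {
        mg <- c(rep("0", x$male[1]), rep("1", x$male[2]),
                rep("0/1", n_mis),
                rep(".", pops$n_male[k] - sum(x$male) - n_mis))
      } else {
        mg <- c(rep("0/0", x$male[1]), rep("0/1", x$male[2]),
                rep("1/1", x$male[3]),
                rep("./.", pops$n_male[k] - sum(x$male)))
      }
      gts <- c(gts, sample(fg), sample(mg))
    }
    lines[v] <- paste(c("X", positions[v], sprintf("sim_%05d", v),
                        "A", "G", ".", "PASS", ".", "GT", gts),
                      collapse = "\t")
    truth[[v]] <- data.frame(
      id = sprintf("sim_%05d", v), pos = positions[v],
      region = config$region, population = pops$label,
      p_f = pops$p_f, delta_f = pops$delta_f,
      p_m = pops$p_m,
      delta_m = if (hemi) NA_real_ else pops$delta_m
    )
  }

  vcf_path <- file.path(dir, "synthetic.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=X,length=%d>", map$chr_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  writeLines(c(header, lines), vcf_path)

  sex_path <- file.path(dir, "sex_map.tsv")
  writeLines(paste(sample_ids, sample_sex, sep = "\t"), sex_path)

  truth_path <- file.path(dir, "truth.tsv")
  data.table::fwrite(data.table::rbindlist(truth), truth_path, sep = "\t",
                     na = "NA", quote = FALSE)

  list(vcf = vcf_path, sex_map = sex_path, truth = truth_path,
       positions = positions)
}

#' Empirical type-I error / power of the pooled-sample sdMAF test
#'
#' Repeatedly draws one variant under `config`, pools the population
#' counts, applies the region-appropriate sdMAF test, and reports the
#' rejection rate at `alpha`. Under a per-population null (`p_f == p_m`
#' everywhere) with unequal frequencies across populations, the pooled
#' female HWD coefficient picks up the Wahlund effect, the denominator of
#' the statistic grows, and the test is conservative; with one homogeneous
#' population the rate is nominal.
#'
#' @param config A [sim_config()]; each replicate uses one variant draw.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param alpha Significance level.
#' @return List with `reject_rate`, `mc_se` (binomial standard error at the
#'   nominal level), `alpha`, `n_reps`, `statistic_type`, and
#'   `mean_pooled_delta_f` (the Wahlund diagnostic).
#' @export
null_typeI_experiment <- function(config, n_reps, alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  draws <- simulate_counts(config, n_reps)
  crit <- -log10(alpha)
  nlp <- numeric(n_reps)
  deltas <- numeric(n_reps)
  stat_type <- if (config$male_layout == "hemizygous") "T_X" else "T_A"
  for (i in seq_len(n_reps)) {
    pooled <- pool_counts(draws[[i]])
    r <- sdmaf_test(pooled)
    nlp[i] <- r$neg_log10_p
    deltas[i] <- r$delta_f
  }
  rate <- mean(nlp > crit)
  list(
    reject_rate = rate,
    mc_se = sqrt(alpha * (1 - alpha) / n_reps),
    alpha = alpha, n_reps = n_reps,
    statistic_type = stat_type,
    mean_pooled_delta_f = mean(deltas)
  )
}
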