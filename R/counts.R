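#' Sex-stratified genotype counts for one biallelic variant
#'
#' The central container of the package. Counts are expressed with respect
#' to a designated allele `A` (by convention the pooled-sample minor allele;
#' see [compute_global_maf()] and [swap_alleles()]): `female = c(f0, f1, f2)`
#' are the numbers of females carrying 0, 1 and 2 copies of `A`. Male layout
#' depends on the region: in NPR/PAR3 males are hemizygous and `male =
#' c(m0, m2)` counts reference-carriers and A-carriers (no heterozygote
#' slot); in PAR1/PAR2 males are diploid and `male = c(m0, m1, m2)`.
#'
#' @param female Integer vector `c(f0, f1, f2)`.
#' @param male Integer vector, length 2 (hemizygous) or 3 (diploid),
#'   consistent with `male_layout`.
#' @param male_layout `"hemizygous"` or `"diploid"`.
#' @param missing_female,missing_male Counts of individuals excluded for
#'   missing (or policy-excluded) genotypes. `NA` when unknown, e.g. counts
#'   read from an aggregated table without totals.
#' @param allele_a,allele_A Symbols for the reference-side allele and the
#'   designated allele of interest.
#' @return An object of class `ss_counts`.
#' @examples
#' # a toy NPR variant: females in HWE at p = 0.2,
#' # males at p = 0.5
#' x <- ss_counts(c(640, 320, 40), c(500, 500), "hemizygous")
#' estimate_freqs(x)
#' @export
ss_counts <- function(female, male,
                      male_layout = c("hemizygous", "diploid"),
                      missing_female = 0L, missing_male = 0L,
                      allele_a = "a", allele_A = "A") {
  male_layout <- match.arg(male_layout)
  female <- as.numeric(female); male <- as.numeric(male)
  if (length(female) != 3L) stop("female must be c(f0, f1, f2)", call. = FALSE)
  want <- if (male_layout == "hemizygous") 2L else 3L
  if (length(male) != want) {
    stop("male counts must have length ", want, " for ", male_layout,
         " layout", call. = FALSE)
  }
  cnts <- c(female, male)
  if (anyNA(cnts) || any(cnts < 0) || any(cnts != round(cnts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  if ((is.finite(missing_female) && missing_female < 0) ||
      (is.finite(missing_male) && missing_male < 0)) {
    stop("missing counts must be non-negative", call. = FALSE)
  }
  structure(
    list(female = female, male = male, male_layout = male_layout,
         missing_female = missing_female, missing_male = missing_male,
         allele_a = allele_a, allele_A = allele_A),
    class = "ss_counts"
  )
}

#' @export
print.ss_counts <- function(x, ...) {
  cat("sex-stratified counts (male layout: ", x$male_layout, ")\n", sep = "")
  cat("  female (", x$allele_a, x$allele_a, ", ", x$allele_a, x$allele_A,
      ", ", x$allele_A, x$allele_A, "): ",
      paste(x$female, collapse = "/"), "\n", sep = "")
  cat("  male: ", paste(x$male, collapse = "/"), "\n", sep = "")
  invisible(x)
}

n_female <- function(x) sum(x$female)
n_male <- function(x) sum(x$male)

#' Allele counts of the designated allele, pooled over sexes
#'
#' Males contribute one allele each under the hemizygous layout and two
#' under the diploid layout; females always contribute two.
#'
#' @param x An [ss_counts()] object.
#' @return Named numeric vector with elements `A` (designated-allele count)
#'   and `total` (total allele count).
#' @export
allele_counts <- function(x) {
  stopifnot(inherits(x, "ss_counts"))
  fA <- 2 * x$female[3] + x$female[2]
  if (x$male_layout == "hemizygous") {
    mA <- x$male[2]; mt <- n_male(x)
  } else {
    mA <- 2 * x$male[3] + x$male[2]; mt <- 2 * n_male(x)
  }
  c(A = fA + mA, total = 2 * n_female(x) + mt)
}

#' Sex-pooled minor allele frequency
#'
#' Pools allele counts over both sexes with the region-appropriate male
#' ploidy and returns the frequency of the less frequent allele. A pooled
#' frequency of exactly 0.5 is a tie; by convention the designated
#' (ALT-side) allele is then reported as minor with `tie = TRUE`.
#'
#' @param x An [ss_counts()] object (male layout already encodes the region).
#' @return List with `maf`, `minor_allele` (symbol), `freq_A` (frequency of
#'   the designated allele), `tie`, and `monomorphic`.
#' @export
compute_global_maf <- function(x) {
  ac <- allele_counts(x)
  if (ac[["total"]] == 0) stop("zero total allele count", call. = FALSE)
  fA <- ac[["A"]] / ac[["total"]]
  tie <- fA == 0.5
  minor <- if (fA <= 0.5) x$allele_A else x$allele_a
  list(
    maf = min(fA, 1 - fA),
    minor_allele = minor,
    freq_A = fA,
    tie = tie,
    monomorphic = fA %in% c(0, 1)
  )
}

#' Swap the allele labelling of a counts object
#'
#' Reverses which allele is designated `A`, reversing the genotype count
#' order within each sex. Statistics are antisymmetric (sdMAF changes sign)
#' or invariant (test statistics, p-values) under this operation.
#'
#' @param x An [ss_counts()] object.
#' @return The relabelled `ss_counts`.
#' @export
swap_alleles <- function(x) {
  stopifnot(inherits(x, "ss_counts"))
  x$female <- rev(x$female)
  x$male <- rev(x$male)
  tmp <- x$allele_a; x$allele_a <- x$allele_A; x$allele_A <- tmp
  x
}

#' Per-sex genotype call rate
#'
#' @param x An [ss_counts()] object with missing counters populated.
#' @param sex `"female"` or `"male"`.
#' @return Percentage of individuals with a non-missing genotype,
#'   `100 * called / (called + missing)`.
#' @export
call_rate <- function(x, sex = c("female", "male")) {
  sex <- match.arg(sex)
  called <- if (sex == "female") n_female(x) else n_male(x)
  miss <- if (sex == "female") x$missing_female else x$missing_male
  if (is.na(miss)) stop("missing-genotype counter not populated", call. = FALSE)
  tot <- called + miss
  if (tot == 0) stop("no individuals of sex ", sex, call. = FALSE)
  if (called == 0) stop("all genotypes missing for sex ", sex, call. = FALSE)
  100 * called / tot
}
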