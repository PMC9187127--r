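#' sdMAF Wald tests
#'
#' Tests whether the frequency of the designated allele differs between
#' females and males, allowing for Hardy-Weinberg disequilibrium within
#' each diploid sex. The statistic is a two-sample Wald chi-square with
#' 1 df:
#'
#' * NPR/PAR3 (hemizygous males):
#'   `T = (p_f - p_m)^2 / [ (p_f(1-p_f) + delta_f)/(2f) + p_m(1-p_m)/m ]`
#' * PAR1/PAR2 (diploid males):
#'   `T = (p_f - p_m)^2 / [ (p_f(1-p_f) + delta_f)/(2f) +
#'                          (p_m(1-p_m) + delta_m)/(2m) ]`
#'
#' With both deltas zero the PAR form reduces to the classical two-sample
#' proportion Wald chi-square. When the variance is exactly zero (genotype
#' fixed within each sex, e.g. one allele only in females and the other
#' only in males) but the frequencies differ, the statistic is reported as
#' `Inf` with `degenerate = TRUE` rather than substituting a constant.
#'
#' `sdmaf_test()` dispatches on the male layout of the counts object;
#' `sdmaf_test_npr()` / `sdmaf_test_par()` insist on a specific layout.
#'
#' @param x An [ss_counts()] object whose designated allele A is the
#'   pooled-sample minor allele (see [compute_global_maf()] /
#'   [swap_alleles()]).
#' @return Object of class `sdmaf_result`: `sdmaf` (female minus male
#'   frequency of allele A), `statistic`, `neg_log10_p`, `p_f`, `p_m`,
#'   `minor_allele_f`, `minor_allele_m`, `flip`, `tie`, `degenerate`, and
#'   `statistic_type` (`"T_X"` or `"T_A"`).
#' @examples
#' x <- ss_counts(c(640, 320, 40), c(500, 500), "hemizygous")
#' r <- sdmaf_test(x)
#' r$statistic      # ~272.73
#' r$neg_log10_p    # ~60.5 (p ~ 2.9e-61)
#' @export
sdmaf_test <- function(x) {
  stopifnot(inherits(x, "ss_counts"))
  if (x$male_layout == "hemizygous") sdmaf_test_npr(x) else sdmaf_test_par(x)
}

#' @rdname sdmaf_test
#' @export
sdmaf_test_npr <- function(x) {
  stopifnot(inherits(x, "ss_counts"))
  if (x$male_layout != "hemizygous") {
    stop("sdmaf_test_npr requires hemizygous male layout", call. = FALSE)
  }
  .sdmaf_result(x, statistic_type = "T_X")
}

#' @rdname sdmaf_test
#' @export
sdmaf_test_par <- function(x) {
  stopifnot(inherits(x, "ss_counts"))
  if (x$male_layout != "diploid") {
    stop("sdmaf_test_par requires diploid male layout", call. = FALSE)
  }
  .sdmaf_result(x, statistic_type = "T_A")
}

.sdmaf_result <- function(x, statistic_type) {
  fe <- estimate_freqs(x)
  num <- (fe$p_f - fe$p_m)^2
  den <- fe$var_f + fe$var_m
  degenerate <- FALSE
  if (den == 0) {
    if (num == 0) {
      statistic <- 0
    } else {
      statistic <- Inf
      degenerate <- TRUE
    }
  } else {
    statistic <- num / den
  }
  flip <- detect_minor_flip(x)
  structure(
    list(
      sdmaf = fe$p_f - fe$p_m,
      statistic = statistic,
      neg_log10_p = chisq1_neg_log10_sf(statistic),
      p_f = fe$p_f, p_m = fe$p_m,
      delta_f = fe$delta_f, delta_m = fe$delta_m,
      minor_allele_f = flip$minor_allele_f,
      minor_allele_m = flip$minor_allele_m,
      flip = flip$flip, tie = flip$tie,
      degenerate = degenerate,
      statistic_type = statistic_type
    ),
    class = "sdmaf_result"
  )
}

#' @export
print.sdmaf_result <- function(x, ...) {
  cat(sprintf("sdMAF test (%s): sdMAF = %.4f, statistic = %.3f, p = %s\n",
              x$statistic_type, x$sdmaf, x$statistic,
              format_pvalue(x$neg_log10_p)))
  if (x$degenerate) cat("  [degenerate: zero variance, infinite statistic]\n")
  invisible(x)
}
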