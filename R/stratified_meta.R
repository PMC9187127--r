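#' Detect a minor-allele flip between the sexes
#'
#' A flip occurs when the within-female minor allele differs from the
#' within-male minor allele at the same variant (equivalently, the
#' frequencies of the same allele fall on opposite sides of 0.5). A
#' within-sex frequency of exactly 0.5 is a tie, reported as such and never
#' counted as a flip.
#'
#' @param x An [ss_counts()] object.
#' @return List with `flip`, `tie`, `minor_allele_f`, `minor_allele_m`,
#'   `p_f`, `p_m` (frequencies of the designated allele A).
#' @export
detect_minor_flip <- function(x) {
  stopifnot(inherits(x, "ss_counts"))
  fe <- estimate_freqs(x)
  minor_of <- function(p) {
    if (p < 0.5) x$allele_A else if (p > 0.5) x$allele_a else NA_character_
  }
  mf <- minor_of(fe$p_f); mm <- minor_of(fe$p_m)
  tie <- is.na(mf) || is.na(mm)
  list(
    flip = !tie && mf != mm,
    tie = tie,
    minor_allele_f = mf, minor_allele_m = mm,
    p_f = fe$p_f, p_m = fe$p_m
  )
}

#' Population-stratified sdMAF analysis
#'
#' Runs the region-appropriate sdMAF test separately in each stratum
#' (population or super-population). The designated minor allele must be
#' fixed from the pooled sample *before* stratifying, so every stratum
#' tests the same allele; a stratified MAF may then legitimately exceed
#' 0.5. Strata monomorphic in both sexes carry no information about a sex
#' difference and are flagged non-polymorphic rather than tested; a
#' stratum whose allele is fixed differently in the two sexes yields an
#' infinite statistic (zero variance), flagged `degenerate`.
#'
#' @param counts_by_stratum Named list of [ss_counts()] objects sharing the
#'   same allele designation and male layout.
#' @return List of `stratum_result` objects: `stratum`, `polymorphic`,
#'   `n_alleles` (allele-count sample size: 2f + m hemizygous, 2f + 2m
#'   diploid), and `result` (an `sdmaf_result`, or `NULL` if not tested).
#' @export
stratified_sdmaf <- function(counts_by_stratum) {
  if (is.null(names(counts_by_stratum)) ||
      any(names(counts_by_stratum) == "")) {
    stop("strata must be named", call. = FALSE)
  }
  lapply(names(counts_by_stratum), function(lab) {
    x <- counts_by_stratum[[lab]]
    stopifnot(inherits(x, "ss_counts"))
    ac <- allele_counts(x)
    poly <- ac[["total"]] > 0 && ac[["A"]] > 0 && ac[["A"]] < ac[["total"]]
    res <- if (poly && n_female(x) >= 1 && n_male(x) >= 1) sdmaf_test(x)
           else NULL
    structure(
      list(stratum = lab, polymorphic = poly,
           n_alleles = unname(ac[["total"]]), result = res),
      class = "stratum_result"
    )
  })
}

#' Sample-size-weighted Z-score meta-analysis of sdMAF
#'
#' Combines per-stratum signed Z-scores `Z_i = sign(sdMAF_i) * sqrt(T_i)`
#' with weights `w_i = sqrt(n_i)`:
#' `Z = sum(w_i Z_i) / sqrt(sum(w_i^2))`, with a two-sided normal p-value.
#' Only strata polymorphic (and tested) in the input are eligible; by
#' default `n_i` is the allele-count contribution recorded by
#' [stratified_sdmaf()], switchable to individual counts via `n_i`.
#' Degenerate (infinite-statistic) strata are flagged and excluded from
#' the weighted sum with a warning rather than forcing the combined
#' p-value to zero.
#'
#' @param strata List of `stratum_result` objects from
#'   [stratified_sdmaf()].
#' @param n_i Optional numeric vector of custom per-stratum sample sizes
#'   (same order as `strata`); defaults to each stratum's allele count.
#' @return Object of class `meta_result`: `z`, `neg_log10_p`, `included`
#'   (stratum labels), `excluded_degenerate`, `sign_heterogeneity` (TRUE if
#'   included strata disagree in sdMAF sign), `empty`.
#' @export
meta_sdmaf <- function(strata, n_i = NULL) {
  labs <- vapply(strata, `[[`, character(1), "stratum")
  if (is.null(n_i)) {
    n_i <- vapply(strata, `[[`, numeric(1), "n_alleles")
  }
  tested <- vapply(strata, function(s) !is.null(s$result), logical(1))
  degen <- tested & vapply(strata, function(s) {
    !is.null(s$result) && s$result$degenerate
  }, logical(1))
  if (any(degen)) {
    warning("excluding ", sum(degen),
            " degenerate (infinite-statistic) stratum/strata from the ",
            "meta-analysis: ", paste(labs[degen], collapse = ", "),
            call. = FALSE)
  }
  use <- tested & !degen
  if (!any(use)) {
    return(structure(
      list(z = NA_real_, neg_log10_p = NA_real_, included = character(0),
           excluded_degenerate = labs[degen], sign_heterogeneity = NA,
           empty = TRUE),
      class = "meta_result"
    ))
  }
  zi <- vapply(strata[use], function(s) {
    sign(s$result$sdmaf) * sqrt(s$result$statistic)
  }, numeric(1))
  wi <- sqrt(n_i[use])
  z <- sum(wi * zi) / sqrt(sum(wi^2))
  signs <- sign(vapply(strata[use], function(s) s$result$sdmaf, numeric(1)))
  structure(
    list(z = z, neg_log10_p = znorm_neg_log10_two_sided(z),
         included = labs[use], excluded_degenerate = labs[degen],
         sign_heterogeneity = length(unique(signs[signs != 0])) > 1,
         empty = FALSE),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  if (x$empty) {
    cat("meta-analysis: no eligible strata\n")
  } else {
    cat(sprintf("meta-analysis Z = %.3f, p = %s (%d strata)\n",
                x$z, format_pvalue(x$neg_log10_p), length(x$included)))
  }
  invisible(x)
}
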