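#' Hardy-Weinberg chi-square tests
#'
#' One-df Pearson chi-square test for HWD within a diploid stratum, in the
#' HWD-coefficient form `T = delta^2 / [ (1/n) p^2 (1-p)^2 ]`. The
#' algebraically identical expected-count form
#' `sum over genotype classes of (obs - exp)^2 / exp`, with HWE expected
#' counts `n(1-p)^2, 2np(1-p), np^2`, is available via `form = "expected"`
#' (both are implemented independently; equality is a package invariant).
#'
#' Scopes: `"female"` uses the female triple; `"male"` requires a diploid
#' male layout (PAR1/PAR2); `"sex_combined"` pools the two diploid triples
#' and uses the pooled frequency and pooled HWD coefficient. HWD testing is
#' only meaningful within a homogeneous stratum: pooling strata with
#' unequal allele frequencies inflates delta (the Wahlund effect), which is
#' why female-only testing is used in NPR/PAR3.
#'
#' A monomorphic stratum has no df for the test: `statistic` and
#' `neg_log10_p` are returned as `NA` (matching the convention of reporting
#' an HWE p-value of NA).
#'
#' @param x An [ss_counts()] object.
#' @param scope `"female"`, `"male"` or `"sex_combined"`.
#' @param form `"delta"` (default) or `"expected"`; numerically identical.
#' @return Object of class `hwe_result` with `scope`, `delta`, `statistic`,
#'   `neg_log10_p`, `method = "chisq"`, `n`, and (for `sex_combined`)
#'   `p_hat`, `n1` (females), `n2` (males).
#' @export
hwe_chisq <- function(x, scope = c("female", "male", "sex_combined"),
                      form = c("delta", "expected")) {
  stopifnot(inherits(x, "ss_counts"))
  scope <- match.arg(scope)
  form <- match.arg(form)
  if (scope != "female" && x$male_layout != "diploid") {
    stop("scope '", scope, "' requires diploid male layout (PAR1/PAR2)",
         call. = FALSE)
  }
  triple <- switch(scope,
    female = x$female,
    male = x$male,
    sex_combined = x$female + x$male
  )
  n <- sum(triple)
  if (n == 0) stop("empty stratum for HWE test", call. = FALSE)
  p <- (2 * triple[3] + triple[2]) / (2 * n)
  delta <- hwd_delta(triple)
  if (p %in% c(0, 1)) {
    statistic <- NA_real_
    nlp <- NA_real_
  } else {
    statistic <- if (form == "delta") {
      delta^2 / ((1 / n) * p^2 * (1 - p)^2)
    } else {
      expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
      sum((triple - expected)^2 / expected)
    }
    nlp <- chisq1_neg_log10_sf(statistic)
  }
  res <- list(scope = scope, delta = delta, statistic = statistic,
              neg_log10_p = nlp, method = "chisq", n = n)
  if (scope == "sex_combined") {
    res$p_hat <- p
    res$n1 <- n_female(x)
    res$n2 <- n_male(x)
  }
  structure(res, class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE test [%s, %s]: delta = %s, p = %s\n",
              x$scope, x$method,
              if (is.na(x$delta)) "NA" else sprintf("%.4f", x$delta),
              format_pvalue(x$neg_log10_p)))
  invisible(x)
}

# log P(het = n1 | allele count nA, n diploids) under HWE, Levene-Haldane:
#   P = n! nA! nB! 2^n1 / (n0! n1! n2! (2n)!)
.levene_log_prob <- function(n, nA, n1) {
  n2 <- (nA - n1) / 2
  n0 <- n - n1 - n2
  nB <- 2 * n - nA
  lgamma(n + 1) - lgamma(n0 + 1) - lgamma(n1 + 1) - lgamma(n2 + 1) +
    n1 * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
}

# relative slack when comparing outcome probabilities to the observed one,
# the standard convention of exact-HWE implementations
.exact_tie_slack <- 1e-7

#' Exact Hardy-Weinberg test within one diploid stratum
#'
#' Levene-Haldane conditional exact test: conditional on the minor-allele
#' count, heterozygote counts of matching parity are enumerated, and the
#' two-sided p-value is the sum of the probabilities of all outcomes no
#' more probable than the observed one. Combinatorics are evaluated in log
#' space, so large strata (tens of thousands of individuals) are handled
#' without overflow.
#'
#' @param triple Genotype counts `c(n0, n1, n2)`.
#' @return Object of class `hwe_result` (`method = "exact_within_sex"`,
#'   `statistic = NA`; p in `(0, 1]`, 1 for a monomorphic triple).
#' @export
hwe_exact_within_sex <- function(triple) {
  if (length(triple) != 3L || anyNA(triple) || any(triple < 0)) {
    stop("need a non-negative genotype triple", call. = FALSE)
  }
  n <- sum(triple)
  if (n == 0) stop("empty genotype triple", call. = FALSE)
  nA <- 2 * triple[3] + triple[2]
  if (nA == 0 || nA == 2 * n) {
    p <- 1
  } else {
    hets <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
    lp <- .levene_log_prob(n, nA, hets)
    lobs <- .levene_log_prob(n, nA, triple[2])
    p <- min(1, sum(exp(lp[lp <= lobs + .exact_tie_slack])))
  }
  structure(
    list(scope = "within_stratum", delta = hwd_delta(triple),
         statistic = NA_real_, neg_log10_p = -log10(p), p = p,
         method = "exact_within_sex", n = n),
    class = "hwe_result"
  )
}

#' Joint exact Hardy-Weinberg test for an X-linked variant
#'
#' Extends the conditional exact test to a variant where males are
#' hemizygous: conditional on the total designated-allele count nA among
#' the N = 2f + m alleles, the male A-carrier count mA and the female
#' heterozygote count f1 are jointly enumerated with probability
#'
#' `P(mA, f1) = C(m, mA) * f! 2^f1 / (f0! f1! f2!) * nA! nB! / N!`
#'
#' (males contribute single alleles, females diploid genotypes; under the
#' null both sexes share the allele frequency and females are in HWE). The
#' two-sided p-value sums all configurations no more probable than the
#' observed one. Note this null is *joint*: a variant with a strong sex
#' difference in allele frequency but HWE females is rejected, so this test
#' confounds HWD with sdMAF; the within-sex tests do not.
#'
#' @param female Genotype triple `c(f0, f1, f2)`.
#' @param male Hemizygous pair `c(m0, m2)` of ref- and A-carriers. `c(0,0)`
#'   reduces the test to [hwe_exact_within_sex()] on the female triple.
#' @return Object of class `hwe_result` (`method = "exact_x_joint"`,
#'   `scope = "sex_combined"`).
#' @examples
#' # strong sdMAF with HWE females: rejected by the joint test
#' hwe_exact_x_joint(c(640, 320, 40), c(500, 500))  # p ~ 6.4e-61
#' @export
hwe_exact_x_joint <- function(female, male) {
  if (length(female) != 3L || length(male) != 2L ||
      anyNA(c(female, male)) || any(c(female, male) < 0)) {
    stop("need female triple c(f0,f1,f2) and male pair c(m0,m2)",
         call. = FALSE)
  }
  f <- sum(female); m <- sum(male)
  if (f == 0 && m == 0) stop("no individuals", call. = FALSE)
  if (m == 0) {
    res <- hwe_exact_within_sex(female)
    res$scope <- "sex_combined"
    res$method <- "exact_x_joint"
    return(res)
  }
  nA <- 2 * female[3] + female[2] + male[2]
  N <- 2 * f + m
  if (N == 0 || nA < 0) stop("degenerate zero-allele input", call. = FALSE)
  nB <- N - nA
  if (nA == 0 || nB == 0) {
    p <- 1
  } else {
    ldenom <- lgamma(N + 1) - lgamma(nA + 1) - lgamma(nB + 1)
    logp_config <- function(mA, f1) {
      fA <- nA - mA
      f2 <- (fA - f1) / 2
      f0 <- f - f1 - f2
      lchoose(m, mA) +
        lgamma(f + 1) - lgamma(f0 + 1) - lgamma(f1 + 1) - lgamma(f2 + 1) +
        f1 * log(2) - ldenom
    }
    lobs <- logp_config(male[2], female[2])
    p <- 0
    for (mA in max(0, nA - 2 * f):min(m, nA)) {
      fA <- nA - mA
      f1max <- min(fA, 2 * f - fA)
      if (f1max < 0) next
      f1s <- seq.int(fA %% 2, f1max, by = 2)
      lp <- logp_config(mA, f1s)
      p <- p + sum(exp(lp[lp <= lobs + .exact_tie_slack]))
    }
    p <- min(1, p)
  }
  structure(
    list(scope = "sex_combined", delta = if (f > 0) hwd_delta(female) else NA_real_,
         statistic = NA_real_, neg_log10_p = -log10(p), p = p,
         method = "exact_x_joint", n = f + m, n1 = f, n2 = m),
    class = "hwe_result"
  )
}
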