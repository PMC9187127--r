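#' Sex-specific allele frequency and HWD estimates
#'
#' For females (always diploid) the frequency of the designated allele A is
#' p_f = (2 f2 + f1) / (2f) with variance (p_f (1 - p_f) + delta_f) / (2f),
#' where delta_f = f2/f - p_f^2 is the Hardy-Weinberg disequilibrium
#' coefficient: the excess of observed AA homozygote frequency over its
#' HWE expectation. Hemizygous males have p_m = m2 / m with binomial
#' variance p_m (1 - p_m) / m and no HWD coefficient (one allele each);
#' diploid males mirror the female formulas.
#'
#' @param x An [ss_counts()] object with at least one individual per sex.
#' @return List of class `freq_estimate` with `p_f`, `p_m`, `var_f`,
#'   `var_m`, `delta_f`, `delta_m` (`NA` for hemizygous males), and
#'   `male_layout`.
#' @export
estimate_freqs <- function(x) {
  stopifnot(inherits(x, "ss_counts"))
  f <- n_female(x); m <- n_male(x)
  if (f < 1 || m < 1) stop("empty sex stratum", call. = FALSE)
  p_f <- (2 * x$female[3] + x$female[2]) / (2 * f)
  delta_f <- x$female[3] / f - p_f^2
  var_f <- (p_f * (1 - p_f) + delta_f) / (2 * f)
  if (x$male_layout == "hemizygous") {
    p_m <- x$male[2] / m
    delta_m <- NA_real_
    var_m <- p_m * (1 - p_m) / m
  } else {
    p_m <- (2 * x$male[3] + x$male[2]) / (2 * m)
    delta_m <- x$male[3] / m - p_m^2
    var_m <- (p_m * (1 - p_m) + delta_m) / (2 * m)
  }
  structure(
    list(p_f = p_f, p_m = p_m, var_f = var_f, var_m = var_m,
         delta_f = delta_f, delta_m = delta_m, male_layout = x$male_layout),
    class = "freq_estimate"
  )
}

#' Hardy-Weinberg disequilibrium coefficient of a genotype triple
#'
#' delta = n2/n - ((2 n2 + n1) / (2n))^2, i.e. observed AA frequency minus
#' squared allele-A frequency. Always lies in
#' [max(-p^2, -(1-p)^2), p(1-p)].
#'
#' @param triple Genotype counts `c(n0, n1, n2)` for 0/1/2 copies of A.
#' @return The HWD coefficient (a single number).
#' @examples
#' hwd_delta(c(640, 320, 40))   # 0: exact HWE proportions at p = 0.2
#' hwd_delta(c(0, 100, 0))      # -0.25: all heterozygotes
#' @export
hwd_delta <- function(triple) {
  if (length(triple) != 3L || anyNA(triple) || any(triple < 0)) {
    stop("need a non-negative genotype triple c(n0, n1, n2)", call. = FALSE)
  }
  n <- sum(triple)
  if (n == 0) stop("empty genotype triple", call. = FALSE)
  p <- (2 * triple[3] + triple[2]) / (2 * n)
  unname(triple[3] / n - p^2)
}
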