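#' Log-space p-values for extreme test statistics
#'
#' Genome-scale sdMAF scans routinely produce chi-square statistics in the
#' thousands, whose survival probabilities underflow double precision
#' (p < 1e-308). All p-values in this package are therefore carried as
#' -log10(p), computed directly from the log survival function, so values
#' of several thousand on the -log10 scale remain exact to representation.
#'
#' @param statistic Non-negative 1-df chi-square statistic; `Inf` (the
#'   zero-variance sentinel) propagates to `Inf`.
#' @return -log10 of the upper-tail probability.
#' @examples
#' chisq1_neg_log10_sf(3.841459)  # ~1.30103, i.e. p = 0.05
#' chisq1_neg_log10_sf(1600)      # ~349.1, far below double-precision p
#' @export
chisq1_neg_log10_sf <- function(statistic) {
  if (any(is.na(statistic)) || any(statistic < 0)) {
    stop("chi-square statistic must be >= 0", call. = FALSE)
  }
  out <- -pchisq(statistic, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  out[is.infinite(statistic)] <- Inf
  out
}

# two-sided standard-normal tail on the -log10 scale
znorm_neg_log10_two_sided <- function(z) {
  if (any(is.na(z))) stop("Z must be finite or Inf", call. = FALSE)
  out <- -(pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
  out[is.infinite(z)] <- Inf
  # |Z| ~ 0 can give tiny negative zero from the log(2) shift; clamp
  pmax(out, 0)
}

#' Render a -log10 p-value the way scan tables print it
#'
#' Values below 1e-300 are floored to the string `"<1E-300"` (the numeric
#' -log10 value should be kept in a separate column); infinite sentinels
#' print as `"0"` p-value with the flag left to the caller.
#'
#' @param neg_log10_p Numeric vector of -log10 p-values.
#' @param floor_exponent Flooring threshold on the -log10 scale.
#' @return Character vector of formatted p-values.
#' @export
format_pvalue <- function(neg_log10_p, floor_exponent = 300) {
  out <- character(length(neg_log10_p))
  out[is.na(neg_log10_p)] <- "NA"
  ok <- !is.na(neg_log10_p)
  big <- ok & neg_log10_p > floor_exponent
  out[big] <- sprintf("<1E-%d", floor_exponent)
  rest <- ok & !big
  out[rest] <- sprintf("%.3G", 10^(-neg_log10_p[rest]))
  out
}
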