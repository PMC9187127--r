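#' Bland-Altman summary of sdMAF against sex-combined MAF
#'
#' For each variant, plots-ready coordinates: x = sex-combined MAF of the
#' pooled minor allele, y = female-minus-male frequency difference of that
#' allele. Points are grouped by region and carry the minor-allele-flip
#' flag; for the flipped subset, theoretical bound curves constrain |y| as
#' a function of x (see [flip_bounds()]).
#'
#' @param results data.frame-like with columns `maf` (sex-combined MAF),
#'   `sdmaf`, `region`, `flip` (and optionally `id`, `pos`).
#' @param female_allele_weight Fraction of pooled alleles contributed by
#'   females, used for the attached bound curves; 0.5 corresponds to equal
#'   allele contributions.
#' @return data.table of points (`x`, `y`, `region`, `flip`, plus any id
#'   columns) with `lower_bound`/`upper_bound` columns giving the flipped-
#'   subset constraint on |y| at each point's x.
#' @export
bland_altman <- function(results, female_allele_weight = 0.5) {
  dt <- data.table::as.data.table(results)
  need <- c("maf", "sdmaf", "region", "flip")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  b <- flip_bounds(dt$maf, female_allele_weight)
  out <- data.table::data.table(dt)
  data.table::setnames(out, c("maf", "sdmaf"), c("x", "y"))
  out$lower_bound <- b$lower
  out$upper_bound <- b$upper
  out[]
}

#' Theoretical |sdMAF| bounds for minor-allele-flipped variants
#'
#' Let w be the fraction of pooled alleles from females and write the
#' pooled frequency of an allele as x = w p_f + (1-w) p_m, so that
#' p_f = x + (1-w) y and p_m = x - w y with y = p_f - p_m. A flip (the
#' within-sex minor alleles differ) means p_f and p_m straddle 0.5. For the
#' allele with pooled frequency x <= 0.5 and p_f > 0.5 > p_m this forces
#'
#' * lower: y > (0.5 - x) / (1 - w)  (from p_f > 0.5)
#' * upper: y <= min( (1 - x)/(1 - w), x/w )  (from p_f <= 1, p_m >= 0)
#'
#' and the mirror-image band for negative y. At w = 0.5 this is the
#' familiar 1 - 2x < |y| <= 2x. Flipped variants are therefore only
#' possible for x > 0.25 (at w = 0.5) and always have |sdMAF| larger than
#' non-flipped variants at the same combined MAF can reach toward 0.
#'
#' @param maf Vector of sex-combined MAF values (in `[0, 0.5]`).
#' @param female_allele_weight w above, in (0, 1).
#' @return List with `lower` and `upper` vectors: the flipped subset
#'   satisfies `lower < abs(sdmaf) <= upper` (lower may exceed upper where
#'   no flipped variant is possible).
#' @export
flip_bounds <- function(maf, female_allele_weight = 0.5) {
  w <- female_allele_weight
  if (w <= 0 || w >= 1) stop("weight must be in (0,1)", call. = FALSE)
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) {
    stop("combined MAF must be in [0, 0.5]", call. = FALSE)
  }
  # bound from either branch (p_f above 0.5, or p_m above 0.5): the looser
  # envelope over branches is reported, which at w = 0.5 coincide
  lower <- pmin((0.5 - maf) / (1 - w), (0.5 - maf) / w)
  upper <- pmax(pmin((1 - maf) / (1 - w), maf / w),
                pmin((1 - maf) / w, maf / (1 - w)))
  list(lower = lower, upper = upper)
}
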