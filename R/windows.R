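#' Sliding-window mean of -log10 p-values
#'
#' Smooths a per-SNP -log10(p) track with fixed-size windows of
#' consecutive SNPs (default 50) advanced by a fixed step (default 25).
#' Only full windows are emitted; each is located at its leftmost SNP's
#' position and valued at the arithmetic mean of the member SNPs'
#' -log10 p. Infinite sentinels (zero-variance degenerate tests) are
#' excluded from the mean and counted per window.
#'
#' @param pos Positions of the SNPs, sorted ascending.
#' @param neg_log10_p Per-SNP -log10 p-values, same order as `pos`.
#' @param window_size Number of SNPs per window (>= 1).
#' @param step Number of SNPs between successive window starts (>= 1).
#' @return data.frame with `start_index`, `pos` (leftmost SNP),
#'   `mean_neg_log10_p`, `n_snps`, `n_infinite`. Zero rows (with a
#'   warning) when there are fewer SNPs than `window_size`.
#' @export
sliding_mean_neglog10 <- function(pos, neg_log10_p,
                                  window_size = 50, step = 25) {
  if (length(pos) != length(neg_log10_p)) {
    stop("pos and neg_log10_p lengths differ", call. = FALSE)
  }
  if (window_size < 1 || step < 1) {
    stop("window_size and step must be >= 1", call. = FALSE)
  }
  if (is.unsorted(pos)) stop("SNPs must be sorted by position", call. = FALSE)
  n <- length(pos)
  if (n < window_size) {
    warning("fewer SNPs (", n, ") than window size (", window_size, ")",
            call. = FALSE)
    return(data.frame(start_index = integer(0), pos = numeric(0),
                      mean_neg_log10_p = numeric(0), n_snps = integer(0),
                      n_infinite = integer(0)))
  }
  starts <- seq.int(1L, n - window_size + 1L, by = step)
  rows <- lapply(starts, function(s) {
    v <- neg_log10_p[s:(s + window_size - 1L)]
    inf <- is.infinite(v)
    data.frame(start_index = s, pos = pos[s],
               mean_neg_log10_p = mean(v[!inf]),
               n_snps = window_size, n_infinite = sum(inf))
  })
  do.call(rbind, rows)
}
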