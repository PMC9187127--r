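# Independent oracles for the exact Hardy-Weinberg tests, deliberately built
# on different arithmetic than the implementation (normalized factorial
# weights, and brute-force allele-subset enumeration for tiny samples).

# within-stratum exact test via normalized weights (no closed-form
# denominator, plain factorials; valid for n <= ~80)
oracle_exact_within <- function(triple) {
  n <- sum(triple)
  nA <- 2 * triple[3] + triple[2]
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
  w <- vapply(hets, function(h) {
    n2 <- (nA - h) / 2; n0 <- n - h - n2
    2^h / (factorial(n0) * factorial(h) * factorial(n2))
  }, numeric(1))
  pr <- w / sum(w)
  obs <- pr[hets == triple[2]]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# joint X-linked exact test via normalized weights over (mA, f1)
oracle_exact_x_joint <- function(female, male) {
  f <- sum(female); m <- sum(male)
  nA <- 2 * female[3] + female[2] + male[2]
  N <- 2 * f + m
  if (nA == 0 || nA == N) return(1)
  cfg <- list(); w <- numeric(0)
  for (mA in max(0, nA - 2 * f):min(m, nA)) {
    fA <- nA - mA
    f1max <- min(fA, 2 * f - fA)
    if (f1max < 0) next
    for (f1 in seq.int(fA %% 2, f1max, by = 2)) {
      f2 <- (fA - f1) / 2; f0 <- f - f1 - f2
      if (f0 < 0 || f2 < 0) next
      w <- c(w, choose(m, mA) * 2^f1 /
               (factorial(f0) * factorial(f1) * factorial(f2)))
      cfg[[length(cfg) + 1L]] <- c(mA, f1)
    }
  }
  pr <- w / sum(w)
  obs_i <- which(vapply(cfg, function(z) {
    z[1] == male[2] && z[2] == female[2]
  }, logical(1)))
  sum(pr[pr <= pr[obs_i] * (1 + 1e-9)])
}

# brute force for very small N: distribute the nA designated alleles over
# the N = 2f + m allele slots uniformly (all subsets equally likely) and
# tally the induced (male A-count, female het-count) distribution
oracle_exact_x_bruteforce <- function(female, male) {
  f <- sum(female); m <- sum(male)
  N <- 2 * f + m
  nA <- 2 * female[3] + female[2] + male[2]
  if (nA == 0 || nA == N) return(1)
  stopifnot(N <= 16)
  subsets <- utils::combn(N, nA)
  is_male_slot <- seq_len(N) <= m
  female_of_slot <- ifelse(is_male_slot, NA, ceiling((seq_len(N) - m) / 2))
  keys <- apply(subsets, 2, function(s) {
    mA <- sum(is_male_slot[s])
    doses <- tabulate(female_of_slot[s][!is.na(female_of_slot[s])], nbins = f)
    paste(mA, sum(doses == 1))
  })
  tab <- table(keys) / ncol(subsets)
  obs <- tab[[paste(male[2], female[2])]]
  sum(tab[tab <= obs * (1 + 1e-9)])
}
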