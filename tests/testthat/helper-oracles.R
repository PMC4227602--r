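# Independent oracles, written from the definitions rather than from the
# implementation (and without stats::fisher.test / chisq.test), used to
# cross-check the package's statistics by brute force on small problems.

# Fisher exact p for the 2x2 table [[a, b], [c, d]] by exhaustive
# enumeration of the conditional hypergeometric distribution.
fisher_enum_oracle <- function(a, b, c, d,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(x == a)
  if (alternative == "greater") {
    sum(p[x >= a])
  } else {
    sum(p[p <= p[obs] * (1 + 1e-7)])
  }
}

# Exact Hardy-Weinberg p by full enumeration of all genotype configurations
# with the observed sample size and allele counts (Levene's conditional
# distribution written as a multinomial ratio, no recursion tricks).
hwe_enum_oracle <- function(hom_alt, het, hom_ref) {
  n <- hom_alt + het + hom_ref
  n_alt <- 2 * hom_alt + het
  configs <- expand.grid(aa = 0:n, ab = 0:n)
  configs$bb <- n - configs$aa - configs$ab
  configs <- configs[configs$bb >= 0 & 2 * configs$aa + configs$ab == n_alt, ]
  prob <- apply(configs, 1, function(g) {
    exp(lfactorial(n) - lfactorial(g[["aa"]]) - lfactorial(g[["ab"]]) -
          lfactorial(g[["bb"]]) + g[["ab"]] * log(2) +
          lfactorial(n_alt) + lfactorial(2 * n - n_alt) - lfactorial(2 * n))
  })
  prob <- prob / sum(prob)
  obs <- which(configs$aa == hom_alt & configs$ab == het)
  sum(prob[prob <= prob[obs] * (1 + 1e-9)])
}

# Pearson chi-square closed form for the 2x2 table [[a, b], [c, d]].
pearson_oracle <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Standard genetic code written out by hand (bases ordered T, C, A, G),
# independent of Biostrings.
codon_oracle_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- character(64); i <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1; codons[i] <- paste0(b1, b2, b3)
  }
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aas, codons)
})

codon_oracle <- function(codon) unname(codon_oracle_table[toupper(codon)])

# ML two-locus haplotype frequencies by grid search over p_AB, exploiting
# marginal conservation (allele frequencies fixed at the observed values)
# and scanning the one free parameter on a fine grid of the multinomial
# likelihood.
grid_hap_oracle <- function(tab, step = 1e-5) {
  n <- sum(tab)
  alt1 <- sum(rowSums(tab) * 0:2) / (2 * n)
  alt2 <- sum(colSums(tab) * 0:2) / (2 * n)
  p_A <- 1 - alt1; p_B <- 1 - alt2
  lo <- max(0, p_A + p_B - 1); hi <- min(p_A, p_B)
  grid <- seq(lo, hi, by = step)
  pAB <- grid; pAb <- p_A - grid; paB <- p_B - grid
  pab <- 1 - p_A - p_B + grid
  # closed-form cell probabilities as functions of p_AB
  cellp <- list(
    `11` = pAB^2,          `12` = 2 * pAB * pAb,          `13` = pAb^2,
    `21` = 2 * pAB * paB,  `22` = 2 * (pAB * pab + pAb * paB),
    `23` = 2 * pAb * pab,
    `31` = paB^2,          `32` = 2 * paB * pab,          `33` = pab^2)
  ll <- numeric(length(grid))
  for (i in 1:3) for (j in 1:3) {
    if (tab[i, j] > 0) {
      v <- cellp[[paste0(i, j)]]
      lv <- suppressWarnings(log(v))
      ll <- ll + ifelse(v > 0, tab[i, j] * lv, -Inf)
    }
  }
  pAB <- grid[which.max(ll)]
  c(AB = pAB, Ab = p_A - pAB, aB = p_B - pAB, ab = 1 - p_A - p_B + pAB)
}

# Solid-spine blocks by definition: test every interval, then pick longest
# first / leftmost among equals / non-overlapping.
blocks_enum_oracle <- function(dmat, threshold = 1) {
  m <- nrow(dmat)
  ok <- function(i, j) {
    for (k in (i + 1):j) {
      if (is.na(dmat[i, k]) || dmat[i, k] < threshold) return(FALSE)
    }
    for (k in i:(j - 1)) {
      if (is.na(dmat[k, j]) || dmat[k, j] < threshold) return(FALSE)
    }
    TRUE
  }
  cand <- list()
  if (m >= 2) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (ok(i, j)) cand[[length(cand) + 1]] <- c(start = i, end = j)
    }
  }
  if (!length(cand)) return(data.frame(start = integer(), end = integer()))
  cand <- as.data.frame(do.call(rbind, cand))
  cand <- cand[order(-(cand$end - cand$start), cand$start), ]
  used <- rep(FALSE, m); keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!any(used[cand$start[r]:cand$end[r]])) {
      keep[r] <- TRUE
      used[cand$start[r]:cand$end[r]] <- TRUE
    }
  }
  out <- cand[keep, ]
  out[order(out$start), ]
}

# random symmetric D' matrix with exact ties to exercise block building
random_dprime_matrix <- function(m) {
  vals <- sample(c(1, 1, 1, 0.9, 0.5, NA), m * (m - 1) / 2, replace = TRUE)
  mat <- matrix(NA_real_, m, m)
  mat[upper.tri(mat)] <- vals
  mat[lower.tri(mat)] <- t(mat)[lower.tri(mat)]
  diag(mat) <- 1
  mat
}
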