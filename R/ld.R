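# Two-locus haplotype machinery. Haplotypes are indexed AB, Ab, aB, ab where
# A/B are the reference alleles and a/b the alternates; genotypes are
# alternate-allele dosages in {0, 1, 2} at each locus. In a 3x3 genotype
# table only the double-heterozygote cell (1,1) is phase-ambiguous.

HAP_NAMES <- c("AB", "Ab", "aB", "ab")

# cell probabilities of the 3x3 genotype table under haplotype freqs p
two_locus_cell_probs <- function(p) {
  # dosage contributed by each haplotype at (locus1, locus2)
  dose <- rbind(AB = c(0, 0), Ab = c(0, 1), aB = c(1, 0), ab = c(1, 1))
  probs <- matrix(0, 3, 3)
  for (h in 1:4) for (k in 1:4) {
    g1 <- dose[h, 1] + dose[k, 1]
    g2 <- dose[h, 2] + dose[k, 2]
    probs[g1 + 1, g2 + 1] <- probs[g1 + 1, g2 + 1] + p[h] * p[k]
  }
  probs
}

two_locus_loglik <- function(tab, p) {
  probs <- two_locus_cell_probs(p)
  keep <- tab > 0
  sum(tab[keep] * log(probs[keep]))
}

# allele frequencies (of the reference alleles A and B) from the table
table_allele_freqs <- function(tab) {
  n <- sum(tab)
  alt1 <- sum(rowSums(tab) * 0:2) / (2 * n)
  alt2 <- sum(colSums(tab) * 0:2) / (2 * n)
  c(p_A = 1 - alt1, p_B = 1 - alt2)
}

#' Two-locus haplotype frequencies by expectation-maximisation
#'
#' Maximum-likelihood haplotype frequencies from an unphased 3x3 genotype
#' table. Every cell except the double heterozygote is phase-unambiguous;
#' the EM iteration splits the double-heterozygote cell between the coupling
#' (AB/ab) and repulsion (Ab/aB) phases in proportion to their current
#' expected probability, until the observed-data log-likelihood changes by
#' less than `tol`. Initialisation is at linkage equilibrium, so degenerate
#' flat likelihoods (e.g. a lone double heterozygote) resolve to the
#' linkage-equilibrium point deterministically.
#'
#' @param tab 3x3 matrix of genotype counts; rows index the alternate-allele
#'   dosage at locus 1 (0, 1, 2), columns at locus 2.
#' @param tol Convergence threshold on the log-likelihood change
#'   (default 1e-10).
#' @param max_iter Iteration cap (default 1000); hitting it sets
#'   `converged = FALSE` with a warning.
#'
#' @return An object of class `hap_em`: haplotype frequencies (`freqs`, named
#'   AB/Ab/aB/ab), the input table, allele frequencies, the log-likelihood
#'   trace, iteration count and convergence flag. Use [tidy()] for the
#'   frequencies, [glance()] for fit statistics including the LD summary.
#' @export
#' @examples
#' tab <- matrix(0, 3, 3)
#' tab[1, 1] <- 4; tab[3, 3] <- 4; tab[2, 2] <- 2
#' hap_em(tab)
hap_em <- function(tab, tol = 1e-10, max_iter = 1000) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(3, 3)), all(tab >= 0))
  n <- sum(tab)
  if (n <= 0) abort("empty genotype table")
  af <- table_allele_freqs(tab)
  p_A <- af[["p_A"]]; p_B <- af[["p_B"]]
  p <- c(p_A * p_B, p_A * (1 - p_B), (1 - p_A) * p_B, (1 - p_A) * (1 - p_B))
  names(p) <- HAP_NAMES

  # fixed haplotype counts from the eight unambiguous cells:
  # cell (g1, g2) contributes two haplotypes per sample
  base <- c(
    AB = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
    Ab = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    aB = 2 * tab[3, 1] + tab[2, 1] + tab[3, 2],
    ab = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  )
  dh <- tab[2, 2]

  ll <- two_locus_loglik(tab, p)
  trace <- ll
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    # E-step: split double heterozygotes between coupling and repulsion
    coup <- p[["AB"]] * p[["ab"]]
    rep_ <- p[["Ab"]] * p[["aB"]]
    alpha <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    counts <- base + dh * c(alpha, 1 - alpha, 1 - alpha, alpha)
    # M-step
    p_new <- counts / (2 * n)
    ll_new <- two_locus_loglik(tab, p_new)
    trace <- c(trace, ll_new)
    delta <- ll_new - ll
    p <- p_new
    ll <- ll_new
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged) warn("EM did not converge within max_iter")
  structure(
    list(freqs = p, table = tab, n = n,
         allele_freqs = c(af, p_a = 1 - p_A, p_b = 1 - p_B),
         loglik = ll, loglik_trace = trace, n_iter = iter,
         converged = converged),
    class = "hap_em"
  )
}

#' @export
print.hap_em <- function(x, ...) {
  cat("Two-locus haplotype EM fit (n =", x$n, "samples)\n")
  print(round(x$freqs, 6))
  cat("log-likelihood", format(x$loglik), "after", x$n_iter, "iterations",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' Pairwise linkage-disequilibrium statistics from haplotype frequencies
#'
#' `D = p_AB - p_A p_B`; `D'` is `|D|` normalised by its attainable maximum
#' given the allele frequencies; `r2 = D^2 / (p_A p_a p_B p_b)`. With a
#' monomorphic locus `D = 0` and `D'`/`r2` are undefined (`NA`).
#'
#' @param freqs Named numeric of haplotype frequencies (`AB`, `Ab`, `aB`,
#'   `ab`), e.g. the `freqs` element of a [hap_em()] fit.
#' @return Tibble with `D`, `dprime`, `r2`.
#' @export
#' @examples
#' ld_stats(c(AB = 0.10, Ab = 0, aB = 0.10, ab = 0.80))
ld_stats <- function(freqs) {
  p <- freqs[HAP_NAMES]
  stopifnot(!anyNA(p), abs(sum(p) - 1) < 1e-6)
  p_A <- p[["AB"]] + p[["Ab"]]; p_B <- p[["AB"]] + p[["aB"]]
  p_a <- 1 - p_A; p_b <- 1 - p_B
  D <- p[["AB"]] - p_A * p_B
  if (p_A %in% c(0, 1) || p_B %in% c(0, 1)) {
    return(tibble(D = 0, dprime = NA_real_, r2 = NA_real_))
  }
  d_max <- if (D > 0) min(p_A * p_b, p_a * p_B) else min(p_A * p_B, p_a * p_b)
  dprime <- if (D == 0) 0 else abs(D) / d_max
  tibble(D = D, dprime = dprime, r2 = D^2 / (p_A * p_a * p_B * p_b))
}

#' LOD score of linkage disequilibrium
#'
#' Base-10 log likelihood ratio of the fitted haplotype frequencies against
#' linkage equilibrium at the same allele frequencies, evaluated on the
#' observed genotype table. Non-negative by construction (the
#' linkage-equilibrium point is in the haplotype-frequency parameter space).
#'
#' @param fit A [hap_em()] fit.
#' @return The LOD score.
#' @export
ld_lod <- function(fit) {
  stopifnot(inherits(fit, "hap_em"))
  p_A <- fit$allele_freqs[["p_A"]]; p_B <- fit$allele_freqs[["p_B"]]
  p_le <- c(p_A * p_B, p_A * (1 - p_B), (1 - p_A) * p_B,
            (1 - p_A) * (1 - p_B))
  max(0, (fit$loglik - two_locus_loglik(fit$table, p_le)) / log(10))
}

#' @rdname hap_em
#' @param x A `hap_em` fit.
#' @param ... Unused.
#' @export
tidy.hap_em <- function(x, ...) {
  tibble(haplotype = HAP_NAMES, frequency = unname(x$freqs))
}

#' @rdname hap_em
#' @export
glance.hap_em <- function(x, ...) {
  ld <- ld_stats(x$freqs)
  tibble(n = x$n, loglik = x$loglik, n_iter = x$n_iter,
         converged = x$converged, D = ld$D, dprime = ld$dprime, r2 = ld$r2,
         lod = ld_lod(x))
}

#' Pairwise LD over an ordered marker set
#'
#' Runs the haplotype EM for every marker pair and reports D, D', r2 and the
#' LOD score, one row per pair. Samples missing a genotype at either marker
#' are dropped for that pair only.
#'
#' @param genotypes Tibble with `sample_id`, `id` (marker) and `dosage`
#'   (0/1/2/NA alternate-allele count).
#' @param marker_order Character vector of marker ids in map order; defaults
#'   to order of appearance.
#' @param tol,max_iter Passed to [hap_em()].
#' @return Tibble with `marker1`, `marker2`, `n`, `D`, `dprime`, `r2`,
#'   `lod`, marker1 preceding marker2 in map order.
#' @export
ld_pairwise <- function(genotypes, marker_order = NULL, tol = 1e-10,
                        max_iter = 1000) {
  genotypes <- as_tibble(genotypes)
  if (is.null(marker_order)) marker_order <- unique(genotypes$id)
  wide <- genotypes |>
    select("sample_id", "id", "dosage") |>
    tidyr::pivot_wider(names_from = "id", values_from = "dosage")
  pairs <- which(upper.tri(diag(length(marker_order))), arr.ind = TRUE)
  map(seq_len(nrow(pairs)), function(r) {
    m1 <- marker_order[pairs[r, "row"]]
    m2 <- marker_order[pairs[r, "col"]]
    d1 <- wide[[m1]]; d2 <- wide[[m2]]
    keep <- !is.na(d1) & !is.na(d2)
    tab <- matrix(0, 3, 3)
    for (s in which(keep)) tab[d1[s] + 1, d2[s] + 1] <-
        tab[d1[s] + 1, d2[s] + 1] + 1
    fit <- hap_em(tab, tol = tol, max_iter = max_iter)
    ld <- ld_stats(fit$freqs)
    tibble(marker1 = m1, marker2 = m2, n = sum(keep), D = ld$D,
           dprime = ld$dprime, r2 = ld$r2, lod = ld_lod(fit))
  }) |> list_rbind() |> arrange(match(.data$marker1, marker_order),
                                match(.data$marker2, marker_order))
}

#' Square D' matrix from a pairwise LD table
#'
#' @param pairwise Output of [ld_pairwise()].
#' @param marker_order Marker ids in map order.
#' @return Symmetric numeric matrix of D' values with unit diagonal.
#' @export
dprime_matrix <- function(pairwise, marker_order = NULL) {
  if (is.null(marker_order)) {
    marker_order <- unique(c(pairwise$marker1, pairwise$marker2))
  }
  m <- length(marker_order)
  mat <- matrix(NA_real_, m, m, dimnames = list(marker_order, marker_order))
  diag(mat) <- 1
  for (r in seq_len(nrow(pairwise))) {
    i <- match(pairwise$marker1[r], marker_order)
    j <- match(pairwise$marker2[r], marker_order)
    mat[i, j] <- mat[j, i] <- pairwise$dprime[r]
  }
  mat
}

#' Solid-spine haplotype blocks
#'
#' A block `[i, j]` is valid when the first marker is in strong LD
#' (`D' >= threshold`) with every other marker of the block and so is the
#' last: `D'(i, k) >= threshold` for all `k` in `(i, j]` and
#' `D'(k, j) >= threshold` for all `k` in `[i, j)`. Pairs with undefined D'
#' break the spine. Blocks are chosen greedily: longest first, leftmost among
#' equals, non-overlapping.
#'
#' @param dmat Symmetric D' matrix over markers in map order (see
#'   [dprime_matrix()]).
#' @param threshold Spine threshold (default 1, i.e. complete D').
#' @return Tibble with `start`, `end` (marker indices), `n_markers`, and
#'   marker names when `dmat` has dimnames.
#' @export
solid_spine_blocks <- function(dmat, threshold = 1) {
  m <- nrow(dmat)
  spine_ok <- function(i, j) {
    ks <- (i + 1):j
    all(!is.na(dmat[i, ks]) & dmat[i, ks] >= threshold) &&
      all(!is.na(dmat[i:(j - 1), j]) & dmat[i:(j - 1), j] >= threshold)
  }
  cand <- list()
  if (m >= 2) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (spine_ok(i, j)) cand[[length(cand) + 1]] <- c(i, j)
    }
  }
  if (length(cand) == 0) {
    return(tibble(start = integer(), end = integer(), n_markers = integer(),
                  first_marker = character(), last_marker = character()))
  }
  cand <- do.call(rbind, cand)
  ord <- order(-(cand[, 2] - cand[, 1]), cand[, 1])
  cand <- cand[ord, , drop = FALSE]
  taken <- rep(FALSE, m)
  picked <- list()
  for (r in seq_len(nrow(cand))) {
    span <- cand[r, 1]:cand[r, 2]
    if (!any(taken[span])) {
      taken[span] <- TRUE
      picked[[length(picked) + 1]] <- cand[r, ]
    }
  }
  picked <- do.call(rbind, picked)
  picked <- picked[order(picked[, 1]), , drop = FALSE]
  nm <- rownames(dmat) %||% as.character(seq_len(m))
  tibble(start = as.integer(picked[, 1]), end = as.integer(picked[, 2]),
         n_markers = as.integer(picked[, 2] - picked[, 1] + 1),
         first_marker = nm[picked[, 1]], last_marker = nm[picked[, 2]])
}
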