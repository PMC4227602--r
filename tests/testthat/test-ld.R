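tab_from_cells <- function(...) {
  # cells given as (g1, g2, count) triples
  cells <- list(...)
  tab <- matrix(0, 3, 3)
  for (cl in cells) tab[cl[1] + 1, cl[2] + 1] <- cl[3]
  tab
}

test_that("EM recovers phase-unambiguous tables by direct counting", {
  tab <- tab_from_cells(c(0, 0, 2), c(2, 2, 2))
  f <- hap_em(tab)
  expect_equal(unname(f$freqs[c("AB", "ab")]), c(0.5, 0.5), tolerance = 1e-9)
  expect_true(f$converged)
})

test_that("EM matches a grid-search likelihood maximiser", {
  tab <- tab_from_cells(c(0, 0, 4), c(2, 2, 4), c(1, 1, 2))
  f <- hap_em(tab)
  oracle <- grid_hap_oracle(tab, step = 1e-5)
  expect_equal(unname(f$freqs), unname(oracle), tolerance = 1e-4)

  withr::with_seed(31, {
    for (i in 1:20) {
      p <- as.vector(rmultinom(1, 40, runif(4) + 0.05)) / 40
      names(p) <- c("AB", "Ab", "aB", "ab")
      tab <- simulate_haplotype_pairs(p, n = 60, seed = i)
      af <- c(sum(tab * c(0, 1, 2)[row(tab)]), sum(tab * c(0, 1, 2)[col(tab)]))
      if (any(af == 0) || any(af == 2 * sum(tab))) next  # monomorphic draw
      f <- hap_em(tab)
      oracle <- grid_hap_oracle(tab, step = 1e-5)
      expect_equal(unname(f$freqs), unname(oracle), tolerance = 1e-4)
    }
  })
})

test_that("a lone double heterozygote resolves to linkage equilibrium", {
  tab <- tab_from_cells(c(1, 1, 1))
  f <- hap_em(tab)
  expect_equal(unname(f$freqs), rep(0.25, 4), tolerance = 1e-9)
})

test_that("EM log-likelihood is monotone and marginals are conserved", {
  withr::with_seed(17, {
    for (i in 1:25) {
      p <- as.vector(rmultinom(1, 50, runif(4) + 0.02)) / 50
      names(p) <- c("AB", "Ab", "aB", "ab")
      tab <- simulate_haplotype_pairs(p, n = 80, seed = 1000 + i)
      f <- hap_em(tab)
      expect_true(all(diff(f$loglik_trace) >= -1e-8))
      # haplotype frequencies reproduce the table's allele frequencies
      expect_equal(f$freqs[["AB"]] + f$freqs[["Ab"]],
                   f$allele_freqs[["p_A"]], tolerance = 1e-9)
      expect_equal(f$freqs[["AB"]] + f$freqs[["aB"]],
                   f$allele_freqs[["p_B"]], tolerance = 1e-9)
    }
  })
})

test_that("LD statistics follow their definitions", {
  # worked example: D = 0.08 at its maximum, r2 = 4/9
  h <- c(AB = 0.10, Ab = 0, aB = 0.10, ab = 0.80)
  s <- ld_stats(h)
  expect_equal(s$D, 0.08, tolerance = 1e-12)
  expect_equal(s$dprime, 1, tolerance = 1e-12)
  expect_equal(s$r2, 0.0064 / (0.1 * 0.9 * 0.2 * 0.8), tolerance = 1e-12)

  # independence
  ind <- c(AB = 0.06, Ab = 0.14, aB = 0.24, ab = 0.56)
  s <- ld_stats(ind)
  expect_equal(s$D, 0, tolerance = 1e-12)
  expect_equal(s$r2, 0, tolerance = 1e-12)

  # monomorphic locus: D zero, normalised measures undefined
  mono <- c(AB = 0.7, Ab = 0.3, aB = 0, ab = 0)
  s <- ld_stats(mono)
  expect_equal(s$D, 0)
  expect_true(is.na(s$dprime) && is.na(s$r2))

  # rare allele entirely on one common background: D' = 1, r2 small
  rare <- c(AB = 0.68, Ab = 0.30, aB = 0.02, ab = 0)
  s <- ld_stats(rare)
  expect_equal(s$dprime, 1, tolerance = 1e-12)
  expect_lt(s$r2, 0.05)
})

test_that("D' and r2 are in [0,1] and r2 never exceeds D'", {
  withr::with_seed(23, {
    for (i in 1:200) {
      p <- as.vector(rmultinom(1, 60, runif(4) + 0.01)) / 60
      names(p) <- c("AB", "Ab", "aB", "ab")
      s <- ld_stats(p)
      if (is.na(s$dprime)) next
      expect_gte(s$dprime, 0); expect_lte(s$dprime, 1 + 1e-12)
      expect_gte(s$r2, 0); expect_lte(s$r2, 1 + 1e-12)
      expect_lte(s$r2, s$dprime + 1e-12)
    }
  })
})

test_that("LOD is the base-10 likelihood ratio against equilibrium", {
  # closed form for a phase-unambiguous table
  tab <- tab_from_cells(c(0, 0, 2), c(2, 2, 2))
  expect_equal(ld_lod(hap_em(tab)), 4 * log10(4), tolerance = 1e-6)

  # data at linkage-equilibrium expectations: LOD ~ 0
  p_A <- 0.5; p_B <- 0.5
  tab_le <- outer(c(p_A^2, 2 * p_A * (1 - p_A), (1 - p_A)^2),
                  c(p_B^2, 2 * p_B * (1 - p_B), (1 - p_B)^2)) * 64
  expect_lt(ld_lod(hap_em(tab_le)), 1e-6)

  withr::with_seed(37, {
    for (i in 1:20) {
      p <- as.vector(rmultinom(1, 30, runif(4) + 0.05)) / 30
      names(p) <- c("AB", "Ab", "aB", "ab")
      tab <- simulate_haplotype_pairs(p, n = 50, seed = 2000 + i)
      expect_gte(ld_lod(hap_em(tab)), 0)
    }
  })
})

test_that("glance and tidy expose the fit; autoplot returns a ggplot", {
  tab <- tab_from_cells(c(0, 0, 4), c(2, 2, 4), c(1, 1, 2))
  f <- hap_em(tab)
  td <- tidy(f)
  expect_equal(td$haplotype, c("AB", "Ab", "aB", "ab"))
  expect_equal(sum(td$frequency), 1, tolerance = 1e-9)
  gl <- glance(f)
  expect_true(all(c("dprime", "r2", "lod", "converged") %in% names(gl)))
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("pairwise LD drops pair-missing samples only", {
  geno <- tibble::tribble(
    ~sample_id, ~id, ~dosage,
    "s1", "m1", 0, "s1", "m2", 0, "s1", "m3", 0,
    "s2", "m1", 2, "s2", "m2", 2, "s2", "m3", NA,
    "s3", "m1", 0, "s3", "m2", 0, "s3", "m3", 1,
    "s4", "m1", 2, "s4", "m2", 2, "s4", "m3", 1
  )
  res <- ld_pairwise(geno, marker_order = c("m1", "m2", "m3"))
  expect_equal(nrow(res), 3)
  expect_equal(res$n[res$marker1 == "m1" & res$marker2 == "m2"], 4)
  expect_equal(res$n[res$marker1 == "m1" & res$marker2 == "m3"], 3)
  expect_equal(res$dprime[res$marker1 == "m1" & res$marker2 == "m2"], 1,
               tolerance = 1e-6)
})

test_that("solid-spine blocks match exhaustive interval search", {
  # two markers in complete LD form one block
  m2 <- matrix(1, 2, 2)
  b <- solid_spine_blocks(m2)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(1, 2))

  # no pair reaches the threshold: no blocks
  weak <- matrix(0.4, 3, 3); diag(weak) <- 1
  expect_equal(nrow(solid_spine_blocks(weak)), 0)

  # crafted 4-marker matrix: spine 1-3 holds, marker 4 dangles
  dm <- matrix(c(1, 1, 1, 0.2,
                 1, 1, 1, 0.3,
                 1, 1, 1, 0.1,
                 0.2, 0.3, 0.1, 1), 4, 4)
  b <- solid_spine_blocks(dm)
  expect_equal(c(b$start, b$end), c(1, 3))

  withr::with_seed(41, {
    for (i in 1:60) {
      m <- sample(2:8, 1)
      dm <- random_dprime_matrix(m)
      got <- solid_spine_blocks(dm)
      want <- blocks_enum_oracle(dm)
      expect_equal(got$start, want$start, info = i)
      expect_equal(got$end, want$end, info = i)
    }
  })
})
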