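test_that("diversity summary matches hand computations", {
  # one locus, genotypes {AB, AB}: H_O = 1, H_E = 0.5, N_a = 2
  g <- genotype_matrix(rbind(1L, 1L), rbind(2L, 2L), pop = c("p", "p"))
  d <- diversity_summary(g, fis = "genalex")
  expect_equal(d$Ho, 1)
  expect_equal(d$He, 0.5)
  expect_equal(d$Na, 2)
  # three observed alleles -> N_a = 3
  g3 <- genotype_matrix(rbind(102L, 104L), rbind(104L, 106L), pop = c("p", "p"))
  expect_equal(diversity_summary(g3, fis = "genalex")$Na, 3)
  # monomorphic population: H_E = 0, not an error
  gm <- genotype_matrix(rbind(1L, 1L), rbind(1L, 1L), pop = c("p", "p"))
  expect_equal(diversity_summary(gm, fis = "genalex")$He, 0)
  # H_E from allele_frequencies equals 1 - sum p^2 exactly
  gmix <- toy_matrix()
  af <- allele_frequencies(gmix, grouping = rep("all", 4))
  d2 <- diversity_summary(
    genotype_matrix(gmix$a1, gmix$a2, pop = rep("all", 4), loci = gmix$loci),
    fis = "genalex")
  he_direct <- mean(vapply(af$freq$all, function(p) 1 - sum(p^2, na.rm = TRUE), 1))
  expect_equal(d2$He, he_direct)
})

test_that("Weir-Cockerham f matches an independent variance-component oracle", {
  # all-heterozygous sample: strong heterozygote excess, f < 0
  g <- genotype_matrix(matrix(1L, 6, 1), matrix(2L, 6, 1), pop = rep("p", 6))
  expect_lt(fis_weir_cockerham(g, "p")$multilocus, 0)

  # counts AA=4, AB=2, BB=4 (n=10): oracle coded directly from the
  # single-population variance components b and c per allele
  wc_f_oracle <- function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB
    f_components <- function(p, h) {
      b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      c(b = b, c = h / 2)
    }
    pA <- (2 * nAA + nAB) / (2 * n)
    h <- nAB / n
    comp <- f_components(pA, h) + f_components(1 - pA, h)
    1 - comp["c"] / sum(comp)
  }
  g2 <- genotype_matrix(matrix(c(rep(1L, 4), rep(1L, 2), rep(2L, 4)), 10, 1),
                        matrix(c(rep(1L, 4), rep(2L, 2), rep(2L, 4)), 10, 1),
                        pop = rep("p", 10))
  expect_equal(fis_weir_cockerham(g2, "p")$multilocus,
               unname(wc_f_oracle(4, 2, 4)), tolerance = 1e-12)
  # degenerate: every locus monomorphic -> error
  gm <- genotype_matrix(matrix(1L, 4, 2), matrix(1L, 4, 2), pop = rep("p", 4))
  expect_error(fis_weir_cockerham(gm, "p"), "undefined at every locus")
})

test_that("Weir-Cockerham f is centred near zero under Hardy-Weinberg", {
  pools <- simulate_parental_pools(sim_config(seed = 2))
  f <- vapply(1:40, function(s) {
    g <- draw_pure_individuals(pools$A, 50, seed = s, pop = "p")
    fis_weir_cockerham(g, "p")$multilocus
  }, 1)
  expect_lt(abs(mean(f)), 3 * stats::sd(f) / sqrt(length(f)))
})

test_that("pairwise theta behaves at the extremes and under permutation", {
  fd <- fixed_difference_pools(4L)
  gA <- draw_pure_individuals(fd$A, 10, seed = 1, pop = "A")
  gB <- draw_pure_individuals(fd$B, 10, seed = 2, pop = "B")
  both <- bind_genotypes(gA, gB)
  res <- pairwise_fst(both, n_perm = 99, seed = 3)
  expect_equal(res$theta["A", "B"], 1)
  expect_equal(res$theta["A", "B"], res$theta["B", "A"])
  expect_lte(res$p_value["A", "B"], 0.05)
  # one panmictic population split arbitrarily in two: theta ~ 0
  pools <- simulate_parental_pools(sim_config(seed = 4))
  g <- draw_pure_individuals(pools$A, 40, seed = 5, pop = "x")
  g$pop <- rep(c("x1", "x2"), 20)
  th <- pairwise_fst(g, n_perm = 0)$theta["x1", "x2"]
  expect_lt(abs(th), 0.05)
  expect_error(pairwise_fst(gA, n_perm = 0), "two populations")
  tiny <- subset_individuals(both, c(1, 11))
  expect_error(pairwise_fst(tiny, n_perm = 0), "fewer than 2")
})

test_that("theta is invariant to allele relabeling and population order", {
  set.seed(10)
  pools <- simulate_parental_pools(sim_config(seed = 10))
  gA <- draw_pure_individuals(pools$A, 15, seed = 1, pop = "A")
  gB <- draw_pure_individuals(pools$B, 15, seed = 2, pop = "B")
  g <- bind_genotypes(gA, gB)
  th1 <- pairwise_fst(g, n_perm = 0)$theta["A", "B"]
  # relabel allele codes monotonically (add 1000)
  g2 <- genotype_matrix(g$a1 + 1000L, g$a2 + 1000L, pop = g$pop, loci = g$loci)
  expect_equal(pairwise_fst(g2, n_perm = 0)$theta["A", "B"], th1)
  # reverse individual order (swaps population order)
  g3 <- subset_individuals(g, rev(seq_len(n_ind(g))))
  expect_equal(pairwise_fst(g3, n_perm = 0)$theta["A", "B"], th1)
})

test_that("individual Nei D_A has its closed-form values and invariances", {
  # identical homozygotes -> 0; disjoint homozygotes -> 1
  g <- genotype_matrix(rbind(c(1L, 1L), c(1L, 1L), c(2L, 2L)),
                       rbind(c(1L, 1L), c(1L, 1L), c(2L, 2L)),
                       pop = rep("p", 3))
  d <- nei_da_individuals(g)
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 1)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  # x = AA, y = AB at a single locus: 1 - sqrt(0.5)
  g2 <- genotype_matrix(rbind(1L, 1L), rbind(1L, 2L), pop = c("p", "p"))
  expect_equal(nei_da_individuals(g2)[1, 2], 1 - sqrt(0.5))
  # locus order and allele relabeling leave D_A unchanged; bounds hold
  pools <- simulate_parental_pools(sim_config(seed = 6))
  gs <- draw_pure_individuals(pools$A, 12, seed = 7)
  d1 <- nei_da_individuals(gs)
  expect_true(all(d1 >= -1e-12 & d1 <= 1 + 1e-12))
  expect_equal(d1, t(d1))
  perm <- sample(n_loci(gs))
  gperm <- genotype_matrix(gs$a1[, perm] + 500L, gs$a2[, perm] + 500L,
                           pop = gs$pop, loci = gs$loci[perm])
  expect_equal(nei_da_individuals(gperm), d1, ignore_attr = TRUE)
  # pair with no shared typed locus is flagged undefined
  a1 <- rbind(c(1L, NA), c(NA, 2L)); a2 <- rbind(c(1L, NA), c(NA, 2L))
  gu <- genotype_matrix(a1, a2, pop = c("p", "p"))
  du <- nei_da_individuals(gu)
  expect_true(is.na(du[1, 2]))
  expect_equal(nrow(attr(du, "undefined")), 1L)
})

test_that("principal coordinates reproduce distance geometry", {
  # two tight clusters about distance 1 apart: axis 1 carries >90% of variance
  set.seed(3)
  pts <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 1, 0.01), 5))
  d <- as.matrix(stats::dist(pts))
  p <- pcoa(d)
  expect_gt(p$percent_variance[1], 90)
  # collinear points: second axis variance ~ 0
  line <- as.matrix(stats::dist(cbind(1:6, 0)))
  pl <- pcoa(line)
  expect_lt(sum(pl$percent_variance[-1]), 1e-6)
  # Euclidean input: coordinates reproduce the distances
  rec <- as.matrix(stats::dist(p$coordinates))
  expect_equal(rec, d, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("principal coordinates agree with an independent implementation", {
  skip_if_not_installed("ape")
  pools <- simulate_parental_pools(sim_config(seed = 8))
  gA <- draw_pure_individuals(pools$A, 8, seed = 1, pop = "A")
  gB <- draw_pure_individuals(pools$B, 8, seed = 2, pop = "B")
  d <- nei_da_individuals(bind_genotypes(gA, gB))
  ours <- pcoa(d)
  ref <- ape::pcoa(stats::as.dist(d))
  k <- min(3, ncol(ours$coordinates))
  for (ax in 1:k)
    expect_equal(abs(ours$coordinates[, ax]), abs(ref$vectors[, ax]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  pos_sum <- sum(ref$values$Eigenvalues[ref$values$Eigenvalues > 0])
  expect_equal(ours$percent_variance[1:k],
               100 * ref$values$Eigenvalues[1:k] / pos_sum, tolerance = 1e-6)
})

test_that("mixed parental populations show the Wahlund heterozygote deficit", {
  # divergent gene pools pooled with few hybrids: F_IS significantly positive
  pools <- simulate_parental_pools(sim_config(seed = 12))
  mix <- simulate_mixed_population(pools$A, pools$B,
                                   c(P1 = 13, P2 = 12, F1 = 2, F2 = 2),
                                   seed = 13, pop = "H")
  f <- fis_weir_cockerham(mix$genotypes, "H")$multilocus
  expect_gt(f, 0.1)
})
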