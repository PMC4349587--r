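test_that("genotype matrix construction enforces structural invariants", {
  g <- toy_matrix()
  expect_s3_class(g, "genotype_matrix")
  expect_equal(n_ind(g), 4L)
  expect_equal(n_loci(g), 2L)
  expect_equal(g$alleles$ssr1, c(102L, 104L))
  # half-missing call rejected
  expect_error(genotype_matrix(rbind(c(1L, NA)), rbind(c(1L, 2L)), pop = "p"),
               "half-missing")
  # empty population label rejected
  expect_error(genotype_matrix(rbind(1L), rbind(1L), pop = ""), "non-empty")
  expect_error(genotype_matrix(matrix(integer(0), 0, 0),
                               matrix(integer(0), 0, 0), pop = character(0)),
               "at least one")
  # validation flags (not drops) high-missingness individuals
  a1 <- rbind(c(1L, 2L), c(NA, NA)); a2 <- rbind(c(1L, 2L), c(NA, NA))
  suppressWarnings(
    expect_warning(out <- validate_genotype_matrix(
      genotype_matrix(a1, a2, pop = c("p", "p"), ids = c("ok", "gappy"))),
      "gappy"))
})

test_that("STRUCTURE two-row files round-trip, including missing sentinels", {
  g <- toy_matrix()
  path <- withr::local_tempfile()
  write_structure(g, path)
  g2 <- read_structure(path, loci = g$loci)
  expect_equal(g2$a1, g$a1)
  expect_equal(g2$a2, g$a2)
  expect_equal(g2$pop, g$pop)
  expect_equal(g2$ids, g$ids)
  # odd row count names the dangling individual
  lines <- readLines(path)
  writeLines(lines[-length(lines)], path)
  expect_error(read_structure(path), "i4")
  # missing sentinel excluded from frequency counts (hand count on toy file)
  af <- allele_frequencies(g)
  expect_equal(af$n_copies["p2", "ssr2"], 2L)  # one of two p2 calls missing
  expect_equal(unname(af$freq$p2$ssr2[c("204", "206")]), c(0.5, 0.5))
})

test_that("GenePop files follow the dialect and round-trip", {
  g <- toy_matrix()
  path <- withr::local_tempfile()
  write_genepop(g, path, digits = 3L)
  g2 <- read_genepop(path)
  expect_equal(g2$a1, g$a1, ignore_attr = TRUE)
  expect_equal(g2$a2, g$a2, ignore_attr = TRUE)
  expect_equal(g2$ids, g$ids)
  expect_equal(length(unique(g2$pop)), 2L)
  # "000000" decodes as a missing call
  expect_true(is.na(g2$a1[4, 2]) && is.na(g2$a2[4, 2]))
  # allele code too wide for the digit budget
  wide <- genotype_matrix(rbind(c(1234L)), rbind(c(1234L)), pop = "p")
  expect_error(write_genepop(wide, path, digits = 3L), "does not fit")
  # inconsistent locus count is a format error
  writeLines(c("t", "L1", "L2", "Pop", "a , 101101"), path)
  expect_error(read_genepop(path), "1 genotypes but 2 loci")
})

test_that("round-trips preserve arbitrary valid genotype matrices", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:8, 1)
    L <- sample(1:4, 1)
    codes <- sample(100:400, 6)
    a1 <- matrix(sample(codes, n * L, replace = TRUE), n, L)
    a2 <- matrix(sample(codes, n * L, replace = TRUE), n, L)
    drop <- matrix(stats::runif(n * L) < 0.15, n, L)
    a1[drop] <- NA; a2[drop] <- NA
    if (all(is.na(a1))) next
    g <- genotype_matrix(a1, a2, pop = sample(c("x", "y"), n, replace = TRUE))
    ps <- withr::local_tempfile(); pg <- withr::local_tempfile()
    write_structure(g, ps)
    gs <- read_structure(ps, loci = g$loci)
    expect_equal(gs$a1, g$a1)
    expect_equal(gs$a2, g$a2)
    # GenePop canonicalizes individual order into population blocks
    canon <- subset_individuals(g, order(match(g$pop, unique(g$pop))))
    write_genepop(g, pg)
    gg <- read_genepop(pg)
    expect_equal(gg$a1, canon$a1, ignore_attr = TRUE)
    expect_equal(gg$a2, canon$a2, ignore_attr = TRUE)
    expect_equal(gg$ids, canon$ids)
  }
})

test_that("allele frequencies count gene copies correctly", {
  # group {AA, AB} at one locus -> p_A = 0.75, p_B = 0.25
  g <- genotype_matrix(rbind(1L, 1L), rbind(1L, 2L), pop = c("g", "g"))
  af <- allele_frequencies(g)
  expect_equal(unname(af$freq$g$L1), c(0.75, 0.25))
  expect_equal(af$n_copies[1, 1], 4L)
  # all calls missing at a locus -> undefined flag, no NaN leakage
  a1 <- rbind(c(1L, NA), c(1L, NA)); a2 <- rbind(c(1L, NA), c(2L, NA))
  g2 <- genotype_matrix(a1, a2, pop = c("g", "g"))
  af2 <- allele_frequencies(g2)
  expect_false(af2$defined[1, 2])
  expect_true(all(is.na(af2$freq$g$L2)))
  expect_false(any(is.nan(unlist(af2$freq$g$L1))))
  # empty group errors
  expect_error(allele_frequencies(g, grouping = c("a", NA)), "group")
})

test_that("gene-copy counts are conserved and frequencies normalized", {
  set.seed(7)
  pools <- simulate_parental_pools(sim_config(seed = 3))
  gA <- draw_pure_individuals(pools$A, 44, seed = 8, pop = "A")
  gB <- draw_pure_individuals(pools$B, 43, seed = 9, pop = "B")
  g <- bind_genotypes(gA, gB)
  af <- allele_frequencies(g)
  for (grp in af$groups) {
    n_grp <- sum(g$pop == grp)
    for (l in seq_along(af$loci)) {
      v <- af$freq[[grp]][[l]]
      expect_equal(sum(v), 1, tolerance = 1e-9)
      n_missing <- sum(is.na(g$a1[g$pop == grp, l]))
      expect_equal(af$n_copies[grp, l], 2L * (n_grp - n_missing))
    }
  }
})
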