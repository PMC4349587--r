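#' Simulation configuration for a two-species hybrid zone
#'
#' Defines the study conditions the simulator emulates: two parental gene
#' pools of controlled divergence (Balding-Nichols model), a microsatellite
#' panel, founder sample sizes and per-class genotype counts.
#'
#' Defaults mirror the study design this package targets: 10 microsatellite
#' loci, 10 alleles per locus in the joint pool (which realizes a mean of
#' about 4.7 observed alleles per locus within a sampled pure population,
#' matching the observed allelic richness of allopatric populations),
#' between-species differentiation around F_ST 0.29-0.37 (divergence
#' F = 0.33), founder panels of 44 and 43 pure individuals, and 50 simulated
#' genotypes per genealogical class.
#'
#' @param n_loci Number of independent loci.
#' @param alleles_per_locus Allele count per locus (scalar or per-locus
#'   vector).
#' @param divergence Balding-Nichols differentiation parameter F in \[0, 1).
#' @param founders Length-2 integer vector: pure individuals sampled per
#'   species (A, B).
#' @param class_sizes Named integer vector of genotypes per class; names from
#'   P1, P2, F1, F2, BC1J, BC1S, Fn.
#' @param fn_parents Length-2 character vector giving the parental classes
#'   whose gametes form an advanced-generation (Fn) hybrid (default F2 x F2).
#' @param seed Integer seed; all simulator randomness descends from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 10L, alleles_per_locus = 10L, divergence = 0.33,
                       founders = c(44L, 43L),
                       class_sizes = c(P1 = 50L, P2 = 50L, F1 = 50L,
                                       F2 = 50L, BC1J = 50L, BC1S = 50L),
                       fn_parents = c("F2", "F2"), seed = 1L) {
  if (!is.numeric(divergence) || divergence < 0 || divergence >= 1)
    stop("divergence F must lie in [0, 1)")
  if (any(alleles_per_locus < 1L)) stop("alleles_per_locus must be positive")
  if (length(alleles_per_locus) == 1L) alleles_per_locus <- rep(alleles_per_locus, n_loci)
  if (length(alleles_per_locus) != n_loci) stop("alleles_per_locus must be scalar or length n_loci")
  if (length(founders) != 2L || any(founders < 1L)) stop("founders must be two positive counts")
  valid <- c("P1", "P2", "F1", "F2", "BC1J", "BC1S", "Fn")
  if (is.null(names(class_sizes)) || !all(names(class_sizes) %in% valid))
    stop(sprintf("class names must be drawn from {%s}", paste(valid, collapse = ", ")))
  if (any(class_sizes < 0L)) stop("class sizes must be non-negative")
  structure(list(n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 divergence = divergence, founders = as.integer(founders),
                 class_sizes = class_sizes, fn_parents = fn_parents,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# internal Dirichlet draw
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1   # degenerate guard for tiny alpha
  x / sum(x)
}

#' Simulate divergent parental allele-frequency pools
#'
#' Draws, per locus, a common ancestral frequency vector from a symmetric
#' Dirichlet(1), then two descendant species pools via the Balding-Nichols
#' model: descendant ~ Dirichlet(p_anc * (1 - F) / F). F = 0 returns two
#' identical copies of the ancestral pool (no-drift limit).
#'
#' @param cfg A [sim_config()].
#' @return List with `A` and `B`: per-locus named frequency vectors (allele
#'   codes `101, 103, ...`), plus `expected_fst = F`.
#' @export
simulate_parental_pools <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$divergence >= 1) stop("divergence F = 1 is degenerate")
  set.seed(cfg$seed)
  L <- cfg$n_loci
  A <- B <- vector("list", L)
  names(A) <- names(B) <- paste0("L", seq_len(L))
  for (l in seq_len(L)) {
    nall <- cfg$alleles_per_locus[l]
    codes <- as.character(seq(101L, by = 2L, length.out = nall))
    anc <- .rdirichlet(rep(1, nall))
    if (cfg$divergence == 0) {
      pa <- pb <- anc
    } else {
      conc <- anc * (1 - cfg$divergence) / cfg$divergence
      pa <- .rdirichlet(conc)
      pb <- .rdirichlet(conc)
    }
    names(pa) <- names(pb) <- codes
    A[[l]] <- pa
    B[[l]] <- pb
  }
  list(A = A, B = B, expected_fst = cfg$divergence)
}

#' Draw pure individuals from one species pool
#'
#' Each individual draws two independent gene copies per locus from the
#' species frequency vector (Hardy-Weinberg, free recombination).
#'
#' @param freqs Per-locus frequency list for one species (as returned in
#'   `simulate_parental_pools()$A`), or a one-group [allele_frequencies()]
#'   table.
#' @param n Number of individuals (> 0).
#' @param seed Integer seed.
#' @param pop Population label for the drawn individuals.
#' @return A [genotype_matrix()].
#' @export
draw_pure_individuals <- function(freqs, n, seed = 1L, pop = "sim") {
  if (n <= 0) stop("n must be positive")
  fl <- .single_pool(freqs)
  set.seed(seed)
  L <- length(fl)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    p <- fl[[l]]
    codes <- as.integer(names(p))
    a1[, l] <- codes[sample.int(length(p), n, replace = TRUE, prob = p)]
    a2[, l] <- codes[sample.int(length(p), n, replace = TRUE, prob = p)]
  }
  genotype_matrix(a1, a2, pop = rep(pop, n), loci = names(fl))
}

#' Simulate genotypes of one genealogical class
#'
#' Gamete-distribution sampling per locus (free recombination, random
#' mating): a species-A gamete draws from the A pool, a species-B gamete
#' from the B pool, and an F1 gamete draws its origin A/B with probability
#' 1/2 per locus. Classes are composed as F1 = (A, B), F2 = (F1, F1),
#' BC1J = (A, F1), BC1S = (B, F1); Fn is the offspring of two configurable
#' hybrid-class parents (default F2 x F2, which shares the F2 gamete
#' marginal under free recombination). The latent per-locus origin pair of
#' every individual is recorded in attributes `origin1`/`origin2` ("A"/"B")
#' for use as a test oracle.
#'
#' @param freqsA,freqsB Per-locus frequency lists for the two species pools.
#' @param cls One of P1, P2, F1, F2, BC1J, BC1S, Fn.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param fn_parents Parental classes for Fn (used only when `cls = "Fn"`).
#' @return A [genotype_matrix()] with origin attributes.
#' @export
simulate_hybrid_class <- function(freqsA, freqsB, cls, n, seed = 1L,
                                  fn_parents = c("F2", "F2")) {
  gametes <- switch(cls,
    P1 = c("A", "A"), P2 = c("B", "B"), F1 = c("A", "B"),
    F2 = c("F1", "F1"), BC1J = c("A", "F1"), BC1S = c("B", "F1"),
    Fn = fn_parents,
    stop(sprintf("unknown genealogical class '%s'", cls)))
  if (n <= 0) stop("n must be positive")
  pools <- list(A = .single_pool(freqsA), B = .single_pool(freqsB))
  if (!identical(names(pools$A), names(pools$B)))
    stop("pools A and B must cover the same loci")
  set.seed(seed)
  L <- length(pools$A)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  o1 <- o2 <- matrix(NA_character_, n, L)
  draw_side <- function(origin) {
    # returns list(code, origin) per locus for one gamete
    o <- origin
    ores <- character(L); codes <- integer(L)
    for (l in seq_len(L)) {
      ol <- if (o %in% c("F1", "F2", "Fn")) (if (stats::runif(1) < 0.5) "A" else "B") else o
      p <- pools[[ol]][[l]]
      codes[l] <- as.integer(names(p))[sample.int(length(p), 1L, prob = p)]
      ores[l] <- ol
    }
    list(code = codes, origin = ores)
  }
  for (i in seq_len(n)) {
    s1 <- draw_side(gametes[1])
    s2 <- draw_side(gametes[2])
    a1[i, ] <- s1$code; a2[i, ] <- s2$code
    o1[i, ] <- s1$origin; o2[i, ] <- s2$origin
  }
  g <- genotype_matrix(a1, a2, pop = rep(cls, n), loci = names(pools$A),
                       ids = paste0(cls, "_", seq_len(n)))
  attr(g, "origin1") <- o1
  attr(g, "origin2") <- o2
  g
}

#' Simulate a mixed population with known class composition
#'
#' Concatenates simulated genotypes class by class (emulating the observed
#' mixed-population compositions of a hybrid zone) and returns the hidden
#' true class labels separately for downstream evaluation.
#'
#' @param freqsA,freqsB Species pools as in [simulate_hybrid_class()].
#' @param composition Named integer vector class -> count (classes with
#'   count 0 allowed).
#' @param seed Integer seed; per-class child seeds are derived from it.
#' @param pop Population label given to all simulated individuals.
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (character vector of true classes, one per individual, in order).
#' @export
simulate_mixed_population <- function(freqsA, freqsB, composition, seed = 1L,
                                      pop = "mix") {
  composition <- composition[composition > 0]
  if (!length(composition)) stop("composition must contain at least one individual")
  parts <- vector("list", length(composition))
  truth <- character(0)
  for (k in seq_along(composition)) {
    cls <- names(composition)[k]
    child_seed <- as.integer((as.numeric(seed) * 1009 + k * 9176) %% 2147483629)
    parts[[k]] <- simulate_hybrid_class(freqsA, freqsB, cls, composition[[k]],
                                        seed = child_seed)
    truth <- c(truth, rep(cls, composition[[k]]))
  }
  g <- bind_genotypes(parts)
  g$pop <- rep(pop, n_ind(g))
  g$ids <- paste0(pop, "_", seq_len(n_ind(g)))
  dimnames(g$a1)[[1]] <- dimnames(g$a2)[[1]] <- g$ids
  list(genotypes = g, truth = truth)
}
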