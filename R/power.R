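#' Simulation-based power study of the classification workflow
#'
#' End-to-end evaluation of how well the marker panel delineates hybrid
#' classes: (1) simulate two diverged parental pools and reference panels
#' of pure individuals; (2) run the admixture model at K = 2 and retain as
#' pure breeding pools only individuals with q > 0.90 in their own cluster
#' (screening out potential introgressants); (3) simulate genotypes of the
#' six genealogical classes from the retained pools; (4) assign them with
#' the six-category model at threshold Tq; (5) score efficiency, accuracy
#' and performance per class.
#'
#' @param cfg A [sim_config()]; its `founders` sizes the reference panels
#'   and `class_sizes` the simulated test set.
#' @param Tq Posterior threshold for acceptance of an assignment.
#' @param q_pure Admixture threshold for the pure-pool screen (default
#'   0.90).
#' @param admix_burn_in,admix_sweeps,nh_burn_in,nh_sweeps MCMC settings for
#'   the two samplers.
#' @param seed Integer seed; stage seeds are derived from it.
#' @return A list: `report` (from [evaluate_performance()]), `assignments`,
#'   `truth`, `n_pure` (retained panel sizes), `seeds`, `settings`.
#' @export
power_study <- function(cfg, Tq = 0.5, q_pure = 0.90,
                        admix_burn_in = 5000L, admix_sweeps = 20000L,
                        nh_burn_in = 5000L, nh_sweeps = 20000L,
                        seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- list(pools = cfg$seed, refA = seed + 101L, refB = seed + 202L,
                admix = seed + 303L, sim = seed + 404L, nh = seed + 505L)
  pools <- simulate_parental_pools(cfg)
  refA <- draw_pure_individuals(pools$A, cfg$founders[1], seed = seeds$refA, pop = "refA")
  refB <- draw_pure_individuals(pools$B, cfg$founders[2], seed = seeds$refB, pop = "refB")
  ref <- bind_genotypes(refA, refB)
  chain <- run_admixture(ref, K = 2L, burn_in = admix_burn_in,
                         sweeps = admix_sweeps, seed = seeds$admix)
  q <- orient_q(chain$q, anchor = which(ref$pop == "refA"))
  pureA <- which(ref$pop == "refA" & q[, 1] > q_pure)
  pureB <- which(ref$pop == "refB" & q[, 2] > q_pure)
  if (length(pureA) < 2L || length(pureB) < 2L)
    stop(sprintf("pure-pool screen (q > %.2f) retained too few individuals (A: %d, B: %d)",
                 q_pure, length(pureA), length(pureB)))
  poolA <- allele_frequencies(subset_individuals(ref, pureA))
  poolB <- allele_frequencies(subset_individuals(ref, pureB))
  flA <- poolA$freq[[1]]
  flB <- poolB$freq[[1]]
  # the two retained panels can observe different allele subsets; put both
  # pools on the union allele universe per locus so gametes share codes
  for (l in seq_along(flA)) {
    all_codes <- sort(unique(c(as.integer(names(flA[[l]])), as.integer(names(flB[[l]])))))
    expand <- function(v) {
      out <- stats::setNames(rep(0, length(all_codes)), as.character(all_codes))
      out[names(v)] <- v
      out
    }
    flA[[l]] <- expand(flA[[l]])
    flB[[l]] <- expand(flB[[l]])
  }
  comp <- cfg$class_sizes[cfg$class_sizes > 0]
  sim <- simulate_mixed_population(flA, flB, comp, seed = seeds$sim, pop = "sim")
  nh <- run_newhybrids(sim$genotypes, burn_in = nh_burn_in, sweeps = nh_sweeps,
                       seed = seeds$nh, anchor = which(sim$truth == "P1"))
  asg <- assign_class(nh, Tq = Tq)
  truth_final <- unname(c(P1 = "LJ", P2 = "LS", F1 = "F1", F2 = "F2",
                          BC1J = "BC1J", BC1S = "BC1S", Fn = "Fn")[sim$truth])
  assigned_final <- as.character(asg$class)
  mapped <- .class_map[assigned_final]
  assigned_final <- ifelse(is.na(mapped), assigned_final, unname(mapped))
  report <- evaluate_performance(truth_final, assigned_final)
  list(report = report,
       assignments = data.frame(individual = asg$individual,
                                truth = truth_final, assigned = assigned_final,
                                posterior = asg$posterior,
                                stringsAsFactors = FALSE),
       truth = truth_final,
       n_pure = c(A = length(pureA), B = length(pureB)),
       seeds = seeds,
       settings = list(Tq = Tq, q_pure = q_pure,
                       admix = c(admix_burn_in, admix_sweeps),
                       newhybrids = c(nh_burn_in, nh_sweeps)))
}
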