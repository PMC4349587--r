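#' Full hybrid-zone analysis report
#'
#' Orchestrates the complete workflow on one genotype data set: diversity
#' summary, pairwise F_ST, individual Nei D_A distances with principal
#' coordinates, admixture inference over a K range with Evanno delta-K and
#' replicate averaging, six-category assignment, composite classification,
#' population composition and per-population dip tests. Optionally writes
#' all tables as CSV plus a JSON-like run manifest that allows an identical
#' re-run.
#'
#' @param g A [genotype_matrix()].
#' @param config A list; required key `anchor_population` (population
#'   label(s) whose individuals anchor the species-A cluster). Optional
#'   keys with defaults: `k_range` (1:4), `replicates` (3), `burn_in`
#'   (2000), `sweeps` (8000), `nh_burn_in` (2000), `nh_sweeps` (8000),
#'   `Tq` (0.5), `n_perm` (200), `dip_boot` (2000), `alpha` (0.05),
#'   `seed` (1).
#' @param out_dir Optional output directory for CSV artifacts.
#' @return A list with all stage results and `manifest`.
#' @export
hybrid_zone_report <- function(g, config = list(), out_dir = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  required <- "anchor_population"
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys))
    stop(sprintf("missing config key: %s", paste(missing_keys, collapse = ", ")))
  defaults <- list(k_range = 1:4, replicates = 3L, burn_in = 2000L,
                   sweeps = 8000L, nh_burn_in = 2000L, nh_sweeps = 8000L,
                   Tq = 0.5, n_perm = 200L, dip_boot = 2000L, alpha = 0.05,
                   seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  if (!any(g$pop %in% cfg$anchor_population))
    stop(sprintf("anchor_population '%s' matches no individuals",
                 paste(cfg$anchor_population, collapse = ",")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  diversity <- stage("diversity", diversity_summary(g))
  fst <- stage("fst", pairwise_fst(g, n_perm = cfg$n_perm, seed = cfg$seed))
  da <- stage("distance", nei_da_individuals(g))
  ord <- stage("pcoa", {
    d <- da
    if (any(is.na(d))) stop("undefined D_A pairs; remove untyped individuals first")
    pcoa(d)
  })
  chains <- stage("admixture", {
    out <- list()
    for (K in cfg$k_range)
      for (r in seq_len(cfg$replicates))
        out[[length(out) + 1L]] <- run_admixture(
          g, K = K, burn_in = cfg$burn_in, sweeps = cfg$sweeps,
          seed = cfg$seed + 1000L * K + r)
    out
  })
  ksel <- stage("select_k", select_k(chains))
  k2 <- chains[vapply(chains, function(ch) ch$K, 1L) == 2L]
  qavg <- stage("align", {
    if (!length(k2)) stop("K = 2 not in k_range")
    align_replicates(lapply(k2, `[[`, "q"))
  })
  q <- orient_q(qavg, anchor = which(g$pop %in% cfg$anchor_population))
  nh <- stage("newhybrids", run_newhybrids(
    g, burn_in = cfg$nh_burn_in, sweeps = cfg$nh_sweeps, seed = cfg$seed + 77L,
    anchor = which(g$pop %in% cfg$anchor_population)))
  records <- stage("classification", classify_all(q[, 1], nh, Tq = cfg$Tq, ids = g$ids))
  comp <- stage("composition", population_composition(
    records, q[, 1], g$pop, alpha = cfg$alpha, n_boot = cfg$dip_boot,
    seed = cfg$seed + 99L))
  manifest <- list(settings = cfg, n_individuals = n_ind(g),
                   n_loci = n_loci(g), populations = table(g$pop),
                   package_version = as.character(utils::packageVersion("hybridzone")))
  res <- list(diversity = diversity, fst = fst, distance = da, pcoa = ord,
              k_selection = ksel, q = q, newhybrids = nh, records = records,
              composition = comp, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(diversity, file.path(out_dir, "diversity.csv"), row.names = FALSE)
    utils::write.csv(fst$theta, file.path(out_dir, "fst_theta.csv"))
    utils::write.csv(fst$p_value, file.path(out_dir, "fst_p.csv"))
    utils::write.csv(ord$coordinates, file.path(out_dir, "pcoa_coordinates.csv"))
    utils::write.csv(ksel, file.path(out_dir, "k_selection.csv"), row.names = FALSE)
    utils::write.csv(data.frame(individual = g$ids, population = g$pop, q),
                     file.path(out_dir, "admixture_q.csv"), row.names = FALSE)
    utils::write.csv(data.frame(individual = g$ids, nh$posterior),
                     file.path(out_dir, "newhybrids_posterior.csv"), row.names = FALSE)
    utils::write.csv(records, file.path(out_dir, "classification.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(comp$counts), file.path(out_dir, "composition.csv"))
    utils::write.csv(comp$dip, file.path(out_dir, "dip_tests.csv"), row.names = FALSE)
    dput(manifest, file.path(out_dir, "manifest.R"))
  }
  res
}
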