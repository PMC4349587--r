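#' Final hybrid-zone categories
#'
#' The nine reporting categories of the composite classification: the two
#' pure species (LJ, LS), first- and second-generation hybrids (F1, F2),
#' advanced-generation hybrids (Fn), first-generation backcrosses (BC1J,
#' BC1S) and later-generation backcrosses (BCJ, BCS).
#' @export
hz_categories <- function() {
  c("LJ", "LS", "F1", "F2", "Fn", "BC1J", "BC1S", "BCJ", "BCS")
}

# six-class sampler category -> final reporting category
.class_map <- c(P1 = "LJ", P2 = "LS", F1 = "F1", F2 = "F2",
                BC1 = "BC1J", BC2 = "BC1S")

#' Composite classification of one individual
#'
#' The decision procedure combining the admixture proportion q1 with the
#' six-category posterior. Rules fire in order: (1) q1 >= 0.9 -> LJ;
#' (2) q1 <= 0.1 -> LS; (3) otherwise the individual is of hybrid origin:
#' if the maximum category posterior reaches Tq the winning category is
#' used (P1/P2 winners map to LJ/LS with a conflict flag, since the two
#' signals disagree); (4) otherwise the individual is taken as a
#' later-generation hybrid and binned by q1: (0.7, 0.9) -> BCJ (backcross
#' toward species A), (0.1, 0.3) -> BCS, [0.3, 0.7] -> Fn. Pure thresholds
#' are inclusive and the Fn band closed, making the rule set total on
#' q1 in [0, 1].
#'
#' @param q1 Admixture proportion toward the species-A cluster, in \[0, 1\].
#' @param post Named six-category posterior vector (names P1, P2, F1, F2,
#'   BC1, BC2), or a row of a posterior matrix.
#' @param Tq Posterior threshold (default 0.5).
#' @return A one-row data.frame: `q1`, `nh_class`, `nh_posterior`, `final`,
#'   `rule` (which rule fired), `conflict` (STRUCTURE-pure signal vs
#'   six-class winner disagreement).
#' @export
classify_individual <- function(q1, post, Tq = 0.5) {
  if (is.na(q1) || q1 < 0 || q1 > 1) stop("q1 must lie in [0, 1]")
  post <- unlist(post)[c("P1", "P2", "F1", "F2", "BC1", "BC2")]
  mx <- max(post)
  tie <- sum(post == mx) > 1L
  win <- names(post)[which.max(post)]
  rec <- function(final, rule, conflict = FALSE)
    data.frame(q1 = q1, nh_class = win, nh_posterior = mx, final = final,
               rule = rule, conflict = conflict, stringsAsFactors = FALSE)
  if (q1 >= 0.9) return(rec("LJ", "q1_pure_A"))
  if (q1 <= 0.1) return(rec("LS", "q1_pure_B"))
  if (mx >= Tq && !tie) {
    final <- .class_map[[win]]
    conflict <- win %in% c("P1", "P2")
    return(rec(final, "six_class_posterior", conflict))
  }
  if (q1 > 0.7) return(rec("BCJ", "fallback_backcross_A"))
  if (q1 < 0.3) return(rec("BCS", "fallback_backcross_B"))
  rec("Fn", "fallback_advanced_generation")
}

#' Classify all individuals
#'
#' Vectorized wrapper around [classify_individual()].
#'
#' @param q1 Vector of admixture proportions.
#' @param post A `hybrid_class_posterior` or an n x 6 posterior matrix
#'   aligned with `q1`.
#' @param Tq Posterior threshold.
#' @param ids Optional individual IDs.
#' @return A data.frame of classification records, one row per individual.
#' @export
classify_all <- function(q1, post, Tq = 0.5, ids = NULL) {
  m <- if (inherits(post, "hybrid_class_posterior")) post$posterior else as.matrix(post)
  if (length(q1) != nrow(m)) stop("q1 and posterior dimensions disagree")
  recs <- do.call(rbind, lapply(seq_along(q1), function(i)
    classify_individual(q1[i], m[i, ], Tq)))
  recs$individual <- ids %||% rownames(m) %||% as.character(seq_along(q1))
  recs[, c("individual", setdiff(names(recs), "individual"))]
}

#' Population composition and modality
#'
#' Tabulates final categories per population, groups them into parental
#' genotypes (the pure categories and all backcross categories, early and
#' later generation) versus intermediate genotypes (F1, F2 and Fn), and
#' tests the modality of each population's q1 distribution with the dip
#' test.
#'
#' @param records Classification records from [classify_all()].
#' @param q1 Admixture proportions aligned with `records`.
#' @param pop Population labels aligned with `records`.
#' @param alpha Significance level for the dip verdict (default 0.05).
#' @param n_boot,seed Dip-test Monte Carlo settings.
#' @return A list: `counts` (population x category table incl. Total),
#'   `grouping` (per population: parental, intermediate, total), `dip`
#'   (per population: D, p, verdict).
#' @export
population_composition <- function(records, q1, pop, alpha = 0.05,
                                   n_boot = 2000L, seed = 1L) {
  if (nrow(records) != length(q1) || length(q1) != length(pop))
    stop("records, q1 and pop must align")
  cats <- hz_categories()
  pops <- unique(pop)
  counts <- t(vapply(pops, function(p)
    table(factor(records$final[pop == p], levels = cats)), integer(length(cats))))
  counts <- cbind(counts, Total = rowSums(counts))
  intermediate_cats <- c("F1", "F2", "Fn")
  grouping <- data.frame(
    population = pops,
    parental = rowSums(counts[, setdiff(cats, intermediate_cats), drop = FALSE]),
    intermediate = rowSums(counts[, intermediate_cats, drop = FALSE]),
    total = counts[, "Total"], row.names = NULL, stringsAsFactors = FALSE)
  dip <- do.call(rbind, lapply(pops, function(p) {
    x <- q1[pop == p]
    if (length(x) < 4L)
      return(data.frame(population = p, D = NA_real_, p_value = NA_real_,
                        bimodal = NA, stringsAsFactors = FALSE))
    dt <- dip_test(x, n_boot = n_boot, seed = seed)
    data.frame(population = p, D = dt$D, p_value = dt$p_value,
               bimodal = dt$p_value < alpha, stringsAsFactors = FALSE)
  }))
  list(counts = counts, grouping = grouping, dip = dip)
}

#' Assignment performance (efficiency, accuracy, performance)
#'
#' Per true class: efficiency is the proportion of true members assigned to
#' the class (recall), accuracy the proportion of individuals assigned to
#' the class that truly belong to it (precision), and performance their
#' product. Accuracy is undefined (NA) for a class to which nobody was
#' assigned.
#'
#' @param truth Character vector of true class labels.
#' @param assigned Character vector of assigned labels (may include
#'   "unassigned").
#' @return A list: `metrics` (data.frame per true class) and `confusion`
#'   (truth x assigned table).
#' @export
evaluate_performance <- function(truth, assigned) {
  truth <- as.character(truth)
  assigned <- as.character(assigned)
  if (!length(truth)) stop("empty labelings")
  if (length(truth) != length(assigned)) stop("truth and assigned must have equal length")
  classes <- unique(truth)
  lev <- unique(c(classes, unique(assigned)))
  confusion <- table(truth = factor(truth, levels = classes),
                     assigned = factor(assigned, levels = lev))
  metrics <- do.call(rbind, lapply(classes, function(cl) {
    n_true <- sum(truth == cl)
    n_assigned <- sum(assigned == cl)
    correct <- sum(truth == cl & assigned == cl)
    eff <- correct / n_true
    acc <- if (n_assigned == 0L) NA_real_ else correct / n_assigned
    data.frame(class = cl, n_true = n_true, n_assigned = n_assigned,
               efficiency = eff, accuracy = acc,
               performance = eff * acc, stringsAsFactors = FALSE)
  }))
  list(metrics = metrics, confusion = confusion)
}
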