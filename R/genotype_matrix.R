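#' Diploid multilocus genotype container
#'
#' A `genotype_matrix` holds unordered diploid genotypes for a set of
#' individuals at a set of codominant loci (microsatellites). Allele calls are
#' integer codes (typically fragment sizes); missing calls are `NA` in both
#' allele slots. Codominant markers carry no phase, so the order of the two
#' allele slots is not meaningful.
#'
#' @param a1,a2 Integer matrices (individuals x loci) with the two allele
#'   calls per genotype. `NA` marks a missing call; a call must be missing in
#'   both slots or in neither.
#' @param pop Character vector of per-individual population labels.
#' @param ids Optional character vector of individual IDs (default `ind1..n`).
#' @param loci Optional character vector of locus names (default `L1..L`).
#' @return An object of class `genotype_matrix` with elements `a1`, `a2`
#'   (integer matrices), `ids`, `pop`, `loci`, and `alleles` (a list, per
#'   locus, of the sorted distinct allele codes observed).
#' @export
genotype_matrix <- function(a1, a2, pop, ids = NULL, loci = NULL) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2))) stop("a1 and a2 must have identical dimensions")
  n <- nrow(a1)
  L <- ncol(a1)
  if (n == 0L || L == 0L) stop("genotype matrix must contain at least one individual and one locus")
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  pop <- as.character(pop)
  if (length(pop) != n) stop("pop must have one label per individual")
  if (any(is.na(pop)) || any(!nzchar(pop))) stop("population labels must be non-empty")
  if (length(ids) != n) stop("ids must have one entry per individual")
  if (length(loci) != L) stop("loci must have one name per locus")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1L, ]
    stop(sprintf("half-missing call for individual %s at locus %s: both allele slots must be missing or neither",
                 ids[bad[1L]], loci[bad[2L]]))
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  alleles <- lapply(seq_len(L), function(l) sort(unique(c(a1[, l], a2[, l])[!is.na(c(a1[, l], a2[, l]))])))
  names(alleles) <- loci
  structure(list(a1 = a1, a2 = a2, ids = ids, pop = pop, loci = loci, alleles = alleles),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d population(s)\n",
              n_ind(x), n_loci(x), length(unique(x$pop))))
  na <- vapply(x$alleles, length, 1L)
  cat(sprintf("  alleles/locus: %s (mean %.2f)\n", paste(range(na), collapse = "-"), mean(na)))
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci
#' @param g A `genotype_matrix`.
#' @export
n_ind <- function(g) nrow(g$a1)

#' @rdname n_ind
#' @export
n_loci <- function(g) ncol(g$a1)

#' Validate a genotype matrix
#'
#' Checks structural invariants: matching dimensions, non-empty population
#' labels, every non-missing call registered in its locus's allele set, and
#' flags (without dropping) individuals missing more than half of their loci.
#'
#' @param g A `genotype_matrix`.
#' @return Invisibly, a list with `high_missing` (IDs of individuals with
#'   >50% missing loci). Errors on structural violations.
#' @export
validate_genotype_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  for (l in seq_len(n_loci(g))) {
    obs <- c(g$a1[, l], g$a2[, l])
    obs <- obs[!is.na(obs)]
    if (!all(obs %in% g$alleles[[l]]))
      stop(sprintf("unregistered allele code at locus %s", g$loci[l]))
  }
  miss_frac <- rowMeans(is.na(g$a1))
  high <- g$ids[miss_frac > 0.5]
  if (length(high))
    warning(sprintf("%d individual(s) with >50%% missing loci: %s",
                    length(high), paste(high, collapse = ", ")))
  invisible(list(high_missing = high))
}

#' Subset individuals of a genotype matrix
#' @param g A `genotype_matrix`.
#' @param idx Integer or logical index over individuals.
#' @export
subset_individuals <- function(g, idx) {
  genotype_matrix(g$a1[idx, , drop = FALSE], g$a2[idx, , drop = FALSE],
                  pop = g$pop[idx], ids = g$ids[idx], loci = g$loci)
}

#' Row-bind genotype matrices sharing the same loci
#' @param ... `genotype_matrix` objects with identical locus names.
#' @export
bind_genotypes <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && !inherits(gs[[1]], "genotype_matrix")) gs <- gs[[1]]
  loci <- gs[[1]]$loci
  for (g in gs) if (!identical(g$loci, loci)) stop("all genotype matrices must share the same loci")
  ids <- unlist(lapply(gs, `[[`, "ids"))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  genotype_matrix(do.call(rbind, lapply(gs, `[[`, "a1")),
                  do.call(rbind, lapply(gs, `[[`, "a2")),
                  pop = unlist(lapply(gs, `[[`, "pop")), ids = ids, loci = loci)
}

#' Tidy long-format export
#'
#' Canonical internal export: one row per individual x locus with both allele
#' calls (NA when missing).
#'
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @export
as.data.frame.genotype_matrix <- function(x, ...) {
  n <- n_ind(x); L <- n_loci(x)
  data.frame(individual = rep(x$ids, times = L),
             population = rep(x$pop, times = L),
             locus = rep(x$loci, each = n),
             allele1 = as.vector(x$a1),
             allele2 = as.vector(x$a2),
             stringsAsFactors = FALSE)
}

#' Per-group allele frequencies
#'
#' Computes per-group, per-locus allele frequency vectors from non-missing
#' gene copies. This is the shared kernel parameterizing all model likelihoods
#' in the package.
#'
#' @param g A `genotype_matrix`.
#' @param grouping Per-individual group labels (defaults to population
#'   labels). Every individual must be mapped; every group must be non-empty.
#' @return An `allele_freq_table`: list with `groups`, `loci`, `alleles`
#'   (per-locus allele codes), `freq` (list\[group\]\[locus\] of named
#'   frequency vectors; `NA` vector where a group has zero observed copies),
#'   `n_copies` (group x locus matrix of gene copies counted) and `defined`
#'   (logical group x locus matrix).
#' @export
allele_frequencies <- function(g, grouping = g$pop) {
  grouping <- as.character(grouping)
  if (length(grouping) != n_ind(g)) stop("grouping must map every individual to a group")
  if (any(is.na(grouping))) stop("grouping must map every individual to a group")
  groups <- unique(grouping)
  if (any(!nzchar(groups))) stop("group labels must be non-empty")
  L <- n_loci(g)
  freq <- vector("list", length(groups))
  names(freq) <- groups
  n_copies <- matrix(0L, length(groups), L, dimnames = list(groups, g$loci))
  for (gi in seq_along(groups)) {
    idx <- grouping == groups[gi]
    if (!any(idx)) stop(sprintf("group %s has zero individuals", groups[gi]))
    fl <- vector("list", L)
    names(fl) <- g$loci
    for (l in seq_len(L)) {
      al <- g$alleles[[l]]
      copies <- c(g$a1[idx, l], g$a2[idx, l])
      copies <- copies[!is.na(copies)]
      n_copies[gi, l] <- length(copies)
      if (length(copies) == 0L) {
        v <- rep(NA_real_, length(al))
      } else {
        v <- as.numeric(tabulate(match(copies, al), nbins = length(al))) / length(copies)
      }
      names(v) <- as.character(al)
      fl[[l]] <- v
    }
    freq[[gi]] <- fl
  }
  structure(list(groups = groups, loci = g$loci, alleles = g$alleles,
                 freq = freq, n_copies = n_copies, defined = n_copies > 0L),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d group(s) x %d loci\n", length(x$groups), length(x$loci)))
  invisible(x)
}

# Single-group frequency list (list over loci of frequency vectors), used by
# the simulators. Accepts an allele_freq_table with one group or a plain list.
.single_pool <- function(freqs, group = NULL) {
  if (inherits(freqs, "allele_freq_table")) {
    if (is.null(group)) {
      if (length(freqs$groups) != 1L) stop("an allele_freq_table with multiple groups needs `group`")
      group <- freqs$groups[1L]
    }
    fl <- freqs$freq[[group]]
  } else {
    fl <- freqs
  }
  if (any(vapply(fl, function(v) any(is.na(v)), TRUE)))
    stop("pool has undefined frequencies at one or more loci")
  fl
}
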