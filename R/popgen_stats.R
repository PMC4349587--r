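#' Per-population diversity summary
#'
#' For each population: mean number of alleles per locus (N_a), observed
#' heterozygosity (H_O, fraction of heterozygotes among non-missing calls),
#' expected heterozygosity (H_E = 1 - sum p^2 from within-population allele
#' frequencies) and the fixation index F_IS. Population values are means
#' over loci; the accompanying spread is the across-locus standard error
#' (sd / sqrt(L); switchable to sd).
#'
#' @param g A [genotype_matrix()].
#' @param unbiased_he If `TRUE`, apply the small-sample correction
#'   `2n/(2n-1)` to H_E per locus. Default `FALSE` (plain 1 - sum p^2).
#' @param fis One of `"wc"` (Weir-Cockerham within-population f, the
#'   default) or `"genalex"` (the calculator-style (H_E - H_O) / H_E,
#'   averaged over loci).
#' @param spread `"se"` (default) or `"sd"` for the across-locus spread.
#' @return A data.frame with one row per population: `population`, `n`,
#'   `Na`, `Na_se`, `Ho`, `Ho_se`, `He`, `He_se`, `Fis`.
#' @export
diversity_summary <- function(g, unbiased_he = FALSE, fis = c("wc", "genalex"),
                              spread = c("se", "sd")) {
  fis <- match.arg(fis)
  spread <- match.arg(spread)
  pops <- unique(g$pop)
  L <- n_loci(g)
  sp <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    s <- stats::sd(v)
    if (spread == "se") s / sqrt(length(v)) else s
  }
  out <- lapply(pops, function(p) {
    idx <- g$pop == p
    na <- ho <- he <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      x1 <- g$a1[idx, l]; x2 <- g$a2[idx, l]
      ok <- !is.na(x1)
      if (!any(ok)) next
      copies <- c(x1[ok], x2[ok])
      tab <- table(copies)
      pfreq <- as.numeric(tab) / length(copies)
      na[l] <- length(tab)
      ho[l] <- mean(x1[ok] != x2[ok])
      he[l] <- 1 - sum(pfreq^2)
      if (unbiased_he) {
        nn <- length(copies)
        he[l] <- he[l] * nn / (nn - 1)
      }
    }
    f <- if (fis == "wc") {
      fw <- tryCatch(fis_weir_cockerham(g, p), error = function(e) NULL)
      if (is.null(fw)) NA_real_ else fw$multilocus
    } else {
      valid <- !is.na(he) & he > 0
      if (!any(valid)) NA_real_ else mean((he[valid] - ho[valid]) / he[valid])
    }
    data.frame(population = p, n = sum(idx),
               Na = mean(na, na.rm = TRUE), Na_se = sp(na),
               Ho = mean(ho, na.rm = TRUE), Ho_se = sp(ho),
               He = mean(he, na.rm = TRUE), He_se = sp(he),
               Fis = f, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Weir-Cockerham variance components for one locus across r populations.
# Returns per-allele a, b, c components (rows: alleles).
# p_mat: r x A allele-frequency matrix; h_mat: r x A observed-heterozygote
# proportions involving each allele; nvec: individuals genotyped per pop.
.wc_components <- function(p_mat, h_mat, nvec) {
  r <- nrow(p_mat)
  nbar <- mean(nvec)
  if (nbar <= 1) return(NULL)
  if (r > 1) {
    nc <- (r * nbar - sum(nvec^2) / (r * nbar)) / (r - 1)
  } else {
    nc <- nbar
  }
  A <- ncol(p_mat)
  comp <- matrix(NA_real_, A, 3, dimnames = list(colnames(p_mat), c("a", "b", "c")))
  for (al in seq_len(A)) {
    p <- p_mat[, al]
    h <- h_mat[, al]
    pbar <- sum(nvec * p) / (r * nbar)
    hbar <- sum(nvec * h) / (r * nbar)
    if (r > 1) {
      s2 <- sum(nvec * (p - pbar)^2) / ((r - 1) * nbar)
      a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
             (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
             ((2 * nbar - 1) / (4 * nbar)) * hbar)
    } else {
      a <- 0
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
             ((2 * nbar - 1) / (4 * nbar)) * hbar)
    }
    cc <- hbar / 2
    comp[al, ] <- c(a, b, cc)
  }
  comp
}

# per-locus W&C components for a subset of individuals split by pop factor
.wc_locus <- function(a1, a2, popf) {
  pops <- levels(popf)
  ok <- !is.na(a1)
  if (sum(ok) < 2L) return(NULL)
  alleles <- sort(unique(c(a1[ok], a2[ok])))
  r <- length(pops)
  p_mat <- h_mat <- matrix(0, r, length(alleles),
                           dimnames = list(pops, as.character(alleles)))
  nvec <- numeric(r)
  for (pi in seq_len(r)) {
    sel <- popf == pops[pi] & ok
    nvec[pi] <- sum(sel)
    if (nvec[pi] == 0) next
    copies <- c(a1[sel], a2[sel])
    p_mat[pi, ] <- tabulate(match(copies, alleles), nbins = length(alleles)) /
      length(copies)
    het <- a1[sel] != a2[sel]
    for (al in seq_along(alleles)) {
      h_al <- het & (a1[sel] == alleles[al] | a2[sel] == alleles[al])
      h_mat[pi, al] <- mean(h_al)
    }
  }
  if (any(nvec < 1)) return(NULL)
  .wc_components(p_mat, h_mat, nvec)
}

#' Weir-Cockerham inbreeding coefficient (f) for one population
#'
#' Estimates the within-population inbreeding coefficient F_IS via the
#' Weir-Cockerham variance components b (among individuals within
#' populations) and c (within individuals): f = 1 - sum(c) / sum(b + c),
#' with components summed over alleles (per locus) and over loci (multilocus
#' estimate). Loci with undefined components (fewer than two genotyped
#' individuals, or monomorphic so that b + c = 0) are skipped and reported.
#'
#' @param g A [genotype_matrix()].
#' @param population Population label to estimate for.
#' @return List with `per_locus` (named numeric, NA where undefined),
#'   `multilocus` (scalar f), and `skipped` (locus names).
#' @export
fis_weir_cockerham <- function(g, population) {
  idx <- g$pop == population
  if (!any(idx)) stop(sprintf("no individuals in population '%s'", population))
  popf <- factor(rep(population, sum(idx)))
  per <- rep(NA_real_, n_loci(g))
  names(per) <- g$loci
  Bsum <- Csum <- 0
  any_def <- FALSE
  for (l in seq_len(n_loci(g))) {
    comp <- .wc_locus(g$a1[idx, l], g$a2[idx, l], popf)
    if (is.null(comp)) next
    b <- sum(comp[, "b"]); cc <- sum(comp[, "c"])
    if (b + cc <= 0) next
    per[l] <- 1 - cc / (b + cc)
    Bsum <- Bsum + b; Csum <- Csum + cc
    any_def <- TRUE
  }
  if (!any_def) stop(sprintf("F_IS undefined at every locus for population '%s'", population))
  list(per_locus = per, multilocus = 1 - Csum / (Bsum + Csum),
       skipped = names(per)[is.na(per)])
}

#' Pairwise Weir-Cockerham theta (F_ST) with permutation tests
#'
#' Multilocus theta per population pair (variance components summed over
#' alleles and loci), with p-values from permutations of whole multilocus
#' individuals between the two populations: p = (1 + #\{theta_perm >=
#' theta_obs\}) / (n_perm + 1).
#'
#' @param g A [genotype_matrix()] with at least two populations.
#' @param n_perm Number of permutations (0 to skip testing).
#' @param seed Integer seed for the permutations.
#' @return List with `theta` (symmetric matrix, NA diagonal) and `p_value`
#'   (matrix, NA when `n_perm = 0`).
#' @export
pairwise_fst <- function(g, n_perm = 1000L, seed = 1L) {
  pops <- unique(g$pop)
  if (length(pops) < 2L) stop("pairwise F_ST needs at least two populations")
  sizes <- table(g$pop)
  if (any(sizes < 2L))
    stop(sprintf("population(s) with fewer than 2 individuals: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  theta_pair <- function(idx, popf) {
    Asum <- Tsum <- 0
    for (l in seq_len(n_loci(g))) {
      comp <- .wc_locus(g$a1[idx, l], g$a2[idx, l], popf)
      if (is.null(comp)) next
      Asum <- Asum + sum(comp[, "a"])
      Tsum <- Tsum + sum(comp)
    }
    if (Tsum == 0) return(NA_real_)
    Asum / Tsum
  }
  P <- length(pops)
  th <- pv <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  set.seed(seed)
  for (i in seq_len(P - 1L)) for (j in seq((i + 1L), P)) {
    idx <- which(g$pop %in% pops[c(i, j)])
    popf <- factor(g$pop[idx], levels = pops[c(i, j)])
    obs <- theta_pair(idx, popf)
    th[i, j] <- th[j, i] <- obs
    if (n_perm > 0L && !is.na(obs)) {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample(popf)
        tp <- theta_pair(idx, perm)
        if (!is.na(tp) && tp >= obs) hits <- hits + 1L
      }
      pv[i, j] <- pv[j, i] <- (hits + 1L) / (n_perm + 1L)
    }
  }
  list(theta = th, p_value = pv)
}

#' Nei's D_A genetic distance between individuals
#'
#' Individual allele "frequencies" per locus are 0, 0.5 or 1. For a pair of
#' individuals, D_A = 1 - (1/L') sum over shared non-missing loci of the sum
#' over alleles of sqrt(x_a * y_a). Pairs sharing no typed locus are flagged
#' undefined (NA).
#'
#' @param g A [genotype_matrix()] with at least two individuals.
#' @return A symmetric matrix (zero diagonal) with attribute `undefined`
#'   listing index pairs with no shared typed loci.
#' @export
nei_da_individuals <- function(g) {
  n <- n_ind(g)
  if (n < 2L) stop("need at least two individuals")
  L <- n_loci(g)
  # per-locus contribution sum_a sqrt(x_a y_a): with individual frequencies
  # in {0, 0.5, 1} this is tcrossprod of the per-locus sqrt-frequency matrix
  sim <- matrix(0, n, n)
  shared <- matrix(0, n, n)
  for (l in seq_len(L)) {
    x1 <- g$a1[, l]; x2 <- g$a2[, l]
    ok <- !is.na(x1)
    if (sum(ok) < 2L) next
    al <- g$alleles[[l]]
    Xs <- matrix(0, n, length(al))
    hom <- ok & x1 == x2
    het <- ok & x1 != x2
    Xs[cbind(which(hom), match(x1[hom], al))] <- 1
    Xs[cbind(which(het), match(x1[het], al))] <- sqrt(0.5)
    Xs[cbind(which(het), match(x2[het], al))] <- sqrt(0.5)
    sim <- sim + tcrossprod(Xs)
    shared <- shared + tcrossprod(as.numeric(ok))
  }
  d <- 1 - sim / shared
  d[shared == 0L] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(g$ids, g$ids)
  und <- which(upper.tri(d) & is.na(d), arr.ind = TRUE)
  attr(d, "undefined") <- und
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling (Gower double-centering of -D^2/2 followed by
#' eigendecomposition, via [stats::cmdscale()]). Axes are ordered by
#' eigenvalue; percent variance is computed over the positive eigenvalues
#' only, and negative eigenvalues are dropped and reported.
#'
#' @param d Symmetric distance matrix with zero diagonal (NA entries are not
#'   allowed; drop undefined pairs first).
#' @param k Number of axes to return (default all positive-eigenvalue axes).
#' @param lingoes If `TRUE`, apply the Lingoes additive correction for
#'   non-Euclidean distance matrices before scaling.
#' @return List with `coordinates` (n x k), `eigenvalues`,
#'   `percent_variance` (over positive eigenvalues), and `n_negative`.
#' @export
pcoa <- function(d, k = NULL, lingoes = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8, na.rm = TRUE))
    stop("distance matrix must be symmetric")
  if (any(is.na(d))) stop("distance matrix contains NA (undefined) entries")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  n <- nrow(d)
  # all axes are requested and the non-positive ones dropped afterwards, so
  # cmdscale's note about fewer positive eigenvalues is expected
  full <- withCallingHandlers(
    stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE, add = lingoes),
    warning = function(w) {
      if (grepl("eigenvalues are > 0", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ev <- full$eig
  pos <- ev > 1e-9 * max(abs(ev))
  if (is.null(k)) k <- sum(pos)
  k <- min(k, sum(pos))
  coords <- full$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(k))
  list(coordinates = coords,
       eigenvalues = ev,
       percent_variance = 100 * ev[pos] / sum(ev[pos]),
       n_negative = sum(ev < -1e-9 * max(abs(ev))))
}
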