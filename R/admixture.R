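# encode allele calls as 0-based indices per locus; loci without any
# observed call are dropped with a warning
.encode_alleles <- function(g) {
  keep <- vapply(g$alleles, length, 1L) > 0L
  if (!all(keep))
    warning(sprintf("dropping %d locus/loci with no observed calls: %s",
                    sum(!keep), paste(g$loci[!keep], collapse = ", ")))
  loci <- which(keep)
  L <- length(loci)
  n <- n_ind(g)
  e1 <- e2 <- matrix(-1L, n, L)
  nall <- integer(L)
  for (j in seq_along(loci)) {
    l <- loci[j]
    al <- g$alleles[[l]]
    nall[j] <- length(al)
    idx1 <- match(g$a1[, l], al) - 1L
    idx2 <- match(g$a2[, l], al) - 1L
    idx1[is.na(idx1)] <- -1L
    idx2[is.na(idx2)] <- -1L
    e1[, j] <- idx1
    e2[, j] <- idx2
  }
  list(g1 = e1, g2 = e2, n_alleles = nall, loci = g$loci[loci])
}

#' Bayesian admixture inference (Gibbs sampler)
#'
#' Fits the admixture model with independent allele frequencies: each gene
#' copy carries a latent cluster-of-origin indicator; cluster allele
#' frequencies have independent Dirichlet(lambda) priors; individual
#' admixture proportions q have a symmetric Dirichlet(alpha) prior with the
#' scalar alpha itself inferred (uniform prior on (0, alpha_max],
#' random-walk Metropolis). No prior population information is used.
#'
#' @param g A [genotype_matrix()].
#' @param K Number of clusters (>= 1).
#' @param burn_in,sweeps MCMC burn-in and retained sweeps. Defaults are the
#'   study-scale settings (50000/100000); a desk-scale profile (e.g.
#'   5000/20000) is adequate for the simulated data sizes used in the
#'   package tests and analysis scripts.
#' @param seed Integer seed.
#' @param lambda Dirichlet prior parameter for cluster allele frequencies.
#' @param alpha_max,alpha_sd Upper bound of the uniform alpha prior and the
#'   Metropolis proposal standard deviation.
#' @return An `admixture_chain`: `q` (n x K posterior means, rows sum to 1),
#'   `lnL` (trace of the log-likelihood of observed gene copies, length
#'   `sweeps`), `K`, `alpha` (posterior mean), `settings`, `seed`.
#' @export
run_admixture <- function(g, K, burn_in = 50000L, sweeps = 100000L, seed = 1L,
                          lambda = 1, alpha_max = 10, alpha_sd = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (K < 1L) stop("K must be at least 1")
  enc <- .encode_alleles(g)
  n <- n_ind(g)
  if (K == 1L) {
    q <- matrix(1, n, 1, dimnames = list(g$ids, "q1"))
    set.seed(seed)
    # single-cluster likelihood still depends on the sampled frequencies
    fit <- .admixture_gibbs_cpp(enc$g1, enc$g2, enc$n_alleles, 1L,
                                as.integer(burn_in), as.integer(sweeps),
                                lambda, 1, alpha_max, alpha_sd)
    chain <- list(q = q, lnL = fit$lnL, K = 1L, alpha = NA_real_,
                  settings = list(burn_in = burn_in, sweeps = sweeps,
                                  lambda = lambda), seed = seed)
    class(chain) <- "admixture_chain"
    return(chain)
  }
  set.seed(seed)
  fit <- .admixture_gibbs_cpp(enc$g1, enc$g2, enc$n_alleles, as.integer(K),
                              as.integer(burn_in), as.integer(sweeps),
                              lambda, 1, alpha_max, alpha_sd)
  q <- fit$q
  dimnames(q) <- list(g$ids, paste0("q", seq_len(K)))
  chain <- list(q = q, lnL = fit$lnL, K = as.integer(K), alpha = fit$alpha,
                settings = list(burn_in = burn_in, sweeps = sweeps,
                                lambda = lambda), seed = seed)
  class(chain) <- "admixture_chain"
  chain
}

#' @export
print.admixture_chain <- function(x, ...) {
  cat(sprintf("admixture_chain: K = %d, %d individuals, lnP(D) ~ %.1f\n",
              x$K, nrow(x$q), mean(x$lnL) - stats::var(x$lnL) / 2))
  invisible(x)
}

#' Model-order selection: mean lnP(D) and Evanno delta-K
#'
#' Estimates, per K, the model evidence lnP(D) from each chain as
#' mean(lnL) - var(lnL)/2, averaged over replicate chains; and for interior
#' K the Evanno statistic delta-K = |L(K+1) - 2 L(K) + L(K-1)| / sd(K),
#' where sd(K) is the standard deviation of lnP(D) over replicates at K.
#'
#' @param replicates A list of `admixture_chain` objects spanning a
#'   contiguous K range, with >= 1 replicate per K (>= 3 recommended for a
#'   stable sd).
#' @return A data.frame with one row per K: `K`, `n_rep`, `mean_lnP`,
#'   `sd_lnP`, `delta_K` (NA at the range edges; +Inf with a warning when
#'   sd is 0).
#' @export
select_k <- function(replicates) {
  Ks <- vapply(replicates, function(ch) ch$K, 1L)
  lnP <- vapply(replicates, function(ch) mean(ch$lnL) - stats::var(ch$lnL) / 2, 1)
  kk <- sort(unique(Ks))
  if (length(kk) > 1L && !all(diff(kk) == 1L)) stop("K range must be contiguous")
  df <- data.frame(K = kk,
                   n_rep = vapply(kk, function(k) sum(Ks == k), 1L),
                   mean_lnP = vapply(kk, function(k) mean(lnP[Ks == k]), 1),
                   sd_lnP = vapply(kk, function(k) stats::sd(lnP[Ks == k]), 1))
  df$delta_K <- NA_real_
  if (nrow(df) >= 3L) {
    for (i in 2:(nrow(df) - 1L)) {
      num <- abs(df$mean_lnP[i + 1] - 2 * df$mean_lnP[i] + df$mean_lnP[i - 1])
      s <- df$sd_lnP[i]
      if (is.na(s)) {
        df$delta_K[i] <- NA_real_
      } else if (s == 0) {
        warning(sprintf("sd of lnP(D) is 0 at K = %d; delta-K reported as Inf", df$K[i]))
        df$delta_K[i] <- Inf
      } else {
        df$delta_K[i] <- num / s
      }
    }
  }
  df
}

# all permutations of 1..k (k small)
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Align and average admixture replicates
#'
#' Resolves label switching across replicate runs: each replicate's cluster
#' columns are permuted to maximize the summed per-individual dot product
#' with the first replicate (exact search over column permutations, K <= 6),
#' then the aligned matrices are averaged element-wise and rows renormalized.
#'
#' @param q_list List of q matrices with identical dimensions.
#' @return The averaged q matrix.
#' @export
align_replicates <- function(q_list) {
  if (!length(q_list)) stop("empty replicate list")
  dims <- vapply(q_list, dim, c(1L, 1L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("replicate q matrices must have identical dimensions")
  K <- ncol(q_list[[1]])
  if (K > 6L) stop("exact permutation alignment supports K <= 6")
  ref <- q_list[[1]]
  perms <- .permutations(K)
  acc <- matrix(0, nrow(ref), K)
  for (qm in q_list) {
    best <- NULL
    best_score <- -Inf
    for (p in perms) {
      score <- sum(ref * qm[, p, drop = FALSE])
      if (score > best_score) {
        best_score <- score
        best <- p
      }
    }
    acc <- acc + qm[, best, drop = FALSE]
  }
  avg <- acc / length(q_list)
  avg <- avg / rowSums(avg)
  dimnames(avg) <- dimnames(ref)
  avg
}

#' Orient a two-cluster q matrix by reference individuals
#'
#' Relabels clusters so that column 1 (`q1`) is the cluster with the higher
#' mean membership among the given anchor individuals (e.g. known or
#' putative members of species A).
#'
#' @param q n x 2 matrix of admixture proportions.
#' @param anchor Indices (or logical mask) of anchor individuals.
#' @return The possibly column-swapped q matrix.
#' @export
orient_q <- function(q, anchor) {
  if (ncol(q) != 2L) stop("orient_q expects a two-cluster q matrix")
  if (mean(q[anchor, 1]) < mean(q[anchor, 2])) q <- q[, c(2L, 1L), drop = FALSE]
  colnames(q) <- c("q1", "q2")
  q
}
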