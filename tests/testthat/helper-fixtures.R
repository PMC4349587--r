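# shared fixtures, built in code

# tiny two-population genotype matrix with one missing call
toy_matrix <- function() {
  a1 <- rbind(c(102L, 204L), c(102L, 206L), c(104L, 204L), c(104L, NA))
  a2 <- rbind(c(102L, 206L), c(104L, 204L), c(104L, 206L), c(102L, NA))
  genotype_matrix(a1, a2, pop = c("p1", "p1", "p2", "p2"),
                  ids = paste0("i", 1:4), loci = c("ssr1", "ssr2"))
}

# fixed-difference species pools: pool A fixed for 101, pool B for 103
fixed_difference_pools <- function(n_loci = 10L) {
  A <- lapply(seq_len(n_loci), function(l) stats::setNames(c(1, 0), c("101", "103")))
  B <- lapply(seq_len(n_loci), function(l) stats::setNames(c(0, 1), c("101", "103")))
  names(A) <- names(B) <- paste0("L", seq_len(n_loci))
  list(A = A, B = B)
}

# random frequency vector on the simplex
runif_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# all unordered diploid genotypes over allele codes
all_genotypes <- function(codes) {
  out <- list()
  for (i in seq_along(codes))
    for (j in i:length(codes))
      out[[length(out) + 1L]] <- c(codes[i], codes[j])
  out
}

# every multiset of size n over a fixed support (for the dip oracle sweep)
all_multisets <- function(n, support) {
  if (n == 0L) return(list(numeric(0)))
  res <- list()
  recurse <- function(prefix, start) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (s in start:length(support)) recurse(c(prefix, support[s]), s)
  }
  recurse(numeric(0), 1L)
  res
}
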