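# Small configurations used across tests; kept tiny so the suite stays fast.
tiny_config <- function(...) {
  args <- list(n_vertices = 120L, n_modes = 3L, n_runs = 1L,
               n_timepoints = 100L, unique_region_size = 15L,
               overlap_region_size = 8L, overlap_pair = c(1L, 2L),
               noise_sd = 0, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

# brute-force assignment oracle: exhaustive search over all permutations
brute_force_match <- function(corr_matrix) {
  n <- nrow(corr_matrix)
  perms <- gtools_permutations(n)
  best <- -Inf; best_perm <- NULL
  for (k in seq_len(nrow(perms))) {
    tot <- sum(corr_matrix[cbind(seq_len(n), perms[k, ])])
    if (tot > best) { best <- tot; best_perm <- perms[k, ] }
  }
  list(permutation = best_perm, total = best)
}

# all permutations of 1..n (base-R recursion; avoids extra dependencies)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (k in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[k, ]])
      row <- row + 1L
    }
  }
  out
}

# independent least-squares oracle via explicit normal equations
normal_equations_fit <- function(y, X) {
  X <- as.matrix(X)
  zpop <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  y <- zpop(y); X <- apply(X, 2, zpop)
  b <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% b
  r2 <- 1 - sum(res^2) / sum(y^2)
  n <- length(y); p <- ncol(X)
  list(betas = as.numeric(b), r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}
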