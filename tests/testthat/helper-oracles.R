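# Independent oracles used across test files. These deliberately re-derive
# results by the most transparent route available (brute force, enumeration),
# not by calling the code paths they check.

# Naive O(n^3) Ward agglomeration: Lance-Williams recurrence applied to
# squared dissimilarities, heights reported on the original scale (sqrt),
# ties broken towards the lowest pair index.
naive_ward <- function(d) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  sz <- rep(1, n)
  act <- seq_len(n)
  lab <- -seq_len(n)
  merges <- matrix(0L, n - 1, 2)
  hts <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- c(NA, NA); bv <- Inf
    for (ii in seq_along(act)) {
      for (jj in seq_len(ii - 1)) {
        v <- D2[act[ii], act[jj]]
        if (v < bv - 1e-12) { bv <- v; best <- c(act[jj], act[ii]) }
      }
    }
    i <- best[1]; j <- best[2]
    hts[s] <- sqrt(bv)
    merges[s, ] <- sort(c(lab[i], lab[j]))
    for (k in act) {
      if (k != i && k != j) {
        D2[i, k] <- D2[k, i] <-
          ((sz[i] + sz[k]) * D2[i, k] + (sz[j] + sz[k]) * D2[j, k] -
             sz[k] * bv) / (sz[i] + sz[j] + sz[k])
      }
    }
    sz[i] <- sz[i] + sz[j]
    lab[i] <- s
    act <- setdiff(act, j)
  }
  list(merge = merges, height = hts)
}

# Gower dissimilarity by the definition, one pair at a time.
naive_gower <- function(x) {
  rng <- apply(x, 2, function(col) diff(range(col)))
  keep <- rng > 0
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- mean(abs(x[i, keep] - x[j, keep]) / rng[keep])
    }
  }
  d
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

kendall_tau_simple <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# Exact Kendall p by full enumeration of rank permutations.
enum_kendall_p <- function(x, y) {
  n <- length(x)
  obs <- kendall_tau_simple(x, y)
  perms <- all_perms(n)
  taus <- apply(perms, 1, function(p) kendall_tau_simple(seq_len(n), p))
  mean(abs(taus) >= abs(obs) - 1e-12)
}

# Hypergeometric upper tail by exhaustive enumeration of all possible gene
# lists of the observed size drawn from the universe.
enum_hyper_p <- function(overlap, set_size, universe_size, list_size) {
  lists <- utils::combn(universe_size, list_size)
  inset <- seq_len(set_size)  # wlog the set is the first set_size genes
  hits <- apply(lists, 2, function(cols) sum(cols %in% inset))
  mean(hits >= overlap)
}
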