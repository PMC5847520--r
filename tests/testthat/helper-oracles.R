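# Shared fixtures and independent oracles.

# constant-probability simulation design for a single cohort
const_spec <- function(phi, p, n = 1, K = 4, region = "Kruger",
                       age = "adult", release = 1) {
  phim <- matrix(phi, 2, 3, dimnames = list(c("Kruger", "KZN"),
                                            c("juvenile", "subadult",
                                              "adult")))
  pm <- matrix(p, 2, K, dimnames = list(c("Kruger", "KZN"), NULL))
  sim_spec(n_occasions = K,
           cohorts = data.frame(region = region, age_at_release = age,
                                release = release, n = n),
           phi = phim, p = pm)
}

# one-bird capture-history set from a 0/1 vector
one_history <- function(h, region = "Kruger", age = "adult", release = 1) {
  capture_histories(matrix(h, nrow = 1), region, age, release)
}

# all possible post-release detection histories for one bird released at
# occasion 1 of K occasions
all_histories <- function(K) {
  suffixes <- as.matrix(expand.grid(rep(list(0:1), K - 1)))
  lapply(seq_len(nrow(suffixes)), function(i) c(1L, suffixes[i, ]))
}

# exact two-sided rank-sum p-value by exhaustive enumeration of group
# assignments (midranks for ties; p = fraction of assignments with a rank
# sum at least as extreme)
perm_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# exact permutation p-value for the Kruskal-Wallis H statistic
perm_kruskal_p <- function(values, groups) {
  groups <- factor(groups)
  H <- function(v) unname(stats::kruskal.test(v, groups)$statistic)
  obs <- H(values)
  perms <- all_permutations(values)
  mean(apply(perms, 1, H) >= obs - 1e-9)
}

all_permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- all_permutations(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}
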