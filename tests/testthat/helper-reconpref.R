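# Shared fixtures and independent oracles (enumeration / brute force).

# a simple noiseless three-state profile plus death
three_state_profile <- function(u_worst, u_mid, u_best) {
  latent_profile(c(worst = u_worst, mid = u_mid, best = u_best, death = 0))
}

# noiseless nine-state profile from a named utility vector
deck_profile <- function(utilities, ...) {
  latent_profile(c(utilities, death = 0), ...)
}

# generator configuration with all stochastic elements off
noiseless_config <- function(...) {
  args <- list(latent_noise_sd = 0, choice_noise = 0, vas_noise_sd = 0,
               unexpected_rank_fraction = 0, equipoise_fraction = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

zero_effects <- function() default_effects()[0, ]

# all permutations of 1:n (n small)
perms_all <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix((seq_len(n))[-i][sub], nrow(sub)))
  }))
}

# exhaustive-permutation Spearman reference (no ties assumed)
spearman_enum <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  S_obs <- sum((rx - ry)^2)
  rho <- 1 - 6 * S_obs / (n^3 - n)
  P <- perms_all(n)
  S_all <- apply(P, 1, function(p) sum((rx - ry[p])^2))
  mean_S <- (n^3 - n) / 6
  p <- if (S_obs > mean_S) 2 * mean(S_all >= S_obs) else
    2 * mean(S_all <= S_obs)
  list(rho = rho, S = S_obs, p = min(p, 1))
}

# exhaustive sign-flip Wilcoxon signed-rank reference (distinct |d|, no zeros)
wilcoxon_enum <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (V_obs > mu) 2 * mean(V_all >= V_obs) else 2 * mean(V_all <= V_obs)
  list(V = V_obs, p = min(p, 1))
}

# independent Kruskal-Wallis H (tie-corrected) and exhaustive permutation p
kw_stat <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(z) length(z) * mean(z)^2)) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

kw_enum_p <- function(values, groups) {
  H_obs <- kw_stat(values, groups)
  P <- perms_all(length(values))
  H_all <- apply(P, 1, function(p) kw_stat(values, groups[p]))
  mean(H_all >= H_obs - 1e-12)
}
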