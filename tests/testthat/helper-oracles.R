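# Independent oracles used to cross-check the package's computations.

# OLS slope/intercept straight from the normal equations.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = unname(beta[1, 1]), slope = unname(beta[2, 1]))
}

# Full-enumeration Mann-Whitney: U statistic for each of the
# choose(n1+n2, n1) equally likely group assignments of the pooled sample
# (tie-free inputs assumed). Returns the observed min-U and the exact
# two-sided p-value.
mw_enumerate <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_of(x, y)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p <- if (u_obs > n1 * n2 / 2) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  list(u_min = min(u_obs, n1 * n2 - u_obs), p_value = min(1, p))
}

# Stepwise substitution oracle for the composition-correction transfer:
# the ratio of (tree ratio / cone-density ratio) is assumed equal in both
# stands, so r1 = density_ratio_1 * (r2 / density_ratio_2).
composition_ratio_oracle <- function(c_ss1, c_lp1, c_ss2, c_lp2, r_ss2) {
  k <- r_ss2 / (c_ss2 / c_lp2)   # tree ratio per unit cone-density ratio
  (c_ss1 / c_lp1) * k
}
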