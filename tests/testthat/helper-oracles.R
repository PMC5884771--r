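# Independent brute-force oracles, deliberately coded by a different route
# than the implementation (pairwise U counting instead of rank sums;
# bitmask sign enumeration instead of expand.grid).

oracle_mw_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

oracle_mw_p_two_sided <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  u_obs <- oracle_mw_u(a, b)
  us <- apply(utils::combn(length(pool), n1), 2, function(idx)
    oracle_mw_u(pool[idx], pool[-idx]))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

oracle_wilcoxon_p_two_sided <- function(x, y) {
  d <- (x - y)[x != y]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  vs <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, 1.0)
  min(1, 2 * min(mean(vs <= v_obs + 1e-9), mean(vs >= v_obs - 1e-9)))
}
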