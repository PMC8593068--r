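# Independent enumeration oracles for the Wilcoxon tests. Both use the
# pair-counting definition of U (not ranks) and explicit sign enumeration,
# so they share no code path with the implementations under test.

oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_of <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(a, b)
  sets <- utils::combn(length(pooled), n)
  us <- apply(sets, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- drop(signs %*% rk)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}
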