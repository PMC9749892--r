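# Independent reference implementations used as oracles.  These deliberately
# avoid the package's code paths: explicit loops, enumeration, closed forms.

# Brute-force two-loop chi-square periodogram statistic for one candidate
# period of P bins: outer loop over phase columns, inner loop over cycles.
qp_bruteforce <- function(x, P) {
  K <- length(x) %/% P
  xx <- x[seq_len(K * P)]
  m <- sum(xx) / length(xx)
  s2 <- 0
  for (v in xx) s2 <- s2 + (v - m)^2
  s2 <- s2 / length(xx)
  acc <- 0
  for (h in seq_len(P)) {
    col_sum <- 0
    for (k in seq_len(K)) col_sum <- col_sum + xx[(k - 1) * P + h]
    acc <- acc + (col_sum / K - m)^2
  }
  K * acc / s2
}

# One-sided Mann-Whitney p-value by full enumeration of group assignments:
# p = P(U <= U_obs) under the permutation null, for alternative "x less".
mw_enumerate_less <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n <- length(x)
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(us <= u_obs + 1e-12)
}

# Benjamini-Hochberg step-up by the definition: sort ascending,
# adj_(i) = min_{j >= i} m p_(j) / j, capped at 1, mapped back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) m * ps[j] / j)
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# tiny builders -------------------------------------------------------------

make_series <- function(counts, dd_start_bin = NA, photoperiod = 12) {
  activity_series("fly", "geno", counts,
                  light_schedule(photoperiod = photoperiod,
                                 dd_start_bin = dd_start_bin))
}

# voltage recording from an explicit per-sweep sample matrix
make_recording <- function(vm, fs = 2000, protocol = NULL) {
  if (is.null(protocol)) {
    sweep_s <- nrow(vm) / fs
    protocol <- sweep_protocol(pre_dark_s = sweep_s * 50 / 150,
                               stim_s = sweep_s * 5 / 150,
                               post_s = sweep_s * 95 / 150,
                               n_sweeps = ncol(vm))
  }
  voltage_recording("cell", "geno", as.numeric(vm), fs, protocol)
}

# spike trains at given per-sweep time lists
make_trains <- function(times_list) {
  lapply(seq_along(times_list), function(i) spike_train(i, times_list[[i]]))
}

# a small protocol for fast ephys tests (10 s sweeps, same 10:1:19 split
# ratios are irrelevant for unit arithmetic, windows given explicitly)
fast_protocol <- function(n_sweeps = 1) {
  sweep_protocol(pre_dark_s = 50, stim_s = 5, post_s = 95, n_sweeps = n_sweeps)
}
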