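# Independent oracles, kept deliberately naive.

# Benjamini-Hochberg step-up by direct definition: q_(i) = min_{j>=i} p_(j)*m/j.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  obs <- u_stat(x, y)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Uncorrected Pearson chi-square on a 2x2 table.
pearson_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Closed-form LIF ramp solution: time at which a ramp a*t (pA/ms) first
# drives V from rest to threshold; returns the injected current then.
lif_ramp_threshold_oracle <- function(lif, a_pa_per_ms) {
  r <- lif$r_mohm / 1000  # mV per pA
  target <- (lif$v_th - lif$v_rest) / (r * a_pa_per_ms)
  f <- function(t) t - lif$tau_ms * (1 - exp(-t / lif$tau_ms)) - target
  t_star <- stats::uniroot(f, c(1e-6, 1e6))$root
  a_pa_per_ms * t_star
}
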