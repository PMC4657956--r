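# shared fixtures built in code

make_dataset <- function(y, r, ...) {
  methylation_dataset(as.matrix(y), as.matrix(r), ...)
}

# small simulated study used by several model tests
tiny_sim <- function(n = 40, n_sites = 60, n_true = 10, pve = 0.15,
                     h2 = 0.3, seed = 42) {
  simulate_dataset(n = n, n_sites = n_sites, n_true = n_true, pve = pve,
                   h2 = h2, sigma2 = 0.5, seed = seed)
}

# exact CDF of -log Gamma(r, 1)
pnlg <- function(x, r) 1 - pgamma(exp(-x), r)

# rescale a vector to exact sample mean m and sd s
with_moments <- function(x, m, s) {
  (x - mean(x)) / stats::sd(x) * s + m
}
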