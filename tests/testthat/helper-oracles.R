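# Independent brute-force oracles used across tests. These re-derive the
# statistics from raw sums / first principles and must stay independent of
# the package's implementation paths.

# Dual-reporter decomposition from raw second moments,
# after unit-mean scaling of each channel.
oracle_decompose <- function(c1, c2) {
  n <- length(c1)
  g <- c1 / (sum(c1) / n)
  r <- c2 / (sum(c2) / n)
  s_gg <- sum(g * g) / n
  s_rr <- sum(r * r) / n
  s_gr <- sum(g * r) / n
  eta_int2 <- (s_gg + s_rr - 2 * s_gr) / 2
  eta_ext2 <- s_gr - 1
  list(eta_int2 = eta_int2, eta_ext2 = eta_ext2,
       eta_tot2 = eta_int2 + eta_ext2)
}

# CV via an explicit loop over raw values (no sd()/mean() shortcuts).
oracle_cv <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sqrt(ss / (n - 1)) / m
}

# Re-derivation of make_telegraph_population's draws from first principles,
# consuming the same RNG stream (states, then extrinsic, then per-allele
# intrinsic and measurement noise).
oracle_telegraph_draws <- function(params, n_cells, seed, n_alleles = 1) {
  withr::with_seed(seed, {
    p_on <- switch(params$lock_mode,
                   toggling = params$k_on / (params$k_on + params$k_off),
                   locked_on = 1, locked_off = 0)
    states <- runif(n_cells) < p_on
    extr <- if (params$sigma_extrinsic == 0) rep(1, n_cells) else {
      s <- params$sigma_extrinsic
      rlnorm(n_cells, -s^2 / 2, s)
    }
    mu <- ifelse(states, params$mu_on, params$mu_off)
    latent <- extr * mu
    chans <- list()
    for (a in seq_len(n_alleles)) {
      intr <- if (params$cv_intrinsic == 0) rep(1, n_cells) else {
        sl <- sqrt(log(1 + params$cv_intrinsic^2))
        rlnorm(n_cells, -sl^2 / 2, sl)
      }
      sig <- latent * intr
      if (params$cv_measurement > 0) {
        sig <- pmax(sig + rnorm(n_cells, 0, params$cv_measurement * sig), 0)
      }
      chans[[a]] <- sig
    }
    list(states = states, latent = latent, channels = chans)
  })
}

# Small default parameter sets reused by several tests.
quiet_params <- function(...) {
  telegraph_params(k_on = 0.1, k_off = 0.1, mu_on = 100, mu_off = 5,
                   cv_intrinsic = 0.1, sigma_extrinsic = 0.1,
                   cv_measurement = 0.1, ...)
}
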