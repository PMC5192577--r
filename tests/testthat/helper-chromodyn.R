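# shared fixtures and small oracles used across test files

# wrap model values into a correlation_function object for fitter tests
make_cf <- function(lags, G, dt = min(lags), window = 10) {
  structure(list(lags = lags, G = G, se = rep(NA_real_, length(G)),
                 n_windows = 1L, skipped = 0L, window = window,
                 channels = c(1L, 1L), dt = dt),
            class = "correlation_function")
}

# brute-force windowed correlator (direct O(N^2) loops)
brute_correlate <- function(Fk, Fl, m, lag_n) {
  n_win <- length(Fk) %/% m
  vapply(lag_n, function(l) {
    g <- c()
    for (w in 0:(n_win - 1)) {
      s <- w * m + 1
      mu_k <- mean(Fk[s:(s + m - 1)])
      mu_l <- mean(Fl[s:(s + m - 1)])
      if (mu_k <= 0 || mu_l <= 0) next
      t <- s:(s + m - 1 - l)
      g <- c(g, mean((Fk[t] - mu_k) * (Fl[t + l] - mu_l)) / (mu_k * mu_l))
    }
    mean(g)
  }, numeric(1))
}

# Table 1 untreated binding parameters
het_binding <- function() steady_state_rates(6, 18, 76, 1.05, 8e-3)
eu_binding <- function() steady_state_rates(6, 31, 63, 0.76, 8e-3)

# small planted rosette used by map tests
planted_rosette_config <- function()
  "lin(100) - dom(600)[loop(150) - loop(150) - loop(150) - loop(150)] - lin(100)"
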