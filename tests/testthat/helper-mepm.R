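# Shared fixtures and independent oracles for the test suite.

# brute-force OLS via explicit normal equations (oracle, never the package path)
ols_oracle <- function(X, y) {
  X <- cbind(1, X)
  solve(crossprod(X), crossprod(X, y))[, 1]
}

# direct quadrature convolution of a boxcar with a kernel, sampled mid-TR
conv_oracle <- function(onset, duration, kern, kern_dt, n_scans, TR) {
  dt <- kern_dt
  n_micro <- ceiling(n_scans * TR / dt)
  tau <- (seq_len(n_micro) - 1) * dt
  u <- as.numeric(tau >= onset & tau < onset + duration)
  t_scan <- (seq_len(n_scans) - 1) * TR + TR / 2
  vapply(t_scan, function(ts) {
    lag <- ts - tau
    ok <- lag >= 0 & lag <= (length(kern) - 1) * dt
    hvals <- numeric(length(tau))
    hvals[ok] <- kern[round(lag[ok] / dt) + 1]
    sum(u * hvals) * dt
  }, numeric(1))
}

# queue-based flood fill (oracle for connected-component labelling)
floodfill_oracle <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  d <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  off <- as.matrix(off[switch(as.character(connectivity),
                              "6" = d == 1, "18" = d <= 2, "26" = d <= 3), ])
  lab <- array(0L, dm)
  nxt <- 0L
  coords <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(coords))) {
    if (lab[coords[s, 1], coords[s, 2], coords[s, 3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(coords[s, ])
    lab[coords[s, 1], coords[s, 2], coords[s, 3]] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(off))) {
        nb <- cur + off[k, ]
        if (any(nb < 1) || any(nb > dm)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  lab
}

# small balanced trial table with fully determined responses
perfect_trial_table <- function(n_per_valence = 25) {
  v <- rep(c(-1L, 0L, 1L), each = n_per_valence)
  data.frame(onset = seq_along(v) * 5, duration = 1,
             trial_type = c("negative", "neutral", "positive")[v + 2L],
             valence = v,
             response = ifelse(v == 1L, 1L, ifelse(v == -1L, -1L, 1L)),
             response_time = 1)
}
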