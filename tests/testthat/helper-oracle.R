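# Independent ODE reference for the pointwise kinetics: classical adaptive
# Cash-Karp RK45 written directly against the rate formulas, sharing no code
# with the package's implicit TR-BDF2 solver.
oracle_rates <- function(y, p) {
  pb <- y[1] * y[2]
  sec <- y[2] * (1 - y[4]) * y[3]
  c(-p$C_poly * pb,
    -p$C_ba * pb - p$C_kba * sec,
    (p$C_poly + p$C_ba) * pb + p$C_kba * sec,
    p$C_k * sec)
}

oracle_rk45 <- function(y0, p, times, rtol = 1e-10, atol = 1e-13) {
  # Cash-Karp coefficients
  a <- list(c(), c(1/5), c(3/40, 9/40), c(3/10, -9/10, 6/5),
            c(-11/54, 5/2, -70/27, 35/27),
            c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
  b5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  b4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  out <- matrix(NA_real_, length(times), 4)
  t <- times[1]
  y <- y0
  out[1, ] <- y
  h <- 1e-3
  for (j in 2:length(times)) {
    tend <- times[j]
    while (t < tend) {
      h <- min(h, tend - t)
      k <- matrix(0, 6, 4)
      k[1, ] <- oracle_rates(y, p)
      for (s in 2:6) {
        ys <- y + h * as.vector(a[[s]] %*% k[seq_len(s - 1), , drop = FALSE])
        k[s, ] <- oracle_rates(ys, p)
      }
      y5 <- y + h * as.vector(b5 %*% k)
      y4 <- y + h * as.vector(b4 %*% k)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (err <= 1) {
        t <- t + h
        y <- y5
      }
      h <- h * min(5, max(0.1, 0.9 * err^(-0.2)))
    }
    out[j, ] <- y
  }
  colnames(out) <- c("rho_poly", "rho_ba", "rho_cross", "kappa")
  out
}

# random valid local states under a fixed seed
random_states <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(rho_poly = runif(n, 0, 2), rho_ba = runif(n, 0, 4),
             rho_cross = runif(n, 0, 3), kappa = runif(n))
}
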