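# Shared fixtures: the six-dose tanh illustration (target rate 20%) and
# small independent oracles used to cross-check the package's numerics.

example_grid <- function() {
  dose_grid(c(-1.47, -1.1, -0.69, -0.42, 0, 0.42), alpha = 0.2, s = 3,
            mode = "linear", offset = -1.5, divisor = 2)
}

# Cohort-level history of the illustration: fast escalation through dose 6,
# first DLT in cohort 6, then four cohorts at dose 5 with one DLT in cohort 8.
example_history <- function(n_cohorts = 10) {
  doses <- c(1, 2, 3, 4, 5, 6, 5, 5, 5, 5)
  dlts  <- c(0, 0, 0, 0, 0, 1, 0, 1, 0, 0)
  data.frame(cohort = seq_len(n_cohorts),
             dose_index = doses[seq_len(n_cohorts)],
             n_patients = 3L,
             n_dlt = dlts[seq_len(n_cohorts)])
}

# Patient-level data inside the top subinterval (2/3, 1] after n_cohorts
# cohorts of the illustration.
example_local_data <- function(n_cohorts = 6) {
  x <- c(rep(0.75, 3), rep(0.96, 3), rep(0.75, 12))
  y <- c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0)
  keep <- seq_len(3 * (n_cohorts - 4))      # subinterval entered at cohort 5
  list(x = x[keep], y = y[keep])
}

# Independent re-derivation of the sequential posterior mean: plain loops and
# explicit formulas, no shared code with the package internals.
oracle_sequential_mean <- function(x, y, v0, v1, alpha, M = 2000) {
  th <- (seq_len(M) - 0.5) / M
  bm <- rep(Inf, M)
  for (j in seq_len(M)) {
    b <- Inf
    if (th[j] > v0) b <- min(b, alpha / (th[j] - v0))
    if (th[j] < v1) b <- min(b, (1 - alpha) / (v1 - th[j]))
    if (th[j] > v1) b <- min(b, alpha / (th[j] - v1))
    bm[j] <- b
  }
  h <- bm^2
  for (i in seq_along(x)) {
    f <- alpha + (2 / 3) * bm * (x[i] - th)
    f <- pmin(pmax(f, 0), 1)
    h <- h * if (y[i] == 1) f else 1 - f
  }
  sum(th * h) / sum(h)
}

# Monte-Carlo oracle for the jointly integrated posterior: importance draws
# of (rho0, rho1) uniform on the triangle, quantile support restricted to the
# dose domain.  Returns the weighted mean and its standard error.
oracle_mc_joint <- function(x, y, v0, v1, alpha, n = 1e6, seed = 1) {
  set.seed(seed)
  u1 <- stats::runif(n); u2 <- stats::runif(n)
  r0 <- pmin(u1, u2); r1 <- pmax(u1, u2)
  th <- v0 + (alpha - r0) / (r1 - r0) * (v1 - v0)
  ll <- rep(0, n)
  for (i in seq_along(x)) {
    Fx <- r0 + (r1 - r0) * (x[i] - v0) / (v1 - v0)
    ll <- ll + if (y[i] == 1) log(Fx) else log1p(-Fx)
  }
  w <- exp(ll) * (th > 0 & th <= 1)
  m <- sum(th * w) / sum(w)
  se <- sqrt(sum(w^2 * (th - m)^2)) / sum(w)
  list(mean = m, se = se)
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2
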