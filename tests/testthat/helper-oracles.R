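# Fixtures and independent brute-force oracles. The oracles evaluate the
# model formulas by explicit loops over months/species, never through the
# package's vectorized implementations.

# hand-built table: arbitrary I, Fp, Fh (no pair-level counts)
make_table <- function(I, Fp, Fh) {
  interaction_table(
    plants = sprintf("p%d", seq_len(nrow(I))),
    birds = sprintf("b%d", seq_len(ncol(I))),
    I = I, Fp = Fp, Fh = Fh)
}

# constant identical phenologies for every species
constant_table <- function(n_p, n_h, I = matrix(1, n_p, n_h), value = 1) {
  make_table(I,
             matrix(value, n_p, 12),
             matrix(value, n_h, 12))
}

# 1 plant x 1 bird with flat unit phenologies (all overlaps 1)
pair_table <- function() constant_table(1, 1)

# phenology rows padded to 12 months
pad12 <- function(...) {
  v <- c(...)
  c(v, rep(0, 12 - length(v)))
}

oracle_O <- function(Fp, Fh) {
  n_p <- nrow(Fp); n_h <- nrow(Fh)
  O <- matrix(0, n_p, n_h)
  for (i in seq_len(n_p)) for (j in seq_len(n_h)) {
    acc <- 0
    for (m in 1:12)
      acc <- acc + (Fp[i, m] / sum(Fp[i, ])) * (Fh[j, m] / max(Fh[j, ]))
    O[i, j] <- acc
  }
  O
}

oracle_Mh <- function(Fp, Fh) {
  n_p <- nrow(Fp); n_h <- nrow(Fh)
  Mh <- array(0, c(n_p, n_h, n_h))
  for (i in seq_len(n_p)) for (k in seq_len(n_h)) for (j in seq_len(n_h)) {
    acc <- 0
    for (m in 1:12)
      acc <- acc + (Fp[i, m] / sum(Fp[i, ])) *
        (Fh[k, m] / max(Fh[k, ])) * (Fh[j, m] / max(Fh[j, ]))
    Mh[i, k, j] <- acc
  }
  Mh
}

oracle_Mp <- function(Fp, Fh) {
  n_p <- nrow(Fp); n_h <- nrow(Fh)
  Mp <- array(0, c(n_h, n_p, n_p))
  for (j in seq_len(n_h)) for (k in seq_len(n_p)) for (i in seq_len(n_p)) {
    acc <- 0
    for (m in 1:12)
      acc <- acc + (Fh[j, m] / max(Fh[j, ])) *
        (Fp[k, m] / sum(Fp[k, ])) * (Fp[i, m] / sum(Fp[i, ]))
    Mp[j, k, i] <- acc
  }
  Mp
}

# competition matrices by explicit summation over species
oracle_competition <- function(H, P, I, O, Mh, Mp) {
  n_p <- nrow(I); n_h <- ncol(I)
  Omega <- matrix(0, n_h, n_h)
  for (j in seq_len(n_h)) {
    den <- 0
    for (i in seq_len(n_p)) den <- den + I[i, j] * P[i] * O[i, j]
    for (k in seq_len(n_h)) {
      if (den == 0) { Omega[k, j] <- 0; next }
      num <- 0
      for (i in seq_len(n_p))
        num <- num + P[i] * I[i, j] * I[i, k] * Mh[i, k, j]
      Omega[k, j] <- num / den
    }
  }
  Theta <- matrix(0, n_p, n_p)
  for (i in seq_len(n_p)) {
    den <- 0
    for (j in seq_len(n_h)) den <- den + I[i, j] * H[j] * O[i, j]
    for (k in seq_len(n_p)) {
      if (den == 0) { Theta[k, i] <- 0; next }
      num <- 0
      for (j in seq_len(n_h))
        num <- num + H[j] * I[i, j] * I[k, j] * Mp[j, k, i]
      Theta[k, i] <- num / den
    }
  }
  list(Omega = Omega, Theta = Theta)
}

# full derivative vector by direct substitution into the growth equations
oracle_rhs <- function(H, P, params, I, O, Mh, Mp) {
  n_p <- nrow(I); n_h <- ncol(I)
  cm <- oracle_competition(H, P, I, O, Mh, Mp)
  dH <- numeric(n_h); dP <- numeric(n_p)
  for (j in seq_len(n_h)) {
    D <- 0
    for (i in seq_len(n_p)) D <- D + I[i, j] * O[i, j] * P[i]
    S <- 0
    for (k in seq_len(n_h)) S <- S + cm$Omega[k, j] * H[k]
    ben <- params$alpha * D / (1 + params$beta * D + params$comp * S)
    space <- 0
    for (k in seq_len(n_h))
      space <- space +
        (if (k == j) params$cs_intra else params$cs_inter) * H[k]
    dH[j] <- H[j] * (params$r_h[j] + ben - space)
  }
  for (i in seq_len(n_p)) {
    D <- 0
    for (j in seq_len(n_h)) D <- D + I[i, j] * O[i, j] * H[j]
    S <- 0
    for (k in seq_len(n_p)) S <- S + cm$Theta[k, i] * P[k]
    ben <- params$alpha * D / (1 + params$beta * D + params$comp * S)
    space <- 0
    for (k in seq_len(n_p))
      space <- space +
        (if (k == i) params$cs_intra else params$cs_inter) * P[k]
    dP[i] <- P[i] * (params$r_p[i] + ben - space)
  }
  list(dH = dH, dP = dP)
}

# analytic 2x2 Jacobian of the 1-plant/1-bird system with all overlaps 1:
# dH = H (r_h + aP/(1 + bP + cH) - H), dP symmetric
oracle_pair_jacobian <- function(H, P, params) {
  a <- params$alpha; b <- params$beta; cc <- params$comp
  gH <- a * P / (1 + b * P + cc * H)
  gP <- a * H / (1 + b * H + cc * P)
  dgH_dP <- a * (1 + cc * H) / (1 + b * P + cc * H)^2
  dgH_dH <- -a * P * cc / (1 + b * P + cc * H)^2
  dgP_dH <- a * (1 + cc * P) / (1 + b * H + cc * P)^2
  dgP_dP <- -a * H * cc / (1 + b * H + cc * P)^2
  J11 <- params$r_h + gH - 2 * H + H * dgH_dH
  J12 <- H * dgH_dP
  J21 <- P * dgP_dH
  J22 <- params$r_p + gP - 2 * P + P * dgP_dP
  matrix(c(J11, J21, J12, J22), 2, 2)  # state order (H, P)
}

# Newton iteration with numerical Jacobian for the pair steady state,
# independent of the package's integrator
oracle_pair_root <- function(params, start = c(1, 1)) {
  f <- function(x) {
    H <- x[1]; P <- x[2]
    c(params$r_h + params$alpha * P / (1 + params$beta * P +
                                         params$comp * H) - H,
      params$r_p + params$alpha * H / (1 + params$beta * H +
                                         params$comp * P) - P)
  }
  x <- start
  for (it in 1:100) {
    fx <- f(x)
    J <- matrix(0, 2, 2)
    h <- 1e-7
    for (k in 1:2) {
      xp <- x; xp[k] <- xp[k] + h
      J[, k] <- (f(xp) - fx) / h
    }
    step <- solve(J, -fx)
    x <- x + step
    if (max(abs(step)) < 1e-12) break
  }
  x
}

# a small random valid table, for property-style loops
random_table <- function(seed) {
  n_p <- sample(2:5, 1)
  n_h <- sample(2:4, 1)
  generate_community(
    community_preset("rnd", n_p, n_h,
                     sample(max(n_p, n_h):(n_p * n_h), 1)),
    phenology_breadth = runif(1, 1.5, 4), seed = seed)
}
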