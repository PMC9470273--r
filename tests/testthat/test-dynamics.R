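params_for <- function(tab, alpha, comp, r = -0.25, beta = 0.8, ...) {
  model_parameters(alpha = alpha, comp = comp,
                   r_p = rep(r, length(tab$plants)),
                   r_h = rep(r, length(tab$birds)), beta = beta, ...)
}

test_that("competition matrices reproduce hand evaluations", {
  # single pair, all overlaps 1: self-competition is exactly 1
  tab <- pair_table()
  cm <- competition_matrices(list(H = 1, P = 2), tab, flat_structure(tab))
  expect_equal(cm$Omega, matrix(1, 1, 1))
  expect_equal(cm$Theta, matrix(1, 1, 1))

  # two birds sharing no plant never compete
  I <- rbind(c(1, 0), c(0, 1))
  tab2 <- constant_table(2, 2, I = I)
  cm2 <- competition_matrices(list(H = c(1, 1), P = c(1, 1)), tab2,
                              flat_structure(tab2))
  expect_equal(cm2$Omega[1, 2], 0)
  expect_equal(cm2$Omega[2, 1], 0)

  # two birds sharing both plants (P = (2,1)): Omega = 3/3 = 1,
  # and halving Mh halves it
  tab3 <- constant_table(2, 2)
  st <- flat_structure(tab3)
  cm3 <- competition_matrices(list(H = c(1, 1), P = c(2, 1)), tab3, st)
  expect_equal(cm3$Omega[2, 1], 1)
  st$Mh[] <- 0.5
  cm4 <- competition_matrices(list(H = c(1, 1), P = c(2, 1)), tab3, st)
  expect_equal(cm4$Omega[2, 1], 0.5)
})

test_that("competition matrices match the brute-force oracle", {
  set.seed(5)
  for (k in 1:8) {
    tab <- random_table(seed = 70 + k)
    s <- seasonal_structure(tab)
    H <- runif(length(tab$birds), 0, 3)
    P <- runif(length(tab$plants), 0, 3)
    got <- competition_matrices(list(H = H, P = P), tab, s)
    want <- oracle_competition(H, P, tab$I, s$O, s$Mh, s$Mp)
    expect_equal(got$Omega, want$Omega, tolerance = 1e-12)
    expect_equal(got$Theta, want$Theta, tolerance = 1e-12)
    expect_true(all(got$Omega >= 0 & got$Omega <= 1 + 1e-12))
    expect_true(all(got$Theta >= 0 & got$Theta <= 1 + 1e-12))
  }
})

test_that("the derivative matches direct substitution", {
  # no mutualism: dH = H(r - H) = 1*(-0.25 - 1)
  tab <- pair_table()
  p0 <- params_for(tab, alpha = 0, comp = 1)
  d0 <- model_rhs(list(H = 1, P = 1), p0, tab, flat_structure(tab))
  expect_equal(d0$dH, -1.25)

  # benefit 2/(1+0.8+1): dH = -0.25 + 0.714286 - 1
  p1 <- params_for(tab, alpha = 2, comp = 1)
  d1 <- model_rhs(list(H = 1, P = 1), p1, tab, flat_structure(tab))
  expect_equal(d1$dH, -0.25 + 2 / 2.8 - 1, tolerance = 1e-12)
  expect_equal(d1$dP, d1$dH, tolerance = 1e-12)

  # extinct species stay put
  d2 <- model_rhs(list(H = 0, P = 1), p1, tab, flat_structure(tab))
  expect_identical(d2$dH, 0)

  expect_error(model_rhs(list(H = NaN, P = 1), p1, tab,
                         flat_structure(tab)), "non-finite")
})

test_that("the derivative matches the oracle on random communities", {
  set.seed(6)
  for (k in 1:8) {
    tab <- random_table(seed = 80 + k)
    s <- seasonal_structure(tab)
    p <- model_parameters(alpha = runif(1, 0, 3), comp = runif(1, 0, 3),
                          r_p = -runif(length(tab$plants), 0, 0.5),
                          r_h = -runif(length(tab$birds), 0, 0.5))
    H <- runif(length(tab$birds), 0, 2)
    P <- runif(length(tab$plants), 0, 2)
    got <- model_rhs(list(H = H, P = P), p, tab, s)
    want <- oracle_rhs(H, P, p, tab$I, s$O, s$Mh, s$Mp)
    expect_equal(got$dH, want$dH, tolerance = 1e-10)
    expect_equal(got$dP, want$dP, tolerance = 1e-10)
  }
})

test_that("the mutualistic benefit is monotone in alpha and comp", {
  set.seed(11)
  tab <- random_table(seed = 91)
  s <- seasonal_structure(tab)
  H <- runif(length(tab$birds), 0.1, 2)
  P <- runif(length(tab$plants), 0.1, 2)
  ben <- function(alpha, comp) {
    p <- model_parameters(alpha = alpha, comp = comp,
                          r_p = rep(0, length(tab$plants)),
                          r_h = rep(0, length(tab$birds)),
                          cs_intra = 0)
    # with r = 0 and no space competition, dX/X is the benefit itself
    d <- model_rhs(list(H = H, P = P), p, tab, s)
    c(d$dH / H, d$dP / P)
  }
  b1 <- ben(1, 1); b2 <- ben(2, 1); b3 <- ben(1, 2)
  expect_true(all(b2 >= b1 - 1e-12))
  expect_true(all(b3 <= b1 + 1e-12))
})

test_that("growth rates are bounded and reproducible", {
  r <- sample_growth_rates(1e5, seed = 1)
  expect_gte(min(r), -0.5)
  expect_lte(max(r), 0)
  expect_identical(as.numeric(sample_growth_rates(10, seed = 3)),
                   as.numeric(sample_growth_rates(10, seed = 3)))
  b <- attr(r, "b")
  expect_true(b >= 0.3 && b <= 15)
})

test_that("growth-rate draws match a two-stage sampling oracle", {
  r <- abs(sample_growth_rates(1e5, seed = 2)) * 2  # back to Beta(1, b)
  # oracle: same two-stage scheme written independently
  set.seed(2)
  b_o <- exp(runif(1, log(0.3), log(15)))
  u <- runif(1e5)
  r_o <- 1 - (1 - u)^(1 / b_o)  # inverse CDF of Beta(1, b)
  ks <- suppressWarnings(stats::ks.test(r, r_o)$statistic)
  expect_lt(unname(ks), 0.01)
})

test_that("integration finds the pair equilibrium found by root-finding", {
  tab <- pair_table()
  p <- params_for(tab, alpha = 3, comp = 0, r = -0.1)
  res <- integrate_to_equilibrium(tab, flat_structure(tab), p)
  expect_true(res$converged)
  root <- oracle_pair_root(p)
  expect_equal(res$H, root[1], tolerance = 1e-6)
  expect_equal(res$P, root[2], tolerance = 1e-6)
})

test_that("an all-zero initial state converges immediately", {
  tab <- pair_table()
  p <- params_for(tab, alpha = 2, comp = 1)
  res <- integrate_to_equilibrium(tab, flat_structure(tab), p,
                                  initial = list(H = 0, P = 0))
  expect_true(res$converged)
  expect_equal(res$windows, 0)
  expect_equal(res$H, 0)
  expect_equal(res$P, 0)
})

test_that("without mutualism every obligate species goes extinct", {
  tab <- generate_community(community_preset("t", 6, 4, 14), seed = 31)
  s <- seasonal_structure(tab)
  p <- model_parameters(alpha = 0, comp = 1,
                        r_p = sample_growth_rates(6, seed = 1),
                        r_h = sample_growth_rates(4, seed = 2))
  res <- integrate_to_equilibrium(tab, s, p)
  expect_equal(sum(res$survivors_h) + sum(res$survivors_p), 0)
  expect_equal(persistence(res), 0)
})

test_that("converged equilibria have small residuals and clean masks", {
  set.seed(12)
  for (k in 1:4) {
    tab <- random_table(seed = 120 + k)
    s <- seasonal_structure(tab)
    p <- model_parameters(alpha = 2.5, comp = 1,
                          r_p = sample_growth_rates(length(tab$plants)),
                          r_h = sample_growth_rates(length(tab$birds)))
    res <- integrate_to_equilibrium(tab, s, p)
    expect_true(res$converged)
    expect_lt(res$residual, equilibrium_control()$tol)
    expect_true(all(res$H >= 0) && all(res$P >= 0))
    expect_true(all(res$H[!res$survivors_h] == 0))
    expect_true(all(res$P[!res$survivors_p] == 0))
    d <- model_rhs(list(H = res$H, P = res$P), p, tab, s)
    alive <- c(res$H, res$P) > p$extinction_threshold
    expect_lt(max(abs(c(d$dH, d$dP)[alive])), equilibrium_control()$tol)
  }
})

test_that("longer handling time weakly lowers pair equilibrium abundance", {
  tab <- pair_table()
  ab <- vapply(c(0.4, 0.8, 1.6), function(beta) {
    p <- params_for(tab, alpha = 3, comp = 0, r = -0.1, beta = beta)
    res <- integrate_to_equilibrium(tab, flat_structure(tab), p)
    res$H
  }, numeric(1))
  expect_true(all(diff(ab) <= 1e-8))
})

test_that("variant transforms adjust growth rates and space competition", {
  p <- model_parameters(alpha = 1, comp = 1,
                        r_p = c(-0.4, -0.3, -0.2, -0.1), r_h = c(-0.2))
  sh <- apply_variant(p, "shifted_r")
  expect_equal(sh$r_p, c(-0.4, -0.3, -0.2, -0.1) + 0.25)
  expect_equal(mean(sh$r_p > 0), 0.5)
  ab <- apply_variant(p, "absolute_r_cs")
  expect_equal(ab$r_p, c(0.4, 0.3, 0.2, 0.1))
  expect_equal(ab$cs_inter, 0.05)
  expect_equal(ab$r_h, p$r_h)  # hummingbirds stay obligate
  expect_equal(apply_variant(p, "none"), p)
})
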