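test_that("combination selection applies the persistence window and c > 0", {
  rec <- expand.grid(alpha = c(1, 2, 3), c = c(0, 1), rep = 1:2)
  rec$persistence <- c(95, 55, 10, 95, 55, 10,    # rep 1
                       95, 55, 10, 95, 55, 10)    # rep 2
  out <- select_combinations(rec)
  # (1, 0): 95% -> excluded; (3, *): 10% -> excluded; c = 0 excluded
  expect_equal(nrow(out), 1)
  expect_equal(out$alpha, 2)
  expect_equal(out$c, 1)
  expect_equal(out$mean_persistence, 55)
  # boundary values are excluded (strict window)
  rec$persistence <- 90
  expect_equal(nrow(select_combinations(rec)), 0)
  rec$persistence <- 20
  expect_equal(nrow(select_combinations(rec)), 0)
  rec$persistence <- 55
  expect_equal(nrow(select_combinations(rec)), 3)  # the three c = 1 cells
})

test_that("known path coefficients are recovered on simulated records", {
  truth <- c("seasonal->diversity" = 0.4,
             "seasonal->total_abundance" = 0.3,
             "seasonal->connectance" = -0.35,
             "seasonal->interaction_overlap" = -0.25,
             "diversity->total_abundance" = 0.3,
             "diversity->connectance" = -0.2,
             "diversity->interaction_overlap" = 0.15,
             "seasonal->resilience" = 0.1,
             "diversity->resilience" = 0.2,
             "connectance->resilience" = 0.3,
             "interaction_overlap->resilience" = -0.3,
             "total_abundance->resilience" = 0.35,
             "seasonal->robustness" = 0.05,
             "diversity->robustness" = 0.25,
             "connectance->robustness" = -0.3,
             "interaction_overlap->robustness" = 0.2,
             "total_abundance->robustness" = 0.3)
  rec <- simulate_path_records(5000, truth, n_communities = 11, seed = 4)
  fit <- suppressWarnings(fit_path_analysis(rec))
  got <- setNames(fit$edges$coefficient,
                  paste0(fit$edges$from, "->", fit$edges$to))
  expect_true(all(abs(got[names(truth)] - truth) < 0.05))
})

test_that("null edges give small effects and calibrated p-values", {
  truth <- c("seasonal->diversity" = 0.5,
             "diversity->resilience" = 0.4)
  # seasonal->resilience is absent (true coefficient 0)
  pvals <- vapply(1:40, function(k) {
    rec <- simulate_path_records(400, truth, n_communities = 6, seed = k)
    fit <- suppressWarnings(fit_path_analysis(rec,
                                              random_intercept = FALSE))
    fit$edges$p_value[fit$edges$from == "seasonal" &
                        fit$edges$to == "resilience"]
  }, numeric(1))
  # type-I error near the nominal 5%
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(mean(pvals < 0.5), 0.25)
})

test_that("a single-predictor fixed-effects path equals the correlation", {
  set.seed(20)
  n <- 500
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n, 0, 0.8)
  rec <- data.frame(community = 1, seasonal = x, diversity = y,
                    connectance = rnorm(n), interaction_overlap = rnorm(n),
                    total_abundance = rnorm(n), resilience = rnorm(n),
                    robustness = rnorm(n))
  edges <- data.frame(from = "seasonal", to = "diversity")
  fit <- suppressWarnings(fit_path_analysis(rec, edges = edges,
                                            random_intercept = FALSE))
  expect_equal(fit$edges$coefficient, cor(x, y), tolerance = 1e-10)
})

test_that("indirect effects are exact products of edge coefficients", {
  truth <- c("seasonal->diversity" = 0.4,
             "diversity->total_abundance" = 0.3,
             "total_abundance->resilience" = 0.35,
             "seasonal->resilience" = 0.1)
  rec <- simulate_path_records(2000, truth, n_communities = 8, seed = 9)
  fit <- suppressWarnings(fit_path_analysis(rec))
  co <- function(a, b)
    fit$edges$coefficient[fit$edges$from == a & fit$edges$to == b]
  path <- fit$indirect[fit$indirect$path ==
                         "seasonal -> diversity -> total_abundance -> resilience", ]
  expect_equal(path$effect,
               co("seasonal", "diversity") *
                 co("diversity", "total_abundance") *
                 co("total_abundance", "resilience"))
  direct <- fit$indirect[fit$indirect$direct &
                           fit$indirect$response == "resilience", ]
  expect_equal(direct$effect, co("seasonal", "resilience"))
  # totals are the sum over all seasonal -> ... -> response paths
  tot <- fit$totals$total_effect[fit$totals$response == "resilience"]
  expect_equal(tot, sum(fit$indirect$effect[
    fit$indirect$response == "resilience"]))
})

test_that("conditional r-squared is never below marginal", {
  truth <- c("seasonal->diversity" = 0.4,
             "diversity->resilience" = 0.3)
  rec <- simulate_path_records(1500, truth, n_communities = 10, icc = 0.15,
                               seed = 12)
  fit <- suppressWarnings(fit_path_analysis(rec))
  expect_true(all(fit$r2$r2_conditional >= fit$r2$r2_marginal - 1e-10))
  expect_true(all(fit$r2$r2_marginal >= 0 & fit$r2$r2_conditional <= 1))
})

test_that("standardization makes coefficients scale-invariant", {
  truth <- c("seasonal->diversity" = 0.4,
             "diversity->resilience" = 0.3)
  rec <- simulate_path_records(1000, truth, n_communities = 8, seed = 3)
  fit1 <- suppressWarnings(fit_path_analysis(rec))
  rec$diversity <- rec$diversity * 1000
  rec$resilience <- rec$resilience * 0.001
  fit2 <- suppressWarnings(fit_path_analysis(rec))
  expect_equal(fit1$edges$coefficient, fit2$edges$coefficient,
               tolerance = 1e-8)
})

test_that("degenerate inputs are handled explicitly", {
  truth <- c("seasonal->diversity" = 0.4)
  rec <- simulate_path_records(200, truth, seed = 5)
  rec$connectance <- 1  # zero variance
  expect_warning(fit_path_analysis(rec, random_intercept = FALSE),
                 "zero-variance")
  expect_error(fit_path_analysis(rec[1:5, ]), "too few")
})
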