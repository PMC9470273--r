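#' Persistence of a community at equilibrium
#'
#' Percentage of the initial species (both guilds pooled) whose equilibrium
#' abundance is strictly above the extinction threshold (`1e-5` by
#' default); an abundance exactly at the threshold counts extinct.
#'
#' @param result An [integrate_to_equilibrium()] result.
#' @return Percentage in `[0, 100]`.
#' @export
persistence <- function(result) {
  stopifnot(inherits(result, "equilibrium_result"))
  100 * (sum(result$survivors_h) + sum(result$survivors_p)) /
    (length(result$H) + length(result$P))
}

#' Feasibility over a set of growth-rate replicates
#'
#' Percentage of replicates whose persistence exceeds 98%. The 98% cut
#' (rather than exactly 100%) tolerates the loss of one species in diverse
#' communities (> 50 species) and none otherwise, reflecting imperfect
#' sampling and open populations.
#'
#' @param persistences Numeric vector of persistence percentages, one per
#'   growth-rate replicate of a single community and parameter combination.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' feasibility(c(100, 97, 99, 0))  # 50
feasibility <- function(persistences) {
  if (length(persistences) == 0)
    stop("feasibility needs at least one persistence value")
  stopifnot(all(is.finite(persistences)))
  100 * mean(persistences > 98)
}

# central finite-difference Jacobian of the survivor-restricted system;
# Omega/Theta depend on the state so differentiating the full rhs captures
# their product-rule terms automatically
equilibrium_jacobian <- function(result, table, structure, params) {
  ctx <- build_model_context(table, structure)
  keep_h <- which(result$survivors_h)
  keep_p <- which(result$survivors_p)
  idx <- c(keep_h, ctx$n_h + keep_p)     # positions in the stacked state
  x0 <- c(result$H, result$P)
  n <- length(idx)
  f <- function(x) {
    d <- context_rhs(x[seq_len(ctx$n_h)], x[ctx$n_h + seq_len(ctx$n_p)],
                     params, ctx)
    c(d$dH, d$dP)[idx]
  }
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    h <- max(1e-6, 1e-6 * abs(x0[idx[k]]))
    xp <- x0; xp[idx[k]] <- xp[idx[k]] + h
    xm <- x0; xm[idx[k]] <- xm[idx[k]] - h
    J[, k] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Resilience of an equilibrium
#'
#' `-max(Re(lambda))` over the eigenvalues of the Jacobian of the system
#' restricted to surviving species, evaluated at the equilibrium by central
#' finite differences. Positive at any locally stable equilibrium; the
#' return time after a small perturbation scales as its inverse. Undefined
#' (NA) for a null equilibrium.
#'
#' @inheritParams model_rhs
#' @param result An [integrate_to_equilibrium()] result.
#' @return Resilience value, or `NA` when no species survives.
#' @export
resilience <- function(result, table, structure, params) {
  if (!any(result$survivors_h) && !any(result$survivors_p)) return(NA_real_)
  J <- equilibrium_jacobian(result, table, structure, params)
  -max(Re(eigen(J, only.values = TRUE)$values))
}

#' Robustness to single hummingbird removals
#'
#' For every hummingbird surviving at the baseline equilibrium, sets its
#' abundance to zero, re-integrates the system from the perturbed state
#' until the next equilibrium, and records the percentage of the remaining
#' baseline survivors (both guilds, the removed bird excluded) that are
#' still alive; robustness is the mean over all removals. Only
#' hummingbirds are removed, but secondary extinctions are counted over
#' both guilds. Removals can only lose species, never resurrect them.
#'
#' @inheritParams resilience
#' @param control Integration control for the post-removal runs; defaults
#'   to the same settings as the baseline.
#' @param include_removed If `TRUE`, count the removed bird itself as a
#'   casualty in the numerator and keep it in the denominator (alternative
#'   accounting); default `FALSE` counts secondary extinctions only.
#' @return Mean percentage in `[0, 100]`, or `NA` when no hummingbird
#'   survives at baseline or only one species survives in total.
#' @export
robustness <- function(result, table, structure, params,
                       control = equilibrium_control(),
                       include_removed = FALSE) {
  surv_h <- which(result$survivors_h)
  n_base <- sum(result$survivors_h) + sum(result$survivors_p)
  if (length(surv_h) == 0 || n_base <= 1) return(NA_real_)
  out <- numeric(length(surv_h))
  for (s in seq_along(surv_h)) {
    j <- surv_h[s]
    H0 <- result$H; H0[j] <- 0
    res2 <- integrate_to_equilibrium(table, structure, params,
                                     control = control,
                                     initial = list(H = H0, P = result$P))
    alive2 <- sum(res2$survivors_h[-j] & result$survivors_h[-j]) +
      sum(res2$survivors_p & result$survivors_p)
    out[s] <- if (include_removed)
      100 * alive2 / n_base
    else
      100 * alive2 / (n_base - 1)
  }
  mean(out)
}

#' All four stability facets of one equilibrium
#'
#' Convenience wrapper returning persistence, diversity (survivor count),
#' resilience and robustness in one list; undefined metrics are `NA`.
#'
#' @inheritParams robustness
#' @param metrics Character subset of
#'   `c("persistence", "resilience", "robustness")`; skipping robustness
#'   avoids its removal re-integrations when only persistence is needed.
#' @return Named list with `persistence`, `diversity`, `resilience`,
#'   `robustness` (unrequested entries `NA`).
#' @export
stability_report <- function(result, table, structure, params,
                             control = equilibrium_control(),
                             metrics = c("persistence", "resilience",
                                         "robustness")) {
  pers <- persistence(result)
  list(
    persistence = pers,
    diversity = sum(result$survivors_h) + sum(result$survivors_p),
    resilience = if ("resilience" %in% metrics)
      resilience(result, table, structure, params) else NA_real_,
    robustness = if ("robustness" %in% metrics)
      robustness(result, table, structure, params, control) else NA_real_
  )
}
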