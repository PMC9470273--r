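#' Parameters of the obligate-mutualism community model
#'
#' Bundles every parameter of one simulation of the bipartite dynamics: the
#' abundance of each hummingbird species `H_j` and of flowers of each plant
#' species `P_i` follows
#' \deqn{\frac{dH_j}{dt} = H_j\Big(r_j +
#'   \frac{\alpha \sum_i I_{ij} O_{ij} P_i}
#'        {1 + \beta \sum_i I_{ij} O_{ij} P_i + c \sum_k \Omega_{kj} H_k}
#'   - \sum_k cs_{j,k} H_k\Big)}
#' and symmetrically for plants with \eqn{\Theta} and `H` and `P` swapped.
#' The saturating mutualistic benefit grows with mutualism strength
#' `alpha`, saturates with handling time `beta`, and is depressed by
#' within-guild competitors for mutualistic partners with maximal strength
#' `comp` (the competition term sits in the denominator of the functional
#' response: crowded partners are shared, not stacked). Competition for
#' space is intraspecific by default (`cs_intra = 1`, `cs_inter = 0`).
#' Negative growth rates make the mutualism obligate: without benefit every
#' species declines.
#'
#' @param alpha Mutualism strength, >= 0.
#' @param comp Competition strength for mutualistic partners (the symbol
#'   usually written `c`, renamed to avoid masking R's `c()`), >= 0.
#' @param r_p,r_h Growth-rate vectors for plants and hummingbirds (length
#'   `n_p`, `n_h`); see [sample_growth_rates()].
#' @param beta Handling time of the functional response (default 0.8).
#' @param cs_intra Intraspecific competition for space (default 1).
#' @param cs_inter Interspecific within-guild competition for space
#'   (default 0).
#' @param extinction_threshold Abundance at or below which a species counts
#'   extinct (default `1e-5`).
#' @param initial_abundance Starting abundance of every species (default 1).
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(alpha, comp, r_p, r_h, beta = 0.8,
                             cs_intra = 1, cs_inter = 0,
                             extinction_threshold = 1e-5,
                             initial_abundance = 1) {
  stopifnot(alpha >= 0, comp >= 0, beta >= 0, cs_intra >= 0, cs_inter >= 0,
            extinction_threshold > 0, initial_abundance >= 0,
            all(is.finite(r_p)), all(is.finite(r_h)))
  structure(list(alpha = alpha, comp = comp, beta = beta,
                 r_p = as.numeric(r_p), r_h = as.numeric(r_h),
                 cs_intra = cs_intra, cs_inter = cs_inter,
                 extinction_threshold = extinction_threshold,
                 initial_abundance = initial_abundance),
            class = "model_parameters")
}

#' Sample obligate-mutualist growth rates
#'
#' Draws one beta-shape parameter `b` from `exp(U(log 0.3, log 15))` per
#' call, then `n_species` independent rates `r = -0.5 * Beta(1, b)`. Values
#' are bounded in `[-0.5, 0]`; small `b` concentrates rates near `-0.5`
#' (strongly dependent species), large `b` near 0. Draw once per guild per
#' replicate so plants and hummingbirds get independent `b` values.
#'
#' @param n_species Number of rates to draw (>= 1).
#' @param seed Optional integer seed; `NULL` uses (and advances) the current
#'   RNG stream.
#' @param b Optional fixed shape parameter, bypassing the lognormal-range
#'   draw (e.g. `b = 1` gives rates uniform on `[-0.5, 0]`).
#' @return Numeric vector of length `n_species` in `[-0.5, 0]`, with the
#'   shape parameter attached as attribute `"b"`.
#' @export
#' @examples
#' r <- sample_growth_rates(5, seed = 1)
#' range(r)
sample_growth_rates <- function(n_species, seed = NULL, b = NULL) {
  stopifnot(n_species >= 1)
  with_seed(seed, {
    if (is.null(b)) b <- exp(runif(1, log(0.3), log(15)))
    stopifnot(b > 0)
    r <- -0.5 * rbeta(n_species, shape1 = 1, shape2 = b)
    attr(r, "b") <- b
    r
  })
}

# Precomputed arrays for fast right-hand-side evaluation.
# Wh[i, k + (j-1)*n_h] = I[i,j] * I[i,k] * Mh[i,k,j], so that
# t(Wh) %*% P unfolds to the numerator matrix [k, j] of Omega; Wp analogous.
build_model_context <- function(table, structure) {
  n_p <- length(table$plants); n_h <- length(table$birds)
  stopifnot(all(dim(structure$O) == c(n_p, n_h)),
            all(dim(structure$Mh) == c(n_p, n_h, n_h)),
            all(dim(structure$Mp) == c(n_h, n_p, n_p)))
  I <- table$I
  IO <- I * structure$O
  Ikj <- I[, rep(1:n_h, times = n_h), drop = FALSE] *
    I[, rep(1:n_h, each = n_h), drop = FALSE]
  Wh <- Ikj * matrix(structure$Mh, nrow = n_p)
  Ih <- t(I)
  Iki <- Ih[, rep(1:n_p, times = n_p), drop = FALSE] *
    Ih[, rep(1:n_p, each = n_p), drop = FALSE]
  Wp <- Iki * matrix(structure$Mp, nrow = n_h)
  list(n_p = n_p, n_h = n_h, IO = IO, Wh = Wh, Wp = Wp)
}

# Omega/Theta and partner-availability sums from a precomputed context
context_competition <- function(H, P, ctx) {
  Dh <- drop(crossprod(ctx$IO, P))                 # sum_i I O P per bird
  numH <- matrix(drop(crossprod(ctx$Wh, P)), ctx$n_h, ctx$n_h)  # [k, j]
  Omega <- numH
  nz <- Dh > 0
  Omega[, nz] <- sweep(numH[, nz, drop = FALSE], 2, Dh[nz], "/")
  Omega[, !nz] <- 0
  Dp <- drop(ctx$IO %*% H)                         # sum_j I O H per plant
  numP <- matrix(drop(crossprod(ctx$Wp, H)), ctx$n_p, ctx$n_p)  # [k, i]
  Theta <- numP
  nz <- Dp > 0
  Theta[, nz] <- sweep(numP[, nz, drop = FALSE], 2, Dp[nz], "/")
  Theta[, !nz] <- 0
  list(Omega = Omega, Theta = Theta, Dh = Dh, Dp = Dp)
}

#' Competition matrices for mutualistic partners
#'
#' Abundance-weighted competition coefficients within each guild:
#' \deqn{\Omega_{kj} = \frac{\sum_i P_i I_{ij} I_{ik} Mh_{ikj}}
#'                         {\sum_i I_{ij} O_{ij} P_i}}
#' (competition imposed by hummingbird `k` on hummingbird `j`), and the
#' analogue \eqn{\Theta_{ki}} for plants weighted by `H`. Entries lie in
#' `[0, 1]` because `Mh_{ikj} <= O_{ij}` termwise. When a focal species has
#' no abundance-weighted partners (zero denominator) its column is set to 0;
#' its mutualistic benefit is then also 0 and it simply decays.
#'
#' @param state List with abundance vectors `H` (birds) and `P` (plants).
#' @param table An [interaction_table()].
#' @param structure A matching `seasonal_structure`.
#' @return List with matrices `Omega` (`n_h x n_h`, `[k, j]`) and `Theta`
#'   (`n_p x n_p`, `[k, i]`).
#' @export
competition_matrices <- function(state, table, structure) {
  ctx <- build_model_context(table, structure)
  if (length(state$H) != ctx$n_h || length(state$P) != ctx$n_p)
    stop("state dimensions do not match the table")
  stopifnot(all(state$H >= 0), all(state$P >= 0))
  cm <- context_competition(state$H, state$P, ctx)
  list(Omega = cm$Omega, Theta = cm$Theta)
}

# core derivative computation on a prebuilt context
context_rhs <- function(H, P, params, ctx) {
  cm <- context_competition(H, P, ctx)
  compH <- drop(crossprod(cm$Omega, H))   # sum_k Omega[k,j] H_k
  compP <- drop(crossprod(cm$Theta, P))   # sum_k Theta[k,i] P_k
  benH <- params$alpha * cm$Dh / (1 + params$beta * cm$Dh + params$comp * compH)
  benP <- params$alpha * cm$Dp / (1 + params$beta * cm$Dp + params$comp * compP)
  spaceH <- params$cs_intra * H + params$cs_inter * (sum(H) - H)
  spaceP <- params$cs_intra * P + params$cs_inter * (sum(P) - P)
  dH <- unname(H * (params$r_h + benH - spaceH))
  dP <- unname(P * (params$r_p + benP - spaceP))
  dH[H == 0] <- 0
  dP[P == 0] <- 0
  list(dH = dH, dP = dP)
}

#' Right-hand side of the community model
#'
#' Evaluates the derivatives of all abundances at a given state. Species at
#' exactly zero abundance have derivative exactly zero (extinction is
#' absorbing in this multiplicative model).
#'
#' @inheritParams competition_matrices
#' @param params A [model_parameters()] object.
#' @return List with derivative vectors `dH` and `dP`.
#' @export
model_rhs <- function(state, params, table, structure) {
  if (any(!is.finite(state$H)) || any(!is.finite(state$P)))
    stop("non-finite abundances in state")
  ctx <- build_model_context(table, structure)
  if (length(state$H) != ctx$n_h || length(state$P) != ctx$n_p)
    stop("state dimensions do not match the table")
  if (length(params$r_h) != ctx$n_h || length(params$r_p) != ctx$n_p)
    stop("growth-rate vectors do not match the table")
  context_rhs(state$H, state$P, params, ctx)
}

#' Control settings for equilibrium integration
#'
#' @param window Length of one integration window in model-time units.
#' @param max_windows Number of windows before giving up. The default (120)
#'   guarantees that with intraspecific space competition of 1 any species
#'   receiving no mutualistic benefit falls below the `1e-5` extinction
#'   threshold within the budget (`dX/dt <= -X^2` implies
#'   `X(t) <= 1/(1 + t)`), however close to zero its growth rate is.
#' @param tol Convergence tolerance on `max |dX/dt|` over surviving species.
#'   The default `1e-10` is the square of the extinction threshold: a
#'   species declining towards zero with a near-zero growth rate has
#'   `|dX/dt| ~ X^2`, so any looser tolerance can declare equilibrium while
#'   such a species still sits above the threshold.
#' @param clamp `"windows"` (default) zeroes species at or below the
#'   extinction threshold after every window; `"end"` only at termination.
#' @param rtol,atol Integrator tolerances passed to [deSolve::ode()].
#' @return A list of class `equilibrium_control`.
#' @export
equilibrium_control <- function(window = 1000, max_windows = 120,
                                tol = 1e-10, clamp = c("windows", "end"),
                                rtol = 1e-8, atol = 1e-12) {
  clamp <- match.arg(clamp)
  stopifnot(window > 0, max_windows >= 1, tol > 0)
  structure(list(window = window, max_windows = max_windows, tol = tol,
                 clamp = clamp, rtol = rtol, atol = atol),
            class = "equilibrium_control")
}

#' Integrate the community model to its ecological equilibrium
#'
#' Solves the stiff system with [deSolve::ode()] (lsoda) in successive
#' windows. After each window species at or below the extinction threshold
#' are clamped to zero (no numerical resurrection), and the run terminates
#' once the largest derivative over surviving species drops below `tol`
#' (converged) or the window budget is exhausted. An all-zero start is an
#' absorbing state and converges immediately.
#'
#' @inheritParams model_rhs
#' @param control An [equilibrium_control()] list.
#' @param initial Optional list with starting vectors `H`, `P`; by default
#'   every species starts at `params$initial_abundance`.
#' @return An object of class `equilibrium_result`: list with `H`, `P`
#'   (extinct species at exactly 0), logical survivor masks `survivors_h`,
#'   `survivors_p` (strictly above the threshold), `converged`, `residual`
#'   (max `|dX/dt|` over survivors at termination), `elapsed_model_time`,
#'   `windows`, and `failed` (integrator error, never an exception).
#' @export
integrate_to_equilibrium <- function(table, structure, params,
                                     control = equilibrium_control(),
                                     initial = NULL) {
  ctx <- build_model_context(table, structure)
  if (length(params$r_h) != ctx$n_h || length(params$r_p) != ctx$n_p)
    stop("growth-rate vectors do not match the table")
  thr <- params$extinction_threshold
  H <- if (is.null(initial)) rep(params$initial_abundance, ctx$n_h)
       else as.numeric(initial$H)
  P <- if (is.null(initial)) rep(params$initial_abundance, ctx$n_p)
       else as.numeric(initial$P)
  stopifnot(length(H) == ctx$n_h, length(P) == ctx$n_p)

  ode_fn <- function(t, y, parms) {
    y[y < 0] <- 0
    d <- context_rhs(y[seq_len(ctx$n_h)],
                     y[ctx$n_h + seq_len(ctx$n_p)], params, ctx)
    list(c(d$dH, d$dP))
  }
  residual_of <- function(H, P) {
    d <- context_rhs(H, P, params, ctx)
    alive <- c(H, P) > thr
    if (!any(alive)) 0 else max(abs(c(d$dH, d$dP)[alive]))
  }

  elapsed <- 0; windows <- 0; failed <- FALSE
  converged <- residual_of(H, P) < control$tol
  while (!converged && windows < control$max_windows) {
    sol <- try(deSolve::ode(
      y = c(H, P), times = c(0, control$window), func = ode_fn,
      parms = NULL, method = "lsoda",
      rtol = control$rtol, atol = control$atol), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < 2 ||
        any(!is.finite(sol[nrow(sol), -1]))) {
      failed <- TRUE
      break
    }
    y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    H <- y[seq_len(ctx$n_h)]; P <- y[ctx$n_h + seq_len(ctx$n_p)]
    if (control$clamp == "windows") {
      H[H <= thr] <- 0
      P[P <= thr] <- 0
    }
    elapsed <- elapsed + control$window
    windows <- windows + 1
    converged <- residual_of(H, P) < control$tol
  }
  if (control$clamp == "end") {
    H[H <= thr] <- 0
    P[P <= thr] <- 0
  }
  structure(list(
    H = H, P = P,
    survivors_h = H > thr, survivors_p = P > thr,
    converged = converged && !failed,
    residual = residual_of(H, P),
    elapsed_model_time = elapsed, windows = windows, failed = failed,
    params = params),
    class = "equilibrium_result")
}

#' @exportS3Method base::print
print.equilibrium_result <- function(x, ...) {
  cat("Equilibrium result: ", sum(x$survivors_p), "/", length(x$P),
      " plants and ", sum(x$survivors_h), "/", length(x$H),
      " hummingbirds surviving\n", sep = "")
  cat("  converged: ", x$converged, " (residual ",
      format(x$residual, digits = 3), ", ", x$windows, " windows)\n",
      sep = "")
  invisible(x)
}

#' Parameter transforms for the relaxed-assumption simulation variants
#'
#' Two model variants relax obligate mutualism before integration:
#' `"shifted_r"` recentres plant growth rates at their median
#' (`r_p - median(r_p)`), making half the plants partially independent of
#' hummingbirds; `"absolute_r_cs"` flips plant growth rates positive
#' (`|r_p|`) and turns on interspecific competition for space
#' (`cs_inter = 0.05`) in both guilds. `"none"` returns the input.
#'
#' @param params A [model_parameters()] object.
#' @param variant One of `"none"`, `"shifted_r"`, `"absolute_r_cs"`.
#' @return A transformed `model_parameters` object.
#' @export
apply_variant <- function(params,
                          variant = c("none", "shifted_r", "absolute_r_cs")) {
  variant <- match.arg(variant)
  if (variant == "shifted_r") {
    params$r_p <- params$r_p - stats::median(params$r_p)
  } else if (variant == "absolute_r_cs") {
    params$r_p <- abs(params$r_p)
    params$cs_inter <- 0.05
  }
  params
}
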