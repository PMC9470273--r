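#' Default path-model edge list
#'
#' The directed acyclic structure used to attribute effects of seasonal
#' structure on stability: the seasonal indicator feeds every mediator
#' (diversity, connectance, interaction overlap, total abundance);
#' diversity is treated as upstream of the other three mediators; the
#' responses (resilience, robustness) receive the seasonal indicator and
#' all four mediators. This DAG is a documented reconstruction — the
#' mediators other than diversity are not linked among themselves.
#'
#' @return Data frame with columns `from`, `to`.
#' @export
path_model_edges <- function() {
  mediators <- c("diversity", "connectance", "interaction_overlap",
                 "total_abundance")
  responses <- c("resilience", "robustness")
  rbind(
    data.frame(from = "seasonal", to = mediators),
    data.frame(from = "diversity",
               to = setdiff(mediators, "diversity")),
    expand.grid(from = c("seasonal", mediators), to = responses,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  )
}

#' Select parameter combinations suitable for path analysis
#'
#' Keeps the (`alpha`, `c`) combinations with intermediate mean persistence
#' (strictly between 20% and 90%, averaged over rows of both seasonal
#' modes pooled), avoiding near-collinear saturated cells and
#' near-collapsed ones, and drops the no-competition control (`c = 0`).
#'
#' @param records Data frame from [run_design()] with columns `alpha`, `c`,
#'   `persistence`.
#' @param lower,upper Persistence bounds (default 20 and 90).
#' @return Data frame with columns `alpha`, `c`, `mean_persistence`.
#' @export
select_combinations <- function(records, lower = 20, upper = 90) {
  agg <- aggregate(records$persistence,
                   by = list(alpha = records$alpha, c = records$c),
                   FUN = mean, na.rm = TRUE)
  names(agg)[3] <- "mean_persistence"
  keep <- agg$c != 0 & agg$mean_persistence > lower &
    agg$mean_persistence < upper
  out <- agg[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Nakagawa variance decomposition of a lmer fit: marginal r2 uses fixed
# effects only, conditional adds the community random intercept
nakagawa_r2 <- function(fit) {
  if (inherits(fit, "lm"))
    return(c(marginal = summary(fit)$r.squared,
             conditional = summary(fit)$r.squared))
  var_f <- var(as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_u <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  var_e <- attr(vc, "sc")^2
  tot <- var_f + var_u + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_u) / tot)
}

# fit one endogenous variable on its parents; mixed model with community
# random intercept, falling back to lm when singular or unfittable
fit_path_equation <- function(data, response, parents, random_intercept) {
  rhs <- paste(parents, collapse = " + ")
  fit <- NULL
  if (random_intercept) {
    form <- as.formula(paste(response, "~", rhs, "+ (1 | community)"))
    fit <- try(suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = data, REML = TRUE))), silent = TRUE)
    if (inherits(fit, "try-error") ||
        lme4::isSingular(fit, tol = 1e-4)) {
      warning("singular or failed mixed fit for '", response,
              "'; falling back to fixed effects only", call. = FALSE)
      fit <- NULL
    }
  }
  if (is.null(fit))
    fit <- lm(as.formula(paste(response, "~", rhs)), data = data)
  sm <- coef(summary(fit))
  keep <- match(parents, rownames(sm))
  pcol <- grep("^Pr\\(", colnames(sm))
  edges <- data.frame(
    from = parents, to = response,
    coefficient = sm[keep, "Estimate"],
    se = sm[keep, "Std. Error"],
    p_value = sm[keep, pcol],
    row.names = NULL)
  r2 <- nakagawa_r2(fit)
  list(edges = edges, r2 = data.frame(variable = response,
                                      r2_marginal = r2[["marginal"]],
                                      r2_conditional = r2[["conditional"]]))
}

# all directed paths from `from` to `to` along an edge list
enumerate_paths <- function(edges, from, to) {
  out <- list()
  walk <- function(node, path) {
    if (node == to) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    nxt <- edges$to[edges$from == node]
    for (n in nxt) walk(n, c(path, n))
  }
  walk(from, from)
  out
}

#' Fit the path analysis for one parameter combination
#'
#' Chained standardized regressions over the DAG of [path_model_edges()]:
#' one model per endogenous variable, with a community random intercept
#' (falling back to fixed effects when the fit is singular). Rows with zero
#' persistence are removed first (resilience and robustness are undefined
#' there), then every variable — including the 0/1 seasonal indicator — is
#' standardized to zero mean and unit variance within the subset, so
#' coefficients are comparable across edges and combinations. Indirect
#' effects are the products of standardized coefficients along each
#' seasonal-to-response path, reported per path and summed per response.
#'
#' @param records Data frame of simulation records for a single (`alpha`,
#'   `c`) combination, with columns `community`, `mode` (or a 0/1
#'   `seasonal` column), the four mediators and the responses. `mode` is
#'   encoded as `seasonal = 1` for `"empirical"` (or `"randomized"`) and 0
#'   for `"flattened"`.
#' @param edges Edge list; default [path_model_edges()].
#' @param random_intercept Use a community random intercept (default TRUE;
#'   needs >= 2 communities).
#' @param drop_zero_variance Drop edges whose variables are constant in the
#'   subset (logged), rather than failing.
#' @return List of class `path_result`: `edges` (standardized coefficient,
#'   standard error, p-value and significance per edge), `r2` (marginal and
#'   conditional r-squared per endogenous variable), `indirect` (one row
#'   per seasonal-to-response path plus per-response totals), `n_records`.
#' @export
fit_path_analysis <- function(records, edges = path_model_edges(),
                              random_intercept = TRUE,
                              drop_zero_variance = TRUE) {
  df <- as.data.frame(records)
  if (!"seasonal" %in% names(df)) {
    stopifnot("mode" %in% names(df))
    df$seasonal <- as.numeric(df$mode != "flattened")
  }
  if ("persistence" %in% names(df)) df <- df[df$persistence > 0, ]
  vars <- unique(c(edges$from, edges$to))
  miss <- setdiff(vars, names(df))
  if (length(miss))
    stop("records lack variable(s): ", paste(miss, collapse = ", "))
  df <- df[complete.cases(df[, vars]), , drop = FALSE]
  if (nrow(df) < 10) stop("too few usable records for a path analysis")
  if (random_intercept && length(unique(df$community)) < 2) {
    warning("fewer than 2 communities; dropping random intercept",
            call. = FALSE)
    random_intercept <- FALSE
  }
  sds <- vapply(df[vars], sd, numeric(1))
  if (any(sds == 0)) {
    if (!drop_zero_variance)
      stop("zero-variance variable(s): ",
           paste(vars[sds == 0], collapse = ", "))
    dead <- vars[sds == 0]
    warning("dropping edges of zero-variance variable(s): ",
            paste(dead, collapse = ", "), call. = FALSE)
    edges <- edges[!(edges$from %in% dead) & !(edges$to %in% dead), ]
    vars <- unique(c(edges$from, edges$to))
  }
  for (v in vars) df[[v]] <- as.numeric(scale(df[[v]]))

  endo <- unique(edges$to)
  fits <- lapply(endo, function(resp)
    fit_path_equation(df, resp, edges$from[edges$to == resp],
                      random_intercept))
  edge_tab <- do.call(rbind, lapply(fits, `[[`, "edges"))
  edge_tab$significant <- edge_tab$p_value < 0.05
  r2_tab <- do.call(rbind, lapply(fits, `[[`, "r2"))

  coef_of <- function(from, to) {
    edge_tab$coefficient[edge_tab$from == from & edge_tab$to == to]
  }
  indirect <- list()
  for (resp in intersect(c("resilience", "robustness"), endo)) {
    paths <- enumerate_paths(edge_tab[, c("from", "to")], "seasonal", resp)
    for (p in paths) {
      eff <- prod(mapply(coef_of, p[-length(p)], p[-1]))
      indirect[[length(indirect) + 1L]] <- data.frame(
        response = resp, path = paste(p, collapse = " -> "),
        effect = eff, direct = length(p) == 2L)
    }
  }
  if (length(indirect)) {
    indirect <- do.call(rbind, indirect)
    totals <- aggregate(effect ~ response, data = indirect, FUN = sum)
    names(totals)[2] <- "total_effect"
  } else {
    indirect <- data.frame(response = character(0), path = character(0),
                           effect = numeric(0), direct = logical(0))
    totals <- data.frame(response = character(0), total_effect = numeric(0))
  }

  structure(list(edges = edge_tab, r2 = r2_tab, indirect = indirect,
                 totals = totals, n_records = nrow(df)),
            class = "path_result")
}

#' @exportS3Method base::print
print.path_result <- function(x, ...) {
  cat("Path analysis over", x$n_records, "records\n")
  sig <- x$edges[x$edges$significant, ]
  cat("  significant edges (p < 0.05):", nrow(sig), "of",
      nrow(x$edges), "\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Simulate records from a known linear path model
#'
#' Validation generator: draws records that follow the package's path DAG
#' with user-chosen standardized coefficients, Gaussian disturbances and
#' community random intercepts. Each variable is constructed with unit
#' variance (loadings tracked analytically on independent shocks), so the
#' chosen coefficients are directly the standardized effects a correct
#' path analysis should recover.
#'
#' @param n Number of records.
#' @param coefficients Named numeric vector of edge coefficients, names
#'   `"from->to"` over the edges of [path_model_edges()]; missing edges
#'   default to 0.
#' @param n_communities Number of communities for the random intercepts.
#' @param icc Variance share of the community intercept in each endogenous
#'   variable (default 0.05).
#' @param seed Integer seed.
#' @return Data frame with `community`, `seasonal` (0/1) and the model's
#'   variables; endogenous variables have (population) unit variance.
#' @export
simulate_path_records <- function(n, coefficients, n_communities = 10,
                                  icc = 0.05, seed = 1) {
  edges <- path_model_edges()
  key <- paste0(edges$from, "->", edges$to)
  beta <- setNames(rep(0, nrow(edges)), key)
  if (!all(names(coefficients) %in% key))
    stop("unknown edge(s): ",
         paste(setdiff(names(coefficients), key), collapse = ", "))
  beta[names(coefficients)] <- coefficients

  with_seed(seed, {
    comm <- sample.int(n_communities, n, replace = TRUE)
    # each variable = loading vector over independent unit shocks
    # (seasonal shock, one intercept shock + one residual shock per
    # endogenous variable); covariances follow from dot products
    order_vars <- c("diversity", "connectance", "interaction_overlap",
                    "total_abundance", "resilience", "robustness")
    shocks <- list(seasonal = c(seasonal = 1))
    values <- list(seasonal = sample(c(-1, 1), n, replace = TRUE))
    shock_draws <- list(seasonal = values$seasonal)
    for (v in order_vars) {
      parents <- edges$from[edges$to == v]
      load <- numeric(0)
      val <- numeric(n)
      for (p in parents) {
        b <- beta[paste0(p, "->", v)]
        pl <- shocks[[p]] * b
        load <- merge_loadings(load, pl)
        val <- val + b * values[[p]]
      }
      explained <- sum(load^2)
      if (explained + icc >= 1)
        stop("coefficients imply variance >= 1 for '", v, "'")
      u <- stats::rnorm(n_communities, 0, sqrt(icc))
      e <- stats::rnorm(n, 0, sqrt(1 - explained - icc))
      val <- val + u[comm] + e
      load <- merge_loadings(load, setNames(sqrt(icc), paste0("u_", v)))
      load <- merge_loadings(load,
                             setNames(sqrt(1 - explained - icc),
                                      paste0("e_", v)))
      shocks[[v]] <- load
      values[[v]] <- val
    }
    out <- data.frame(community = factor(comm), seasonal = values$seasonal)
    for (v in order_vars) out[[v]] <- values[[v]]
    out$persistence <- 50  # all records usable downstream
    out
  })
}

# add two sparse loading vectors (named numerics) entrywise
merge_loadings <- function(a, b) {
  keys <- union(names(a), names(b))
  out <- setNames(numeric(length(keys)), keys)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out
}
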