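#' Specify a factorial simulation design
#'
#' A design crosses communities with growth-rate replicates, mutualism
#' strengths, competition strengths and seasonal modes. Growth rates are
#' drawn once per (community, replicate) and shared across every `alpha`,
#' `comp` level and mode of that replicate, so with/without-seasonality
#' contrasts are paired: the two rows of a pair differ only in the seasonal
#' structure.
#'
#' @param communities Named list of [interaction_table()] objects, or a
#'   list/vector of presets (names or [community_preset()]s) generated at
#'   run time with seeds derived from `master_seed`.
#' @param n_replicates Growth-rate replicates per community.
#' @param alpha_levels,c_levels Numeric vectors of mutualism and
#'   competition strengths (>= 0).
#' @param modes Subset of `c("empirical", "flattened", "randomized")`.
#' @param variant One of `"none"`, `"shifted_r"`, `"absolute_r_cs"`; see
#'   [apply_variant()].
#' @param master_seed Integer seed from which every community, replicate
#'   and randomization seed is derived deterministically.
#' @param phenology_breadth Kernel breadth passed to [generate_community()]
#'   when communities are presets.
#' @return An object of class `design_spec`.
#' @seealso [paper_design_spec()], [desk_design_spec()]
#' @export
design_spec <- function(communities, n_replicates, alpha_levels, c_levels,
                        modes = c("empirical", "flattened"),
                        variant = "none", master_seed = 1,
                        phenology_breadth = 2) {
  modes <- match.arg(modes, c("empirical", "flattened", "randomized"),
                     several.ok = TRUE)
  variant <- match.arg(variant, c("none", "shifted_r", "absolute_r_cs"))
  stopifnot(length(communities) >= 1, n_replicates >= 1,
            length(alpha_levels) >= 1, length(c_levels) >= 1,
            all(alpha_levels >= 0), all(c_levels >= 0))
  if (is.character(communities)) communities <- as.list(communities)
  nm <- names(communities)
  if (is.null(nm)) {
    nm <- vapply(communities, function(x) {
      if (inherits(x, "community_preset")) x$name
      else if (is.character(x)) x
      else stop("unnamed interaction tables; supply a named list")
    }, character(1))
    names(communities) <- nm
  }
  structure(list(communities = communities, n_replicates = n_replicates,
                 alpha_levels = sort(unique(alpha_levels)),
                 c_levels = sort(unique(c_levels)), modes = modes,
                 variant = variant, master_seed = as.integer(master_seed),
                 phenology_breadth = phenology_breadth),
            class = "design_spec")
}

#' The full published-scale factorial design
#'
#' 11 communities x 250 replicates x 7 mutualism levels x 7 competition
#' levels x 2 seasonal modes = 269,500 simulations. Enumeration is instant;
#' running it is a long batch job.
#'
#' @param master_seed Master seed.
#' @return A [design_spec()].
#' @export
paper_design_spec <- function(master_seed = 1) {
  design_spec(as.list(community_presets()$name), n_replicates = 250,
              alpha_levels = seq(0, 3, 0.5), c_levels = seq(0, 3, 0.5),
              modes = c("empirical", "flattened"),
              master_seed = master_seed)
}

#' A desk-scale design for interactive work
#'
#' Two synthetic communities at the dimensions of the two smallest empirical
#' ones (Alaspungo 40x7, Yanacocha 32x11), 25 replicates, four levels per
#' strength axis, both seasonal modes. Runs in minutes on one core.
#'
#' @param master_seed Master seed.
#' @return A [design_spec()].
#' @export
desk_design_spec <- function(master_seed = 1) {
  design_spec(
    list(community_preset("Alaspungo"), community_preset("Yanacocha")),
    n_replicates = 25,
    alpha_levels = c(0, 1, 2, 3), c_levels = c(0, 1, 2, 3),
    modes = c("empirical", "flattened"),
    master_seed = master_seed)
}

#' Enumerate the configurations of a design
#'
#' Cartesian product of communities, replicates, `alpha` levels, `c` levels
#' and modes, with deterministic per-row seed bookkeeping. One row per
#' simulation to run; growth-rate seeds repeat across the `alpha`/`c`/mode
#' dimensions within a replicate (paired design).
#'
#' @param spec A [design_spec()].
#' @return A data frame with columns `community`, `replicate`, `alpha`,
#'   `c`, `mode`, `growth_seed`, `randomization_seed`.
#' @export
#' @examples
#' nrow(enumerate_design(paper_design_spec()))  # 269500
enumerate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  nm <- names(spec$communities)
  n_c <- length(nm)
  seeds <- derive_seeds(spec$master_seed,
                        n_c + 2L * n_c * spec$n_replicates)
  community_seed <- seeds[seq_len(n_c)]
  growth_seed <- matrix(seeds[n_c + seq_len(n_c * spec$n_replicates)],
                        nrow = n_c)
  rand_seed <- matrix(seeds[n_c + n_c * spec$n_replicates +
                              seq_len(n_c * spec$n_replicates)],
                      nrow = n_c)
  grid <- expand.grid(
    mode = spec$modes, c = spec$c_levels, alpha = spec$alpha_levels,
    replicate = seq_len(spec$n_replicates), community = nm,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("community", "replicate", "alpha", "c", "mode")]
  ci <- match(grid$community, nm)
  grid$community_seed <- community_seed[ci]
  grid$growth_seed <- growth_seed[cbind(ci, grid$replicate)]
  grid$randomization_seed <- rand_seed[cbind(ci, grid$replicate)]
  rownames(grid) <- NULL
  grid
}

#' Run a factorial simulation design
#'
#' Executes every configuration of the design: builds (or reuses) each
#' community, draws one growth-rate vector per guild per (community,
#' replicate) — shared across all `alpha`, `c` and modes of that replicate —
#' computes the seasonal structure for the requested mode (empirical
#' overlaps, all-ones, or a per-replicate phenology permutation), integrates
#' to equilibrium and records stability metrics and network indices.
#' Per-row integrator failures are recorded and the batch continues.
#'
#' @param spec A [design_spec()].
#' @param metrics Which expensive metrics to compute in addition to
#'   persistence/diversity: subset of `c("resilience", "robustness",
#'   "indices")`.
#' @param control An [equilibrium_control()].
#' @param progress Print one line per community x replicate.
#' @param resume Optional data frame from a previous partial run (or path
#'   to its CSV); matching rows are copied over instead of re-simulated.
#' @return A data frame of simulation records: identifiers, parameters,
#'   `b_p`/`b_h` (growth-rate shape draws), `converged`, `persistence`,
#'   `diversity`, `resilience`, `robustness`, `connectance`,
#'   `interaction_overlap`, `total_abundance`. Undefined metrics are `NA`.
#' @export
run_design <- function(spec, metrics = c("resilience", "robustness",
                                         "indices"),
                       control = equilibrium_control(), progress = FALSE,
                       resume = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (length(metrics))
    metrics <- match.arg(metrics, c("resilience", "robustness", "indices"),
                         several.ok = TRUE)
  grid <- enumerate_design(spec)
  if (is.character(resume)) resume <- read.csv(resume)
  if (!is.null(resume)) {
    key <- function(d) paste(d$community, d$replicate, d$alpha, d$c, d$mode)
    done <- match(key(grid), key(resume))
  } else done <- rep(NA_integer_, nrow(grid))

  nm <- names(spec$communities)
  tables <- list()
  for (k in seq_along(nm)) {
    obj <- spec$communities[[k]]
    tables[[nm[k]]] <- if (inherits(obj, "interaction_table")) obj
    else generate_community(
      if (is.character(obj)) community_preset(obj) else obj,
      phenology_breadth = spec$phenology_breadth,
      seed = grid$community_seed[match(nm[k], grid$community)])
  }
  structures <- lapply(tables, seasonal_structure)
  flats <- lapply(tables, flat_structure)

  rows <- vector("list", nrow(grid))
  cache <- new.env(parent = emptyenv())  # per-replicate growth rates etc.
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    if (!is.na(done[r])) {
      rows[[r]] <- resume[done[r], , drop = FALSE]
      next
    }
    tab <- tables[[g$community]]
    ck <- paste(g$community, g$replicate)
    if (is.null(cache[[ck]])) {
      gr <- with_seed(g$growth_seed, list(
        r_h = sample_growth_rates(length(tab$birds)),
        r_p = sample_growth_rates(length(tab$plants))))
      r_h <- gr$r_h
      r_p <- gr$r_p
      rnd <- if ("randomized" %in% spec$modes)
        seasonal_structure(
          randomize_phenologies(tab, seed = g$randomization_seed))
      else NULL
      cache[[ck]] <- list(r_p = r_p, r_h = r_h, rnd = rnd)
      if (progress)
        message(g$community, " replicate ", g$replicate)
    }
    cc <- cache[[ck]]
    str_use <- switch(as.character(g$mode),
                      empirical = structures[[g$community]],
                      flattened = flats[[g$community]],
                      randomized = cc$rnd)
    params <- apply_variant(
      model_parameters(alpha = g$alpha, comp = g$c,
                       r_p = cc$r_p, r_h = cc$r_h),
      spec$variant)
    res <- integrate_to_equilibrium(tab, str_use, params, control = control)
    rep_row <- data.frame(
      community = g$community, replicate = g$replicate,
      alpha = g$alpha, c = g$c, mode = g$mode, variant = spec$variant,
      growth_seed = g$growth_seed,
      b_p = attr(cc$r_p, "b"), b_h = attr(cc$r_h, "b"),
      converged = res$converged, failed = res$failed,
      persistence = persistence(res),
      diversity = diversity(res),
      resilience = NA_real_, robustness = NA_real_,
      connectance = NA_real_, interaction_overlap = NA_real_,
      total_abundance = total_abundance(res),
      stringsAsFactors = FALSE)
    if (!res$failed) {
      if ("resilience" %in% metrics)
        rep_row$resilience <- resilience(res, tab, str_use, params)
      if ("robustness" %in% metrics)
        rep_row$robustness <- robustness(res, tab, str_use, params,
                                         control = control)
      if ("indices" %in% metrics) {
        rep_row$connectance <- connectance(res, tab, str_use)
        rep_row$interaction_overlap <-
          interaction_overlap(res, tab, str_use)
      }
    }
    rows[[r]] <- rep_row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative change of a metric due to seasonal structure
#'
#' `100 * (with - without) / without`, the percentage change of a stability
#' metric when the seasonal structure is accounted for, relative to the
#' matched no-seasonality baseline. Undefined (NA) when the baseline is
#' zero — an impossible division, reported as missing rather than
#' infinite.
#'
#' @param metric_with,metric_without Metric values from paired
#'   configurations differing only in seasonal mode. Vectorized.
#' @return Percentage change(s); `NA` where `metric_without` is 0 or
#'   either input is missing.
#' @export
#' @examples
#' relative_change(75, 50)  # +50
relative_change <- function(metric_with, metric_without) {
  out <- 100 * (metric_with - metric_without) / metric_without
  out[!is.na(metric_without) & metric_without == 0] <- NA_real_
  out
}

#' Mode contrast of a metric over a results table
#'
#' Averages a metric per (`alpha`, `c`) cell within each seasonal mode and
#' returns the relative change of one mode against a baseline mode,
#' mirroring the with/without heatmap comparison.
#'
#' @param records Data frame from [run_design()].
#' @param metric Column name to contrast (e.g. `"persistence"`).
#' @param mode_with,mode_without Mode labels to compare (default
#'   `"empirical"` vs `"flattened"`).
#' @return Data frame with `alpha`, `c`, `mean_with`, `mean_without`,
#'   `relative_change`.
#' @export
mode_contrast <- function(records, metric, mode_with = "empirical",
                          mode_without = "flattened") {
  stopifnot(metric %in% names(records))
  agg <- function(mode) {
    d <- records[records$mode == mode, ]
    out <- aggregate(d[[metric]], by = list(alpha = d$alpha, c = d$c),
                     FUN = mean, na.rm = TRUE)
    names(out)[3] <- "value"
    out
  }
  w <- agg(mode_with); wo <- agg(mode_without)
  m <- merge(w, wo, by = c("alpha", "c"), suffixes = c("_with", "_without"))
  data.frame(alpha = m$alpha, c = m$c,
             mean_with = m$value_with, mean_without = m$value_without,
             relative_change = relative_change(m$value_with,
                                              m$value_without))
}
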