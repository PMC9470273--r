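#' Phenological overlap indices of a community
#'
#' Derives the seasonal structure of a community from its monthly counts:
#' the among-guild overlap matrix `O` and the within-guild overlap arrays
#' `Mh` (hummingbird pairs per shared plant) and `Mp` (plant pairs per
#' shared hummingbird). With plant phenologies normalized to sum one and
#' hummingbird phenologies normalized by their maximum,
#' \deqn{O_{ij} = \sum_m \frac{F^p_{im}}{\sum_m F^p_{im}}
#'                        \frac{F^h_{jm}}{\max_m F^h_{jm}},}
#' \deqn{Mh_{ikj} = \sum_m \frac{F^p_{im}}{\sum_m F^p_{im}}
#'   \frac{F^h_{km}}{\max_m F^h_{km}} \frac{F^h_{jm}}{\max_m F^h_{jm}},}
#' \deqn{Mp_{jki} = \sum_m \frac{F^h_{jm}}{\max_m F^h_{jm}}
#'   \frac{F^p_{km}}{\sum_m F^p_{km}} \frac{F^p_{im}}{\sum_m F^p_{im}}.}
#' All entries lie in `[0, 1]`; both normalizations are scale-free, so
#' rescaling any species' phenology row leaves every overlap unchanged.
#'
#' The default `convention = "printed"` uses exactly these normalizations.
#' Under it, two plants with identical constant phenologies have
#' `Mp = 1/12` (each sum-normalized profile contributes `1/12` per month)
#' while two such hummingbirds have `Mh = 1`; `convention = "symmetric"`
#' instead normalizes the focal-guild pair by its maxima and the shared
#' partner by its sum in *both* arrays, making `Mp` scale like `Mh`. The
#' default should not be changed lightly: downstream competition
#' coefficients are calibrated against it.
#'
#' @param table An [interaction_table()].
#' @param convention `"printed"` (default) or `"symmetric"`; affects `Mp`
#'   only.
#' @return An object of class `seasonal_structure`: list with `O`
#'   (`n_p x n_h`), `Mh` (`n_p x n_h x n_h`, symmetric in its last two
#'   indices), `Mp` (`n_h x n_p x n_p`, symmetric in its last two indices)
#'   and `convention`.
#' @seealso [flatten_structure()], [randomize_phenologies()]
#' @export
#' @examples
#' tab <- generate_community(community_preset("t", 4, 3, 6), seed = 1)
#' s <- seasonal_structure(tab)
#' range(s$O)
seasonal_structure <- function(table, convention = c("printed", "symmetric")) {
  convention <- match.arg(convention)
  validate_interaction_table(table)
  n_p <- length(table$plants); n_h <- length(table$birds)
  psum <- rowSums(table$Fp)
  hmax <- apply(table$Fh, 1, max)
  if (any(psum == 0) || any(hmax == 0))
    stop("species with all-zero phenology; overlaps undefined")
  pnorm <- table$Fp / psum          # plant profiles sum to 1
  hnorm <- table$Fh / hmax          # bird profiles peak at 1

  O <- pnorm %*% t(hnorm)
  Mh <- array(0, dim = c(n_p, n_h, n_h))
  for (m in 1:12)
    Mh <- Mh + outer(pnorm[, m], outer(hnorm[, m], hnorm[, m]))
  if (convention == "printed") {
    Mp <- array(0, dim = c(n_h, n_p, n_p))
    for (m in 1:12)
      Mp <- Mp + outer(hnorm[, m], outer(pnorm[, m], pnorm[, m]))
  } else {
    hsum <- table$Fh / rowSums(table$Fh)
    pmaxn <- table$Fp / apply(table$Fp, 1, max)
    Mp <- array(0, dim = c(n_h, n_p, n_p))
    for (m in 1:12)
      Mp <- Mp + outer(hsum[, m], outer(pmaxn[, m], pmaxn[, m]))
  }
  dimnames(O) <- list(table$plants, table$birds)
  dimnames(Mh) <- NULL
  dimnames(Mp) <- NULL
  structure(list(O = O, Mh = Mh, Mp = Mp, convention = convention),
            class = "seasonal_structure")
}

#' @rdname seasonal_structure
#' @return `within_guild_overlaps()` returns `list(Mh, Mp)`;
#'   `among_guild_overlap()` returns the matrix `O`.
#' @export
within_guild_overlaps <- function(table,
                                  convention = c("printed", "symmetric")) {
  s <- seasonal_structure(table, convention)
  list(Mh = s$Mh, Mp = s$Mp)
}

#' @rdname seasonal_structure
#' @export
among_guild_overlap <- function(table) {
  seasonal_structure(table)$O
}

#' @exportS3Method base::print
print.seasonal_structure <- function(x, ...) {
  cat("Seasonal structure (", nrow(x$O), " plants x ", ncol(x$O),
      " hummingbirds, convention '", x$convention, "')\n", sep = "")
  cat("  mean among-guild overlap O: ", round(mean(x$O), 3), "\n", sep = "")
  invisible(x)
}

#' Remove the seasonal structure
#'
#' Sets every entry of `O`, `Mh` and `Mp` to one, the "without seasonal
#' structure" treatment: all interactions behave as if fully simultaneous.
#' Idempotent.
#'
#' @param structure A `seasonal_structure`.
#' @return A `seasonal_structure` of identical shape, all entries 1.
#' @export
flatten_structure <- function(structure) {
  stopifnot(inherits(structure, "seasonal_structure"))
  out <- structure
  out$O[] <- 1
  out$Mh[] <- 1
  out$Mp[] <- 1
  out
}

#' Flat (no-seasonality) structure for a community
#'
#' Convenience constructor of the all-ones structure matching a table's
#' dimensions, without computing empirical overlaps first.
#'
#' @param table An [interaction_table()].
#' @return An all-ones `seasonal_structure`.
#' @export
flat_structure <- function(table) {
  n_p <- length(table$plants); n_h <- length(table$birds)
  structure(list(O = matrix(1, n_p, n_h,
                            dimnames = list(table$plants, table$birds)),
                 Mh = array(1, dim = c(n_p, n_h, n_h)),
                 Mp = array(1, dim = c(n_h, n_p, n_p)),
                 convention = "flat"),
            class = "seasonal_structure")
}

#' Randomize the seasonal structure of a community
#'
#' Null model: permutes the monthly phenology profiles among species within
#' each guild (plants and hummingbirds independently), leaving the binary
#' backbone `I` untouched, so randomized communities keep the same
#' interactions but a shuffled temporal organization. The multiset of
#' profiles is conserved exactly. An alternative mode shuffles the positive
#' monthly values within each guild's positive-cell mask instead.
#'
#' @param table An [interaction_table()].
#' @param seed Integer seed; identical seeds give identical permutations.
#' @param unit `"species"` (default; permute whole rows of `Fp` and `Fh`)
#'   or `"cells"` (shuffle positive values in place across the guild).
#' @return An [interaction_table()] with identical `I` and permuted
#'   phenologies. The pair-by-month `counts` array is dropped (it is no
#'   longer consistent with the permuted marginals).
#' @export
randomize_phenologies <- function(table, seed, unit = c("species", "cells")) {
  unit <- match.arg(unit)
  validate_interaction_table(table)
  n_p <- length(table$plants); n_h <- length(table$birds)
  with_seed(seed, {
    Fp <- table$Fp; Fh <- table$Fh
    if (unit == "species") {
      Fp <- Fp[sample.int(n_p), , drop = FALSE]
      Fh <- Fh[sample.int(n_h), , drop = FALSE]
    } else {
      mp <- Fp > 0; mh <- Fh > 0
      Fp[mp] <- sample(Fp[mp])
      Fh[mh] <- sample(Fh[mh])
    }
    rownames(Fp) <- table$plants
    rownames(Fh) <- table$birds
    interaction_table(table$plants, table$birds, table$I, Fp, Fh,
                      counts = NULL)
  })
}
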