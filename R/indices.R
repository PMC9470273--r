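# restrict a table and structure to the surviving species of a result
subset_community <- function(table, structure, keep_p, keep_h) {
  sub_table <- structure(list(
    plants = table$plants[keep_p], birds = table$birds[keep_h],
    I = table$I[keep_p, keep_h, drop = FALSE],
    Fp = table$Fp[keep_p, , drop = FALSE],
    Fh = table$Fh[keep_h, , drop = FALSE],
    counts = NULL), class = "interaction_table")
  sub_structure <- structure(list(
    O = structure$O[keep_p, keep_h, drop = FALSE],
    Mh = structure$Mh[keep_p, keep_h, keep_h, drop = FALSE],
    Mp = structure$Mp[keep_h, keep_p, keep_p, drop = FALSE],
    convention = structure$convention), class = "seasonal_structure")
  list(table = sub_table, structure = sub_structure)
}

#' Phenology-corrected connectance at equilibrium
#'
#' Mean of all entries of the network matrix `N = I * O` (elementwise)
#' restricted to surviving species. With a flat structure this reduces to
#' the binary connectance of the surviving backbone.
#'
#' @inheritParams resilience
#' @return Value in `[0, 1]`, or `NA` if either guild has no survivor.
#' @export
connectance <- function(result, table, structure) {
  keep_p <- which(result$survivors_p); keep_h <- which(result$survivors_h)
  if (length(keep_p) == 0 || length(keep_h) == 0) return(NA_real_)
  N <- (table$I * structure$O)[keep_p, keep_h, drop = FALSE]
  mean(N)
}

#' Within-guild interaction overlap at equilibrium
#'
#' Mean of all entries of the competition matrices `Omega` and `Theta`
#' (pooled), computed with every surviving abundance set to one and extinct
#' species removed — an abundance-free measure of functional redundancy
#' within guilds. Diagonal (self-overlap) entries are included by default.
#'
#' @inheritParams resilience
#' @param include_diagonal Include the self-competition diagonal in the
#'   mean (default `TRUE`).
#' @return Value in `[0, 1]`, or `NA` if either guild has no survivor.
#' @export
interaction_overlap <- function(result, table, structure,
                                include_diagonal = TRUE) {
  keep_p <- which(result$survivors_p); keep_h <- which(result$survivors_h)
  if (length(keep_p) == 0 || length(keep_h) == 0) return(NA_real_)
  sub <- subset_community(table, structure, keep_p, keep_h)
  cm <- competition_matrices(
    list(H = rep(1, length(keep_h)), P = rep(1, length(keep_p))),
    sub$table, sub$structure)
  vals <- if (include_diagonal) {
    c(cm$Omega, cm$Theta)
  } else {
    c(cm$Omega[row(cm$Omega) != col(cm$Omega)],
      cm$Theta[row(cm$Theta) != col(cm$Theta)])
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Total abundance and diversity at equilibrium
#'
#' `total_abundance()` sums hummingbird and flower abundances over
#' surviving species (a measure of community productivity); `diversity()`
#' counts the survivors.
#'
#' @param result An [integrate_to_equilibrium()] result.
#' @return A nonnegative number (sum or count).
#' @export
total_abundance <- function(result) {
  sum(result$H[result$survivors_h]) + sum(result$P[result$survivors_p])
}

#' @rdname total_abundance
#' @export
diversity <- function(result) {
  sum(result$survivors_h) + sum(result$survivors_p)
}

#' Equilibrium network indices
#'
#' Convenience wrapper returning connectance, interaction overlap, total
#' abundance and diversity of one equilibrium in one list.
#'
#' @inheritParams resilience
#' @return Named list `connectance`, `interaction_overlap`,
#'   `total_abundance`, `diversity`; undefined indices are `NA`.
#' @export
network_indices <- function(result, table, structure) {
  list(
    connectance = connectance(result, table, structure),
    interaction_overlap = interaction_overlap(result, table, structure),
    total_abundance = total_abundance(result),
    diversity = diversity(result)
  )
}
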