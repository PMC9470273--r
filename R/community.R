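#' Community presets emulating the 11 empirical plant-hummingbird networks
#'
#' Named presets with the plant richness, hummingbird richness and number of
#' unique pairwise interactions of the 11 Ecuadorian communities the package
#' is designed to emulate. [generate_community()] turns a preset into a
#' synthetic month-resolved interaction table with the same dimensions.
#'
#' @return A data frame with columns `name`, `n_plants`, `n_birds`,
#'   `target_links`, one row per community.
#' @seealso [community_preset()], [generate_community()]
#' @export
#' @examples
#' community_presets()
community_presets <- function() {
  data.frame(
    name = c("Alaspungo", "LasGralarias", "Maquipucuna", "MashpiCapuchin",
             "MashpiLaguna", "Sachatamia", "SantaLuciaLower",
             "SantaLuciaUpper", "UnPocoDelChoco", "Verdecocha", "Yanacocha"),
    n_plants = c(40, 59, 65, 43, 41, 44, 71, 55, 46, 46, 32),
    n_birds = c(7, 13, 17, 15, 17, 10, 22, 14, 13, 14, 11),
    target_links = c(113, 163, 238, 100, 126, 125, 221, 235, 130, 138, 101),
    stringsAsFactors = FALSE
  )
}

#' Define a community preset
#'
#' A preset fixes the dimensions of a synthetic community: how many plant and
#' hummingbird species it holds and how many unique plant-bird pairs ever
#' interact (the size of the binary backbone).
#'
#' @param name Community label. If it matches a row of [community_presets()]
#'   and the remaining arguments are missing, that row is used.
#' @param n_plants,n_birds Species richness per guild (>= 1).
#' @param target_links Number of unique interacting pairs; must satisfy
#'   `max(n_plants, n_birds) <= target_links <= n_plants * n_birds` so a
#'   backbone with no isolated species exists.
#' @return An object of class `community_preset`.
#' @export
#' @examples
#' community_preset("Alaspungo")
#' community_preset("tiny", n_plants = 4, n_birds = 3, target_links = 6)
community_preset <- function(name, n_plants, n_birds, target_links) {
  if (missing(n_plants) && missing(n_birds) && missing(target_links)) {
    reg <- community_presets()
    hit <- match(name, reg$name)
    if (is.na(hit))
      stop("unknown preset '", name, "'; see community_presets()")
    n_plants <- reg$n_plants[hit]
    n_birds <- reg$n_birds[hit]
    target_links <- reg$target_links[hit]
  }
  n_plants <- as.integer(n_plants)
  n_birds <- as.integer(n_birds)
  target_links <- as.integer(target_links)
  if (n_plants < 1L || n_birds < 1L || target_links < 1L)
    stop("n_plants, n_birds and target_links must all be >= 1")
  if (target_links > n_plants * n_birds)
    stop("target_links (", target_links, ") exceeds n_plants * n_birds (",
         n_plants * n_birds, ")")
  if (target_links < max(n_plants, n_birds))
    stop("target_links (", target_links, ") below max(n_plants, n_birds); ",
         "some species would have no partner")
  structure(list(name = name, n_plants = n_plants, n_birds = n_birds,
                 target_links = target_links),
            class = "community_preset")
}

#' @exportS3Method base::print
print.community_preset <- function(x, ...) {
  cat("Community preset '", x$name, "': ", x$n_plants, " plants x ",
      x$n_birds, " hummingbirds, ", x$target_links, " links\n", sep = "")
  invisible(x)
}

#' Construct a month-resolved interaction table
#'
#' The central data container: a binary backbone `I` (`I[i, j] = 1` iff plant
#' `i` and hummingbird `j` ever interact) together with monthly interaction
#' counts per species, `Fp` (plants x 12) and `Fh` (birds x 12). Counts are
#' real-valued: empirical tables average several years of sampling per month.
#'
#' @param plants,birds Character vectors of species labels.
#' @param I Binary matrix, `length(plants)` x `length(birds)`; no all-zero
#'   row or column is allowed (every species needs at least one partner).
#' @param Fp,Fh Nonnegative matrices of monthly counts (rows = species,
#'   12 columns); every row needs at least one positive month.
#' @param counts Optional pair-by-month array (`n_p` x `n_h` x 12) whose
#'   marginals are `Fp` and `Fh`; kept when known so the table can be written
#'   back to the long CSV format.
#' @return An object of class `interaction_table`.
#' @seealso [generate_community()], [read_long_csv()]
#' @export
interaction_table <- function(plants, birds, I, Fp, Fh, counts = NULL) {
  plants <- as.character(plants)
  birds <- as.character(birds)
  I <- matrix(as.numeric(I != 0), nrow = length(plants),
              dimnames = list(plants, birds))
  Fp <- matrix(as.numeric(Fp), nrow = length(plants),
               dimnames = list(plants, paste0("m", 1:12)))
  Fh <- matrix(as.numeric(Fh), nrow = length(birds),
               dimnames = list(birds, paste0("m", 1:12)))
  out <- structure(list(plants = plants, birds = birds, I = I,
                        Fp = Fp, Fh = Fh, counts = counts),
                   class = "interaction_table")
  validate_interaction_table(out)
  out
}

validate_interaction_table <- function(x) {
  stopifnot(inherits(x, "interaction_table"))
  n_p <- length(x$plants); n_h <- length(x$birds)
  if (n_p < 1L || n_h < 1L) stop("need at least one species per guild")
  if (!all(dim(x$I) == c(n_p, n_h))) stop("I has wrong dimensions")
  if (!all(x$I %in% c(0, 1))) stop("I must be binary")
  if (any(rowSums(x$I) == 0)) stop("I has an all-zero row (partnerless plant)")
  if (any(colSums(x$I) == 0)) stop("I has an all-zero column (partnerless bird)")
  if (!all(dim(x$Fp) == c(n_p, 12L))) stop("Fp must be n_plants x 12")
  if (!all(dim(x$Fh) == c(n_h, 12L))) stop("Fh must be n_birds x 12")
  bad <- !is.finite(x$Fp) | x$Fp < 0
  if (any(bad)) stop("Fp has negative or non-finite entries")
  bad <- !is.finite(x$Fh) | x$Fh < 0
  if (any(bad)) stop("Fh has negative or non-finite entries")
  if (any(rowSums(x$Fp) == 0)) stop("a plant has an all-zero phenology")
  if (any(rowSums(x$Fh) == 0)) stop("a hummingbird has an all-zero phenology")
  invisible(x)
}

#' @exportS3Method base::print
print.interaction_table <- function(x, ...) {
  cat("Interaction table: ", length(x$plants), " plants x ", length(x$birds),
      " hummingbirds, ", sum(x$I), " links\n", sep = "")
  act_p <- rowSums(x$Fp > 0); act_h <- rowSums(x$Fh > 0)
  cat("  active months/species: plants ", round(mean(act_p), 1),
      ", hummingbirds ", round(mean(act_h), 1), " (mean)\n", sep = "")
  invisible(x)
}

# wrapped bell-shaped kernel over the 12-month cycle; entries below
# floor_frac of the peak are cut to exact 0 so species have real off-months
phenology_kernel <- function(peak, breadth, floor_frac = 0.05) {
  d <- abs(1:12 - peak)
  d <- pmin(d, 12 - d)
  w <- exp(-d^2 / (2 * breadth^2))
  w[w < floor_frac * max(w)] <- 0
  w
}

#' Generate a synthetic community with seasonal interaction structure
#'
#' Builds a month-resolved interaction table matching a preset's dimensions.
#' Each species receives a unimodal circular phenology: a peak month drawn
#' uniformly, a wrapped bell-shaped kernel of the given breadth truncated to
#' exact zero in its tails, and a lognormal species-level intensity. The
#' binary backbone first links every species (a spanning assignment weighted
#' by phenological co-occurrence), then adds links with probability
#' proportional to co-occurrence until exactly `target_links` pairs interact,
#' so backbones are phenologically plausible by construction. Pair-by-month
#' counts are the product of the two species' phenologies, and `Fp`/`Fh` are
#' their marginals.
#'
#' @param preset A [community_preset()] (or a name understood by it).
#' @param phenology_breadth Standard deviation of the wrapped kernel, in
#'   months, in `[1, 12]`. Default 2 gives roughly nine active months per
#'   species.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param max_retries Attempts allowed when sampled phenologies leave some
#'   forced link without temporal co-occurrence (only relevant at very small
#'   breadths).
#' @return An [interaction_table()].
#' @export
#' @examples
#' tab <- generate_community(community_preset("Alaspungo"), seed = 1)
#' sum(tab$I)  # 113 unique interactions
generate_community <- function(preset, phenology_breadth = 2, seed,
                               max_retries = 100L) {
  if (is.character(preset)) preset <- community_preset(preset)
  stopifnot(inherits(preset, "community_preset"))
  if (phenology_breadth < 1 || phenology_breadth > 12)
    stop("phenology_breadth must lie in [1, 12]")
  n_p <- preset$n_plants; n_h <- preset$n_birds; L <- preset$target_links

  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      kp <- t(vapply(sample.int(12, n_p, replace = TRUE),
                     phenology_kernel, numeric(12),
                     breadth = phenology_breadth))
      kh <- t(vapply(sample.int(12, n_h, replace = TRUE),
                     phenology_kernel, numeric(12),
                     breadth = phenology_breadth))
      int_p <- rlnorm(n_p, meanlog = log(5), sdlog = 0.75)
      int_h <- rlnorm(n_h, meanlog = log(5), sdlog = 0.75)
      co <- kp %*% t(kh)  # phenological co-occurrence weight per pair

      I <- try(sample_backbone(co, L), silent = TRUE)
      if (inherits(I, "try-error")) next

      counts <- array(0, dim = c(n_p, n_h, 12))
      for (m in 1:12)
        counts[, , m] <- I * outer(int_p * kp[, m], int_h * kh[, m])
      Fp <- apply(counts, c(1, 3), sum)
      Fh <- apply(counts, c(2, 3), sum)
      if (any(rowSums(Fp) == 0) || any(rowSums(Fh) == 0)) next

      plants <- sprintf("plant_%02d", seq_len(n_p))
      birds <- sprintf("bird_%02d", seq_len(n_h))
      dimnames(counts) <- list(plants, birds, paste0("m", 1:12))
      return(interaction_table(plants, birds, I, Fp, Fh, counts = counts))
    }
    stop("could not generate a valid community for preset '", preset$name,
         "' after ", max_retries, " attempts; increase phenology_breadth")
  })
}

# spanning-first backbone: every species gets one partner (weighted by
# co-occurrence, positive weight required), then remaining links are drawn
# without replacement with probability proportional to co-occurrence
sample_backbone <- function(co, L) {
  n_p <- nrow(co); n_h <- ncol(co)
  I <- matrix(0, n_p, n_h)
  pick <- function(w) {
    if (all(w <= 0)) stop("no co-occurring partner available")
    if (length(w) == 1L) 1L else sample.int(length(w), 1L, prob = w)
  }
  if (n_p >= n_h) {
    first <- sample.int(n_p, n_h)  # these plants cover all birds
    birds_order <- sample.int(n_h)
    for (b in seq_len(n_h)) I[first[b], birds_order[b]] <- 1
    if (any(colSums(I * (co > 0)) == 0)) stop("zero-weight forced link")
    for (i in setdiff(seq_len(n_p), first)) I[i, pick(co[i, ])] <- 1
  } else {
    first <- sample.int(n_h, n_p)
    plants_order <- sample.int(n_p)
    for (p in seq_len(n_p)) I[plants_order[p], first[p]] <- 1
    if (any(rowSums(I * (co > 0)) == 0)) stop("zero-weight forced link")
    for (j in setdiff(seq_len(n_h), first)) I[pick(co[, j]), j] <- 1
  }
  if (any(I[I == 1] * co[I == 1] == 0)) stop("forced link without co-occurrence")
  extra <- L - sum(I)
  if (extra < 0) stop("spanning structure already exceeds target_links")
  if (extra > 0) {
    free <- which(I == 0 & co > 0)
    if (length(free) < extra) stop("not enough co-occurring pairs")
    add <- if (length(free) == 1L) free else
      sample(free, extra, prob = co[free])
    I[add] <- 1
  }
  I
}

#' Read a long-format monthly interaction CSV
#'
#' Expects a UTF-8 CSV with header columns `plant`, `hummingbird`, `month`
#' (1-12) and `count` (>= 0, real-valued); one row per plant-bird-month
#' record, duplicates summed. Species order follows first appearance.
#'
#' @param path File path.
#' @return An [interaction_table()] carrying the pair-by-month counts, with
#'   `I[i, j] = 1` iff some record for the pair is positive, and `Fp`/`Fh`
#'   the per-species monthly marginals over partners.
#' @seealso [write_long_csv()]
#' @export
read_long_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant", "hummingbird", "month", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  mo <- suppressWarnings(as.numeric(df$month))
  ct <- suppressWarnings(as.numeric(df$count))
  bad <- which(!is.finite(mo) | mo != round(mo) | mo < 1 | mo > 12)
  if (length(bad))
    stop("month outside 1-12 at row ", bad[1], " (value '",
         df$month[bad[1]], "')")
  bad <- which(!is.finite(ct) | ct < 0)
  if (length(bad))
    stop("negative or non-numeric count at row ", bad[1], " (value '",
         df$count[bad[1]], "')")
  plants <- unique(as.character(df$plant))
  birds <- unique(as.character(df$hummingbird))
  counts <- array(0, dim = c(length(plants), length(birds), 12),
                  dimnames = list(plants, birds, paste0("m", 1:12)))
  ip <- match(df$plant, plants); ib <- match(df$hummingbird, birds)
  for (r in seq_len(nrow(df)))
    counts[ip[r], ib[r], mo[r]] <- counts[ip[r], ib[r], mo[r]] + ct[r]
  pos <- counts > 0
  I <- apply(pos, c(1, 2), any) * 1
  dead_p <- plants[rowSums(I) == 0]
  if (length(dead_p))
    stop("plant(s) with no positive record: ", paste(dead_p, collapse = ", "))
  dead_h <- birds[colSums(I) == 0]
  if (length(dead_h))
    stop("hummingbird(s) with no positive record: ",
         paste(dead_h, collapse = ", "))
  Fp <- apply(counts, c(1, 3), sum)
  Fh <- apply(counts, c(2, 3), sum)
  interaction_table(plants, birds, I, Fp, Fh, counts = counts)
}

#' Write an interaction table to the long CSV format
#'
#' Writes one row per positive plant-bird-month count. Requires the table to
#' carry pair-by-month counts (tables from [generate_community()] or
#' [read_long_csv()] do; tables whose phenologies were permuted by the null
#' model do not).
#'
#' @param table An [interaction_table()] with a `counts` array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(table, path) {
  validate_interaction_table(table)
  if (is.null(table$counts))
    stop("table carries no pair-by-month counts and cannot be written; ",
         "only tables built from pair-level records can round-trip")
  idx <- which(table$counts > 0, arr.ind = TRUE)
  df <- data.frame(
    plant = table$plants[idx[, 1]],
    hummingbird = table$birds[idx[, 2]],
    month = idx[, 3],
    count = table$counts[idx]
  )
  df <- df[order(match(df$plant, table$plants),
                 match(df$hummingbird, table$birds), df$month), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
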