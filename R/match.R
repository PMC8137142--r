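#' Pair spots across channels by distance-gated optimal assignment
#'
#' Solves the two-channel pairing as a linear assignment problem
#' (Hungarian/Jonker-Volgenant): among all pairings whose every pair is
#' within `gate_radius` (um, Euclidean), it returns the one of maximum
#' cardinality and, among those, minimum total distance. The gate is
#' implemented by padding the cost matrix with per-spot "unmatched"
#' dummy slots; the dummy cost is scaled to `(min(nA, nB) + 1) *
#' gate_radius` so that gaining a pair always outweighs any total
#' distance that a maximum-cardinality pairing can accumulate — a dummy
#' cost equal to the gate itself would let two short pairs beat three
#' near-gate pairs and lose cardinality. Within equal cardinality the
#' dummy contribution is constant, so the distance ordering is
#' untouched.
#'
#' Matching is intended to be computed within one cell; use
#' [coloc_cohort()] to process many cells.
#'
#' @param spots_a,spots_b spot positions: either matrices with columns
#'   `(z_um, y_um, x_um)` or spot tables containing those columns.
#' @param gate_radius maximum pairing distance in um (> 0). Default 0.3
#'   um, roughly one PSF width.
#' @param cell_id optional label carried into the result.
#' @return object of class `match_result`: list with `cell_id`, `pairs`
#'   (data.frame `index_a, index_b, distance`, sorted by `index_a`),
#'   `unmatched_a`, `unmatched_b`, `gate_radius`, `n_a`, `n_b`.
#' @examples
#' a <- cbind(z_um = c(0, 1), y_um = 0, x_um = 0)
#' match_spots(a, a, gate_radius = 0.3)$pairs$distance
#' @export
match_spots <- function(spots_a, spots_b, gate_radius = 0.3,
                        cell_id = NA_integer_) {
  if (!is.numeric(gate_radius) || gate_radius <= 0)
    stop_mod("match_spots", "gate_radius", "must be > 0")
  pa <- spot_positions(spots_a)
  pb <- spot_positions(spots_b)
  na <- nrow(pa); nb <- nrow(pb)
  empty_pairs <- data.frame(index_a = integer(0), index_b = integer(0),
                            distance = numeric(0))
  if (na == 0L || nb == 0L)
    return(structure(list(cell_id = cell_id, pairs = empty_pairs,
                          unmatched_a = seq_len(na),
                          unmatched_b = seq_len(nb),
                          gate_radius = gate_radius, n_a = na, n_b = nb),
                     class = "match_result"))

  dmat <- cross_distances(pa, pb)
  dummy <- (min(na, nb) + 1) * gate_radius   # cardinality dominates cost
  big <- (na + nb + 2) * dummy               # forbidden, still feasible
  n <- na + nb
  cost <- matrix(big, n, n)
  cost[seq_len(na), seq_len(nb)] <- ifelse(dmat <= gate_radius, dmat, big)
  for (i in seq_len(na)) cost[i, nb + i] <- dummy   # A_i unmatched
  for (j in seq_len(nb)) cost[na + j, j] <- dummy   # B_j unmatched
  cost[(na + 1):n, (nb + 1):n] <- 0                 # dummy-dummy

  assign <- lap_solve(cost)
  ia <- seq_len(na)
  jb <- assign[ia]
  real <- jb <= nb & dmat[cbind(ia, pmin(jb, nb))] <= gate_radius
  pairs <- data.frame(index_a = ia[real], index_b = jb[real],
                      distance = dmat[cbind(ia[real], jb[real])])
  pairs <- pairs[order(pairs$index_a, pairs$index_b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(cell_id = cell_id, pairs = pairs,
                 unmatched_a = setdiff(seq_len(na), pairs$index_a),
                 unmatched_b = setdiff(seq_len(nb), pairs$index_b),
                 gate_radius = gate_radius, n_a = na, n_b = nb),
            class = "match_result")
}

spot_positions <- function(x) {
  cols <- c("z_um", "y_um", "x_um")
  if (is.data.frame(x)) {
    if (!all(cols %in% names(x)))
      stop_mod("match_spots", "spots", "need z_um/y_um/x_um columns")
    as.matrix(x[, cols, drop = FALSE])
  } else if (is.matrix(x)) {
    if (ncol(x) != 3L)
      stop_mod("match_spots", "spots", "position matrix must have 3 columns")
    x
  } else if (length(x) == 0L) {
    matrix(numeric(0), ncol = 3L)
  } else stop_mod("match_spots", "spots", "unsupported input type")
}

cross_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result: cell", x$cell_id, "-", nrow(x$pairs), "pairs of",
      x$n_a, "A /", x$n_b, "B spots (gate", x$gate_radius, "um)\n")
  invisible(x)
}

#' Co-localized fraction of a cell
#'
#' Matched pairs over the reference-channel spot count. The reference
#' channel is the denominator — "X co-localized with Y" counts the
#' fraction of X spots with a Y partner. Cells without reference spots
#' return `NA` and are excluded from summaries.
#'
#' @param match a `match_result`.
#' @param n_reference reference-channel spot count (defaults to `n_a`).
#' @return fraction in `[0, 1]`, or `NA` when `n_reference` is 0.
#' @export
coloc_fraction <- function(match, n_reference = match$n_a) {
  stopifnot(inherits(match, "match_result"))
  np <- nrow(match$pairs)
  if (n_reference == 0L) return(NA_real_)
  if (n_reference < np)
    stop_mod("coloc_fraction", "n_reference",
             sprintf("%d pairs exceed %d reference spots", np, n_reference))
  np / n_reference
}

#' Summarize per-cell co-localization fractions
#'
#' Mean and SEM (sample sd over sqrt(n)) across cells, the paper-style
#' "average +/- SEM over >150 cells" summary, plus the nuclear /
#' cytoplasmic split of matched pairs when compartment counts are given.
#'
#' @param per_cell numeric vector of per-cell fractions; `NA` entries
#'   (cells without reference spots) are dropped.
#' @param compartments optional named counts `c(nuclear =, cytoplasmic =)`
#'   of matched pairs by compartment.
#' @param reference_channel label recorded in the summary.
#' @return object of class `coloc_summary`: list with `per_cell_fraction`,
#'   `mean`, `sem` (`NA` when n = 1), `n_cells`, `nuclear_share`,
#'   `cytoplasmic_share`, `reference_channel`.
#' @examples
#' s <- summarize_coloc(c(0.2, 0.4, 0.6))
#' c(s$mean, s$sem)
#' @export
summarize_coloc <- function(per_cell, compartments = NULL,
                            reference_channel = "a") {
  per_cell <- per_cell[!is.na(per_cell)]
  if (length(per_cell) == 0L)
    stop_mod("summarize_coloc", "per_cell", "no defined per-cell fractions")
  if (any(per_cell < 0 | per_cell > 1))
    stop_mod("summarize_coloc", "per_cell", "fractions must lie in [0, 1]")
  n <- length(per_cell)
  nuc <- cyt <- NA_real_
  if (!is.null(compartments)) {
    tot <- sum(compartments)
    if (tot > 0) {
      nuc <- unname(compartments[["nuclear"]] / tot)
      cyt <- unname(compartments[["cytoplasmic"]] / tot)
    }
  }
  structure(list(per_cell_fraction = per_cell,
                 mean = mean(per_cell),
                 sem = if (n > 1L) sd(per_cell) / sqrt(n) else NA_real_,
                 n_cells = n,
                 nuclear_share = nuc, cytoplasmic_share = cyt,
                 reference_channel = reference_channel),
            class = "coloc_summary")
}

#' @export
print.coloc_summary <- function(x, ...) {
  cat(sprintf("coloc_summary: %.1f%% +/- %.1f%% (mean +/- SEM, n = %d cells)\n",
              100 * x$mean, 100 * (x$sem %||% NA_real_), x$n_cells))
  if (!is.na(x$nuclear_share))
    cat(sprintf("  pairs: %.1f%% nuclear / %.1f%% cytoplasmic\n",
                100 * x$nuclear_share, 100 * x$cytoplasmic_share))
  invisible(x)
}

#' Unpaired (Welch) two-sample t-test between per-cell fraction groups
#'
#' Welch's unequal-variance t-test, the figure-legend "unpaired t-test".
#' Degenerate inputs follow stated conventions: both groups constant with
#' equal means gives `t = 0, p = 1`; both constant with different means
#' gives `t = +/-Inf, p = 0`.
#'
#' @param group1,group2 numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p_value`.
#' @export
compare_groups <- function(group1, group2) {
  if (length(group1) < 2L || length(group2) < 2L)
    stop_mod("compare_groups", "groups", "need n >= 2 per group")
  v1 <- var(group1); v2 <- var(group2)
  if (v1 == 0 && v2 == 0) {
    if (mean(group1) == mean(group2))
      return(list(t = 0, df = length(group1) + length(group2) - 2,
                  p_value = 1))
    return(list(t = sign(mean(group1) - mean(group2)) * Inf,
                df = length(group1) + length(group2) - 2, p_value = 0))
  }
  ht <- stats::t.test(group1, group2, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Expected chance co-localization for unrelated spots
#'
#' Probability that a reference spot has at least one partner-channel
#' spot within the gate when partners form a spatial Poisson process:
#' `1 - exp(-density * (4/3) * pi * gate_radius^3)`. The analytic control
#' for the no-co-localization case.
#'
#' @param spot_density partner-channel density in spots per um^3.
#' @param gate_radius gate in um.
#' @return fraction in `[0, 1)`.
#' @examples
#' chance_coloc_expectation(0.1, 0.3)
#' @export
chance_coloc_expectation <- function(spot_density, gate_radius) {
  if (spot_density < 0)
    stop_mod("chance_coloc_expectation", "spot_density", "must be >= 0")
  1 - exp(-spot_density * (4 / 3) * pi * gate_radius^3)
}

#' Match and summarize a cohort of simulated or measured cells
#'
#' Runs [match_spots()] per cell (never across cell boundaries), computes
#' per-cell fractions against the reference channel, and summarizes.
#'
#' @param fields list of `spot_field` objects, or a spot table with
#'   `channel` and `cell_id` columns.
#' @param gate_radius pairing gate (um).
#' @param reference `"a"` or `"b"`; the denominator channel.
#' @return list with `per_cell` (data.frame `cell_id, n_a, n_b, n_pairs,
#'   fraction`), `matches` (list of `match_result`), `summary`
#'   (a `coloc_summary`).
#' @export
coloc_cohort <- function(fields, gate_radius = 0.3, reference = c("a", "b")) {
  reference <- match.arg(reference)
  if (is.data.frame(fields)) fields <- table_to_fields(fields)
  matches <- lapply(fields, function(f)
    match_spots(f$spots_a, f$spots_b, gate_radius, cell_id = f$cell_id))
  per_cell <- do.call(rbind, lapply(matches, function(m) {
    n_ref <- if (reference == "a") m$n_a else m$n_b
    data.frame(cell_id = m$cell_id, n_a = m$n_a, n_b = m$n_b,
               n_pairs = nrow(m$pairs),
               fraction = coloc_fraction(m, n_ref))
  }))
  list(per_cell = per_cell, matches = matches,
       summary = summarize_coloc(per_cell$fraction,
                                 reference_channel = reference))
}

# split a (channel, cell_id, z_um, y_um, x_um) table into spot_field-like
# objects, one per cell
table_to_fields <- function(tab) {
  stopifnot(all(c("channel", "cell_id", "z_um", "y_um", "x_um") %in%
                names(tab)))
  tab <- tab[!is.na(tab$cell_id), , drop = FALSE]
  lapply(split(tab, tab$cell_id), function(d) {
    structure(list(
      cell_id = d$cell_id[1],
      spots_a = as.matrix(d[d$channel == "a", c("z_um", "y_um", "x_um")]),
      spots_b = as.matrix(d[d$channel == "b", c("z_um", "y_um", "x_um")]),
      pairing = NULL, true_rho = NA_real_, jitter_sigma = NA_real_),
      class = "spot_field")
  })
}
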