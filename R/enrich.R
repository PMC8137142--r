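#' Expression matrix container
#'
#' A light container for gene x sample expression values with sample
#' roles (`pulldown` / `control`) and a unit tag (`"counts"` or `"TPM"`).
#'
#' @param values non-negative numeric matrix, genes in rows.
#' @param genes unique gene labels (default: rownames).
#' @param samples sample labels (default: colnames).
#' @param roles per-sample role, `"pulldown"` or `"control"`; at least
#'   one control is required.
#' @param unit `"counts"` or `"TPM"`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              samples = colnames(values), roles,
                              unit = c("counts", "TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (any(values < 0) || any(!is.finite(values)))
    stop_mod("expression_matrix", "values", "must be finite and >= 0")
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(values)))
  if (anyDuplicated(genes))
    stop_mod("expression_matrix", "genes", "labels must be unique")
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  if (length(roles) != ncol(values) ||
      !all(roles %in% c("pulldown", "control")))
    stop_mod("expression_matrix", "roles",
             "one of 'pulldown'/'control' per sample")
  if (!any(roles == "control"))
    stop_mod("expression_matrix", "roles", "need at least one control")
  dimnames(values) <- list(genes, samples)
  structure(list(values = values, genes = genes, samples = samples,
                 roles = roles, unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", length(x$genes), "genes x", length(x$samples),
      "samples (", x$unit, "),", sum(x$roles == "pulldown"), "pulldown /",
      sum(x$roles == "control"), "control\n")
  invisible(x)
}

#' Control-subtracted log2 enrichment
#'
#' The heatmap transform: `log2(TPM + 1)` per sample, minus the control's
#' `log2(TPM + 1)` per gene. Multiple controls are averaged on the log
#' scale first. Input must be in TPM.
#'
#' @param em an [expression_matrix()] with `unit = "TPM"`.
#' @return gene x pulldown-sample matrix of log2-unit enrichment values.
#' @examples
#' em <- expression_matrix(cbind(p = c(7, 0), c = c(3, 0)),
#'                         genes = c("g1", "g2"),
#'                         roles = c("pulldown", "control"), unit = "TPM")
#' log_enrichment(em)  # log2(8) - log2(4) = 1 for g1; 0 for g2
#' @export
log_enrichment <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "TPM")
    stop_mod("log_enrichment", "unit", "requires TPM values")
  ctrl <- em$roles == "control"
  if (!any(ctrl)) stop_mod("log_enrichment", "roles", "missing control")
  lg <- log2(em$values + 1)
  ref <- rowMeans(lg[, ctrl, drop = FALSE])
  out <- lg[, !ctrl, drop = FALSE] - ref
  out
}

#' Fixed-dispersion negative-binomial exact test
#'
#' Two-sided exact test for a difference between two count observations
#' under a negative-binomial model with known dispersion
#' (`variance = mu + dispersion * mu^2`). Counts are first scaled to a
#' common effective library size (mean of the size factors, rounded to
#' integers), then the test conditions on the scaled total: under the
#' null both counts share one mean, the conditional law of one count
#' given the total is dispersion-dependent but mean-free, and the
#' two-sided p-value sums the probabilities of all splits at most as
#' probable as the observed one. `dispersion = 0` reduces to the
#' conditional-binomial (Poisson) exact test.
#'
#' This reimplements the fixed-dispersion exact test popularized by
#' count-based differential-expression tools; it deliberately skips
#' their quantile-adjusted pseudo-count machinery, so p-values can differ
#' slightly from those tools for unequal library sizes.
#'
#' @param count_a,count_b non-negative integer counts (vectorized). With
#'   replicated libraries, pass the within-group sums and set
#'   `n_rep_a`/`n_rep_b`.
#' @param size_factor_a,size_factor_b positive library-size factors (for
#'   group sums, the summed library sizes).
#' @param dispersion per-library NB dispersion phi >= 0 (default 0.1).
#' @param n_rep_a,n_rep_b number of libraries summed into each count; a
#'   sum of `n` independent NB(mu, phi) draws is NB(n mu, phi / n), so
#'   the conditional law uses size `n / phi` per group.
#' @return two-sided p-value(s) in `[0, 1]`.
#' @examples
#' nb_exact_test(10, 10)                   # symmetric -> 1
#' nb_exact_test(50, 5, dispersion = 0.1)
#' @export
nb_exact_test <- function(count_a, count_b,
                          size_factor_a = 1, size_factor_b = 1,
                          dispersion = 0.1, n_rep_a = 1L, n_rep_b = 1L) {
  if (any(dispersion < 0))
    stop_mod("nb_exact_test", "dispersion", "must be >= 0")
  if (any(size_factor_a <= 0) || any(size_factor_b <= 0))
    stop_mod("nb_exact_test", "size_factor", "must be > 0")
  if (any(count_a < 0) || any(count_b < 0))
    stop_mod("nb_exact_test", "counts", "must be >= 0")
  n <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, n); count_b <- rep_len(count_b, n)
  size_factor_a <- rep_len(size_factor_a, n)
  size_factor_b <- rep_len(size_factor_b, n)
  vapply(seq_len(n), function(i)
    nb_exact_one(count_a[i], count_b[i], size_factor_a[i],
                 size_factor_b[i], dispersion, n_rep_a, n_rep_b),
    numeric(1))
}

nb_exact_one <- function(a, b, sfa, sfb, phi, nra = 1L, nrb = 1L) {
  common <- mean(c(sfa, sfb))
  a2 <- round_half_up(a * common / sfa)
  b2 <- round_half_up(b * common / sfb)
  s <- a2 + b2
  if (s == 0) return(1)
  k <- 0:s
  if (phi == 0) {
    # Poisson limit: conditional on the total, counts are binomial with
    # probability proportional to the library count per group
    lw <- dbinom(k, s, nra / (nra + nrb), log = TRUE)
  } else {
    mu <- s / 2        # conditional law is free of mu; any value works
    lw <- dnbinom(k, size = nra / phi, mu = mu, log = TRUE) +
      dnbinom(s - k, size = nrb / phi, mu = mu, log = TRUE)
  }
  w <- exp(lw - max(lw))
  p_obs <- w[a2 + 1]
  min(1, sum(w[w <= p_obs * (1 + 1e-10)]) / sum(w))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1 and
#' returned in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted values (FDR) in the same order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_mod("bh_fdr", "p_values", "must lie in [0, 1]")
  n <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p_values[o]))[ro]
}

#' Score pulldown enrichment gene by gene
#'
#' For count input, replicate columns are pooled by summation within
#' role, size factors are the pooled column totals (total-count scaling),
#' each gene is tested with [nb_exact_test()] at the given fixed
#' per-library dispersion (the pooled sums are tested with size
#' `n_libraries / dispersion` per group, so replication increases
#' power), p-values are BH-adjusted, and fold changes are computed on
#' size-factor-normalized counts with a prior count of 0.5 per group. The
#' `enriched` flag applies the fold/FDR filter.
#'
#' @param em an [expression_matrix()] of unit `"counts"`.
#' @param dispersion fixed NB dispersion (default 0.1).
#' @param min_fold minimum fold change, inclusive (default 4).
#' @param max_fdr FDR ceiling, exclusive (default 0.001).
#' @return an enrichment table: data.frame with columns `gene,
#'   fold_change, p_value, fdr, enriched` (class `enrichment_table`).
#' @export
score_enrichment <- function(em, dispersion = 0.1, min_fold = 4,
                             max_fdr = 0.001) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "counts")
    stop_mod("score_enrichment", "unit", "requires count values")
  pull <- em$roles == "pulldown"
  ctrl <- em$roles == "control"
  if (!any(pull)) stop_mod("score_enrichment", "roles", "missing pulldown")
  a <- rowSums(em$values[, pull, drop = FALSE])
  b <- rowSums(em$values[, ctrl, drop = FALSE])
  sfa <- sum(a); sfb <- sum(b)
  p <- nb_exact_test(a, b, sfa, sfb, dispersion,
                     n_rep_a = sum(pull), n_rep_b = sum(ctrl))
  fdr <- bh_fdr(p)
  common <- mean(c(sfa, sfb))
  fold <- (a * common / sfa + 0.5) / (b * common / sfb + 0.5)
  out <- data.frame(gene = em$genes, fold_change = fold, p_value = p,
                    fdr = fdr,
                    enriched = fold >= min_fold & fdr < max_fdr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Apply the fold-change / FDR enrichment filter
#'
#' Retains genes at least `min_fold`-fold enriched (inclusive, "at least
#' fourfold") with `fdr < max_fdr` (strict).
#'
#' @param table an enrichment table from [score_enrichment()].
#' @param min_fold minimum fold change (default 4).
#' @param max_fdr FDR ceiling (default 0.001).
#' @return character vector of enriched gene labels.
#' @export
apply_enrichment_filter <- function(table, min_fold = 4, max_fdr = 0.001) {
  stopifnot(is.data.frame(table),
            all(c("gene", "fold_change", "fdr") %in% names(table)))
  table$gene[table$fold_change >= min_fold & table$fdr < max_fdr]
}

#' Restrict and order an enrichment matrix for heatmap plotting
#'
#' @param enrichment gene x sample matrix (e.g. from [log_enrichment()]).
#' @param gene_subset ordered gene labels; must all exist.
#' @return the reordered submatrix with dimnames preserved.
#' @export
heatmap_matrix <- function(enrichment, gene_subset) {
  if (length(gene_subset) == 0L)
    stop_mod("heatmap_matrix", "gene_subset", "must be non-empty")
  missing <- setdiff(gene_subset, rownames(enrichment))
  if (length(missing) > 0L)
    stop_mod("heatmap_matrix", "gene_subset",
             paste("unknown gene label(s):",
                   paste(head(missing, 5), collapse = ", ")))
  enrichment[gene_subset, , drop = FALSE]
}
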