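#' Simulate a paired pulldown/control count matrix
#'
#' Emulates an RNA pulldown sequencing experiment: per-gene control means
#' follow a log-uniform abundance distribution (10 to 1000 before
#' normalization, geometric mean 100), scaled so the control column sums
#' to `lib_size`; pulldown means equal control means times `fold` for the
#' designated enriched genes and times 1 otherwise. Counts are negative-
#' binomially distributed with the edgeR-style quadratic dispersion
#' (`variance = mu + dispersion * mu^2`); `dispersion = 0` gives Poisson
#' counts.
#'
#' @param n_genes number of genes.
#' @param enriched_ids character labels of the truly enriched genes; must
#'   be a subset of the generated gene labels (`"gene%05d"`).
#' @param fold enrichment factor (>= 1) applied to enriched genes.
#' @param dispersion NB dispersion (>= 0).
#' @param lib_size expected control library size; default gives a mean
#'   control count of 100 per gene.
#' @param rng_seed integer seed.
#' @param n_reps replicate libraries per condition (default 1, matching a
#'   single pulldown vs a single control library).
#' @return An `expression_matrix` (see [expression_matrix()]) of unit
#'   `"counts"` with samples `pulldown*` and `control*`; the generating
#'   truth (means, enriched set) is attached as attribute `"truth"`.
#' @examples
#' em <- simulate_count_matrix(100, enriched_ids = c("gene00001"),
#'                             fold = 8, dispersion = 0.1, rng_seed = 1)
#' dim(em$values)
#' @export
simulate_count_matrix <- function(n_genes,
                                  enriched_ids = character(0),
                                  fold = 4,
                                  dispersion = 0.1,
                                  lib_size = 100 * n_genes,
                                  rng_seed = 1L,
                                  n_reps = 1L) {
  if (fold < 1) stop_mod("simulate_count_matrix", "fold", "must be >= 1")
  if (dispersion < 0)
    stop_mod("simulate_count_matrix", "dispersion", "must be >= 0")
  genes <- sprintf("gene%05d", seq_len(n_genes))
  if (!all(enriched_ids %in% genes))
    stop_mod("simulate_count_matrix", "enriched_ids",
             "must be a subset of the gene labels")
  set.seed(rng_seed)

  abundance <- exp(runif(n_genes, log(10), log(1000)))
  mu_control <- abundance / sum(abundance) * lib_size
  mu_pull <- mu_control * ifelse(genes %in% enriched_ids, fold, 1)

  draw <- function(mu) {
    if (dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  }
  cols <- c(lapply(seq_len(n_reps), function(i) draw(mu_pull)),
            lapply(seq_len(n_reps), function(i) draw(mu_control)))
  values <- do.call(cbind, cols)
  samples <- c(sprintf("pulldown%d", seq_len(n_reps)),
               sprintf("control%d", seq_len(n_reps)))
  roles <- rep(c("pulldown", "control"), each = n_reps)
  em <- expression_matrix(values, genes = genes, samples = samples,
                          roles = roles, unit = "counts")
  attr(em, "truth") <- list(mu_control = mu_control, mu_pulldown = mu_pull,
                            enriched_ids = enriched_ids, fold = fold,
                            dispersion = dispersion)
  em
}
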