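#' Configuration for the synthetic tumor/normal cohort
#'
#' Parameters of the generator that emulates the structure signature
#' scorers face in cancer scRNA-seq: two labelled cell populations,
#' negative-binomial counts over log-normally heterogeneous gene means,
#' known true up-/down-regulated gene programs in the tumor cells, and a
#' systematic detected-gene (dropout) imbalance — tumor cells detect
#' `detect_shift` times as many genes as normal cells on average,
#' produced by binomially thinning the normal cells' counts.
#'
#' @param n_tumor,n_normal cells per group (defaults 200 + 200).
#' @param n_genes genes (default 2,000 — runs the full benchmark in
#'   minutes).
#' @param meanlog,sdlog log-normal parameters of the per-gene mean
#'   expression.
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param detect_shift target ratio of tumor to normal mean detected-gene
#'   counts (>= 1).
#' @param n_up,n_down number of true up-/down-regulated genes.
#' @param effect_size fold change of true DE genes in tumor cells (> 1).
#' @param depth_jitter per-cell uniform depth multiplier half-width in
#'   \[0, 1): cells vary around their group's target depth.
#' @param seed integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_tumor = 200L, n_normal = 200L, n_genes = 2000L,
                          meanlog = 0, sdlog = 1.5, dispersion = 2,
                          detect_shift = 1.4, n_up = 300L, n_down = 300L,
                          effect_size = 3, depth_jitter = 0.1, seed = 1L) {
  stopifnot(n_up + n_down <= n_genes, detect_shift >= 1, effect_size > 0,
            dispersion > 0, depth_jitter >= 0, depth_jitter < 1,
            n_tumor >= 1, n_normal >= 1)
  structure(list(n_tumor = n_tumor, n_normal = n_normal, n_genes = n_genes,
                 meanlog = meanlog, sdlog = sdlog, dispersion = dispersion,
                 detect_shift = detect_shift, n_up = n_up, n_down = n_down,
                 effect_size = effect_size, depth_jitter = depth_jitter,
                 seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic tumor/normal cohort with known DE truth
#'
#' Draws counts per cell x gene from a negative binomial with
#' log-normal gene means; true up (down) genes have their tumor-cell
#' means multiplied (divided) by `effect_size`. Dropout imbalance is
#' then imposed by binomial thinning: normal cells are thinned at the
#' retention rate that makes their expected detected-gene count equal
#' to the tumor cells' divided by `detect_shift` (solved from the
#' negative-binomial zero probability), modelling dropouts the same way
#' the down-sampling experiments do rather than by zero inflation.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A list with `matrix` (an [expr_matrix()], counts),
#'   `annotation` (tibble `cell_id`, `group` in `{Tumor, Normal}`), and
#'   `truth` (list with `up_genes`, `down_genes`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    mu <- stats::rlnorm(cf$n_genes, cf$meanlog, cf$sdlog)
    genes <- sprintf("gene%04d", seq_len(cf$n_genes))
    de_idx <- sample.int(cf$n_genes, cf$n_up + cf$n_down)
    up_idx <- de_idx[seq_len(cf$n_up)]
    down_idx <- de_idx[cf$n_up + seq_len(cf$n_down)]
    mu_tumor <- mu
    mu_tumor[up_idx] <- mu[up_idx] * cf$effect_size
    mu_tumor[down_idx] <- mu[down_idx] / cf$effect_size
    thin_normal <- normal_thinning_rate(mu, mu_tumor, cf$dispersion,
                                        cf$detect_shift, cf$n_genes)
    n_cells <- cf$n_tumor + cf$n_normal
    jit <- stats::runif(n_cells, 1 - cf$depth_jitter, 1 + cf$depth_jitter)
    counts <- base::matrix(0, n_cells, cf$n_genes)
    for (ci in seq_len(n_cells)) {
      is_tumor <- ci <= cf$n_tumor
      m <- if (is_tumor) mu_tumor else mu
      k <- stats::rnbinom(cf$n_genes, size = cf$dispersion, mu = m)
      keep <- min(1, (if (is_tumor) 1 else thin_normal) * jit[ci])
      if (keep < 1) k <- stats::rbinom(cf$n_genes, size = k, prob = keep)
      counts[ci, ] <- k
    }
  })
  cells <- c(sprintf("tumor%04d", seq_len(cf$n_tumor)),
             sprintf("normal%04d", seq_len(cf$n_normal)))
  dimnames(counts) <- list(cells, genes)
  list(matrix = expr_matrix(counts, layer = "counts"),
       annotation = tibble::tibble(
         cell_id = cells,
         group = rep(c("Tumor", "Normal"), c(cf$n_tumor, cf$n_normal))),
       truth = list(up_genes = genes[sort(up_idx)],
                    down_genes = genes[sort(down_idx)]))
}

# expected detected genes after thinning NB(mu, theta) counts at rate r:
# P(detect g) = 1 - (theta / (theta + mu_g r))^theta; solve for the
# normal-cell rate giving tumor detection / detect_shift
normal_thinning_rate <- function(mu_normal, mu_tumor, theta, detect_shift,
                                 n_genes) {
  expected_detect <- function(m, r) sum(1 - (theta / (theta + m * r))^theta)
  target <- expected_detect(mu_tumor, 1) / detect_shift
  if (target >= n_genes)
    stop("infeasible dropout target: expected detection exceeds n_genes",
         call. = FALSE)
  if (detect_shift == 1 &&
      abs(expected_detect(mu_normal, 1) - target) < 1e-6) return(1)
  stats::uniroot(function(r) expected_detect(mu_normal, r) - target,
                 interval = c(1e-6, 1), tol = 1e-9)$root
}

#' True differential-expression pools of a cohort
#'
#' Returns the generator's known up- and down-regulated gene lists, the
#' gold-standard pools fed to [simulate_noisy_sets()] in place of a
#' differential-expression step on real data.
#'
#' @param cohort a list from [generate_cohort()].
#' @return List with `up_pool` and `down_pool` character vectors.
#' @export
truth_pools <- function(cohort) {
  list(up_pool = cohort$truth$up_genes, down_pool = cohort$truth$down_genes)
}

#' Write a cohort as matrix + annotation + truth GMT fixtures
#'
#' @param cohort a list from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_mtx(cohort$matrix, file.path(dir, "matrix.mtx"),
                   file.path(dir, "genes.txt"), file.path(dir, "cells.txt"))
  readr::write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_gmt(gene_sets(list(true_up = cohort$truth$up_genes,
                           true_down = cohort$truth$down_genes),
                      descriptions = c("direction=up", "direction=down")),
            file.path(dir, "truth.gmt"))
  invisible(cohort)
}
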