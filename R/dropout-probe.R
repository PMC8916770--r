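#' Dummy expression profile with known ranking
#'
#' A strictly decreasing positive profile: gene i (of `n_genes`) has
#' value `n_genes - i + 1`, so gene index equals its high-to-low
#' expression rank, and the ranking is identical at every dropout rate
#' by construction. Values are deterministic — only the ranking matters
#' to the rank-based scorers this profile probes.
#'
#' @param n_genes number of genes (>= 3; default 10,000).
#' @return Named numeric vector (`gene00001`, ...).
#' @export
make_dummy_cell <- function(n_genes = 10000L) {
  stopifnot(n_genes >= 3)
  stats::setNames(as.numeric(n_genes:1),
                  sprintf("gene%05d", seq_len(n_genes)))
}

#' Zero out the lowest-expressed fraction of a cell
#'
#' Sets the `floor(rate * n)` lowest-expressed genes to zero, turning
#' them into dropouts; all other values are unchanged.
#'
#' @param cell named numeric vector.
#' @param rate dropout rate in \[0, 1).
#' @return The vector with dropouts applied.
#' @export
apply_dropout <- function(cell, rate) {
  stopifnot(rate >= 0, rate < 1)
  k <- floor(rate * length(cell))
  if (k == 0) return(cell)
  cell[order(cell, seq_along(cell))[seq_len(k)]] <- 0
  cell
}

#' Shared tie rank of a cell's dropout genes
#'
#' With genes ranked from high to low expression and ties placed at
#' their average position, all zero-expression genes share one rank:
#' the mean of the positions they occupy, `(n_expressed + 1 + n) / 2`.
#'
#' @param cell named numeric vector with at least one zero.
#' @return The shared (possibly half-integer) tie rank.
#' @export
tie_rank_of_dropouts <- function(cell) {
  n <- length(cell)
  nz <- sum(cell > 0)
  if (nz == n) stop("cell has no dropout genes", call. = FALSE)
  (nz + 1 + n) / 2
}

#' Floating-gene dropout sweep
#'
#' The dropout probe: a signature of `n_fixed` genes drawn (seeded) from
#' the top `top_pool` ranks plus one "floating" gene swept over every
#' rank from `top_pool + 1` to the bottom of the list. At each position
#' the `n_fixed + 1`-gene signature is scored on the reference cell and
#' on its dropout twin ([apply_dropout()] at `rate`), each cell scored
#' independently with the backend's raw single-cell score (no cross-cell
#' normalization — backends that need one, such as JASMINE's min-max
#' scaling, refuse with an error). The two curves expose how dropouts
#' alone move a score: for ssGSEA they coincide while the floating gene
#' is expressed in both cells, then teeter around the dropout tie rank.
#'
#' The ssGSEA walk is evaluated incrementally (the full running sum
#' collapses to a closed form per position), so the complete sweep is
#' cheap even at 10,000 genes.
#'
#' @param cell named numeric vector, e.g. [make_dummy_cell()].
#' @param rate dropout rate in \[0, 1).
#' @param n_fixed number of fixed signature genes (default 99).
#' @param top_pool size of the top-rank pool the fixed genes come from
#'   (default 1,000).
#' @param scorer `"ssgsea"`, `"scse"`, or `"aucell"`.
#' @param tau ssGSEA rank-weight exponent.
#' @param top_fraction AUCell cutoff fraction.
#' @param seed integer seed for the fixed-gene draw (and AUCell ties).
#' @return A `dropout_curve` tibble with columns `position`,
#'   `score_reference`, `score_dropout`, plus attributes and a
#'   [glance()] method reporting `divergence_rank` (largest position
#'   with exactly equal scores), `crossing_rank` (largest position with
#'   `score_dropout >= score_reference`), and `tie_rank`.
#' @export
floating_gene_sweep <- function(cell, rate, n_fixed = 99L, top_pool = 1000L,
                                scorer = c("ssgsea", "scse", "aucell",
                                           "jasmine"),
                                tau = 0.25, top_fraction = 0.05, seed = 1L) {
  scorer <- match.arg(scorer)
  if (scorer == "jasmine")
    stop("jasmine has no raw single-cell score: its components are ",
         "min-max scaled across cells", call. = FALSE)
  n <- length(cell)
  stopifnot(top_pool < n, n_fixed < top_pool)
  dropped <- apply_dropout(cell, rate)
  rank_desc <- order(-cell, seq_len(n))        # high-to-low gene order
  fixed <- withr::with_seed(seed, rank_desc[sample.int(top_pool, n_fixed)])
  floats <- rank_desc[(top_pool + 1):n]        # gene index at each rank
  ref <- sweep_curve(cell, fixed, floats, scorer, tau, top_fraction, seed)
  drp <- sweep_curve(dropped, fixed, floats, scorer, tau, top_fraction, seed)
  out <- tibble::tibble(position = (top_pool + 1):n,
                        score_reference = ref, score_dropout = drp)
  eq <- out$score_reference == out$score_dropout
  geq <- out$score_dropout >= out$score_reference
  structure(out,
            rate = rate, n_genes = n, n_fixed = n_fixed,
            top_pool = top_pool, scorer = scorer, seed = seed,
            fixed_genes = names(cell)[fixed],
            divergence_rank = if (any(eq)) as.numeric(max(out$position[eq]))
                              else NA_real_,
            crossing_rank = if (any(geq)) as.numeric(max(out$position[geq]))
                            else NA_real_,
            tie_rank = if (any(dropped == 0)) tie_rank_of_dropouts(dropped)
                       else NA_real_,
            class = c("dropout_curve", class(out)))
}

# raw single-cell score of {fixed + one floating gene} for every floating
# gene index, vectorized over positions
sweep_curve <- function(values, fixed, positions, scorer, tau, top_fraction,
                        seed) {
  n <- length(values)
  values <- unname(values)
  if (scorer == "scse") {
    tot <- sum(values)
    if (tot <= 0) stop("cell with zero total", call. = FALSE)
    return((sum(values[fixed]) + values[positions]) / tot * 100)
  }
  if (scorer == "aucell") {
    k <- as.integer(ceiling(top_fraction * n))
    pos <- integer(n)
    tb <- withr::with_seed(seed, sample.int(n))
    pos[order(-values, tb)] <- seq_len(n)
    u <- pmax(k - pos + 1, 0)
    s <- min(length(fixed) + 1L, k)
    return((sum(u[fixed]) + u[positions]) / (k * s - s * (s - 1) / 2))
  }
  # ssgsea: closed-form running sum (see ssgsea_core)
  r <- rank(values, ties.method = "average")
  w <- r^tau
  pos <- integer(n)
  pos[order(-values, seq_len(n))] <- seq_len(n)
  v <- n - pos + 1
  s <- length(fixed) + 1L
  wf <- sum(w[fixed] * v[fixed])
  uf <- sum(w[fixed])
  vf <- sum(v[fixed])
  total <- n * (n + 1) / 2
  (wf + w[positions] * v[positions]) / (uf + w[positions]) -
    (total - vf - v[positions]) / (n - s)
}

#' @export
glance.dropout_curve <- function(x, ...) {
  tibble::tibble(scorer = attr(x, "scorer"), rate = attr(x, "rate"),
                 n_genes = attr(x, "n_genes"), n_fixed = attr(x, "n_fixed"),
                 top_pool = attr(x, "top_pool"),
                 divergence_rank = attr(x, "divergence_rank"),
                 crossing_rank = attr(x, "crossing_rank"),
                 tie_rank = attr(x, "tie_rank"))
}

#' @export
autoplot.dropout_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::starts_with("score_"),
                              names_to = "cell", names_prefix = "score_",
                              values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$score,
                                     colour = .data$cell)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "floating gene rank", y = "raw signature score",
                  colour = NULL,
                  subtitle = sprintf("%s, dropout rate %.0f%%",
                                     attr(object, "scorer"),
                                     100 * attr(object, "rate")))
}

#' Write a dropout curve and its summary
#'
#' @param curve a `dropout_curve`.
#' @param path curve TSV path; the summary goes to `<path>.summary.json`.
#' @return `curve`, invisibly.
#' @export
write_dropout_curve <- function(curve, path) {
  readr::write_tsv(tibble::as_tibble(curve), path)
  jsonlite::write_json(as.list(glance(curve)),
                       paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(curve)
}
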