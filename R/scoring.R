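#' Score gene signatures per cell
#'
#' The tidyverse front door to the four scoring backends. Every method
#' maps (expression matrix, gene set) to one activity score per cell,
#' independent of group labels:
#'
#' * `jasmine_or` / `jasmine_lr` — JASMINE: the mean rank of expressed
#'   signature genes among a cell's expressed genes, averaged with a
#'   min-max-scaled odds-ratio (or likelihood-ratio) enrichment of the
#'   signature in the expressed-gene fraction. Scores lie in \[0, 1\].
#' * `scse` — normalized total expression of the signature genes:
#'   signature sum / cell total, times `scale_factor`.
#' * `aucell` — area under the recovery curve of signature genes among
#'   the top `top_fraction` of the cell's ranked genes, normalized to
#'   \[0, 1\].
#' * `ssgsea` — the single-sample running-sum enrichment score with
#'   rank weights `rank^tau`.
#'
#' Sets are first intersected with the matrix's gene universe; a set with
#' an empty intersection is an error.
#'
#' @param matrix an [expr_matrix()].
#' @param sets a [gene_sets()] collection, or a character vector treated
#'   as a single signature.
#' @param method one of `"jasmine_or"`, `"jasmine_lr"`, `"scse"`,
#'   `"aucell"`, `"ssgsea"`.
#' @param scale_factor SCSE multiplier (default 100; affects neither
#'   rankings nor Cohen's d).
#' @param top_fraction AUCell ranking cutoff as a fraction of the
#'   universe (default 0.05).
#' @param tau ssGSEA rank-weight exponent (default 0.25).
#' @param normalize ssGSEA: divide all scores by the range (max - min)
#'   of the whole signatures x cells score matrix.
#' @param seed integer seed for AUCell's random tie-breaking.
#' @return A `sig_scores` tibble with columns `signature`, `cell`,
#'   `score`, carrying the method and its parameters as attributes.
#'   Use [score_matrix()] for the wide signatures x cells form.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_tumor = 20, n_normal = 20,
#'                                         n_genes = 300, seed = 1))
#' sets <- random_gene_sets(gene_ids(cohort$matrix), sizes = 30, n = 3)
#' score_genesets(cohort$matrix, sets, method = "jasmine_or")
#' @export
score_genesets <- function(matrix, sets,
                           method = c("jasmine_or", "jasmine_lr", "scse",
                                      "aucell", "ssgsea"),
                           scale_factor = 100, top_fraction = 0.05,
                           tau = 0.25, normalize = TRUE, seed = 1L) {
  method <- match.arg(method)
  if (is.character(sets)) sets <- gene_sets(list(signature = sets))
  stopifnot(inherits(matrix, "expr_matrix"), inherits(sets, "gene_sets"))
  eff <- effective_sizes(sets, matrix)
  if (any(eff == 0L))
    stop("gene set(s) with no genes in the matrix universe: ",
         paste(utils::head(names(sets)[eff == 0L], 5), collapse = ", "),
         call. = FALSE)
  sm <- switch(method,
    jasmine_or = jasmine_core(matrix, sets, variant = "or"),
    jasmine_lr = jasmine_core(matrix, sets, variant = "lr"),
    scse = scse_core(matrix, sets, scale_factor = scale_factor),
    aucell = aucell_core(matrix, sets, top_fraction = top_fraction,
                         seed = seed),
    ssgsea = ssgsea_core(matrix, sets, tau = tau, normalize = normalize))
  params <- switch(method,
    scse = list(scale_factor = scale_factor),
    aucell = list(top_fraction = top_fraction, seed = seed),
    ssgsea = list(tau = tau, normalize = normalize),
    list())
  out <- tibble::tibble(
    signature = rep(rownames(sm), ncol(sm)),
    cell = rep(colnames(sm), each = nrow(sm)),
    score = as.vector(sm))
  structure(out, method = method, params = params,
            class = c("sig_scores", class(out)))
}

#' Wide signatures-by-cells view of a score table
#'
#' @param scores a `sig_scores` tibble from [score_genesets()].
#' @return A dense numeric matrix, signatures in rows, cells in columns.
#' @export
score_matrix <- function(scores) {
  sigs <- unique(scores$signature)
  cells <- unique(scores$cell)
  m <- base::matrix(NA_real_, length(sigs), length(cells),
                    dimnames = list(sigs, cells))
  m[cbind(match(scores$signature, sigs), match(scores$cell, cells))] <-
    scores$score
  m
}

## ---- per-cell rank machinery ------------------------------------------

# ranks of expressed genes within each cell (ascending: highest expressed
# gene gets rank N = number of expressed genes; ties share average rank),
# returned as a G x C sparse matrix with the same pattern as t(values)
expressed_rank_matrix <- function(matrix) {
  xt <- methods::as(Matrix::t(matrix$values), "CsparseMatrix") # genes x cells
  p <- xt@p
  xs <- xt@x
  for (j in seq_len(ncol(xt))) {
    if (p[j + 1] > p[j]) {
      idx <- (p[j] + 1):p[j + 1]
      xs[idx] <- rank(xs[idx], ties.method = "average")
    }
  }
  xt@x <- xs
  xt
}

## ---- JASMINE ----------------------------------------------------------

jasmine_core <- function(matrix, sets, variant = c("or", "lr")) {
  variant <- match.arg(variant)
  X <- matrix$values
  n_cells <- nrow(X)
  if (n_cells < 2)
    stop("JASMINE needs at least 2 cells (min-max scaling across cells)",
         call. = FALSE)
  G <- ncol(X)
  n_expr <- Matrix::rowSums(X > 0)
  if (any(n_expr == 0))
    stop("cell(s) with no expressed genes: ",
         paste(utils::head(cell_ids(matrix)[n_expr == 0], 5), collapse = ", "),
         call. = FALSE)
  Z <- set_indicator(sets, gene_ids(matrix))          # sets x genes
  Rt <- expressed_rank_matrix(matrix)                 # genes x cells
  eff <- effective_sizes(sets, matrix)
  a <- as.matrix(Z %*% (Rt > 0))                      # m: expressed sig genes
  sum_rank <- as.matrix(Z %*% Rt)
  Nmat <- base::matrix(n_expr, nrow(Z), n_cells, byrow = TRUE)
  vmean <- ifelse(a > 0, sum_rank / (a * Nmat), 0)
  b <- eff - a
  cc <- Nmat - a
  d <- G - eff - cc
  if (any(cc == 0))
    stop("degenerate cell: no expressed non-signature genes", call. = FALSE)
  enr <- if (variant == "or") {
    (a * d) / (ifelse(b == 0, 1, b) * cc)
  } else {
    (a * (cc + d)) / (cc * (a + b))
  }
  out <- (minmax_rows(vmean) + minmax_rows(enr)) / 2
  dimnames(out) <- list(names(sets), cell_ids(matrix))
  out
}

# min-max scale each row to [0,1]; a constant row becomes all zeros
minmax_rows <- function(m) {
  lo <- apply(m, 1, min)
  hi <- apply(m, 1, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    warning(sum(flat), " constant score component(s) scaled to all zeros",
            call. = FALSE)
    rng[flat] <- 1
  }
  out <- (m - lo) / rng
  out[flat, ] <- 0
  out
}

#' JASMINE building blocks for one cell
#'
#' `jasmine_mean_rank()` is the rank-based approximate signature mean for
#' a single cell: expressed genes (value > 0) are ranked ascending so the
#' highest-expressed gene has rank N (ties share the average rank), and
#' the mean rank of the m expressed signature genes is divided by N.
#' Returns 0 when no signature gene is expressed. `contingency()` tabulates
#' the signature against the expressed/not-expressed split of the whole
#' universe, and `enrichment_or()` / `enrichment_lr()` turn those counts
#' into the odds ratio (a d)/(b c) — with b replaced by 1 when b = 0 — or
#' the expressed-fraction likelihood ratio (a/(a+b)) / (c/(c+d)).
#'
#' @param cell_values named numeric vector, one cell's expression over the
#'   gene universe.
#' @param signature character vector of gene ids.
#' @param universe character vector of gene ids (defaults to
#'   `names(cell_values)`).
#' @param counts named vector or list with elements `a`, `b`, `c`, `d`:
#'   signature genes expressed / not expressed, non-signature genes
#'   expressed / not expressed.
#' @return `jasmine_mean_rank()`: a scalar in \[0, 1\]. `contingency()`: a
#'   named integer vector `c(a, b, c, d)`. The enrichment functions: a
#'   non-negative scalar.
#' @examples
#' v <- c(g1 = 5, g2 = 3, g3 = 0, g4 = 1)
#' jasmine_mean_rank(v, c("g2", "g4"))   # (1 + 2) / (2 * 3) = 0.5
#' enrichment_or(c(a = 20, b = 0, c = 480, d = 9500))
#' @export
jasmine_mean_rank <- function(cell_values, signature) {
  expr <- cell_values > 0
  if (!any(expr)) stop("cell has no expressed genes", call. = FALSE)
  n <- sum(expr)
  r <- rank(cell_values[expr], ties.method = "average")
  in_sig <- names(cell_values)[expr] %in% signature
  m <- sum(in_sig)
  if (m == 0L) return(0)
  sum(r[in_sig]) / (m * n)
}

#' @rdname jasmine_mean_rank
#' @export
contingency <- function(cell_values, signature, universe = names(cell_values)) {
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  cell_values <- cell_values[universe]
  sig <- universe %in% signature
  expr <- cell_values > 0
  c(a = sum(sig & expr), b = sum(sig & !expr),
    c = sum(!sig & expr), d = sum(!sig & !expr))
}

#' @rdname jasmine_mean_rank
#' @export
enrichment_or <- function(counts) {
  counts <- unlist(counts)[c("a", "b", "c", "d")]
  if (counts[["c"]] == 0)
    stop("degenerate cell: no expressed non-signature genes (c = 0)",
         call. = FALSE)
  b <- if (counts[["b"]] == 0) 1 else counts[["b"]]
  (counts[["a"]] * counts[["d"]]) / (b * counts[["c"]])
}

#' @rdname jasmine_mean_rank
#' @export
enrichment_lr <- function(counts) {
  counts <- unlist(counts)[c("a", "b", "c", "d")]
  if (counts[["c"]] == 0)
    stop("degenerate cell: no expressed non-signature genes (c = 0)",
         call. = FALSE)
  if (counts[["a"]] + counts[["b"]] == 0)
    stop("empty signature (a + b = 0)", call. = FALSE)
  (counts[["a"]] * (counts[["c"]] + counts[["d"]])) /
    (counts[["c"]] * (counts[["a"]] + counts[["b"]]))
}

## ---- SCSE -------------------------------------------------------------

scse_core <- function(matrix, sets, scale_factor = 100) {
  stopifnot(scale_factor > 0)
  X <- matrix$values
  tot <- Matrix::rowSums(X)
  if (any(tot <= 0))
    stop("cell(s) with zero total: ",
         paste(utils::head(cell_ids(matrix)[tot <= 0], 5), collapse = ", "),
         call. = FALSE)
  Z <- set_indicator(sets, gene_ids(matrix))
  sig_sum <- as.matrix(Z %*% Matrix::t(X))            # sets x cells
  out <- sweep(sig_sum, 2, tot, "/") * scale_factor
  dimnames(out) <- list(names(sets), cell_ids(matrix))
  out
}

## ---- AUCell-style -----------------------------------------------------

# recovery-curve weights: gene at descending position pos contributes
# max(k - pos + 1, 0) to the AUC of any signature containing it
aucell_core <- function(matrix, sets, top_fraction = 0.05, seed = 1L) {
  X <- matrix$values
  G <- ncol(X)
  k <- as.integer(ceiling(top_fraction * G))
  if (k < 1) stop("top_fraction too small: no genes in the top set",
                  call. = FALSE)
  n_cells <- nrow(X)
  ii <- jj <- xx <- vector("list", n_cells)
  withr::with_seed(seed, {
    for (ci in seq_len(n_cells)) {
      v <- as.numeric(X[ci, ])
      ord <- order(-v, sample.int(G))   # ties (incl. zeros) by random perm
      top <- ord[seq_len(k)]
      ii[[ci]] <- top
      jj[[ci]] <- rep.int(ci, k)
      xx[[ci]] <- k - seq_len(k) + 1
    }
  })
  U <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(G, n_cells))
  Z <- set_indicator(sets, gene_ids(matrix))
  auc <- as.matrix(Z %*% U)
  s <- pmin(effective_sizes(sets, matrix), k)
  max_auc <- k * s - s * (s - 1) / 2    # signature packed into the top ranks
  out <- auc / max_auc
  dimnames(out) <- list(names(sets), cell_ids(matrix))
  out
}

## ---- ssGSEA -----------------------------------------------------------

# Running-sum score in closed form. Rank all G genes (highest expression
# -> rank G, ties average); walk positions descending. Summing the
# deviation P_in(i) - P_out(i) over all positions i collapses to
#   sum_{g in S} w_g v_g / sum_{g in S} w_g  -  (T - sum_{g in S} v_g)/(G - s)
# where w_g = rank_g^tau, v_g = G - pos_g + 1 (positions a gene has been
# "in" for), and T = G(G+1)/2. The walk order breaks ties by gene storage
# position (stable), while tied weights use the average rank — this is
# what gives all dropout genes one shared tie rank.
ssgsea_core <- function(matrix, sets, tau = 0.25, normalize = TRUE) {
  stopifnot(tau >= 0)
  X <- matrix$values
  G <- ncol(X)
  n_cells <- nrow(X)
  eff <- effective_sizes(sets, matrix)
  if (any(eff >= G))
    stop("signature covers the entire gene universe: ",
         paste(names(sets)[eff >= G], collapse = ", "), call. = FALSE)
  W <- Vp <- base::matrix(0, G, n_cells)
  for (ci in seq_len(n_cells)) {
    v <- as.numeric(X[ci, ])
    W[, ci] <- rank(v, ties.method = "average")^tau
    pos <- integer(G)
    pos[order(-v, seq_len(G))] <- seq_len(G)
    Vp[, ci] <- G - pos + 1
  }
  Z <- set_indicator(sets, gene_ids(matrix))
  sin <- as.matrix(Z %*% (W * Vp)) / as.matrix(Z %*% W)
  sout <- (G * (G + 1) / 2 - as.matrix(Z %*% Vp)) / (G - eff)
  out <- sin - sout
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  dimnames(out) <- list(names(sets), cell_ids(matrix))
  out
}

## ---- single-signature vector wrappers ---------------------------------

#' Per-cell score vectors for a single signature
#'
#' Convenience wrappers around the scoring backends for one gene set,
#' returning a named per-cell numeric vector. See [score_genesets()] for
#' parameter semantics.
#'
#' @inheritParams score_genesets
#' @param signature character vector of gene ids.
#' @param variant JASMINE enrichment variant, `"or"` or `"lr"`.
#' @return Named numeric vector, one score per cell.
#' @export
jasmine_scores <- function(matrix, signature, variant = c("or", "lr")) {
  variant <- match.arg(variant)
  single_sig(matrix, signature,
             method = paste0("jasmine_", variant))
}

#' @rdname jasmine_scores
#' @export
scse_scores <- function(matrix, signature, scale_factor = 100) {
  single_sig(matrix, signature, method = "scse", scale_factor = scale_factor)
}

#' @rdname jasmine_scores
#' @export
aucell_scores <- function(matrix, signature, top_fraction = 0.05, seed = 1L) {
  single_sig(matrix, signature, method = "aucell",
             top_fraction = top_fraction, seed = seed)
}

#' @rdname jasmine_scores
#' @export
ssgsea_scores <- function(matrix, signature, tau = 0.25, normalize = TRUE) {
  single_sig(matrix, signature, method = "ssgsea", tau = tau,
             normalize = normalize)
}

single_sig <- function(matrix, signature, method, ...) {
  sc <- score_genesets(matrix, gene_sets(list(signature = signature)),
                       method = method, ...)
  stats::setNames(sc$score, sc$cell)
}

#' Write scores and their run parameters
#'
#' Writes the wide signatures x cells table as TSV plus a JSON sidecar
#' recording the method and its parameters.
#'
#' @param scores a `sig_scores` tibble.
#' @param path output TSV path; the sidecar is `<path>.params.json`.
#' @return `scores`, invisibly.
#' @export
write_scores <- function(scores, path) {
  m <- score_matrix(scores)
  tb <- tibble::as_tibble(m, rownames = "signature")
  readr::write_tsv(tb, path)
  meta <- c(list(method = attr(scores, "method")), attr(scores, "params"))
  jsonlite::write_json(meta, paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(scores)
}
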