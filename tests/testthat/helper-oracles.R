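# Naive, loop-based reference implementations used as independent oracles.
# They share nothing with the package internals beyond base R.

# random sparse cells x genes count fixture
make_fixture <- function(n_cells = 10, n_genes = 50, seed = 1,
                         sparsity = 0.6, lambda = 3) {
  set.seed(seed)
  x <- matrix(rpois(n_cells * n_genes, lambda) *
                (runif(n_cells * n_genes) > sparsity),
              n_cells, n_genes,
              dimnames = list(paste0("c", seq_len(n_cells)),
                              paste0("g", seq_len(n_genes))))
  x
}

oracle_gene_counts <- function(x) {
  out <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) if (x[i, j] > 0) out[i] <- out[i] + 1L
  }
  out
}

oracle_contingency <- function(v, sig) {
  a <- b <- cc <- d <- 0L
  for (g in names(v)) {
    if (g %in% sig) {
      if (v[[g]] > 0) a <- a + 1L else b <- b + 1L
    } else {
      if (v[[g]] > 0) cc <- cc + 1L else d <- d + 1L
    }
  }
  c(a = a, b = b, c = cc, d = d)
}

# step-by-step JASMINE on a dense matrix: per-cell mean rank and
# enrichment, min-max scaled across cells, averaged
oracle_jasmine <- function(x, sig, variant = "or") {
  n_cells <- nrow(x)
  vmean <- enr <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    v <- x[i, ]
    expr <- v > 0
    r <- rank(v[expr], ties.method = "average")
    in_sig <- names(v)[expr] %in% sig
    vmean[i] <- if (any(in_sig)) sum(r[in_sig]) / (sum(in_sig) * sum(expr))
                else 0
    ct <- oracle_contingency(v, sig)
    enr[i] <- if (variant == "or") {
      (ct["a"] * ct["d"]) / (max(ct["b"], 1) * ct["c"])
    } else {
      (ct["a"] * (ct["c"] + ct["d"])) / (ct["c"] * (ct["a"] + ct["b"]))
    }
  }
  scale01 <- function(z) {
    if (diff(range(z)) == 0) return(rep(0, length(z)))
    (z - min(z)) / diff(range(z))
  }
  (scale01(vmean) + scale01(enr)) / 2
}

oracle_scse <- function(x, sig, scale_factor = 100) {
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x)))
    out[i] <- sum(x[i, colnames(x) %in% sig]) / sum(x[i, ]) * scale_factor
  out
}

# recovery-curve AUC; only valid when no ties fall inside the top k
oracle_aucell <- function(x, sig, top_fraction = 0.05) {
  G <- ncol(x)
  k <- ceiling(top_fraction * G)
  s <- min(sum(colnames(x) %in% sig), k)
  max_auc <- sum(pmin(seq_len(k), s))
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    ord <- order(-x[i, ])
    stopifnot(length(unique(x[i, ord[seq_len(k + 1)]])) == k + 1) # tie-free
    hits <- colnames(x)[ord[seq_len(k)]] %in% sig
    out[i] <- sum(cumsum(hits)) / max_auc
  }
  out
}

# literal position-by-position ssGSEA running sum, one cell
oracle_ssgsea_cell <- function(v, sig, tau = 0.25) {
  G <- length(v)
  w <- rank(v, ties.method = "average")^tau
  ord <- order(-v, seq_along(v))
  in_sig <- names(v)[ord] %in% sig
  p_in <- cumsum(w[ord] * in_sig) / sum(w[ord] * in_sig)
  p_out <- cumsum(!in_sig) / (G - sum(in_sig))
  sum(p_in - p_out)
}

oracle_ssgsea <- function(x, sig, tau = 0.25) {
  vapply(seq_len(nrow(x)),
         function(i) oracle_ssgsea_cell(x[i, ], sig, tau), 0)
}

oracle_cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}
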