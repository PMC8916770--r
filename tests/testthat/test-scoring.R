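test_that("jasmine_mean_rank follows the rank formula", {
  v5 <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  expect_equal(jasmine_mean_rank(v5, "e"), 1.0)       # top gene, rank N
  expect_equal(jasmine_mean_rank(v5, names(v5)), 6 / 10) # (N+1)/(2N), N=5
  v <- c(g1 = 5, g2 = 3, g3 = 0, g4 = 1)
  expect_equal(jasmine_mean_rank(v, c("g2", "g4")), 0.5)
  expect_equal(jasmine_mean_rank(v, "g3"), 0)          # m = 0 rule
  expect_error(jasmine_mean_rank(c(x = 0, y = 0), "x"), "no expressed")
})

test_that("contingency tabulates signature vs expression correctly", {
  uni <- paste0("g", 1:10000)
  v <- stats::setNames(c(rep(1, 4000), rep(0, 6000)), uni)
  sig <- uni[1:20]
  ct <- contingency(v, sig)
  expect_identical(ct, c(a = 20L, b = 0L, c = 3980L, d = 6000L))
  expect_identical(sum(ct), 10000L)          # counts partition the universe
  expect_identical(unname(ct[["a"]] + ct[["b"]]), length(sig))
  v2 <- stats::setNames(c(rep(0, 20), rep(1, 30)), paste0("g", 1:50))
  expect_identical(contingency(v2, paste0("g", 1:20))[c("a", "b")],
                   c(a = 0L, b = 20L))
  # random fixture vs brute-force two-way tabulation
  x <- make_fixture(1, 60, seed = 3)[1, ]
  sig3 <- sample(names(x), 15)
  expect_identical(contingency(x, sig3), oracle_contingency(x, sig3))
  expect_error(contingency(numeric(0), "g1", character(0)), "empty")
})

test_that("odds- and likelihood-ratio enrichment match hand arithmetic", {
  expect_equal(enrichment_or(c(a = 10, b = 10, c = 100, d = 100)), 1.0)
  expect_equal(enrichment_or(c(a = 20, b = 0, c = 480, d = 9500)),
               20 * 9500 / 480)                        # b -> 1 rule
  expect_equal(enrichment_or(c(a = 30, b = 70, c = 500, d = 9400)),
               282000 / 35000)
  expect_equal(enrichment_lr(c(a = 30, b = 70, c = 300, d = 700)), 1.0)
  expect_equal(enrichment_lr(c(a = 30, b = 70, c = 500, d = 9400)),
               0.3 / (500 / 9900))
  expect_equal(enrichment_lr(c(a = 0, b = 20, c = 100, d = 100)), 0)
  expect_error(enrichment_or(c(a = 5, b = 5, c = 0, d = 10)), "degenerate")
  # both ratios exceed 1 exactly when the expressed fraction is enriched
  set.seed(4)
  for (i in 1:20) {
    ct <- c(a = sample(0:30, 1), b = sample(1:30, 1),
            c = sample(1:500, 1), d = sample(1:500, 1))
    enriched <- ct[["a"]] / (ct[["a"]] + ct[["b"]]) >
      ct[["c"]] / (ct[["c"]] + ct[["d"]])
    expect_identical(enrichment_or(ct) > 1, enriched)
    expect_identical(enrichment_lr(ct) > 1, enriched)
  }
})

test_that("every scorer matches its naive loop-based oracle", {
  for (seed in 1:3) {
    x <- make_fixture(10, 50, seed = seed)
    x <- x[rowSums(x) > 0, , drop = FALSE]
    em <- expr_matrix(x, layer = "counts")
    set.seed(seed + 100)
    sig <- sample(colnames(x), 12)
    expect_equal(unname(jasmine_scores(em, sig, "or")),
                 oracle_jasmine(x, sig, "or"))
    expect_equal(unname(jasmine_scores(em, sig, "lr")),
                 oracle_jasmine(x, sig, "lr"))
    expect_equal(unname(scse_scores(em, sig)), oracle_scse(x, sig))
    expect_equal(unname(ssgsea_scores(em, sig, normalize = FALSE)),
                 oracle_ssgsea(x, sig))
  }
})

test_that("AUCell equals the enumerated recovery curve when ties are absent", {
  # distinct positive values everywhere -> tie-breaking cannot matter
  set.seed(11)
  x <- matrix(sample(seq_len(600)), 10, 60,
              dimnames = list(paste0("c", 1:10), paste0("g", 1:60)))
  em <- expr_matrix(x, layer = "counts")
  sig <- sample(colnames(x), 8)
  expect_equal(unname(aucell_scores(em, sig, top_fraction = 0.2, seed = 1)),
               oracle_aucell(x, sig, top_fraction = 0.2))
  # spec walk-through: 10 genes, k = 3, signature at descending ranks 1, 3
  m1 <- expr_matrix(matrix(10:1, 1, 10,
                           dimnames = list("c", paste0("g", 1:10))),
                    layer = "counts")
  expect_equal(unname(aucell_scores(m1, c("g1", "g3"), top_fraction = 0.3)),
               0.8)
  expect_equal(unname(aucell_scores(m1, c("g1", "g2"), top_fraction = 0.3)),
               1.0)   # signature packs the top ranks
  expect_equal(unname(aucell_scores(m1, c("g9", "g10"), top_fraction = 0.3)),
               0.0)   # no signature gene in the top k
  # same seed reproduces; the score stays in [0,1] whatever the seed does
  em2 <- expr_matrix(make_fixture(6, 40, seed = 2), layer = "counts")
  s2 <- paste0("g", 1:10)
  expect_identical(aucell_scores(em2, s2, seed = 5),
                   aucell_scores(em2, s2, seed = 5))
  expect_true(all(aucell_scores(em2, s2, seed = 6) >= 0 &
                    aucell_scores(em2, s2, seed = 6) <= 1))
})

test_that("ssGSEA hand-walked running sum and order invariance", {
  m <- expr_matrix(matrix(c(4, 3, 2, 1), 1, 4,
                          dimnames = list("c1", paste0("g", 1:4))),
                   layer = "counts")
  expect_equal(unname(ssgsea_scores(m, "g1", normalize = FALSE)), 2.0)
  expect_equal(unname(ssgsea_scores(m, "g4", normalize = FALSE)), -2.0)
  expect_error(ssgsea_scores(m, paste0("g", 1:4)), "entire gene universe")
  # permuting gene storage order leaves scores unchanged on tie-free
  # profiles (with ties, the walk visits tied genes in storage order —
  # the stable order that pins dropout genes to their positions)
  set.seed(8)
  x <- matrix(sample(seq_len(150)) + 0, 5, 30,
              dimnames = list(paste0("c", 1:5), paste0("g", 1:30)))
  perm <- sample(ncol(x))
  sig <- colnames(x)[1:6]
  s1 <- ssgsea_scores(expr_matrix(x, layer = "counts"), sig,
                      normalize = FALSE)
  s2 <- ssgsea_scores(expr_matrix(x[, perm], layer = "counts"), sig,
                      normalize = FALSE)
  expect_equal(s1, s2)
  # matrix-range normalization just rescales by one global constant
  em <- expr_matrix(x, layer = "counts")
  sets <- gene_sets(list(a = colnames(x)[1:6], b = colnames(x)[7:16]))
  raw <- score_matrix(score_genesets(em, sets, method = "ssgsea",
                                     normalize = FALSE))
  nrm <- score_matrix(score_genesets(em, sets, method = "ssgsea",
                                     normalize = TRUE))
  expect_equal(nrm, raw / (max(raw) - min(raw)))
})

test_that("JASMINE stays in [0,1] and sees only ranks and zero patterns", {
  for (seed in 4:6) {
    x <- make_fixture(12, 60, seed = seed)
    x <- x[rowSums(x) > 0, , drop = FALSE]
    em <- expr_matrix(x, layer = "counts")
    sets <- random_gene_sets(colnames(x), sizes = c(8, 15, 25), n = 3,
                             seed = seed)
    for (v in c("jasmine_or", "jasmine_lr")) {
      sc <- score_genesets(em, sets, method = v)
      expect_true(all(sc$score >= 0 & sc$score <= 1))
      # strictly increasing zero-preserving transform of each cell
      xt <- x
      for (i in seq_len(nrow(xt))) {
        pos <- xt[i, ] > 0
        xt[i, pos] <- exp(xt[i, pos] / max(xt[i, pos])) + i
      }
      sc2 <- score_genesets(expr_matrix(xt, layer = "normalized"), sets,
                            method = v)
      expect_equal(sc$score, sc2$score)
    }
  }
})

test_that("SCSE is a rescaled expression fraction", {
  x <- matrix(0, 2, 4, dimnames = list(c("c1", "c2"), paste0("g", 1:4)))
  x[1, ] <- c(30, 20, 500, 450)   # signature sum 50 of total 1000
  x[2, ] <- c(1, 1, 1, 1)
  em <- expr_matrix(x, layer = "counts")
  expect_equal(unname(scse_scores(em, c("g1", "g2"))), c(5, 50))
  expect_equal(unname(scse_scores(em, paste0("g", 1:4))), c(100, 100))
  # per-cell rescaling invariance
  x2 <- x * 7
  expect_equal(scse_scores(expr_matrix(x2, layer = "counts"), c("g1", "g2")),
               scse_scores(em, c("g1", "g2")))
  x3 <- rbind(x, zero = 0)
  expect_error(scse_scores(expr_matrix(x3, layer = "counts"), "g1"), "zero")
})

test_that("score_genesets guards its preconditions and tags its output", {
  x <- make_fixture(4, 20, seed = 1)
  x <- x[rowSums(x) > 0, , drop = FALSE]
  em <- expr_matrix(x, layer = "counts")
  expect_error(score_genesets(em, "absent_gene", method = "scse"),
               "no genes in the matrix universe")
  one <- subset_cells(em, cells = 1)
  expect_error(score_genesets(one, colnames(x)[1:3], method = "jasmine_or"),
               "at least 2 cells")
  sc <- score_genesets(em, colnames(x)[1:3], method = "scse")
  expect_identical(attr(sc, "method"), "scse")
  expect_identical(sort(unique(sc$cell)), sort(cell_ids(em)))
  wide <- score_matrix(sc)
  expect_identical(dim(wide), c(1L, nrow(x)))
})

test_that("score tables round-trip through TSV with a parameter sidecar", {
  em <- expr_matrix(make_fixture(4, 20, seed = 6)[-3, ], layer = "counts")
  sets <- gene_sets(list(s1 = paste0("g", 1:5), s2 = paste0("g", 6:12)))
  sc <- score_genesets(em, sets, method = "ssgsea", tau = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores(sc, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_identical(back$signature, c("s1", "s2"))
  expect_equal(as.matrix(back[, -1]), score_matrix(sc), tolerance = 1e-12,
               ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".params.json"))
  expect_identical(meta$method, "ssgsea")
  expect_equal(meta$tau, 0.5)
})
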