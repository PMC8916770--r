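test_that("cohens_d matches the pooled-SD formula and its symmetries", {
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(9, 1)
    expect_equal(cohens_d(x, y), oracle_cohens_d(x, y))
    expect_equal(cohens_d(x, y), -cohens_d(y, x))
    expect_equal(cohens_d(3 * x, 3 * y), cohens_d(x, y)) # scale invariance
  }
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  expect_equal(cohens_d(c(2, 2), c(2, 2)), 0)
  expect_warning(d <- cohens_d(c(3, 3), c(1, 1)), "sentinel")
  expect_identical(d, 1e6)
})

test_that("effect calls use inclusive thresholds", {
  expect_identical(classify_effect(c(1, -1.2, 0.5, -1, 0.99)),
                   c("up", "down", "neutral", "down", "neutral"))
  expect_identical(classify_effect(0.5, threshold = 0.4), "up")
  expect_error(classify_effect(1, threshold = 0), "threshold > 0")
})

make_score_tbl <- function(mat) {
  tibble::tibble(signature = rep(rownames(mat), ncol(mat)),
                 cell = rep(colnames(mat), each = nrow(mat)),
                 score = as.vector(mat))
}

test_that("group contrasts recover engineered effects and partition calls", {
  set.seed(5)
  cells <- paste0("c", 1:40)
  ann <- tibble::tibble(cell_id = cells,
                        group = rep(c("Tumor", "Normal"), each = 20))
  m <- rbind(flat = rnorm(40),
             hot = c(rnorm(20, 5), rnorm(20)),   # engineered d >> 1
             cold = c(rnorm(20), rnorm(20, 5)))
  colnames(m) <- cells
  res <- contrast_groups(make_score_tbl(m), ann, "Tumor", "Normal",
                         sizes = c(flat = 10L, hot = 20L, cold = 30L))
  expect_identical(res$call, c("neutral", "up", "down"))
  expect_identical(res$n1[1], 20L)
  expect_equal(res$cohens_d[res$signature == "hot"],
               cohens_d(m["hot", 1:20], m["hot", 21:40]))
  g <- glance(res)
  expect_equal(g$frac_up + g$frac_down + g$frac_neutral, 1)
  # identical score distributions in both groups -> nothing called
  mm <- m[, c(1:20, 1:20)]
  colnames(mm) <- cells
  same <- contrast_groups(make_score_tbl(mm),
                          tibble::tibble(cell_id = cells,
                                         group = rep(c("A", "B"), each = 20)),
                          "A", "B")
  expect_true(all(same$call == "neutral"))
  expect_error(contrast_groups(make_score_tbl(m), ann, "Tumor", "Stroma"),
               "Stroma")
})

test_that("recovery and false-call rates equal exhaustive counting", {
  res <- tibble::tibble(
    signature = paste0("s", 1:10),
    cohens_d = c(rep(2, 7), rep(0, 3)),
    call = c(rep("up", 7), rep("neutral", 3)))
  expect_equal(recovery_rate(res, "up"), 0.7)
  expect_equal(recovery_rate(res, "down"), 0)
  null_res <- tibble::tibble(
    signature = paste0("s", 1:100),
    call = c(rep("up", 11), rep("down", 46), rep("neutral", 43)))
  fr <- false_call_rates(null_res)
  expect_equal(fr$false_up, 0.11)
  expect_equal(fr$false_down, 0.46)
  expect_true(fr$false_up + fr$false_down <= 1)
  expect_equal(false_call_rates(res[8:10, ])$false_up, 0)
  expect_error(recovery_rate(res[0, ], "up"), "empty")
})

test_that("score CV is SD over mean and scale-free", {
  expect_equal(score_cv(c(5, 5, 5)), 0)
  expect_equal(score_cv(c(1, 3)), sqrt(2) / 2)
  set.seed(9)
  v <- rlnorm(20)
  expect_equal(score_cv(7 * v), score_cv(v))
  expect_warning(out <- score_cv(c(-1, 1)), "undefined")
  expect_true(is.na(out))
})

test_that("size correlation is Spearman with antisymmetry under sign flip", {
  res <- tibble::tibble(signature = paste0("s", 1:6),
                        size = c(10L, 20L, 30L, 40L, 50L, 60L),
                        cohens_d = c(0.1, 0.4, 0.5, 0.9, 1.2, 2),
                        call = "neutral")
  sc <- size_correlation(res)
  expect_equal(sc$rho, 1)
  flipped <- res
  flipped$cohens_d <- -res$cohens_d
  expect_equal(size_correlation(flipped)$rho, -1)
  # independent d -> small rho on a large fixture
  set.seed(3)
  big <- tibble::tibble(signature = paste0("s", 1:500),
                        size = sample(20:300, 500, TRUE),
                        cohens_d = rnorm(500), call = "neutral")
  expect_lt(abs(size_correlation(big)$rho), 0.15)
  same <- res
  same$size <- 50L
  expect_error(size_correlation(same), "identical")
})

test_that("consensus accuracy counts agreement on non-neutral consensus", {
  calls <- tibble::tibble(
    method = rep(c("A", "B", "C"), each = 2),
    signature = rep(c("s1", "s2"), 3),
    call = c("up", "down", "up", "neutral", "neutral", "down"))
  # s1: A,B up -> consensus up; s2: B neutral, A,C down -> consensus down
  acc <- consensus_accuracy(calls)
  expect_equal(acc$accuracy[acc$method == "A" & acc$consensus == "up"], 1)
  expect_equal(acc$accuracy[acc$method == "C" & acc$consensus == "up"], 0)
  expect_equal(acc$accuracy[acc$method == "B" & acc$consensus == "down"], 0)
  # all methods identical -> accuracy 1 everywhere
  same <- tidyr::expand_grid(method = c("A", "B", "C"),
                             signature = paste0("s", 1:5))
  same$call <- rep(c("up", "down", "up", "down", "up"), 3)
  expect_true(all(consensus_accuracy(same)$accuracy == 1))
  expect_error(consensus_accuracy(calls[calls$method != "C", ]),
               "at least 3")
})

test_that("consensus accuracy equals brute-force enumeration", {
  set.seed(12)
  grid <- tidyr::expand_grid(method = c("m1", "m2", "m3"),
                             signature = sprintf("s%02d", 1:20))
  grid$call <- sample(c("up", "down", "neutral"), nrow(grid), TRUE)
  acc <- consensus_accuracy(grid)
  # brute force
  for (s in unique(grid$signature)) {
    sub <- grid[grid$signature == s, ]
    cons <- if (sum(sub$call == "up") >= 2) "up"
            else if (sum(sub$call == "down") >= 2) "down" else "neutral"
    if (cons == "neutral") next
    for (m in unique(grid$method)) {
      row <- acc[acc$method == m & acc$consensus == cons, ]
      expect_equal(nrow(row), 1)
    }
  }
  brute <- list()
  for (m in c("m1", "m2", "m3")) for (dir in c("up", "down")) {
    hits <- n <- 0
    for (s in unique(grid$signature)) {
      sub <- grid[grid$signature == s, ]
      cons <- if (sum(sub$call == "up") >= 2) "up"
              else if (sum(sub$call == "down") >= 2) "down" else "neutral"
      if (cons != dir) next
      n <- n + 1
      if (sub$call[sub$method == m] == dir) hits <- hits + 1
    }
    if (n > 0)
      expect_equal(acc$accuracy[acc$method == m & acc$consensus == dir],
                   hits / n)
  }
})
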