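#' Simulate noisy gold-standard gene sets
#'
#' Builds benchmark signatures of known direction from pools of true
#' up- and down-regulated genes. For each direction x size x noise x
#' replicate combination, `round((1 - noise) * size)` genes are drawn
#' without replacement from that direction's pool and the remainder —
#' the noise genes — from the universe minus that pool, so higher noise
#' levels attenuate more of the signal. The default grid (sizes 50, 100,
#' 150, 200, 300; noise 0, 0.2, 0.4, 0.6, 0.8; 200 replicates) yields
#' 5,000 sets per direction. The noise count uses round-half-away-from-
#' zero; on the default grid every product is exact so the rule never
#' bites. Replicates consume one seeded stream in direction-major, then
#' size, noise, replicate order, so output is reproducible everywhere.
#'
#' @param up_pool,down_pool character vectors of true up-/down-regulated
#'   genes; must be disjoint.
#' @param universe character vector containing all candidate genes.
#' @param sizes integer vector of set sizes.
#' @param noise_levels numeric vector in \[0, 1).
#' @param n_per_combo replicates per direction x size x noise cell.
#' @param seed integer seed.
#' @return A tibble with one row per simulated set: `name`, `direction`,
#'   `size`, `noise`, `replicate`, `n_true`, and a `genes` list-column.
#'   Convert with [sim_sets_as_gene_sets()] for scoring, or export with
#'   [write_gmt()].
#' @export
simulate_noisy_sets <- function(up_pool, down_pool, universe,
                                sizes = c(50, 100, 150, 200, 300),
                                noise_levels = c(0, 0.2, 0.4, 0.6, 0.8),
                                n_per_combo = 200L, seed = 1L) {
  if (length(intersect(up_pool, down_pool)))
    stop("up and down pools must be disjoint", call. = FALSE)
  stopifnot(all(up_pool %in% universe), all(down_pool %in% universe),
            all(noise_levels >= 0), all(noise_levels < 1))
  pools <- list(up = up_pool, down = down_pool)
  grid <- tidyr::expand_grid(direction = c("up", "down"), size = sizes,
                             noise = noise_levels,
                             replicate = seq_len(n_per_combo))
  grid$n_true <- grid$size - round_half_away(grid$noise * grid$size)
  for (d in names(pools)) {
    need <- grid[grid$direction == d, ]
    if (any(need$n_true > length(pools[[d]])))
      stop(sprintf("pool too small for direction=%s at size %d, noise %.2f",
                   d, need$size[which.max(need$n_true)][1],
                   need$noise[which.max(need$n_true)][1]), call. = FALSE)
    if (any(need$size - need$n_true > length(universe) - length(pools[[d]])))
      stop("universe too small for the requested noise genes", call. = FALSE)
  }
  withr::with_seed(seed, {
    grid$genes <- purrr::pmap(
      grid[c("direction", "size", "n_true")],
      function(direction, size, n_true) {
        pool <- pools[[direction]]
        c(sample(pool, n_true),
          sample(setdiff(universe, pool), size - n_true))
      })
  })
  grid$name <- sprintf("sim_%s_s%d_q%02d_r%03d", grid$direction, grid$size,
                       as.integer(round(100 * grid$noise)), grid$replicate)
  tibble::as_tibble(grid[c("name", "direction", "size", "noise",
                           "replicate", "n_true", "genes")])
}

# round half away from zero (base round() is half-to-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @rdname simulate_noisy_sets
#' @param sim a tibble from `simulate_noisy_sets()` (or a filtered
#'   subset of one).
#' @export
sim_sets_as_gene_sets <- function(sim) {
  gene_sets(stats::setNames(sim$genes, sim$name),
            descriptions = sprintf("%s|%d|%g|%d", sim$direction, sim$size,
                                   sim$noise, sim$replicate))
}

#' Binomial down-sampling of a count matrix
#'
#' Thins each count k to a Binomial(k, rate) draw — the standard model of
#' reduced sequencing depth — creating additional dropouts while never
#' turning a zero positive. With `rescale = TRUE` each cell is scaled
#' back to its own original total afterwards, so groups are compared at
#' equal coverage; the zero pattern of the thinned matrix is kept. A
#' rate of 1 returns the input unchanged.
#'
#' @param matrix an [expr_matrix()] with a counts layer.
#' @param rate retention probability in (0, 1\].
#' @param seed integer seed.
#' @param rescale scale each cell back to its original total.
#' @return An `expr_matrix` (layer `"normalized"` when rescaled, else
#'   `"counts"`).
#' @export
downsample_matrix <- function(matrix, rate, seed = 1L, rescale = TRUE) {
  stopifnot(inherits(matrix, "expr_matrix"), rate > 0, rate <= 1)
  if (matrix$layer != "counts")
    stop("down-sampling needs a counts layer", call. = FALSE)
  if (rate == 1) return(matrix)
  v <- matrix$values
  orig_tot <- Matrix::rowSums(v)
  withr::with_seed(seed, {
    v@x <- as.double(stats::rbinom(length(v@x), size = as.integer(v@x),
                                   prob = rate))
  })
  v <- Matrix::drop0(v)
  if (!rescale) return(expr_matrix(v, layer = "counts"))
  new_tot <- Matrix::rowSums(v)
  if (any(new_tot == 0))
    stop("down-sampling emptied cell(s); use a higher rate", call. = FALSE)
  expr_matrix(v * (orig_tot / new_tot), layer = "normalized")
}

#' Down-sampling null specificity experiment
#'
#' The specificity probe: draw `n_cells` tumor cells, thin each to
#' `rate` of its coverage (then rescale to equal totals), score the
#' original and down-sampled twins with one backend, and contrast
#' original vs down-sampled with Cohen's d. Because the two groups are
#' the same cells, every non-neutral call is false; summarise with
#' [false_call_rates()]. The same seed-fixed cell subset should be
#' reused across methods so they are compared on identical cells (pass
#' the same `seed`).
#'
#' @param matrix an [expr_matrix()] counts layer.
#' @param annotation tibble with `cell_id`, `group`.
#' @param sets a [gene_sets()] collection.
#' @param method scoring backend tag, as in [score_genesets()].
#' @param tumor_label annotation group to sample from.
#' @param n_cells number of cells to draw (default 100).
#' @param rate down-sampling rate (default 0.5).
#' @param threshold effect-size call threshold.
#' @param seed integer seed driving the cell draw and the thinning.
#' @param ... further arguments to [score_genesets()].
#' @return A `sig_contrast` tibble (group1 = original cells).
#' @export
null_specificity_experiment <- function(matrix, annotation, sets,
                                        method = "jasmine_or",
                                        tumor_label = "Tumor",
                                        n_cells = 100L, rate = 0.5,
                                        threshold = 1, seed = 1L, ...) {
  tumor <- annotation$cell_id[annotation$group == tumor_label]
  tumor <- intersect(tumor, cell_ids(matrix))
  if (length(tumor) < n_cells)
    stop("fewer than ", n_cells, " cells labelled ", tumor_label,
         call. = FALSE)
  picked <- withr::with_seed(seed, sample(tumor, n_cells))
  orig <- subset_cells(matrix, cells = picked)
  down <- downsample_matrix(orig, rate = rate, seed = seed + 1L,
                            rescale = TRUE)
  # one two-group matrix so cross-cell scorers see both groups at once
  dv <- down$values
  rownames(dv) <- paste0(picked, "_ds")
  both <- expr_matrix(rbind(methods::as(orig$values, "CsparseMatrix"), dv),
                      layer = "normalized")
  ann <- tibble::tibble(cell_id = c(picked, paste0(picked, "_ds")),
                        group = rep(c("original", "downsampled"),
                                    each = n_cells))
  scores <- score_genesets(both, sets, method = method, ...)
  contrast_groups(scores, ann, "original", "downsampled",
                  threshold = threshold,
                  sizes = effective_sizes(sets, both))
}
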