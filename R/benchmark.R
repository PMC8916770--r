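#' Run the full scoring benchmark on a cohort
#'
#' Orchestrates the gold-standard experiment end to end: simulate noisy
#' up/down gene sets from the cohort's true DE pools
#' ([simulate_noisy_sets()]), score every set with every requested
#' backend, contrast tumor vs normal cells with Cohen's d, and
#' summarise recovery per method x direction x size x noise. When at
#' least three methods are run, accuracy against the >= 2-method
#' consensus is also reported. A down-sampling null
#' ([null_specificity_experiment()]) on neutral random sets yields
#' false-call rates and score CV stability per method.
#'
#' @param cohort list with `matrix`, `annotation`, `truth`
#'   (as from [generate_cohort()]).
#' @param methods scoring backend tags (see [score_genesets()]).
#' @param sizes,noise_levels,n_per_combo simulation grid passed to
#'   [simulate_noisy_sets()].
#' @param threshold Cohen's d call threshold.
#' @param group1,group2 annotation labels contrasted (d > 0 = higher in
#'   `group1`).
#' @param n_null_sets,n_null_cells,null_rate down-sampling null design:
#'   number of neutral random sets, cells drawn, and retention rate.
#' @param seed integer seed driving every stochastic step.
#' @return List of tibbles: `recovery` (per method/direction/size/noise),
#'   `calls` (per method/signature), `consensus` (accuracy vs consensus,
#'   when >= 3 methods), `null` (false-call rates and mean CVs per
#'   method).
#' @export
run_benchmark <- function(cohort,
                          methods = c("jasmine_or", "scse", "aucell",
                                      "ssgsea"),
                          sizes = c(50, 100, 150, 200, 300),
                          noise_levels = c(0, 0.2, 0.4, 0.6, 0.8),
                          n_per_combo = 10L, threshold = 1,
                          group1 = "Tumor", group2 = "Normal",
                          n_null_sets = 50L, n_null_cells = 100L,
                          null_rate = 0.5, seed = 1L) {
  mat <- cohort$matrix
  pools <- truth_pools(cohort)
  sim <- simulate_noisy_sets(pools$up_pool, pools$down_pool,
                             universe = gene_ids(mat), sizes = sizes,
                             noise_levels = noise_levels,
                             n_per_combo = n_per_combo, seed = seed)
  sets <- sim_sets_as_gene_sets(sim)
  calls <- purrr::map_dfr(methods, function(m) {
    sc <- score_genesets(mat, sets, method = m, seed = seed)
    ct <- contrast_groups(sc, cohort$annotation, group1, group2,
                          threshold = threshold)
    dplyr::bind_cols(method = m, tidy(ct))
  })
  truth_cols <- sim[c("name", "direction", "size", "noise")]
  calls <- dplyr::left_join(calls, truth_cols,
                            by = c(signature = "name"))
  recovery <- calls |>
    dplyr::group_by(.data$method, .data$direction, .data$size,
                    .data$noise) |>
    dplyr::summarise(recovery = mean(.data$call == .data$direction),
                     n = dplyr::n(), .groups = "drop")
  consensus <- if (length(methods) >= 3L) {
    consensus_accuracy(calls[c("method", "signature", "call")])
  } else NULL
  null_sets <- random_gene_sets(gene_ids(mat),
                                sizes = rep(sizes,
                                            length.out = n_null_sets),
                                n = n_null_sets, seed = seed + 1L)
  null_tbl <- purrr::map_dfr(methods, function(m) {
    res <- null_specificity_experiment(mat, cohort$annotation, null_sets,
                                       method = m, tumor_label = group1,
                                       n_cells = n_null_cells,
                                       rate = null_rate,
                                       threshold = threshold, seed = seed)
    dplyr::bind_cols(method = m, false_call_rates(res))
  })
  list(recovery = recovery, calls = tibble::as_tibble(calls),
       consensus = consensus, null = null_tbl)
}

#' Plot recovery rates across noise levels
#'
#' One line per method, faceted by true direction, averaging over set
#' sizes — the standard sensitivity panel of a scoring benchmark.
#'
#' @param recovery the `recovery` tibble from [run_benchmark()].
#' @return A ggplot object.
#' @export
plot_recovery <- function(recovery) {
  avg <- recovery |>
    dplyr::group_by(.data$method, .data$direction, .data$noise) |>
    dplyr::summarise(recovery = mean(.data$recovery), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$noise, y = .data$recovery,
                                    colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$direction)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "noise level", y = "recovery rate")
}
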