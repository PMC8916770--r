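#' Cohen's d with pooled standard deviation
#'
#' The classic (uncorrected) standardized mean difference
#' d = (mean(x) - mean(y)) / s_pooled, with
#' s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)) using
#' sample variances. When both groups are constant and equal, d = 0; when
#' s_pooled = 0 but the means differ, a signed large sentinel
#' (`sign * 1e6`) is returned with a warning so downstream up/down calls
#' stay finite and correct.
#'
#' @param x,y numeric score vectors for the two groups, each of length
#'   >= 2.
#' @return A scalar.
#' @examples
#' cohens_d(c(2, 4), c(1, 3))  # 1 / sqrt(2)
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  md <- mean(x) - mean(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) {
    if (md == 0) return(0)
    warning("zero pooled SD with unequal means; returning signed sentinel",
            call. = FALSE)
    return(sign(md) * 1e6)
  }
  md / sp
}

#' Call a signature up, down, or neutral from its effect size
#'
#' Thresholds are inclusive: d >= `threshold` is `"up"`,
#' d <= -`threshold` is `"down"`, anything between is `"neutral"`.
#' The conventional threshold is 1.
#'
#' @param d numeric vector of Cohen's d values.
#' @param threshold positive scalar (default 1).
#' @return Character vector in `c("up", "down", "neutral")`.
#' @export
classify_effect <- function(d, threshold = 1) {
  stopifnot(threshold > 0)
  dplyr::case_when(d >= threshold ~ "up",
                   d <= -threshold ~ "down",
                   TRUE ~ "neutral")
}

#' Contrast signature scores between two cell groups
#'
#' Computes Cohen's d per signature between the cells labelled `group1`
#' and `group2` (d > 0 means higher scores in `group1`) and classifies
#' each signature with [classify_effect()].
#'
#' @param scores a `sig_scores` tibble from [score_genesets()], or any
#'   tibble with columns `signature`, `cell`, `score`.
#' @param annotation tibble with columns `cell_id`, `group`.
#' @param group1,group2 group labels to contrast; both must annotate at
#'   least 2 scored cells.
#' @param threshold effect-size call threshold (default 1).
#' @param sizes optional named integer vector of effective signature
#'   sizes to attach (e.g. from [effective_sizes()]).
#' @return A `sig_contrast` tibble with columns `signature`, `cohens_d`,
#'   `call`, `n1`, `n2` (and `size` when supplied). [glance()] summarises
#'   it to one row with the up/down/neutral fractions; [autoplot()]
#'   draws d against size.
#' @export
contrast_groups <- function(scores, annotation, group1, group2,
                            threshold = 1, sizes = NULL) {
  stopifnot(all(c("signature", "cell", "score") %in% names(scores)),
            all(c("cell_id", "group") %in% names(annotation)))
  for (g in c(group1, group2))
    if (!g %in% annotation$group)
      stop("group label not in annotation: ", g, call. = FALSE)
  joined <- dplyr::inner_join(scores,
                              annotation[c("cell_id", "group")],
                              by = c(cell = "cell_id"))
  joined <- dplyr::filter(joined, .data$group %in% c(group1, group2))
  res <- joined |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(
      cohens_d = cohens_d(.data$score[.data$group == group1],
                          .data$score[.data$group == group2]),
      n1 = sum(.data$group == group1),
      n2 = sum(.data$group == group2),
      .groups = "drop") |>
    dplyr::mutate(call = classify_effect(.data$cohens_d, threshold),
                  .after = "cohens_d")
  # keep the scoring order of signatures
  res <- res[match(unique(scores$signature), res$signature), ]
  if (!is.null(sizes))
    res$size <- as.integer(sizes[res$signature])
  structure(res, threshold = threshold,
            method = attr(scores, "method"),
            class = c("sig_contrast", class(res)))
}

#' @export
glance.sig_contrast <- function(x, ...) {
  tibble::tibble(
    n_signatures = nrow(x),
    frac_up = mean(x$call == "up"),
    frac_down = mean(x$call == "down"),
    frac_neutral = mean(x$call == "neutral"),
    threshold = attr(x, "threshold"))
}

#' @export
tidy.sig_contrast <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
autoplot.sig_contrast <- function(object, ...) {
  thr <- attr(object, "threshold")
  p <- if (!is.null(object$size)) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$cohens_d,
                                         colour = .data$call))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = seq_len(nrow(object)),
                                         y = .data$cohens_d,
                                         colour = .data$call)) +
      ggplot2::xlab("signature")
  }
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::labs(y = "Cohen's d", colour = "call")
}

#' Benchmark summary statistics over contrast results
#'
#' `recovery_rate()` is the fraction of gold-standard signatures whose
#' call matches their true direction. `false_call_rates()` summarises a
#' null contrast (same cells vs their down-sampled twins), where any
#' non-neutral call is false by construction. `score_cv()` is the
#' coefficient of variation (sample SD / mean) of a score vector.
#' `size_correlation()` is the Spearman correlation of Cohen's d with
#' effective signature size (two-sided asymptotic p-value).
#'
#' @param results a `sig_contrast` tibble (for `size_correlation()` it
#'   must carry a `size` column).
#' @param truth_direction `"up"` or `"down"`.
#' @param scores numeric vector of one signature's scores.
#' @return `recovery_rate()`: scalar in \[0, 1\]. `false_call_rates()`:
#'   tibble with `false_up`, `false_down`. `score_cv()`: scalar (NA with
#'   a warning when the mean is 0). `size_correlation()`: tibble with
#'   `rho`, `p_value`.
#' @export
recovery_rate <- function(results, truth_direction = c("up", "down")) {
  truth_direction <- match.arg(truth_direction)
  if (nrow(results) == 0L) stop("empty contrast result", call. = FALSE)
  mean(results$call == truth_direction)
}

#' @rdname recovery_rate
#' @export
false_call_rates <- function(results) {
  if (nrow(results) == 0L) stop("empty contrast result", call. = FALSE)
  tibble::tibble(false_up = mean(results$call == "up"),
                 false_down = mean(results$call == "down"))
}

#' @rdname recovery_rate
#' @export
score_cv <- function(scores) {
  m <- mean(scores)
  if (m == 0) {
    warning("zero mean score; CV undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::sd(scores) / m
}

#' @rdname recovery_rate
#' @export
size_correlation <- function(results) {
  if (is.null(results$size))
    stop("contrast result carries no signature sizes", call. = FALSE)
  if (length(unique(results$size)) < 2L)
    stop("all signature sizes identical", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(results$size, results$cohens_d, method = "spearman",
                    alternative = "two.sided", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Accuracy against the cross-method consensus
#'
#' The consensus call of a signature is the direction (`"up"` or
#' `"down"`) supported by at least `min_agree` methods; otherwise
#' neutral. A method's accuracy is the fraction of consensus signatures
#' it agrees with, reported separately for the up-consensus and
#' down-consensus sets (signatures with a neutral consensus are not
#' counted). With more than 3 methods a simultaneous double consensus
#' (>= `min_agree` up and >= `min_agree` down) is an error.
#'
#' @param calls tibble with columns `method`, `signature`, `call`, fully
#'   crossed over >= 3 methods (e.g. row-bound [tidy()] contrast results
#'   with a `method` column).
#' @param min_agree minimum number of agreeing methods (default 2).
#' @return Tibble with columns `method`, `consensus`, `accuracy`, `n`.
#' @export
consensus_accuracy <- function(calls, min_agree = 2L) {
  stopifnot(all(c("method", "signature", "call") %in% names(calls)))
  methods <- unique(calls$method)
  if (length(methods) < 3L) stop("need at least 3 methods", call. = FALSE)
  cons <- calls |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(n_up = sum(.data$call == "up"),
                     n_down = sum(.data$call == "down"),
                     .groups = "drop")
  if (any(cons$n_up >= min_agree & cons$n_down >= min_agree))
    stop("conflicting consensus: both directions reach min_agree",
         call. = FALSE)
  cons$consensus <- dplyr::case_when(cons$n_up >= min_agree ~ "up",
                                     cons$n_down >= min_agree ~ "down",
                                     TRUE ~ "neutral")
  joined <- dplyr::inner_join(calls, cons[c("signature", "consensus")],
                              by = "signature") |>
    dplyr::filter(.data$consensus != "neutral")
  joined |>
    dplyr::group_by(.data$method, .data$consensus) |>
    dplyr::summarise(accuracy = mean(.data$call == .data$consensus),
                     n = dplyr::n(), .groups = "drop")
}

#' Write a contrast result as TSV
#'
#' @param results a `sig_contrast` tibble.
#' @param path output path.
#' @return `results`, invisibly.
#' @export
write_contrast <- function(results, path) {
  readr::write_tsv(tibble::as_tibble(results), path)
  invisible(results)
}
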