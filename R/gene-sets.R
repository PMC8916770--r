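#' Gene set collections
#'
#' A gene set (used interchangeably with "gene signature") is a named,
#' non-empty collection of unique gene identifiers. A collection is stored
#' as a named list of character vectors of class `gene_sets`, with a
#' parallel `descriptions` attribute. Genes are matched by exact string
#' equality everywhere in this package — no symbol aliasing or case
#' folding.
#'
#' @param sets named list of character vectors.
#' @param descriptions optional character vector, one per set.
#' @return A `gene_sets` object.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  nm <- names(sets)
  if (length(sets) && (is.null(nm) || any(!nzchar(nm))))
    stop("every gene set needs a non-empty name", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate gene set name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L))
    stop("empty gene set not allowed", call. = FALSE)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  stopifnot(length(descriptions) == length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, nm),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d sets, sizes %d-%d\n", length(x),
              if (length(x)) min(lengths(x)) else 0L,
              if (length(x)) max(lengths(x)) else 0L))
  invisible(x)
}

#' @export
`[.gene_sets` <- function(x, i) {
  gene_sets(unclass(x)[i], descriptions = unname(attr(x, "descriptions")[i]))
}

#' @export
as_tibble.gene_sets <- function(x, ...) {
  tibble::tibble(set = rep(names(x), lengths(x)),
                 gene = unlist(x, use.names = FALSE))
}

#' Read and write GMT gene set files
#'
#' GMT is the tab-separated MSigDB distribution format: one set per line,
#' fields name, description, then genes. Duplicate genes within a line are
#' collapsed; set order is preserved; a duplicate set name or a line with
#' fewer than three fields is an error (the parse error names the line).
#'
#' @param path file path.
#' @return `read_gmt()` returns a [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 3 tab-separated fields",
         call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nm)
  gene_sets(sets, descriptions = desc)
}

#' @rdname read_gmt
#' @param x a [gene_sets()] collection.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  desc <- attr(x, "descriptions")
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, desc[[nm]], x[[nm]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(x)
}

#' Effective signature size and minimum-size filtering
#'
#' The effective size of a set is the size of its intersection with the
#' matrix's gene universe; that intersection is what every scorer uses.
#' `filter_min_size()` keeps sets whose effective size is at least
#' `min_size` (default 20, the conventional floor for signature
#' collections). The boundary is inclusive.
#'
#' @param x a [gene_sets()] collection.
#' @param matrix an [expr_matrix()] supplying the gene universe.
#' @param min_size integer >= 1.
#' @return A filtered `gene_sets` collection (possibly empty, with a
#'   warning).
#' @export
filter_min_size <- function(x, matrix, min_size = 20L) {
  stopifnot(inherits(x, "gene_sets"), min_size >= 1)
  eff <- effective_sizes(x, matrix)
  keep <- eff >= min_size
  if (!any(keep))
    warning("no gene sets left after the minimum-size filter", call. = FALSE)
  x[keep]
}

#' @rdname filter_min_size
#' @export
effective_sizes <- function(x, matrix) {
  stopifnot(inherits(x, "gene_sets"), inherits(matrix, "expr_matrix"))
  uni <- gene_ids(matrix)
  vapply(x, function(g) sum(g %in% uni), 0L)
}

# signatures x genes sparse indicator matrix over the matrix universe;
# sets with empty intersection keep an all-zero row.
set_indicator <- function(sets, universe) {
  idx <- lapply(unclass(sets), function(g) which(universe %in% g))
  Matrix::sparseMatrix(
    i = rep(seq_along(idx), lengths(idx)),
    j = unlist(idx, use.names = FALSE),
    x = 1,
    dims = c(length(sets), length(universe)),
    dimnames = list(names(sets), universe))
}

#' Generate random gene sets from a universe
#'
#' Uniform draws without replacement — "neutral" signatures carrying no
#' differential signal, used for specificity and bias probes.
#'
#' @param universe character vector of gene ids.
#' @param sizes integer vector of set sizes, recycled over `n`.
#' @param n number of sets.
#' @param seed integer seed.
#' @return A [gene_sets()] collection.
#' @export
random_gene_sets <- function(universe, sizes, n = length(sizes), seed = 1L) {
  sizes <- rep_len(sizes, n)
  stopifnot(all(sizes <= length(universe)))
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n), function(i) sample(universe, sizes[i]))
  })
  names(sets) <- sprintf("random_%03d_s%d", seq_len(n), sizes)
  gene_sets(sets, descriptions = sprintf("size=%d", sizes))
}
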