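#' Build a gene-set collection
#'
#' Wraps named gene sets with the universe they are tested against. Members
#' outside the universe are dropped (with a message giving the count), and
#' sets left empty after restriction are removed.
#'
#' @param sets named list of character vectors.
#' @param universe character vector of all testable gene/target ids.
#' @return a `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) {
    abort("universe is empty", class = "herb_validation_error")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("gene sets must be named")
  }
  assert_unique_ids(names(sets), "gene set name")
  restricted <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  dropped <- sum(lengths(sets) - lengths(restricted))
  if (dropped > 0) {
    inform(sprintf("dropped %d set member(s) outside the universe", dropped))
  }
  empty <- names(restricted)[lengths(restricted) == 0]
  if (length(empty) > 0) {
    warn(sprintf("removed empty set(s) after universe restriction: %s",
                 paste(empty, collapse = ", ")))
    restricted <- restricted[lengths(restricted) > 0]
  }
  structure(list(sets = restricted, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over a universe of %d ids\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-delimited: set name, description, then the member ids.
#'
#' @param path file path.
#' @return [read_gmt()]: named list of character member vectors (the
#'   description field is kept in attribute `"description"`).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(bad, collapse = ", ")),
          class = "herb_format_error")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  attr(sets, "description") <- setNames(vapply(fields, `[`, character(1), 2),
                                        names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of descriptions (recycled
#'   `"na"` when absent).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description") %||% rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query set overlaps it more than
#' expected by chance when drawing from the universe. With universe size N,
#' set size K, query size n and overlap k, the p-value is the upper
#' hypergeometric tail P(X >= k). P-values are adjusted across all sets in
#' the collection with the Benjamini-Hochberg step-up procedure.
#'
#' Query members outside the universe are dropped before testing (with a
#' message giving the count).
#'
#' @param query character vector of gene/target ids.
#' @param collection a [gene_set_collection()].
#' @return a `herb_enrichment` tibble sorted by p: `set`, `k` (overlap),
#'   `K` (set size), `n` (query size), `N` (universe size), `p`, `q`.
#' @export
hypergeom_enrich <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  in_univ <- query[query %in% collection$universe]
  if (length(in_univ) < length(query)) {
    inform(sprintf("dropped %d query id(s) outside the universe",
                   length(query) - length(in_univ)))
  }
  N <- length(collection$universe)
  n <- length(in_univ)
  res <- purrr::imap_dfr(collection$sets, function(members, name) {
    K <- length(members)
    k <- length(intersect(in_univ, members))
    # upper tail P(X >= k) of Hypergeometric(N, K, n)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = name, k = k, K = K, n = n, N = N, p = p)
  })
  res$q <- bh_adjust(res$p)
  res <- dplyr::arrange(res, .data$p, .data$set)
  class(res) <- c("herb_enrichment", class(res))
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as a named
#' surface so enrichment results document their FDR control.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted q-values, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    abort("p-values must lie in (0, 1]", class = "herb_validation_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' @export
autoplot.herb_enrichment <- function(object, top = 15, ...) {
  df <- head(object, top)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q),
                                   y = stats::reorder(.data$set, -.data$q),
                                   size = .data$k)) +
    ggplot2::geom_point(colour = "#e6550d") +
    ggplot2::labs(x = expression(-log[10] ~ q), y = NULL, size = "overlap",
                  title = "Gene-set over-representation") +
    ggplot2::theme_minimal()
}
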