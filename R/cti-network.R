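#' Build a compound-target interaction network
#'
#' Collapses per-compound target predictions (or any compound-target edge
#' table) into a strictly bipartite network: a compound and a target are
#' linked iff the compound is predicted (or known) to act on the protein.
#' Duplicate pairs are collapsed to a single edge, with the multiplicity
#' recorded. Optional annotation tables are joined left-outer onto the two
#' node classes; nodes without an annotation row keep `NA`.
#'
#' @param predictions tibble with columns `query_id`/`compound_id` and
#'   `target_id` (extra columns such as `rank`/`score` are ignored), e.g.
#'   the output of [predict_targets_all()].
#' @param compound_annotations optional tibble keyed by `compound_id`
#'   (e.g. `structural_class`).
#' @param target_annotations optional tibble keyed by `target_id`
#'   (e.g. tissue classification, pathway membership).
#' @return a `cti_network` object.
#' @export
build_cti <- function(predictions, compound_annotations = NULL,
                      target_annotations = NULL) {
  predictions <- as_tibble(predictions)
  if ("query_id" %in% names(predictions) && !"compound_id" %in% names(predictions)) {
    predictions <- dplyr::rename(predictions, compound_id = "query_id")
  }
  if (nrow(predictions) == 0) {
    edges <- tibble(compound_id = character(), target_id = character())
  } else {
    assert_columns(predictions, c("compound_id", "target_id"), "predictions")
    edges <- predictions |>
      dplyr::mutate(compound_id = as.character(.data$compound_id),
                    target_id = as.character(.data$target_id)) |>
      dplyr::select(dplyr::all_of(c("compound_id", "target_id")))
  }
  n_raw <- nrow(edges)
  edges <- dplyr::distinct(edges)
  if (nrow(edges) < n_raw) {
    inform(sprintf("collapsed %d duplicate compound-target pair(s)",
                   n_raw - nrow(edges)))
  }
  clash <- intersect(edges$compound_id, edges$target_id)
  if (length(clash) > 0) {
    abort(sprintf("id(s) used as both compound and target: %s",
                  paste(clash, collapse = ", ")),
          class = "herb_validation_error")
  }
  compounds <- tibble(compound_id = unique(edges$compound_id))
  targets <- tibble(target_id = unique(edges$target_id))
  if (!is.null(compound_annotations)) {
    compounds <- dplyr::left_join(compounds,
                                  dplyr::distinct(as_tibble(compound_annotations),
                                                  .data$compound_id, .keep_all = TRUE),
                                  by = "compound_id")
  }
  if (!is.null(target_annotations)) {
    targets <- dplyr::left_join(targets,
                                dplyr::distinct(as_tibble(target_annotations),
                                                .data$target_id, .keep_all = TRUE),
                                by = "target_id")
  }
  structure(list(edges = edges, compounds = compounds, targets = targets),
            class = "cti_network")
}

#' @export
print.cti_network <- function(x, ...) {
  cat(sprintf("<cti_network> %d compounds, %d targets, %d edges\n",
              nrow(x$compounds), nrow(x$targets), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.cti_network <- function(x, ...) x$edges

#' @export
glance.cti_network <- function(x, ...) {
  tibble(n_compounds = nrow(x$compounds), n_targets = nrow(x$targets),
         n_edges = nrow(x$edges))
}

#' Targets shared by a set of compounds
#'
#' Intersection of the selected compounds' target neighbourhoods: the
#' proteins every one of them is linked to. Shrinks monotonically as
#' compounds are added.
#'
#' @param network a `cti_network`.
#' @param compounds character vector of compound ids present in the network.
#' @return sorted character vector of common target ids.
#' @export
common_targets <- function(network, compounds) {
  stopifnot(inherits(network, "cti_network"))
  compounds <- unique(as.character(compounds))
  unknown <- setdiff(compounds, network$compounds$compound_id)
  if (length(unknown) > 0) {
    abort(sprintf("unknown compound id(s): %s", paste(unknown, collapse = ", ")),
          class = "herb_validation_error")
  }
  nbhd <- split(network$edges$target_id, network$edges$compound_id)
  sort(Reduce(intersect, nbhd[compounds]))
}

#' Fraction of network targets covered by a subset
#'
#' `|subset intersect targets| / |targets|`, e.g. the share of the network's
#' targets that belong to a pathway of interest.
#'
#' @param network a `cti_network`.
#' @param target_subset character vector of target ids.
#' @return a number in \[0, 1\] (report to 0.1% precision).
#' @export
coverage_fraction <- function(network, target_subset) {
  stopifnot(inherits(network, "cti_network"))
  tg <- network$targets$target_id
  if (length(tg) == 0) return(0)
  length(intersect(unique(as.character(target_subset)), tg)) / length(tg)
}

#' Export a CTI network for Cytoscape
#'
#' `"sif"` writes one `compound<TAB>cti<TAB>target` line per edge (the
#' interaction label is fixed to `"cti"`, direction compound to target).
#' `"graphml"` writes the bipartite graph via igraph with a `node_class`
#' attribute (`compound`/`target`) plus every annotation column; missing
#' annotations are exported as the string `"NA"`. Node annotations are also
#' available as a flat TSV via [write_node_attributes()].
#'
#' @param network a `cti_network`.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "graphml")) {
  stopifnot(inherits(network, "cti_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(
                       sprintf("unknown export format: %s", format[1]),
                       class = "herb_argument_error"))
  if (format == "sif") {
    readr::write_lines(
      sprintf("%s\tcti\t%s", network$edges$compound_id, network$edges$target_id),
      path)
    return(invisible(path))
  }
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a CTI network to an igraph bipartite graph
#'
#' @param network a `cti_network`.
#' @return an igraph object with vertex attributes `node_class`, `type`
#'   (logical bipartite flag, `TRUE` for targets) and all annotations.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "cti_network"))
  verts <- dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(network$compounds, name = "compound_id"),
                  node_class = "compound", type = FALSE),
    dplyr::mutate(dplyr::rename(network$targets, name = "target_id"),
                  node_class = "target", type = TRUE)
  )
  # GraphML has no NA notion; export missing annotations as the string "NA"
  for (col in setdiff(names(verts), c("name", "type"))) {
    v <- verts[[col]]
    if (!is.character(v)) v <- as.character(v)
    v[is.na(v)] <- "NA"
    verts[[col]] <- v
  }
  igraph::graph_from_data_frame(network$edges, directed = FALSE, vertices = verts)
}

#' Import a CTI network from an exported file
#'
#' Reads back [export_network()] output; the edge set round-trips exactly
#' for both formats (GraphML additionally restores node annotations).
#'
#' @param path file path.
#' @param format `"sif"` or `"graphml"`.
#' @return a `cti_network`.
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(
                       sprintf("unknown import format: %s", format[1]),
                       class = "herb_argument_error"))
  if (format == "sif") {
    lines <- readr::read_lines(path, progress = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3)) {
      abort("malformed SIF line (expected 3 tab-separated fields)",
            class = "herb_format_error")
    }
    edges <- tibble(compound_id = vapply(parts, `[`, character(1), 1),
                    target_id = vapply(parts, `[`, character(1), 3))
    return(build_cti(edges))
  }
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  cls <- setNames(va$node_class, va$name)
  edges <- tibble(
    compound_id = ifelse(cls[ed$from] == "compound", ed$from, ed$to),
    target_id = ifelse(cls[ed$from] == "compound", ed$to, ed$from)
  )
  ann <- as_tibble(va)
  comp_ann <- dplyr::rename(ann[ann$node_class == "compound",
                                setdiff(names(ann), c("node_class", "type")),
                                drop = FALSE], compound_id = "name")
  targ_ann <- dplyr::rename(ann[ann$node_class == "target",
                                setdiff(names(ann), c("node_class", "type")),
                                drop = FALSE], target_id = "name")
  build_cti(edges,
            compound_annotations = if (ncol(comp_ann) > 1) comp_ann else NULL,
            target_annotations = if (ncol(targ_ann) > 1) targ_ann else NULL)
}

#' Write node annotations as a flat TSV
#'
#' One row per node: `node_id`, `node_class`, then every annotation column
#' present on either node class (missing values as `NA`).
#'
#' @param network a `cti_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(network, path) {
  stopifnot(inherits(network, "cti_network"))
  nodes <- dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(network$compounds, node_id = "compound_id"),
                  node_class = "compound"),
    dplyr::mutate(dplyr::rename(network$targets, node_id = "target_id"),
                  node_class = "target")
  )
  readr::write_tsv(nodes, path, progress = FALSE)
  invisible(path)
}

#' @export
autoplot.cti_network <- function(object, ...) {
  deg <- dplyr::bind_rows(
    dplyr::count(object$edges, id = .data$compound_id) |>
      dplyr::mutate(node_class = "compound"),
    dplyr::count(object$edges, id = .data$target_id) |>
      dplyr::mutate(node_class = "target")
  )
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "#756bb1") +
    ggplot2::facet_wrap(~node_class, scales = "free") +
    ggplot2::labs(x = "degree", y = "nodes",
                  title = "CTI network degree distribution") +
    ggplot2::theme_minimal()
}
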