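#' Ordered protein expression levels
#'
#' Ordinal scale used by antibody-based tissue expression tables.
#' @export
expression_levels <- c("not_detected", "low", "medium", "high")

#' Read a tissue protein-expression table
#'
#' TSV with column `target_id` and one column per tissue / cell type; cells
#' are the ordinal levels of [expression_levels].
#'
#' @param path TSV file path.
#' @return a tibble with `target_id` and character tissue columns.
#' @export
read_expression_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  assert_columns(df, "target_id", "expression table")
  assert_unique_ids(df$target_id, "target_id")
  validate_expression_levels(df)
}

validate_expression_levels <- function(df) {
  for (col in setdiff(names(df), "target_id")) {
    bad <- setdiff(unique(df[[col]]), c(expression_levels, NA))
    if (length(bad) > 0) {
      abort(sprintf("expression column '%s' has non-level cells: %s",
                    col, paste(bad, collapse = ", ")),
            class = "herb_validation_error")
    }
  }
  df
}

#' Classify targets by keratinocyte / melanocyte expression
#'
#' Partitions a predicted target set by where each protein is detected. A
#' target counts as expressed in a tissue iff its level is at or above
#' `detected_threshold` on the ordinal scale
#' `not_detected < low < medium < high`. The five classes — `both`,
#' `keratinocyte_only`, `melanocyte_only`, `neither`, and `unmapped`
#' (absent from the table) — always partition the input set. The
#' skin-relevant retained set is `both` plus the two `_only` classes.
#'
#' @param targets character vector (or single-column data frame) of target
#'   ids to classify.
#' @param expression expression tibble (see [read_expression_table()]) with
#'   columns `keratinocyte` and `melanocyte`.
#' @param detected_threshold minimum level counted as expressed
#'   (default `"low"`; raising it can only shrink the retained set).
#' @return a `herb_tissue` tibble: `target_id`, `keratinocyte`,
#'   `melanocyte` (levels, `NA` when unmapped), `classification`, `retained`.
#' @export
classify_targets <- function(targets, expression,
                             detected_threshold = c("low", "medium", "high", "not_detected")) {
  detected_threshold <- match.arg(detected_threshold)
  if (is.data.frame(targets)) targets <- targets[[1]]
  targets <- unique(as.character(targets))
  assert_columns(expression, c("target_id", "keratinocyte", "melanocyte"),
                 "expression table")
  validate_expression_levels(expression)
  thr <- match(detected_threshold, expression_levels)
  lev <- function(x) match(x, expression_levels)

  out <- tibble(target_id = targets) |>
    dplyr::left_join(
      dplyr::select(expression, dplyr::all_of(c("target_id", "keratinocyte", "melanocyte"))),
      by = "target_id") |>
    dplyr::mutate(
      k_expr = !is.na(.data$keratinocyte) & lev(.data$keratinocyte) >= thr,
      m_expr = !is.na(.data$melanocyte) & lev(.data$melanocyte) >= thr,
      classification = dplyr::case_when(
        is.na(.data$keratinocyte) & is.na(.data$melanocyte) &
          !(.data$target_id %in% expression$target_id) ~ "unmapped",
        .data$k_expr & .data$m_expr ~ "both",
        .data$k_expr ~ "keratinocyte_only",
        .data$m_expr ~ "melanocyte_only",
        TRUE ~ "neither"
      ),
      retained = .data$classification %in% c("both", "keratinocyte_only", "melanocyte_only")
    ) |>
    dplyr::select(dplyr::all_of(c("target_id", "keratinocyte", "melanocyte",
                                  "classification", "retained")))
  n_unmapped <- sum(out$classification == "unmapped")
  if (n_unmapped > 0) {
    inform(sprintf("%d target(s) absent from the expression table (unmapped)",
                   n_unmapped))
  }
  class(out) <- c("herb_tissue", class(out))
  out
}

#' Partition sets from a tissue classification
#'
#' @param classification a `herb_tissue` tibble from [classify_targets()].
#' @return named list of character vectors: `both`, `keratinocyte_only`,
#'   `melanocyte_only`, `neither`, `unmapped`, plus `retained`.
#' @export
tissue_partition <- function(classification) {
  stopifnot(inherits(classification, "herb_tissue"))
  cls <- c("both", "keratinocyte_only", "melanocyte_only", "neither", "unmapped")
  sets <- lapply(cls, function(cl) {
    classification$target_id[classification$classification == cl]
  })
  names(sets) <- cls
  sets$retained <- classification$target_id[classification$retained]
  sets
}

#' @export
autoplot.herb_tissue <- function(object, ...) {
  counts <- dplyr::count(object, .data$classification)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$classification, y = .data$n)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = NULL, y = "targets",
                  title = "Tissue expression classification") +
    ggplot2::theme_minimal()
}
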