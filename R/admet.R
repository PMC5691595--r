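#' CYP450 isoforms scored by the metabolism ranking
#' @export
cyp_isoforms <- c("CYP1A2", "CYP2C9", "CYP2D6", "CYP2C19", "CYP3A4")

#' Default CYP inhibition-model accuracy weights
#'
#' Overall predictive accuracies Q of the binary inhibitor classifiers for
#' the five major CYP450 isoforms, used to weight the signed class
#' probabilities in [cyp_score()]. These are the published accuracies of the
#' admetSAR inhibition models (1A2 = 0.8147, 2C9 = 0.8018, 2D6 = 0.8551,
#' 2C19 = 0.8054, 3A4 = 0.6450).
#'
#' @return named numeric vector over [cyp_isoforms].
#' @export
default_cyp_weights <- function() {
  c(CYP1A2 = 0.8147, CYP2C9 = 0.8018, CYP2D6 = 0.8551,
    CYP2C19 = 0.8054, CYP3A4 = 0.6450)
}

#' Read CYP accuracy weights from YAML
#'
#' The YAML file maps each isoform name to its model accuracy Q in (0, 1].
#'
#' @param path YAML file path.
#' @return named numeric vector over the five isoforms.
#' @export
read_cyp_weights <- function(path) {
  w <- unlist(yaml::read_yaml(path))
  validate_cyp_weights(w)
}

validate_cyp_weights <- function(weights) {
  missing <- setdiff(cyp_isoforms, names(weights))
  if (length(missing) > 0) {
    abort(sprintf("missing isoform accuracy weight(s): %s",
                  paste(missing, collapse = ", ")),
          class = "herb_validation_error")
  }
  w <- as.numeric(weights[cyp_isoforms])
  names(w) <- cyp_isoforms
  if (any(!is.finite(w)) || any(w <= 0) || any(w > 1)) {
    abort("accuracy weights must lie in (0, 1]", class = "herb_validation_error")
  }
  w
}

# parse "+0.9218" / "-0.6993" / "−0.6993" (Unicode minus) / plain numeric
parse_signed <- function(x, what = "signed probability") {
  if (is.numeric(x)) {
    v <- x
  } else {
    s <- gsub("−", "-", trimws(as.character(x)))
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v) & !is.na(x))) {
      abort(sprintf("cannot parse %s value(s): %s", what,
                    paste(unique(x[is.na(v) & !is.na(x)]), collapse = ", ")),
            class = "herb_format_error")
    }
  }
  bad <- is.finite(v) & (abs(v) <= 0 | abs(v) > 1)
  if (any(bad)) {
    abort(sprintf("%s magnitudes must lie in (0, 1]; offending values: %s",
                  what, paste(unique(v[bad]), collapse = ", ")),
          class = "herb_validation_error")
  }
  v
}

#' Read an ADMET prediction table
#'
#' Tab-delimited table of signed class probabilities, one row per compound:
#' columns `compound_id`, `HIA`, `Caco2`, and the five isoforms of
#' [cyp_isoforms]. The sign encodes the predicted class (`+` = positive
#' absorption / CYP inhibitor, `-` = negative / non-inhibitor) and the
#' magnitude the class probability in (0, 1]. Both the ASCII hyphen and the
#' Unicode minus sign are accepted; a separate `<col>_class` / `<col>_prob`
#' two-column dialect is folded into the signed form.
#'
#' @param path TSV file path.
#' @return a tibble with `compound_id`, `hia`, `caco2`, and one signed
#'   numeric column per CYP isoform.
#' @export
read_admet_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  # fold the class/probability two-column dialect into signed values
  for (col in c("HIA", "Caco2", cyp_isoforms)) {
    cls <- paste0(col, "_class"); prb <- paste0(col, "_prob")
    if (!col %in% names(df) && all(c(cls, prb) %in% names(df))) {
      sgn <- ifelse(df[[cls]] %in% c("+", "1", "positive", "inhibitor"), 1, -1)
      df[[col]] <- sgn * as.numeric(df[[prb]])
      df[[cls]] <- NULL; df[[prb]] <- NULL
    }
  }
  assert_columns(df, c("compound_id", "HIA", "Caco2", cyp_isoforms), "ADMET table")
  assert_unique_ids(df$compound_id, "compound_id")
  out <- tibble(
    compound_id = df$compound_id,
    hia = parse_signed(df$HIA, "HIA"),
    caco2 = parse_signed(df$Caco2, "Caco-2")
  )
  for (iso in cyp_isoforms) out[[iso]] <- parse_signed(df[[iso]], iso)
  out
}

#' Filter compounds by predicted oral absorption
#'
#' Keeps exactly the records called positive by both the HIA and the Caco-2
#' models, i.e. rows with `hia > 0` and `caco2 > 0`. Only the class sign
#' gates; probability magnitudes are carried through for reporting. Row
#' order is preserved and the filter is idempotent.
#'
#' @param admet an ADMET tibble (see [read_admet_table()]).
#' @return the retained rows, same columns.
#' @export
absorption_filter <- function(admet) {
  assert_columns(admet, c("compound_id", "hia", "caco2"), "ADMET table")
  dplyr::filter(admet, .data$hia > 0, .data$caco2 > 0)
}

#' Accuracy-weighted signed CYP-inhibition score
#'
#' For each compound, sums the signed inhibition probability of every CYP
#' isoform weighted by that isoform's model accuracy Q:
#' \deqn{score = \sum_k result_k \, Q_k}
#' where \eqn{result_k} is the class-signed probability (+p for a predicted
#' inhibitor, -p for a predicted non-inhibitor). The score therefore rewards
#' confidently predicted inhibition of the major drug-metabolising CYPs and
#' is bounded by \eqn{\sum_k Q_k} in absolute value (3.9220 under the
#' default weights), with equality exactly when every probability is 1.
#'
#' @param admet ADMET tibble with the five isoform columns.
#' @param weights named accuracy vector (default [default_cyp_weights()]).
#' @return the input tibble with a `score` column appended.
#' @export
cyp_score <- function(admet, weights = default_cyp_weights()) {
  weights <- validate_cyp_weights(weights)
  assert_columns(admet, c("compound_id", cyp_isoforms), "ADMET table")
  score <- rep(0, nrow(admet))
  for (iso in cyp_isoforms) score <- score + admet[[iso]] * weights[[iso]]
  dplyr::mutate(admet, score = score)
}

#' Rank compounds by CYP score and keep the leads
#'
#' Scores every record with [cyp_score()], sorts by score descending with
#' ties broken by `compound_id` ascending, and truncates to the `top_n`
#' leads after the full ranking. The input is expected to be
#' absorption-filtered already (the ranking never re-filters; compose with
#' [absorption_filter()]).
#'
#' @param admet ADMET tibble.
#' @param weights named accuracy vector.
#' @param top_n number of leads to keep; `Inf` keeps all.
#' @return a `herb_ranking` tibble with `compound_id`, `score`, `rank`
#'   (dense over the full table before truncation).
#' @export
rank_compounds <- function(admet, weights = default_cyp_weights(), top_n = 5) {
  if (!is.numeric(top_n) || length(top_n) != 1 || is.na(top_n) || top_n < 1) {
    abort("`top_n` must be a positive number", class = "herb_argument_error")
  }
  scored <- cyp_score(admet, weights)
  ranked <- scored |>
    dplyr::arrange(dplyr::desc(.data$score), .data$compound_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(dplyr::all_of(c("compound_id", "score", "rank")))
  out <- head(ranked, n = if (is.finite(top_n)) top_n else nrow(ranked))
  class(out) <- c("herb_ranking", class(out))
  out
}

#' @export
autoplot.herb_ranking <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$compound_id, .data$score),
                               y = .data$score)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "accuracy-weighted CYP inhibition score",
                  title = "Lead compound ranking") +
    ggplot2::theme_minimal()
}
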