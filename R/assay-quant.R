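#' Read a qRT-PCR Ct table
#'
#' CSV with columns `sample_id`, `gene`, `condition` (`control`/`treated`),
#' `ct_target`, `ct_reference`. Ct values must lie in (0, 45], the cycle
#' range of a 45-cycle protocol.
#'
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_ct_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_ct_table(df)
}

validate_ct_table <- function(df) {
  assert_columns(df, c("sample_id", "gene", "condition", "ct_target", "ct_reference"),
                 "Ct table")
  bad_cond <- setdiff(unique(df$condition), c("control", "treated"))
  if (length(bad_cond) > 0) {
    abort(sprintf("condition must be control/treated; found: %s",
                  paste(bad_cond, collapse = ", ")),
          class = "herb_validation_error")
  }
  ct <- c(df$ct_target, df$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct > 45)) {
    abort("Ct values must lie in (0, 45]", class = "herb_validation_error")
  }
  as_tibble(df)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per gene: normalises each well's target Ct by its reference-gene Ct
#' (dCt = ct_target - ct_reference), averages dCt within each condition,
#' takes ddCt = mean dCt(treated) - mean dCt(control), and reports the fold
#' change 2^-ddCt (treated relative to control). Per-replicate fold changes
#' (each treated well against the mean control dCt) are attached for
#' dispersion reporting.
#'
#' @param ct a Ct tibble (see [read_ct_table()]) containing both conditions
#'   for every gene.
#' @return a tibble, one row per gene: `gene`, `dct_control`, `dct_treated`,
#'   `ddct`, `fold_change`, with per-replicate folds in attribute
#'   `"replicates"`.
#' @export
ddct_fold_change <- function(ct) {
  ct <- validate_ct_table(ct)
  have <- ct |>
    dplyr::distinct(.data$gene, .data$condition) |>
    dplyr::count(.data$gene)
  incomplete <- have$gene[have$n < 2]
  if (length(incomplete) > 0) {
    abort(sprintf("gene(s) missing a condition: %s",
                  paste(incomplete, collapse = ", ")),
          class = "herb_validation_error")
  }
  dct <- dplyr::mutate(ct, dct = .data$ct_target - .data$ct_reference)
  means <- dct |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(dct = mean(.data$dct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "dct",
                       names_prefix = "dct_")
  out <- means |>
    dplyr::mutate(ddct = .data$dct_treated - .data$dct_control,
                  fold_change = 2^(-.data$ddct)) |>
    dplyr::arrange(.data$gene)
  reps <- dct |>
    dplyr::filter(.data$condition == "treated") |>
    dplyr::left_join(dplyr::select(means, dplyr::all_of(c("gene", "dct_control"))),
                     by = "gene") |>
    dplyr::mutate(fold_change = 2^(-(.data$dct - .data$dct_control))) |>
    dplyr::select(dplyr::all_of(c("sample_id", "gene", "fold_change")))
  attr(out, "replicates") <- reps
  out
}
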