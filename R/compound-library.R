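#' Compound structural classes
#'
#' Classes used to annotate herbal constituents. Purely descriptive metadata:
#' nothing downstream computes on them, they only decorate network exports.
#' @export
structural_classes <- c("steroid", "terpene", "flavonoid", "fatty_acid", "other")

#' Read a compound library from CSV
#'
#' Loads a compound library with one row per herbal constituent. The file must
#' be comma-delimited with a header containing at least `compound_id` and
#' `smiles`; `name` and `structural_class` are optional metadata and are
#' filled with `NA` when absent. SMILES strings are normalised on load (see
#' [normalize_smiles()]); records whose SMILES cannot be parsed are kept and
#' flagged rather than dropped.
#'
#' @param path path to a CSV file.
#' @param backend SMILES canonicalisation backend passed to
#'   [normalize_smiles()]: `"chemistry"` (use ChemmineR/OpenBabel when
#'   installed, fall back with a warning otherwise) or `"none"`
#'   (whitespace-trim only).
#' @return a tibble with columns `compound_id`, `name`, `smiles`
#'   (canonicalised), `smiles_raw`, `structural_class`,
#'   `normalization_failed`.
#' @export
read_compound_library <- function(path, backend = c("chemistry", "none")) {
  backend <- match.arg(backend)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  assert_columns(df, c("compound_id", "smiles"), what = "compound library")
  assert_unique_ids(df$compound_id, "compound_id")
  if (nrow(df) > 0 && any(is.na(df$smiles) | !nzchar(df$smiles))) {
    abort("compound library contains empty SMILES", class = "herb_validation_error")
  }
  if (!"name" %in% names(df)) df$name <- NA_character_
  if (!"structural_class" %in% names(df)) df$structural_class <- NA_character_
  bad_class <- setdiff(unique(df$structural_class[!is.na(df$structural_class)]),
                       structural_classes)
  if (length(bad_class) > 0) {
    warn(sprintf("unknown structural_class value(s) kept as-is: %s",
                 paste(bad_class, collapse = ", ")))
  }
  norm <- normalize_smiles(df$smiles, backend = backend)
  tibble(
    compound_id = df$compound_id,
    name = df$name,
    smiles = norm$smiles,
    smiles_raw = df$smiles,
    structural_class = df$structural_class,
    normalization_failed = norm$failed
  )
}

#' Write a compound library to CSV
#'
#' Inverse of [read_compound_library()]: writes `compound_id`, `name`,
#' `smiles`, `structural_class` so that a read/write round trip reproduces
#' the table up to column order.
#'
#' @param library a compound library tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compound_library <- function(library, path) {
  assert_columns(library, c("compound_id", "smiles"), "compound library")
  out <- tibble(
    compound_id = library$compound_id,
    name = library$name %||% NA_character_,
    smiles = library$smiles,
    structural_class = library$structural_class %||% NA_character_
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

chemistry_available <- function() {
  requireNamespace("ChemmineR", quietly = TRUE) &&
    requireNamespace("ChemmineOB", quietly = TRUE)
}

#' Canonicalise SMILES strings
#'
#' Maps each SMILES to a canonical form so that alternative encodings of the
#' same molecule (e.g. Kekule vs aromatic benzene) collapse to one string.
#' With the `"chemistry"` backend the OpenBabel canonicaliser is used (via
#' ChemmineOB); when that backend is not installed, or with
#' `backend = "none"`, strings are whitespace-trimmed and passed through
#' unchanged, with a one-time warning. Unparseable SMILES are never an error:
#' the original string is preserved and the record flagged.
#'
#' Canonicalisation is idempotent: `normalize_smiles(normalize_smiles(s))`
#' equals `normalize_smiles(s)` element-wise.
#'
#' @param smiles character vector of SMILES strings (non-empty).
#' @param backend `"chemistry"` or `"none"`.
#' @return a tibble with columns `smiles` (canonical or original) and
#'   `failed` (logical: canonicalisation failed, original preserved).
#' @export
normalize_smiles <- function(smiles, backend = c("chemistry", "none")) {
  backend <- match.arg(backend)
  stopifnot(is.character(smiles))
  smiles <- trimws(smiles)
  if (length(smiles) == 0) {
    return(tibble(smiles = character(), failed = logical()))
  }
  if (any(!nzchar(smiles))) {
    abort("empty SMILES string", class = "herb_validation_error")
  }
  if (backend == "chemistry" && !chemistry_available()) {
    warn("chemistry backend not installed; SMILES passed through untouched")
    backend <- "none"
  }
  if (backend == "none") {
    return(tibble(smiles = smiles, failed = FALSE))
  }
  out <- vapply(smiles, function(s) {
    res <- tryCatch(
      trimws(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
      error = function(e) NA_character_
    )
    if (is.na(res) || !nzchar(res)) NA_character_ else res
  }, character(1), USE.NAMES = FALSE)
  failed <- is.na(out)
  if (any(failed)) {
    warn(sprintf("%d SMILES could not be canonicalised; originals kept and flagged",
                 sum(failed)))
  }
  tibble(smiles = ifelse(failed, smiles, out), failed = failed)
}

#' Fingerprint a compound library
#'
#' Produces the binary substructure-presence matrix that seeds target
#' diffusion. Two backends are supported: a named SMARTS dictionary
#' (each key is matched against each compound's SMILES with a chemistry
#' toolkit), or a precomputed matrix file/tibble that is merely validated and
#' reindexed to the library. Substructure columns that match no compound are
#' dropped with a warning, so the returned matrix never carries an all-zero
#' column.
#'
#' @param library compound library tibble (from [read_compound_library()] or
#'   built in code) with `compound_id` and `smiles`.
#' @param smarts named character vector of SMARTS patterns, or `NULL`.
#' @param matrix precomputed fingerprint tibble (first column `compound_id`,
#'   remaining columns 0/1) or a path to such a TSV, or `NULL`. Exactly one
#'   of `smarts`/`matrix` must be given.
#' @param drop_empty_substructures drop all-zero columns (default `TRUE`).
#' @return a fingerprint tibble: `compound_id` plus one 0/1 integer column
#'   per substructure key.
#' @export
fingerprint_library <- function(library, smarts = NULL, matrix = NULL,
                                drop_empty_substructures = TRUE) {
  assert_columns(library, "compound_id", "compound library")
  if (is.null(smarts) == is.null(matrix)) {
    abort("supply exactly one fingerprint backend: `smarts` or `matrix`")
  }
  if (!is.null(matrix)) {
    fp <- if (is.character(matrix)) read_fingerprint_matrix(matrix) else as_tibble(matrix)
    assert_columns(fp, "compound_id", "fingerprint matrix")
    missing <- setdiff(library$compound_id, fp$compound_id)
    if (length(missing) > 0) {
      abort(sprintf("compound(s) absent from fingerprint matrix: %s",
                    paste(missing, collapse = ", ")),
            class = "herb_validation_error")
    }
    fp <- fp[match(library$compound_id, fp$compound_id), , drop = FALSE]
  } else {
    assert_columns(library, "smiles", "compound library")
    if (is.null(names(smarts)) || any(!nzchar(names(smarts)))) {
      abort("`smarts` must be a named character vector of SMARTS patterns")
    }
    if (!chemistry_available()) {
      abort("SMARTS fingerprinting requires the ChemmineR/ChemmineOB backend")
    }
    hits <- vapply(seq_len(nrow(library)), function(i) {
      smarts_match_one(library$smiles[i], smarts)
    }, integer(length(smarts)))
    m <- if (length(smarts) == 1) matrix(hits, nrow = nrow(library)) else t(hits)
    colnames(m) <- names(smarts)
    fp <- dplyr::bind_cols(tibble(compound_id = library$compound_id), as_tibble(m))
  }
  validate_fingerprint_matrix(fp, drop_empty = drop_empty_substructures)
}

# 0/1 hit vector of one SMILES against a SMARTS dictionary; molecules the
# toolkit cannot round-trip (e.g. single-atom SDF) count as all-zero
smarts_match_one <- function(smiles, smarts) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, "q"))),
                  error = function(e) NULL)
  ok <- !is.null(sdf) && tryCatch(any(ChemmineR::validSDF(sdf)),
                                  error = function(e) FALSE)
  vapply(unname(smarts), function(pat) {
    if (!ok) return(0L)
    n <- tryCatch(ChemmineR::smartsSearchOB(sdf, pat, uniqueMatches = TRUE),
                  error = function(e) 0)
    as.integer(sum(n) > 0)
  }, integer(1))
}

validate_fingerprint_matrix <- function(fp, drop_empty = TRUE) {
  assert_columns(fp, "compound_id", "fingerprint matrix")
  assert_unique_ids(fp$compound_id, "compound_id")
  keys <- setdiff(names(fp), "compound_id")
  for (k in keys) {
    v <- fp[[k]]
    if (!all(v %in% c(0, 1))) {
      abort(sprintf("fingerprint column '%s' has non-binary cells", k),
            class = "herb_validation_error")
    }
    fp[[k]] <- as.integer(v)
  }
  if (drop_empty && length(keys) > 0) {
    zero <- keys[vapply(keys, function(k) sum(fp[[k]]) == 0, logical(1))]
    if (length(zero) > 0) {
      warn(sprintf("dropping %d all-zero substructure column(s): %s",
                   length(zero), paste(zero, collapse = ", ")))
      fp <- fp[, c("compound_id", setdiff(keys, zero)), drop = FALSE]
    }
  }
  as_tibble(fp)
}

#' Read / write a fingerprint matrix TSV
#'
#' Tab-delimited interchange: first column `compound_id`, remaining columns
#' substructure keys with 0/1 cells.
#'
#' @param path file path.
#' @return [read_fingerprint_matrix()]: a fingerprint tibble (all-zero
#'   columns kept; validation happens in [fingerprint_library()]).
#' @export
read_fingerprint_matrix <- function(path) {
  fp <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(fp, "compound_id", "fingerprint matrix")
  fp$compound_id <- as.character(fp$compound_id)
  fp
}

#' @rdname read_fingerprint_matrix
#' @param fp fingerprint tibble.
#' @export
write_fingerprint_matrix <- function(fp, path) {
  readr::write_tsv(fp, path, progress = FALSE)
  invisible(path)
}
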