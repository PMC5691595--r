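#' Build a substructure-drug-target network
#'
#' Assembles the tripartite graph over which target diffusion runs: known
#' drug-target interaction (DTI) edges plus substructure-drug edges derived
#' from a binary fingerprint matrix of the known drugs. Query compounds are
#' deliberately *not* nodes: new chemical entities inject mass through the
#' substructures they carry (see [diffuse()]).
#'
#' Duplicated DTI edges are collapsed (with a message giving the count);
#' drugs whose fingerprint row is all zeros are kept but warned about (they
#' can never receive diffused mass); drugs that carry substructures but have
#' no targets are flagged as dangling (mass reaching them leaks). Node
#' identifiers must be disjoint across the three classes.
#'
#' @param dti tibble or data frame with columns `drug_id`, `target_id`, or a
#'   path to such a TSV.
#' @param fingerprints fingerprint tibble (`compound_id` + 0/1 substructure
#'   columns) covering every drug in `dti`, or a path to a fingerprint TSV.
#' @return an `sdt_network` object.
#' @export
build_sdt_network <- function(dti, fingerprints) {
  if (is.character(dti)) dti <- read_dti(dti)
  if (is.character(fingerprints)) fingerprints <- read_fingerprint_matrix(fingerprints)
  dti <- as_tibble(dti)
  assert_columns(dti, c("drug_id", "target_id"), "DTI edge list")
  if (nrow(dti) == 0) {
    abort("DTI edge list is empty", class = "herb_validation_error")
  }
  dti <- dplyr::mutate(dti, drug_id = as.character(.data$drug_id),
                       target_id = as.character(.data$target_id))
  n_raw <- nrow(dti)
  dti <- dplyr::distinct(dti, .data$drug_id, .data$target_id)
  if (nrow(dti) < n_raw) {
    inform(sprintf("deduplicated %d repeated DTI edge(s)", n_raw - nrow(dti)))
  }
  if (any(dti$drug_id == dti$target_id)) {
    abort("self-loop: a drug_id equals its target_id", class = "herb_validation_error")
  }
  fp <- as_tibble(fingerprints)
  assert_columns(fp, "compound_id", "fingerprint matrix")
  missing <- setdiff(unique(dti$drug_id), fp$compound_id)
  if (length(missing) > 0) {
    abort(sprintf("drug(s) in DTI absent from fingerprints: %s",
                  paste(missing, collapse = ", ")),
          class = "herb_validation_error")
  }
  keys <- setdiff(names(fp), "compound_id")
  zero_fp <- fp$compound_id[rowSums(as.matrix(fp[keys])) == 0]
  zero_fp <- intersect(zero_fp, dti$drug_id)
  if (length(zero_fp) > 0) {
    warn(sprintf("drug(s) with all-zero fingerprint kept: %s",
                 paste(zero_fp, collapse = ", ")))
  }
  sub_drug <- fp |>
    tidyr::pivot_longer(dplyr::all_of(keys), names_to = "substructure",
                        values_to = "present") |>
    dplyr::filter(.data$present == 1) |>
    dplyr::select(substructure = "substructure", drug_id = "compound_id")
  new_sdt_network(sub_drug, dti)
}

# internal constructor: precomputes adjacency lists + degrees; `quiet` skips
# the dangling-drug message during cross-validation fold rebuilds
new_sdt_network <- function(sub_drug, drug_target, quiet = FALSE) {
  subs <- unique(sub_drug$substructure)
  drugs <- unique(c(sub_drug$drug_id, drug_target$drug_id))
  targets <- unique(drug_target$target_id)
  clash <- c(intersect(subs, drugs), intersect(subs, targets),
             intersect(drugs, targets))
  if (length(clash) > 0) {
    abort(sprintf("node ids shared across classes: %s",
                  paste(unique(clash), collapse = ", ")),
          class = "herb_validation_error")
  }
  drugs_by_sub <- split(sub_drug$drug_id, sub_drug$substructure)
  targets_by_drug <- split(drug_target$target_id, drug_target$drug_id)
  subs_by_drug <- split(sub_drug$substructure, sub_drug$drug_id)
  drug_out_degree <- setNames(integer(length(drugs)), drugs)
  deg <- lengths(targets_by_drug)
  drug_out_degree[names(deg)] <- deg
  target_in_degree <- table(drug_target$target_id)
  dangling <- names(drug_out_degree)[drug_out_degree == 0]
  if (length(dangling) > 0 && !quiet) {
    inform(sprintf("%d dangling drug(s) without targets (mass reaching them leaks): %s",
                   length(dangling), paste(dangling, collapse = ", ")))
  }
  structure(
    list(
      sub_drug = as_tibble(sub_drug),
      drug_target = as_tibble(drug_target),
      drugs_by_sub = drugs_by_sub,
      targets_by_drug = targets_by_drug,
      subs_by_drug = subs_by_drug,
      drug_out_degree = drug_out_degree,
      target_in_degree = setNames(as.integer(target_in_degree),
                                  names(target_in_degree)),
      substructures = subs, drugs = drugs, targets = targets,
      dangling_drugs = dangling
    ),
    class = "sdt_network"
  )
}

#' Read a drug-target interaction edge list TSV
#'
#' @param path TSV with header columns `drug_id`, `target_id`.
#' @return a tibble of character edges.
#' @export
read_dti <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  assert_columns(df, c("drug_id", "target_id"), "DTI edge list")
  df
}

#' @export
print.sdt_network <- function(x, ...) {
  cat(sprintf(
    "<sdt_network> %d substructures, %d drugs (%d dangling), %d targets; %d S-D edges, %d D-T edges\n",
    length(x$substructures), length(x$drugs), length(x$dangling_drugs),
    length(x$targets), nrow(x$sub_drug), nrow(x$drug_target)))
  invisible(x)
}

#' @export
glance.sdt_network <- function(x, ...) {
  tibble(n_substructures = length(x$substructures), n_drugs = length(x$drugs),
         n_targets = length(x$targets), n_sub_drug_edges = nrow(x$sub_drug),
         n_drug_target_edges = nrow(x$drug_target),
         n_dangling_drugs = length(x$dangling_drugs))
}

#' Diffuse unit resource from a query's substructures to targets
#'
#' Three-hop degree-normalised resource allocation. A unit of mass is split
#' equally over the query's substructures that exist in the network; each
#' substructure splits its mass equally over the drugs that carry it; each
#' drug splits its mass over its known targets (equally when `alpha = 0`,
#' proportionally to in-degree^`alpha` otherwise). Mass that reaches a drug
#' with no targets is accounted in `leaked_mass`, never renormalised:
#' renormalisation would silently inflate the scores of reached targets.
#' Total resource plus leaked mass always equals 1 (to machine precision).
#'
#' Query substructures absent from the network are dropped with a warning
#' before the initial split; a query with no in-network substructure returns
#' an empty resource table with `leaked_mass = 1`.
#'
#' @param network an `sdt_network`.
#' @param query_substructures character vector of substructure keys carried
#'   by the query compound.
#' @param alpha neighbour-degree exponent for the drug-to-target hop
#'   (default 0 = canonical equal split; any value conserves mass).
#' @return an `sdt_diffusion` object: list with `resource` (tibble
#'   `target_id`, `resource`), `leaked_mass`, and `dropped` (query keys not
#'   in the network).
#' @export
diffuse <- function(network, query_substructures, alpha = 0) {
  stopifnot(inherits(network, "sdt_network"))
  qs <- unique(as.character(query_substructures))
  present <- qs[qs %in% names(network$drugs_by_sub)]
  dropped <- setdiff(qs, present)
  if (length(dropped) > 0) {
    warn(sprintf("query substructure(s) not in network dropped: %s",
                 paste(dropped, collapse = ", ")))
  }
  empty <- structure(
    list(resource = tibble(target_id = character(), resource = numeric()),
         leaked_mass = 1, dropped = dropped),
    class = "sdt_diffusion")
  if (length(present) == 0) return(empty)

  # hop 1+2: substructure mass -> drug mass
  dl <- network$drugs_by_sub[present]
  per_sub <- 1 / length(present)
  d_ids <- unlist(dl, use.names = FALSE)
  d_w <- rep(per_sub / lengths(dl), lengths(dl))
  drug_mass <- rowsum(d_w, d_ids)
  dm <- drug_mass[, 1]
  names(dm) <- rownames(drug_mass)

  # hop 3: drug mass -> target resource; dangling drugs leak
  deg <- network$drug_out_degree[names(dm)]
  leaked <- sum(dm[deg == 0])
  live <- names(dm)[deg > 0]
  if (length(live) == 0) {
    empty$leaked_mass <- 1
    return(empty)
  }
  tl <- network$targets_by_drug[live]
  if (alpha == 0) {
    t_w <- rep(dm[live] / lengths(tl), lengths(tl))
    t_ids <- unlist(tl, use.names = FALSE)
  } else {
    t_ids <- unlist(tl, use.names = FALSE)
    w_raw <- as.numeric(network$target_in_degree[t_ids])^alpha
    grp <- rep(seq_along(tl), lengths(tl))
    denom <- rowsum(w_raw, grp)[, 1]
    t_w <- rep(dm[live], lengths(tl)) * w_raw / denom[grp]
  }
  res <- rowsum(t_w, t_ids)
  structure(
    list(resource = tibble(target_id = rownames(res), resource = res[, 1]),
         leaked_mass = leaked, dropped = dropped),
    class = "sdt_diffusion")
}

#' @export
print.sdt_diffusion <- function(x, ...) {
  cat(sprintf("<sdt_diffusion> %d targets reached, leaked mass %.4g\n",
              nrow(x$resource), x$leaked_mass))
  invisible(x)
}

#' @export
tidy.sdt_diffusion <- function(x, ...) {
  dplyr::arrange(x$resource, dplyr::desc(.data$resource), .data$target_id)
}

#' Rank predicted targets for a query compound
#'
#' Runs [diffuse()] and returns the targets sorted by received resource
#' (descending; ties broken by `target_id` ascending), truncated to the top
#' `k`. The default `k = 20` stores the top 20 predictions as the putative
#' target set of the compound.
#'
#' @inheritParams diffuse
#' @param k cutoff (positive integer).
#' @return tibble `rank`, `target_id`, `score` (length at most `k`), with
#'   the leaked mass in attribute `"leaked_mass"`.
#' @export
predict_targets <- function(network, query_substructures, k = 20, alpha = 0) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    abort("`k` must be a positive integer", class = "herb_argument_error")
  }
  d <- diffuse(network, query_substructures, alpha = alpha)
  out <- d$resource |>
    dplyr::arrange(dplyr::desc(.data$resource), .data$target_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(rank = "rank", target_id = "target_id", score = "resource") |>
    head(n = k)
  attr(out, "leaked_mass") <- d$leaked_mass
  out
}

#' Predict targets for a batch of query compounds
#'
#' Applies [predict_targets()] to every row of a query fingerprint matrix.
#'
#' @param network an `sdt_network`.
#' @param query_fp fingerprint tibble of the queries (`compound_id` + 0/1
#'   substructure columns).
#' @inheritParams predict_targets
#' @return tibble `query_id`, `rank`, `target_id`, `score`.
#' @export
predict_targets_all <- function(network, query_fp, k = 20, alpha = 0) {
  assert_columns(query_fp, "compound_id", "query fingerprints")
  keys <- setdiff(names(query_fp), "compound_id")
  purrr::map_dfr(seq_len(nrow(query_fp)), function(i) {
    qs <- keys[query_fp[i, keys] == 1]
    pt <- predict_targets(network, qs, k = k, alpha = alpha)
    dplyr::bind_cols(tibble(query_id = query_fp$compound_id[i]), pt)
  })
}

#' Cross-validate target prediction on the known DTI edges
#'
#' Estimates ranking performance by hiding drug-target edges and asking the
#' diffusion to recover them. Edges are partitioned into folds (10-fold by
#' default, or leave-one-out); for each fold the network is rebuilt without
#' the held-out edges, every held-out drug is treated as a query through its
#' own substructures, and each held-out positive target is compared against
#' `n_negatives` non-targets of that drug sampled uniformly (targets not
#' linked to the drug anywhere in the full network; unreached targets score
#' 0). The per-positive AUC is the fraction of comparisons the positive
#' wins, counting ties as half; fold AUC averages over its positives.
#'
#' @param network an `sdt_network` with at least as many DTI edges as folds.
#' @param scheme `"kfold"` (default, 10 folds) or `"loo"`.
#' @param k_folds number of folds for `"kfold"`.
#' @param n_negatives sampled non-edges per held-out positive.
#' @param seed integer seed making folds and negative samples reproducible.
#' @param alpha passed to [diffuse()].
#' @return an `sdt_cv` object; `tidy()` gives per-fold AUCs, `glance()` the
#'   mean AUC.
#' @export
cross_validate <- function(network, scheme = c("kfold", "loo"), k_folds = 10,
                           n_negatives = 10, seed = 1, alpha = 0) {
  scheme <- match.arg(scheme)
  edges <- network$drug_target
  n_edges <- nrow(edges)
  n_folds <- if (scheme == "loo") n_edges else k_folds
  if (n_edges < n_folds) {
    abort(sprintf("need at least %d DTI edges for %s cross-validation, have %d",
                  n_folds, scheme, n_edges),
          class = "herb_validation_error")
  }
  all_targets <- network$targets
  targets_of <- network$targets_by_drug # full-network positives per drug

  fold_of <- with_seed(derive_seed(seed, 1L), {
    sample(rep_len(seq_len(n_folds), n_edges))
  })
  fold_auc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    held <- edges[fold_of == f, , drop = FALSE]
    kept <- edges[fold_of != f, , drop = FALSE]
    net_f <- new_sdt_network(network$sub_drug, kept, quiet = TRUE)
    aucs <- numeric(nrow(held))
    # one diffusion per distinct held-out drug in the fold
    for (d in unique(held$drug_id)) {
      qs <- network$subs_by_drug[[d]] %||% character()
      scores <- if (length(qs) > 0) {
        r <- suppressWarnings(diffuse(net_f, qs, alpha = alpha))
        setNames(r$resource$resource, r$resource$target_id)
      } else {
        setNames(numeric(0), character(0))
      }
      score_of <- function(t) if (t %in% names(scores)) scores[[t]] else 0
      negatives_pool <- setdiff(all_targets, targets_of[[d]])
      rows <- which(held$drug_id == d)
      for (j in rows) {
        pos <- score_of(held$target_id[j])
        negs <- with_seed(derive_seed(seed, 7L * f + 131L * j), {
          sample(negatives_pool, size = min(n_negatives, length(negatives_pool)),
                 replace = length(negatives_pool) < n_negatives)
        })
        neg_scores <- vapply(negs, score_of, numeric(1))
        aucs[j] <- mean((pos > neg_scores) + 0.5 * (pos == neg_scores))
      }
    }
    fold_auc[f] <- mean(aucs)
  }
  structure(
    list(folds = tibble(fold = seq_len(n_folds), auc = fold_auc,
                        n_held_out = as.integer(table(factor(fold_of, seq_len(n_folds))))),
         mean_auc = mean(fold_auc), scheme = scheme, seed = seed,
         n_edges = n_edges, n_negatives = n_negatives),
    class = "sdt_cv")
}

#' @export
print.sdt_cv <- function(x, ...) {
  cat(sprintf("<sdt_cv> %s over %d edges: mean AUC = %.4f\n",
              x$scheme, x$n_edges, x$mean_auc))
  invisible(x)
}

#' @export
tidy.sdt_cv <- function(x, ...) x$folds

#' @export
glance.sdt_cv <- function(x, ...) {
  tibble(mean_auc = x$mean_auc, scheme = x$scheme, n_folds = nrow(x$folds),
         n_edges = x$n_edges, n_negatives = x$n_negatives, seed = x$seed)
}

#' @export
autoplot.sdt_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds, ggplot2::aes(x = .data$fold, y = .data$auc)) +
    ggplot2::geom_point(size = 2, colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = object$mean_auc, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0.5, colour = "grey60") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "fold", y = "AUC",
                  title = sprintf("%s cross-validation (mean AUC %.3f)",
                                  object$scheme, object$mean_auc)) +
    ggplot2::theme_minimal()
}
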