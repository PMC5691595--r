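#' Configuration for the synthetic-data generators
#'
#' One configuration object drives every generator, so a whole study's worth
#' of inputs is a pure function of the seed. Defaults mirror the screening
#' study the pipeline emulates: a 48-compound herbal library split
#' 18/13/11/3/3 over steroids, terpenes, flavonoids, fatty acids and others,
#' of which exactly 37 pass the double-positive absorption gate; a DTI
#' training network in which substructure sharing carries target signal
#' (each planted substructure-target association is obeyed with probability
#' `strength`); a two-tissue expression table; and gene-set collections with
#' one planted enriched set.
#'
#' @param seed integer master seed.
#' @param n_compounds library size.
#' @param class_mix named integer vector over [structural_classes] summing
#'   to `n_compounds`.
#' @param admet_pass_count how many compounds are HIA- and Caco-2-positive.
#' @param n_drugs,n_targets,n_substructures DTI network dimensions.
#' @param n_planted number of substructure-target associations planted
#'   (capped at `min(n_substructures, n_targets)`).
#' @param strength probability that a drug carrying a planted substructure
#'   has the associated target.
#' @param sub_carry_prob probability a drug (or extra query) carries any
#'   given substructure.
#' @param random_edge_prob background probability of a random drug-target
#'   edge.
#' @param n_queries number of seeded query compounds.
#' @param detection_rate named vector: probability a target is detected in
#'   `keratinocyte` / `melanocyte`.
#' @param n_gene_sets,gene_set_size gene-set collection shape.
#' @param planted_fraction fraction of the planted set drawn from the
#'   designated query set.
#' @param enriched_set_name name of the planted enriched set.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_compounds = 48,
                         class_mix = c(steroid = 18, terpene = 13, flavonoid = 11,
                                       fatty_acid = 3, other = 3),
                         admet_pass_count = 37,
                         n_drugs = 100, n_targets = 20, n_substructures = 30,
                         n_planted = 15, strength = 0.95,
                         sub_carry_prob = 0.08, random_edge_prob = 0.005,
                         n_queries = 20,
                         detection_rate = c(keratinocyte = 0.8, melanocyte = 0.75),
                         n_gene_sets = 10, gene_set_size = 20,
                         planted_fraction = 0.9,
                         enriched_set_name = "planted_pathway") {
  cfg <- list(seed = as.integer(seed), n_compounds = n_compounds,
              class_mix = class_mix, admet_pass_count = admet_pass_count,
              n_drugs = n_drugs, n_targets = n_targets,
              n_substructures = n_substructures,
              n_planted = min(n_planted, n_substructures, n_targets),
              strength = strength, sub_carry_prob = sub_carry_prob,
              random_edge_prob = random_edge_prob, n_queries = n_queries,
              detection_rate = detection_rate, n_gene_sets = n_gene_sets,
              gene_set_size = gene_set_size,
              planted_fraction = planted_fraction,
              enriched_set_name = enriched_set_name)
  stopifnot(cfg$n_compounds > 0, cfg$admet_pass_count <= cfg$n_compounds,
            cfg$admet_pass_count >= 0, sum(class_mix) == n_compounds,
            cfg$strength >= 0, cfg$strength <= 1)
  structure(cfg, class = "synth_config")
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, max(2, nchar(n)), seq_len(n))

#' Generate a synthetic compound library
#'
#' Compounds get simple valid aliphatic SMILES (chains of carbons with an
#' optional hydroxyl) so any canonicaliser accepts them; structural classes
#' follow the configured mix. Real chemistry is out of scope for fixtures.
#'
#' @param config a [synth_config()].
#' @return a compound library tibble (`compound_id`, `name`, `smiles`,
#'   `structural_class`).
#' @export
gen_compound_library <- function(config = synth_config()) {
  with_seed(derive_seed(config$seed, 11L), {
    n <- config$n_compounds
    classes <- sample(rep(names(config$class_mix), config$class_mix))
    len <- sample(1:9, n, replace = TRUE)
    oh <- sample(c("", "O"), n, replace = TRUE)
    tibble(
      compound_id = pad_ids("C", n),
      name = sprintf("compound_%02d", seq_len(n)),
      smiles = paste0(strrep("C", len), oh),
      structural_class = classes
    )
  })
}

#' Generate a synthetic ADMET prediction table
#'
#' Emits signed class probabilities in the admetSAR style: magnitudes drawn
#' uniformly from (0.5, 1]; exactly `admet_pass_count` compounds are
#' positive on both HIA and Caco-2 (the remainder are negative on at least
#' one, chosen at random); CYP inhibitor calls get a random sign per
#' isoform. The ground-truth pass list is returned alongside so tests never
#' re-derive it from the generator's internals.
#'
#' @param config a [synth_config()].
#' @return list with `admet` (tibble in [read_admet_table()] layout) and
#'   `truth` (tibble `compound_id`, `passes_absorption`).
#' @export
gen_admet_table <- function(config = synth_config()) {
  with_seed(derive_seed(config$seed, 23L), {
    n <- config$n_compounds
    ids <- pad_ids("C", n)
    pass <- sort(sample(n, config$admet_pass_count))
    mag <- function() runif(n, 0.5, 1)
    hia_sign <- rep(1, n); caco_sign <- rep(1, n)
    for (i in setdiff(seq_len(n), pass)) {
      which_neg <- sample(3, 1) # 1 = HIA, 2 = Caco-2, 3 = both
      if (which_neg != 2) hia_sign[i] <- -1
      if (which_neg != 1) caco_sign[i] <- -1
    }
    admet <- tibble(compound_id = ids,
                    hia = hia_sign * mag(), caco2 = caco_sign * mag())
    for (iso in cyp_isoforms) {
      admet[[iso]] <- sample(c(-1, 1), n, replace = TRUE) * mag()
    }
    list(admet = admet,
         truth = tibble(compound_id = ids,
                        passes_absorption = seq_len(n) %in% pass))
  })
}

#' Write an ADMET table in the signed TSV dialect
#'
#' @param admet tibble as returned in `gen_admet_table()$admet` or by
#'   [read_admet_table()].
#' @param path output TSV path.
#' @param digits decimal places for the signed cells.
#' @return `path`, invisibly.
#' @export
write_admet_table <- function(admet, path, digits = 4) {
  assert_columns(admet, c("compound_id", "hia", "caco2", cyp_isoforms),
                 "ADMET table")
  fmt <- function(x) sprintf(paste0("%+.", digits, "f"), x)
  out <- tibble(compound_id = admet$compound_id,
                HIA = fmt(admet$hia), Caco2 = fmt(admet$caco2))
  for (iso in cyp_isoforms) out[[iso]] <- fmt(admet[[iso]])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Generate a DTI network with planted substructure-target signal
#'
#' Emulates the statistical structure the diffusion method assumes: drugs
#' that share substructures tend to share targets. Each drug receives a
#' random substructure profile (every key carried independently with
#' probability `sub_carry_prob`; an empty profile is patched with one random
#' key). `n_planted` substructure-target pairs are planted: a drug carrying
#' planted substructure i gains target i with probability `strength`. Every
#' drug additionally gains each target with the small background probability
#' `random_edge_prob`. Query compounds are built to carry one planted
#' substructure each (cycling through the planted list) plus random extras,
#' and the truth table records which target each query should recover.
#'
#' @param config a [synth_config()].
#' @return list: `dti` (tibble `drug_id`, `target_id`), `fingerprints`
#'   (drug fingerprint tibble), `query_fp` (query fingerprint tibble),
#'   `truth` (tibble `query_id`, `planted_substructure`, `expected_target`),
#'   `planted` (tibble `substructure`, `target_id`, `strength`).
#' @export
gen_dti_with_signal <- function(config = synth_config()) {
  if (config$n_planted < 1) {
    abort("at least one planted association is required",
          class = "herb_validation_error")
  }
  with_seed(derive_seed(config$seed, 37L), {
    subs <- pad_ids("S", config$n_substructures)
    drugs <- pad_ids("D", config$n_drugs)
    targets <- pad_ids("T", config$n_targets)
    planted <- tibble(substructure = subs[seq_len(config$n_planted)],
                      target_id = targets[seq_len(config$n_planted)],
                      strength = config$strength)

    fp_mat <- matrix(rbinom(config$n_drugs * config$n_substructures, 1,
                            config$sub_carry_prob),
                     nrow = config$n_drugs, dimnames = list(drugs, subs))
    empty <- rowSums(fp_mat) == 0
    for (i in which(empty)) fp_mat[i, sample(config$n_substructures, 1)] <- 1L

    edge_list <- vector("list", config$n_drugs)
    for (i in seq_len(config$n_drugs)) {
      carried <- subs[fp_mat[i, ] == 1]
      pl <- planted[planted$substructure %in% carried, ]
      gained <- pl$target_id[runif(nrow(pl)) < pl$strength]
      background <- targets[runif(config$n_targets) < config$random_edge_prob]
      tg <- unique(c(gained, background))
      if (length(tg) > 0) {
        edge_list[[i]] <- tibble(drug_id = drugs[i], target_id = tg)
      }
    }
    dti <- dplyr::bind_rows(edge_list)

    # queries: one chosen planted (signal) key each, extras only from the
    # unplanted (noise) keys so distinct planted targets never compete
    q_ids <- pad_ids("Q", config$n_queries)
    q_mat <- matrix(0L, nrow = config$n_queries, ncol = config$n_substructures,
                    dimnames = list(q_ids, subs))
    noise_cols <- setdiff(seq_len(config$n_substructures),
                          seq_len(config$n_planted))
    if (length(noise_cols) > 0) {
      q_mat[, noise_cols] <- rbinom(config$n_queries * length(noise_cols), 1,
                                    config$sub_carry_prob)
    }
    planted_idx <- rep_len(seq_len(config$n_planted), config$n_queries)
    for (i in seq_len(config$n_queries)) q_mat[i, planted_idx[i]] <- 1L

    list(
      dti = dti,
      fingerprints = dplyr::bind_cols(tibble(compound_id = drugs),
                                      as_tibble(fp_mat)),
      query_fp = dplyr::bind_cols(tibble(compound_id = q_ids),
                                  as_tibble(q_mat)),
      truth = tibble(query_id = q_ids,
                     planted_substructure = planted$substructure[planted_idx],
                     expected_target = planted$target_id[planted_idx]),
      planted = planted
    )
  })
}

#' Generate a synthetic tissue expression table
#'
#' Each target is detected in each tissue independently with the configured
#' rate; detected targets get a level drawn uniformly from low/medium/high,
#' the rest are `not_detected`.
#'
#' @param targets character vector of target ids.
#' @param config a [synth_config()].
#' @return expression tibble (`target_id`, `keratinocyte`, `melanocyte`)
#'   plus a `truth` attribute with the logical detection matrix.
#' @export
gen_expression_table <- function(targets, config = synth_config()) {
  targets <- unique(as.character(targets))
  with_seed(derive_seed(config$seed, 53L), {
    draw <- function(rate) {
      det <- runif(length(targets)) < rate
      ifelse(det, sample(c("low", "medium", "high"), length(targets),
                         replace = TRUE), "not_detected")
    }
    out <- tibble(target_id = targets,
                  keratinocyte = draw(config$detection_rate[["keratinocyte"]]),
                  melanocyte = draw(config$detection_rate[["melanocyte"]]))
    attr(out, "truth") <- tibble(
      target_id = targets,
      detected_keratinocyte = out$keratinocyte != "not_detected",
      detected_melanocyte = out$melanocyte != "not_detected")
    out
  })
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Background sets are uniform draws from the universe; the planted set
#' draws `planted_fraction` of its members from the designated query set and
#' the rest from outside it, so over-representation analysis of that query
#' should rank it first.
#'
#' @param universe character vector of all gene/target ids.
#' @param query character vector (subset of `universe`) the planted set is
#'   enriched for.
#' @param config a [synth_config()].
#' @return list: `sets` (named list incl. the planted set),
#'   `enriched_set_name`.
#' @export
gen_gene_sets <- function(universe, query, config = synth_config()) {
  universe <- unique(as.character(universe))
  query <- intersect(unique(as.character(query)), universe)
  stopifnot(length(query) > 0, length(universe) > length(query))
  with_seed(derive_seed(config$seed, 71L), {
    size <- min(config$gene_set_size, length(universe))
    sets <- lapply(seq_len(config$n_gene_sets), function(i) {
      sample(universe, size)
    })
    names(sets) <- pad_ids("GS", config$n_gene_sets)
    n_from_query <- min(round(config$planted_fraction * size), length(query))
    planted <- c(sample(query, n_from_query),
                 sample(setdiff(universe, query), size - n_from_query))
    sets[[config$enriched_set_name]] <- planted
    list(sets = sets, enriched_set_name = config$enriched_set_name)
  })
}

#' Write every synthetic input to a directory
#'
#' Emits the full fixture bundle (library CSV, ADMET TSV + truth, DTI TSV,
#' drug and query fingerprints, DTI truth, expression TSV, GMT) so each
#' consuming reader can be exercised on files. All outputs are pure
#' functions of `config`.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
gen_all <- function(config = synth_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  lib <- gen_compound_library(config)
  adm <- gen_admet_table(config)
  net <- gen_dti_with_signal(config)
  expr <- gen_expression_table(pad_ids("T", config$n_targets), config)
  readr::write_csv(lib, p("library.csv"), progress = FALSE)
  write_admet_table(adm$admet, p("admet.tsv"))
  readr::write_tsv(adm$truth, p("admet_truth.tsv"), progress = FALSE)
  readr::write_tsv(net$dti, p("dti.tsv"), progress = FALSE)
  write_fingerprint_matrix(net$fingerprints, p("fingerprints.tsv"))
  write_fingerprint_matrix(net$query_fp, p("query_fp.tsv"))
  readr::write_tsv(net$truth, p("dti_truth.tsv"), progress = FALSE)
  readr::write_tsv(expr, p("expression.tsv"), progress = FALSE)
  gs <- gen_gene_sets(pad_ids("T", config$n_targets),
                      net$planted$target_id[seq_len(min(5, nrow(net$planted)))],
                      config)
  write_gmt(gs$sets, p("sets.gmt"))
  files <- c(library = p("library.csv"), admet = p("admet.tsv"),
             admet_truth = p("admet_truth.tsv"), dti = p("dti.tsv"),
             fingerprints = p("fingerprints.tsv"), query_fp = p("query_fp.tsv"),
             dti_truth = p("dti_truth.tsv"), expression = p("expression.tsv"),
             gmt = p("sets.gmt"))
  invisible(files)
}
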