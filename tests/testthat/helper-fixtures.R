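# shared fixtures and independent oracles (never call package internals)

# the worked diffusion toy: s1 -> {d1,d2}, s2 -> {d1}; d1 -> {t1,t2}, d2 -> {t2}
toy_sdt <- function() {
  list(
    sub_drug = tibble::tibble(substructure = c("s1", "s1", "s2"),
                              drug_id = c("d1", "d2", "d1")),
    dti = tibble::tibble(drug_id = c("d1", "d1", "d2"),
                         target_id = c("t1", "t2", "t2")),
    fingerprints = tibble::tibble(compound_id = c("d1", "d2"),
                                  s1 = c(1L, 1L), s2 = c(1L, 0L))
  )
}

# independent diffusion oracle: explicit sum over s -> d -> t paths of
# products of inverse out-degrees
diffuse_oracle <- function(sub_drug, drug_target, query) {
  qs <- intersect(unique(query), unique(sub_drug$substructure))
  resource <- stats::setNames(numeric(0), character(0))
  leaked <- 0
  if (length(qs) == 0) return(list(resource = resource, leaked = 1))
  for (s in qs) {
    ds <- sub_drug$drug_id[sub_drug$substructure == s]
    for (d in ds) {
      m <- (1 / length(qs)) * (1 / length(ds))
      ts <- drug_target$target_id[drug_target$drug_id == d]
      if (length(ts) == 0) {
        leaked <- leaked + m
      } else {
        for (t in ts) {
          resource[t] <- (if (t %in% names(resource)) resource[[t]] else 0) +
            m / length(ts)
        }
      }
    }
  }
  list(resource = resource, leaked = leaked)
}

# random small tripartite instance for oracle-equivalence sweeps
random_small_sdt <- function(n_s, n_d, n_t, p_sd = 0.5, p_dt = 0.5, seed = 1) {
  set.seed(seed)
  subs <- paste0("s", seq_len(n_s))
  drugs <- paste0("d", seq_len(n_d))
  targets <- paste0("t", seq_len(n_t))
  sd_pairs <- expand.grid(substructure = subs, drug_id = drugs,
                          stringsAsFactors = FALSE)
  sd_edges <- sd_pairs[runif(nrow(sd_pairs)) < p_sd, , drop = FALSE]
  if (nrow(sd_edges) == 0) sd_edges <- sd_pairs[1, , drop = FALSE]
  dt_pairs <- expand.grid(drug_id = drugs, target_id = targets,
                          stringsAsFactors = FALSE)
  dt_edges <- dt_pairs[runif(nrow(dt_pairs)) < p_dt, , drop = FALSE]
  if (nrow(dt_edges) == 0) dt_edges <- dt_pairs[1, , drop = FALSE]
  fp <- tibble::as_tibble(
    cbind(data.frame(compound_id = drugs),
          matrix(0L, n_d, n_s, dimnames = list(NULL, subs))))
  for (i in seq_len(nrow(sd_edges))) {
    fp[fp$compound_id == sd_edges$drug_id[i], sd_edges$substructure[i]] <- 1L
  }
  list(sub_drug = tibble::as_tibble(sd_edges),
       dti = tibble::as_tibble(dt_edges), fingerprints = fp,
       subs = subs, drugs = drugs, targets = targets)
}

build_quiet <- function(dti, fp) {
  suppressMessages(suppressWarnings(build_sdt_network(dti, fp)))
}

diffusion_scores <- function(net, qs) {
  d <- suppressWarnings(diffuse(net, qs))
  stats::setNames(d$resource$resource, d$resource$target_id)
}

# ADMET tibble of the five published lead compounds (signed calls)
lead_admet <- function() {
  read_admet_table(system.file("extdata", "lead_admet_calls.tsv",
                               package = "herbnetpharm"))
}
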