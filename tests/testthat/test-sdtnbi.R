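test_that("network construction validates edges, degrees and coverage", {
  toy <- toy_sdt()
  net <- build_sdt_network(toy$dti, toy$fingerprints)
  # hand-counted degrees
  expect_equal(net$drug_out_degree[["d1"]], 2L)
  expect_equal(net$drug_out_degree[["d2"]], 1L)
  expect_equal(sort(net$drugs_by_sub$s1), c("d1", "d2"))
  expect_equal(net$drugs_by_sub$s2, "d1")
  expect_length(net$dangling_drugs, 0)

  # duplicated DTI edge deduplicated with a message
  expect_message(
    net2 <- build_sdt_network(rbind(toy$dti, toy$dti[1, ]), toy$fingerprints),
    "deduplicated")
  expect_equal(nrow(net2$drug_target), 3)

  # drug missing from fingerprints is named
  dti_bad <- rbind(toy$dti, tibble::tibble(drug_id = "d9", target_id = "t1"))
  expect_error(build_sdt_network(dti_bad, toy$fingerprints), "d9",
               class = "herb_validation_error")

  expect_error(build_sdt_network(toy$dti[0, ], toy$fingerprints),
               class = "herb_validation_error")

  # all-zero fingerprint row is kept with a warning
  fp0 <- toy$fingerprints
  fp0[fp0$compound_id == "d2", c("s1", "s2")] <- 0L
  expect_warning(build_sdt_network(toy$dti, fp0), "d2")
})

test_that("diffusion reproduces the worked example and its contracts", {
  toy <- toy_sdt()
  net <- build_sdt_network(toy$dti, toy$fingerprints)
  d <- diffuse(net, c("s1", "s2"))
  res <- setNames(d$resource$resource, d$resource$target_id)
  expect_equal(res[["t1"]], 0.375)
  expect_equal(res[["t2"]], 0.625)
  expect_equal(d$leaked_mass, 0)

  # single chain conserves all mass onto the lone target
  chain <- build_sdt_network(
    tibble::tibble(drug_id = "d1", target_id = "t1"),
    tibble::tibble(compound_id = "d1", s1 = 1L))
  expect_equal(diffusion_scores(chain, "s1")[["t1"]], 1)

  # target-less drug leaks the full unit mass
  dangle <- suppressMessages(build_sdt_network(
    tibble::tibble(drug_id = "d1", target_id = "t1"),
    tibble::tibble(compound_id = c("d1", "d2"), s1 = c(1L, 0L), s2 = c(0L, 1L))))
  d2 <- diffuse(dangle, "s2")
  expect_equal(nrow(d2$resource), 0)
  expect_equal(d2$leaked_mass, 1)

  # absent query keys are dropped with a warning; none present -> leak 1
  expect_warning(d3 <- diffuse(net, c("s1", "nope")), "nope")
  expect_equal(sum(d3$resource$resource) + d3$leaked_mass, 1)
  expect_warning(d4 <- diffuse(net, "nope"), "nope")
  expect_equal(d4$leaked_mass, 1)
})

test_that("diffusion equals brute-force path enumeration on random small nets", {
  for (seed in 1:25) {
    dims <- 1 + (c(seed, seed + 7, seed + 13) %% 6)
    inst <- random_small_sdt(dims[1], dims[2], dims[3],
                             p_sd = 0.4 + 0.2 * (seed %% 3), seed = seed)
    net <- build_quiet(inst$dti, inst$fingerprints)
    set.seed(seed + 1000)
    qs <- sample(inst$subs, sample(length(inst$subs), 1))
    got <- suppressWarnings(diffuse(net, qs))
    want <- diffuse_oracle(inst$sub_drug, inst$dti, qs)
    expect_equal(got$leaked_mass, want$leaked, tolerance = 1e-12)
    got_v <- setNames(got$resource$resource, got$resource$target_id)
    expect_equal(sort(names(got_v)), sort(names(want$resource)))
    expect_equal(got_v[sort(names(got_v))],
                 want$resource[sort(names(got_v))], tolerance = 1e-12)
    expect_equal(sum(got_v) + got$leaked_mass, 1, tolerance = 1e-12)
  }
})

test_that("relabeling node ids permutes diffusion results identically", {
  inst <- random_small_sdt(4, 5, 4, seed = 9)
  net <- build_quiet(inst$dti, inst$fingerprints)
  ren <- function(x, prefix) paste0(prefix, x, "x")
  dti2 <- tibble::tibble(drug_id = ren(inst$dti$drug_id, "D"),
                         target_id = ren(inst$dti$target_id, "T"))
  fp2 <- inst$fingerprints
  fp2$compound_id <- ren(fp2$compound_id, "D")
  names(fp2) <- c("compound_id", ren(inst$subs, "S"))
  net2 <- build_quiet(dti2, fp2)
  qs <- inst$subs[1:2]
  a <- diffusion_scores(net, qs)
  b <- diffusion_scores(net2, ren(qs, "S"))
  expect_equal(unname(b[ren(names(a), "T")]), unname(a))
})

test_that("duplicating a drug leaves other queries' target ranking unchanged", {
  inst <- random_small_sdt(5, 5, 5, seed = 21)
  # clone drug d1: same fingerprint row, same targets, new id
  dti_dup <- rbind(inst$dti,
                   transform(inst$dti[inst$dti$drug_id == "d1", ],
                             drug_id = "d1clone"))
  fp_dup <- rbind(inst$fingerprints,
                  transform(inst$fingerprints[inst$fingerprints$compound_id == "d1", ],
                            compound_id = "d1clone"))
  net <- build_quiet(inst$dti, inst$fingerprints)
  net_dup <- build_quiet(dti_dup, fp_dup)
  qs <- inst$subs[1:3]
  a <- suppressWarnings(predict_targets(net, qs, k = 10))
  b <- suppressWarnings(predict_targets(net_dup, qs, k = 10))
  expect_equal(b$target_id, a$target_id)
})

test_that("target prediction ranks by resource with id tie-break and cutoff", {
  toy <- toy_sdt()
  net <- build_sdt_network(toy$dti, toy$fingerprints)
  top1 <- predict_targets(net, c("s1", "s2"), k = 1)
  expect_equal(top1$target_id, "t2")

  # k beyond the reached targets returns them all
  all_t <- predict_targets(net, c("s1", "s2"), k = 50)
  expect_equal(nrow(all_t), 2)

  # exact ties order by target id
  sym <- build_sdt_network(
    tibble::tibble(drug_id = c("d1", "d1"), target_id = c("tb", "ta")),
    tibble::tibble(compound_id = "d1", s1 = 1L))
  expect_equal(predict_targets(sym, "s1", k = 2)$target_id, c("ta", "tb"))

  expect_error(predict_targets(net, "s1", k = 0), class = "herb_argument_error")
})

test_that("hop weighting by target degree conserves mass and reorders hubs", {
  inst <- random_small_sdt(4, 6, 5, seed = 33)
  net <- build_quiet(inst$dti, inst$fingerprints)
  d <- suppressWarnings(diffuse(net, inst$subs, alpha = -0.8))
  expect_equal(sum(d$resource$resource) + d$leaked_mass, 1, tolerance = 1e-12)
})

test_that("cross-validation is seeded, leak-free and guarded", {
  # two disjoint chains: holding out an edge must leave its target unscored
  dti <- tibble::tibble(drug_id = c("d1", "d2"), target_id = c("t1", "t2"))
  fp <- tibble::tibble(compound_id = c("d1", "d2"),
                       s1 = c(1L, 0L), s2 = c(0L, 1L))
  net <- build_sdt_network(dti, fp)
  cv <- suppressMessages(cross_validate(net, scheme = "loo", seed = 4))
  # a leaky implementation would score the held-out target 1.0 and reach AUC 1
  expect_equal(cv$mean_auc, 0.5)

  sim <- gen_dti_with_signal(synth_config(seed = 5, n_drugs = 40))
  netb <- build_quiet(sim$dti, sim$fingerprints)
  cv1 <- cross_validate(netb, seed = 17)
  cv2 <- cross_validate(netb, seed = 17)
  expect_equal(glance(cv1)$mean_auc, glance(cv2)$mean_auc)
  expect_equal(tidy(cv1), tidy(cv2))
  expect_equal(sum(tidy(cv1)$n_held_out), nrow(netb$drug_target))

  small <- build_sdt_network(toy_sdt()$dti, toy_sdt()$fingerprints)
  expect_error(cross_validate(small, k_folds = 10),
               class = "herb_validation_error")
})
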