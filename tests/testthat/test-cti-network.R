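toy_cti <- function() {
  build_cti(tibble::tibble(
    compound_id = c("c1", "c1", "c1", "c2", "c2", "c2"),
    target_id = c("t1", "t2", "t3", "t2", "t3", "t4")))
}

test_that("CTI construction is bipartite, deduplicated and annotated", {
  # 2 compounds each with 3 targets, one of them shared pairwise
  preds <- tibble::tibble(query_id = c("c1", "c1", "c1", "c2", "c2", "c2"),
                          target_id = c("t1", "t2", "t3", "t3", "t4", "t5"))
  net <- build_cti(preds)
  expect_equal(glance(net)$n_compounds + glance(net)$n_targets, 7)
  expect_equal(glance(net)$n_edges, 6)

  # empty predictions give an empty network
  expect_equal(glance(build_cti(preds[0, ]))$n_edges, 0)

  # duplicate pairs collapse to one edge, multiplicity logged
  expect_message(dup <- build_cti(rbind(preds, preds[1, ])), "1 duplicate")
  expect_equal(glance(dup)$n_edges, 6)

  # bipartite handshake: degree sums on both sides equal the edge count
  edges <- tidy(net)
  expect_equal(sum(table(edges$compound_id)), nrow(edges))
  expect_equal(sum(table(edges$target_id)), nrow(edges))

  # annotations join left-outer, missing rows kept as NA
  ann <- build_cti(preds,
                   compound_annotations = tibble::tibble(
                     compound_id = "c1", structural_class = "flavonoid"))
  expect_equal(ann$compounds$structural_class,
               c("flavonoid", NA_character_))
})

test_that("common targets intersect neighbourhoods and shrink monotonically", {
  net <- toy_cti()
  expect_equal(common_targets(net, c("c1", "c2")), c("t2", "t3"))
  expect_equal(common_targets(net, "c1"), c("t1", "t2", "t3"))
  expect_true(all(common_targets(net, c("c1", "c2")) %in%
                    common_targets(net, "c1")))
  expect_error(common_targets(net, "c9"), "c9",
               class = "herb_validation_error")

  disjoint <- build_cti(tibble::tibble(compound_id = c("a", "b"),
                                       target_id = c("t1", "t2")))
  expect_length(common_targets(disjoint, c("a", "b")), 0)
})

test_that("coverage fraction counts the subset share of network targets", {
  net <- toy_cti()
  expect_equal(coverage_fraction(net, c("t1", "t2", "t3", "t4")), 1)
  expect_equal(coverage_fraction(net, character()), 0)
  # 26 of 72 targets -> 0.361 at the reported 0.1% precision
  big <- build_cti(tibble::tibble(compound_id = "c",
                                  target_id = sprintf("t%02d", 1:72)))
  expect_equal(round(coverage_fraction(big, sprintf("t%02d", 1:26)), 3), 0.361)
})

test_that("SIF export writes one edge per line and round-trips", {
  net <- toy_cti()
  f <- withr::local_tempfile(fileext = ".sif")
  export_network(net, f, format = "sif")
  lines <- readLines(f)
  expect_length(lines, 6)
  expect_true(all(grepl("^\\S+\tcti\t\\S+$", lines)))
  back <- import_network(f, format = "sif")
  expect_equal(dplyr::arrange(tidy(back), compound_id, target_id),
               dplyr::arrange(tidy(net), compound_id, target_id))
})

test_that("GraphML export carries annotations and round-trips edges", {
  preds <- tibble::tibble(compound_id = c("c1", "c1", "c2"),
                          target_id = c("t1", "t2", "t2"))
  net <- build_cti(
    preds,
    compound_annotations = tibble::tibble(compound_id = "c1",
                                          structural_class = "steroid"),
    target_annotations = tibble::tibble(target_id = c("t1", "t2"),
                                        tissue = c("both", "neither")))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f, format = "graphml")
  back <- import_network(f, format = "graphml")
  expect_equal(dplyr::arrange(tidy(back), compound_id, target_id),
               dplyr::arrange(tidy(net), compound_id, target_id))
  # unannotated node exported with the literal string "NA"
  expect_equal(back$compounds$structural_class[back$compounds$compound_id == "c2"],
               "NA")
  expect_equal(back$targets$tissue, c("both", "neither"))

  expect_error(export_network(net, f, format = "dot"),
               class = "herb_argument_error")
  expect_error(import_network(f, format = "dot"),
               class = "herb_argument_error")
})

test_that("node attribute TSV lists every node with its class", {
  net <- toy_cti()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_node_attributes(net, f)
  nodes <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(nodes), 6)
  expect_setequal(unique(nodes$node_class), c("compound", "target"))
})
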