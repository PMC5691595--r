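test_that("signed-probability parser accepts both dialects", {
  # unicode minus and ascii hyphen
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "compound_id\tHIA\tCaco2\tCYP1A2\tCYP2C9\tCYP2D6\tCYP2C19\tCYP3A4",
    "A\t+0.9\t+0.8\t+0.5\t−0.6\t-0.7\t+0.8\t+0.9"), f)
  tab <- read_admet_table(f)
  expect_equal(tab$CYP2C9, -0.6)
  expect_equal(tab$CYP2D6, -0.7)

  # separate class/probability columns fold into signed values
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("compound_id", "HIA_class", "HIA_prob", "Caco2", "CYP1A2",
            "CYP2C9", "CYP2D6", "CYP2C19", "CYP3A4"), collapse = "\t"),
    "A\t-\t0.9\t+0.8\t+0.5\t+0.6\t+0.7\t+0.8\t+0.9"), f2)
  expect_equal(read_admet_table(f2)$hia, -0.9)

  # out-of-range magnitude is rejected
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "compound_id\tHIA\tCaco2\tCYP1A2\tCYP2C9\tCYP2D6\tCYP2C19\tCYP3A4",
    "A\t+1.9\t+0.8\t+0.5\t+0.6\t+0.7\t+0.8\t+0.9"), f3)
  expect_error(read_admet_table(f3), class = "herb_validation_error")

  # missing isoform column is named
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tHIA\tCaco2\tCYP1A2\tCYP2C9\tCYP2D6\tCYP2C19",
               "A\t+0.9\t+0.8\t+0.5\t+0.6\t+0.7\t+0.8"), f4)
  expect_error(read_admet_table(f4), "CYP3A4", class = "herb_format_error")
})

test_that("absorption filter gates on double-positive sign only", {
  leads <- lead_admet()
  expect_equal(nrow(absorption_filter(leads)), 5) # all published leads pass

  tab <- tibble::tibble(compound_id = c("A", "B", "C", "D"),
                        hia = c(0.9, -0.9, 0.9, -0.2),
                        caco2 = c(0.9, 0.9, -0.1, -0.9))
  kept <- absorption_filter(tab)
  expect_equal(kept$compound_id, "A")
  # idempotent, order preserving, empty-safe
  expect_equal(absorption_filter(kept), kept)
  expect_equal(nrow(absorption_filter(tab[0, ])), 0)
})

test_that("CYP score reproduces the published worked examples exactly", {
  scored <- cyp_score(lead_admet())
  expected <- c(Isorhamnetin = 1.92963575, Kaempferide = 1.92963575,
                Isoliquiritigenin = 1.92766477, Apigenin = 1.76820103,
                Liquiritigenin = 1.72194393)
  expect_true(all(abs(scored$score[match(names(expected), scored$compound_id)] -
                        expected) < 1e-8))
})

test_that("score is bounded, additive in weights, and flip-symmetric", {
  set.seed(42)
  q <- default_cyp_weights()
  n <- 50
  tab <- tibble::tibble(compound_id = sprintf("X%02d", 1:n))
  for (iso in cyp_isoforms) {
    tab[[iso]] <- sample(c(-1, 1), n, TRUE) * runif(n, 0.01, 1)
  }
  s <- cyp_score(tab, q)$score
  expect_true(all(abs(s) <= sum(q) + 1e-12))

  # the bound is attained exactly by unit-probability calls of one sign
  tab1 <- tab
  for (iso in cyp_isoforms) tab1[[iso]] <- 1
  expect_equal(cyp_score(tab1, q)$score, rep(sum(q), n))
  for (iso in cyp_isoforms) tab1[[iso]] <- -1
  expect_equal(cyp_score(tab1, q)$score, rep(-sum(q), n))
  # and by nothing below unit magnitude
  expect_true(all(abs(s) < sum(q)))

  # flipping one call's sign changes the score by 2 * p * Q_k
  for (iso in cyp_isoforms) {
    flipped <- tab
    flipped[[iso]] <- -flipped[[iso]]
    delta <- cyp_score(tab, q)$score - cyp_score(flipped, q)$score
    expect_equal(delta, 2 * tab[[iso]] * q[[iso]])
  }

  # zero-magnitude limit: score of all-epsilon calls tends to 0
  eps <- tab
  for (iso in cyp_isoforms) eps[[iso]] <- 1e-9
  expect_lt(abs(cyp_score(eps, q)$score[1]), 1e-6)
})

test_that("ranking is score-descending with id tie-break and top-n truncation", {
  ranked <- rank_compounds(lead_admet(), top_n = 5)
  expect_equal(ranked$compound_id,
               c("Isorhamnetin", "Kaempferide", "Isoliquiritigenin",
                 "Apigenin", "Liquiritigenin"))
  expect_equal(ranked$rank, 1:5)

  # single record ranks first regardless of score
  one <- rank_compounds(lead_admet()[3, ], top_n = 5)
  expect_equal(one$rank, 1L)

  # permutation matches an independent sort oracle on 100 random records
  set.seed(11)
  n <- 100
  tab <- tibble::tibble(compound_id = sprintf("R%03d", sample(n)))
  for (iso in cyp_isoforms) {
    tab[[iso]] <- sample(c(-1, 1), n, TRUE) * runif(n, 0.01, 1)
  }
  full <- rank_compounds(tab, top_n = Inf)
  scores <- cyp_score(tab)$score
  oracle <- tab$compound_id[order(-scores, tab$compound_id)]
  expect_equal(full$compound_id, oracle)

  expect_error(rank_compounds(lead_admet(), top_n = 0),
               class = "herb_argument_error")
})

test_that("weights load from YAML and validate", {
  w <- read_cyp_weights(system.file("extdata", "cyp_accuracy_weights.yaml",
                                    package = "herbnetpharm"))
  expect_equal(w, default_cyp_weights())
  expect_error(cyp_score(lead_admet(), weights = w[-2]),
               "CYP2C9", class = "herb_validation_error")
})
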