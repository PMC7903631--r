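test_that("parse_obo builds the DAG, registers alt_ids and drops obsolete terms", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: T1", "name: root", "",
    "[Term]", "id: T2", "name: mid", "alt_id: A9",
    "synonym: \"middle term\" EXACT []", "is_a: T1 ! root", "",
    "[Term]", "id: T3", "is_a: T2", "",
    "[Term]", "id: T4", "is_a: T1", "is_obsolete: true", ""
  )
  onto <- parse_obo(obo)
  expect_s3_class(onto, "ontology")
  expect_equal(onto$n_terms, 3L)
  expect_setequal(onto$ids, c("T1", "T2", "T3"))
  expect_equal(sum(lengths(onto$parents)), 2L)
  expect_equal(onto$roots, "T1")
  expect_equal(unname(onto$alt["A9"]), "T2")
  expect_equal(onto$synonyms[["T2"]], "middle term")
  expect_false("T4" %in% onto$ids)
})

test_that("parse_obo rejects cycles and duplicate ids", {
  cyc <- c("[Term]", "id: T1", "is_a: T2", "[Term]", "id: T2", "is_a: T1")
  expect_error(parse_obo(cyc), "cycle")
  dup <- c("[Term]", "id: T1", "[Term]", "id: T1")
  expect_error(parse_obo(dup), "duplicate")
  clash <- c("[Term]", "id: T1", "alt_id: T2", "[Term]", "id: T2", "is_a: T1")
  expect_error(parse_obo(clash), "collide")
})

test_that("resolve_id handles primary and secondary ids, with a strict mode", {
  onto <- fixture_toy()$ontology
  expect_equal(resolve_id(onto, "T:C"), "T:C")
  expect_equal(resolve_id(onto, "S:C9"), "T:C")
  # a primary-id-only pipeline fails on merged-away secondary accessions
  expect_error(resolve_id(onto, "S:C9", strict = TRUE), "not found")
  expect_error(resolve_id(onto, "nope"), "not found")
})

test_that("ancestors_or_self is the reflexive-transitive is_a closure", {
  chain <- parse_obo(c("[Term]", "id: T1", "[Term]", "id: T2", "is_a: T1",
                       "[Term]", "id: T3", "is_a: T2"))
  expect_setequal(ancestors_or_self(chain, "T3"), c("T3", "T2", "T1"))
  expect_equal(ancestors_or_self(chain, "T1"), "T1")
  diamond <- parse_obo(c("[Term]", "id: A", "[Term]", "id: B", "is_a: A",
                         "[Term]", "id: C", "is_a: A",
                         "[Term]", "id: D", "is_a: B", "is_a: C"))
  expect_setequal(ancestors_or_self(diamond, "D"), c("D", "B", "C", "A"))
})

test_that("intrinsic IC matches direct evaluation on the five-term DAG", {
  toy <- fixture_toy()$ontology
  ic <- compute_ic(toy)
  expect_equal(ic[["T:R"]], 0)
  expect_equal(ic[["T:C"]], log2(5))
  expect_equal(ic[["T:A"]], -log2(3 / 5))
  expect_true(all(ic >= 0))
})

test_that("shared IC is the most informative common ancestor's IC", {
  toy <- fixture_toy()$ontology
  ic <- compute_ic(toy)
  expect_equal(shared_ic(toy, ic, "T:C", "T:D"), -log2(3 / 5))
  expect_equal(shared_ic(toy, ic, "T:C", "T:B"), 0)
  expect_equal(shared_ic(toy, ic, "T:C", "T:C"), ic[["T:C"]])
})

test_that("the three similarity measures match hand-derived toy values", {
  toy <- fixture_toy()$ontology
  ic <- compute_ic(toy)
  expect_equal(sim_resnik(toy, ic, "T:C", "T:D"), toy_expected$resnik_cd)
  expect_equal(sim_lin(toy, ic, "T:C", "T:D"), toy_expected$lin_cd)
  expect_equal(sim_jc(toy, ic, "T:C", "T:D"), toy_expected$jc_cd)
  expect_equal(sim_jc(toy, ic, "T:C", "T:B"), toy_expected$jc_cb)
  # self-similarity and identity conventions
  expect_equal(sim_lin(toy, ic, "T:C", "T:C"), 1)
  expect_equal(sim_jc(toy, ic, "T:C", "T:C"), 1)
  expect_equal(sim_resnik(toy, ic, "T:C", "T:C"), ic[["T:C"]])
  expect_equal(sim_lin(toy, ic, "T:R", "T:B"), 0)
  # secondary accessions resolve before scoring
  expect_equal(sim_lin(toy, ic, "S:C9", "T:D"), toy_expected$lin_cd)
})

test_that("similarities agree with the brute-force oracle on random DAGs", {
  for (seed in 1:10) {
    set.seed(1000 + seed)
    n <- sample(5:25, 1)
    parents <- random_parent_list(n, seed)
    onto <- ontology_from_parents(parents)
    ic <- compute_ic(onto)
    expect_equal(ic, oracle_ic(parents)[onto$ids], tolerance = 1e-12)
    picks <- t(replicate(15, sample(onto$ids, 2, replace = TRUE)))
    for (r in seq_len(nrow(picks))) {
      a <- picks[r, 1]; b <- picks[r, 2]
      want <- oracle_sims(parents, a, b)
      expect_equal(sim_resnik(onto, ic, a, b), unname(want["resnik"]), tolerance = 1e-12)
      expect_equal(sim_lin(onto, ic, a, b), unname(want["lin"]), tolerance = 1e-12)
      expect_equal(sim_jc(onto, ic, a, b), unname(want["jc"]), tolerance = 1e-12)
      # symmetry is exact
      expect_identical(sim_lin(onto, ic, a, b), sim_lin(onto, ic, b, a))
      expect_identical(sim_jc(onto, ic, a, b), sim_jc(onto, ic, b, a))
    }
  }
})
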