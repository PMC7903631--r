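# A hand-buildable store: arbitrary symmetric values over a small universe.
manual_store <- function(vals) {
  # vals: data.frame(item_a, item_b, s); fills all three measures with s
  vals$item_a2 <- pmin(vals$item_a, vals$item_b)
  vals$item_b2 <- pmax(vals$item_a, vals$item_b)
  pairs <- data.frame(item_a = vals$item_a2, item_b = vals$item_b2,
                      resnik = vals$s, lin = vals$s, jc = vals$s,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$item_a, pairs$item_b), ]
  ontorec:::new_sim_cache(sort(unique(c(vals$item_a, vals$item_b))), pairs)
}

test_that("the score is the mean similarity to the n most similar train items", {
  st <- manual_store(data.frame(
    item_a = "t", item_b = c("x", "y", "z"), s = c(0.2, 0.4, 0.6)))
  expect_equal(score_items_onto(st, c("x", "y", "z"), "t", "lin", n = "all")$score, 0.4)
  expect_equal(score_items_onto(st, c("x", "y", "z"), "t", "lin", n = 2)$score, 0.5)
  expect_equal(score_items_onto(st, c("x", "y", "z"), "t", "lin", n = 1)$score, 0.6)
  # single train item: the score is that similarity whatever n is
  one <- manual_store(data.frame(item_a = "t", item_b = "x", s = 0.33))
  for (n in c(1, 5, Inf)) {
    expect_equal(score_items_onto(one, "x", "t", "lin", n = n)$score, 0.33)
  }
})

test_that("n_used reports the number of train items actually averaged", {
  st <- manual_store(data.frame(
    item_a = "t", item_b = c("x", "y", "z"), s = c(0.2, 0.4, 0.6)))
  sc <- score_items_onto(st, c("x", "y", "z"), "t", "lin", n = 10)
  expect_equal(sc$n_used, 3L)
  expect_equal(sc$score, 0.4)
})

test_that("empty or fully-unknown train sets are errors; unknown items shrink m", {
  st <- manual_store(data.frame(item_a = "t", item_b = c("x", "y"), s = c(0.1, 0.3)))
  expect_error(score_items_onto(st, character(0), "t", "lin"), "empty train set")
  expect_error(suppressWarnings(score_items_onto(st, "nope", "t", "lin")),
               "empty train set")
  expect_warning(sc <- score_items_onto(st, c("x", "y", "nope"), "t", "lin"),
                 "nope")
  expect_equal(sc$n_used, 2L)
  expect_equal(sc$score, 0.2)
})

test_that("scores match brute-force means on random stores, and n=1 is the max", {
  for (seed in 1:20) {
    set.seed(seed)
    onto <- gen_ontology(sample(10:35, 1), seed = seed)
    ic <- compute_ic(onto)
    store <- build_sim_cache(onto, ic, onto$ids)
    train <- sample(onto$ids, sample(2:6, 1))
    tests <- sample(onto$ids, 5)
    for (m in c("resnik", "lin", "jc")) {
      sims <- vapply(tests, function(t) {
        s <- get_similarity(store, t, train, m)
        c(mean(s), max(s), mean(sort(s, decreasing = TRUE)[seq_len(min(2, length(s)))]))
      }, numeric(3))
      sc_all <- score_items_onto(store, train, tests, m, n = "all")
      sc_one <- score_items_onto(store, train, tests, m, n = 1)
      sc_two <- score_items_onto(store, train, tests, m, n = 2)
      expect_equal(sc_all$score, unname(sims[1, ]), tolerance = 1e-14)
      expect_equal(sc_one$score, unname(sims[2, ]), tolerance = 1e-14)
      expect_equal(sc_two$score, unname(sims[3, ]), tolerance = 1e-14)
    }
  }
})

test_that("adding a train item above the current mean never lowers the n=all score", {
  st <- manual_store(data.frame(
    item_a = "t", item_b = c("w", "x", "y", "z"), s = c(0.1, 0.5, 0.3, 0.9)))
  base <- score_items_onto(st, c("w", "x", "y"), "t", "lin", n = "all")$score
  more <- score_items_onto(st, c("w", "x", "y", "z"), "t", "lin", n = "all")$score
  expect_gte(more, base)
})

test_that("structurally identical leaves receive identical scores", {
  # C and D are exchangeable leaves under the same parent with equal
  # descendant counts, so any train set not containing them scores them equally
  toy <- fixture_toy()
  store <- build_sim_cache(toy$ontology, compute_ic(toy$ontology), toy$ontology$ids)
  for (m in c("resnik", "lin", "jc")) {
    sc <- score_items_onto(store, c("T:A", "T:B"), c("T:C", "T:D"), m, n = "all")
    expect_equal(sc$score[1], sc$score[2])
  }
})

test_that("an item with no ratings anywhere is still scorable from the ontology", {
  toy <- fixture_toy()
  store <- build_sim_cache(toy$ontology, compute_ic(toy$ontology), toy$ontology$ids)
  rated <- unique(toy$ratings$item)
  expect_false("T:R" %in% rated)   # never rated by anyone
  sc <- score_items_onto(store, c("T:C", "T:D"), "T:R", "lin", n = "all")
  expect_true(is.finite(sc$score))
})
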