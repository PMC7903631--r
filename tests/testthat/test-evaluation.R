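test_that("folds partition users and items into paired blocks", {
  df <- expand.grid(user = sprintf("U%02d", 1:10), item = sprintf("I%02d", 1:10),
                    stringsAsFactors = FALSE)
  df$rating <- 1
  data <- ratings_dataset(df)
  folds <- split_folds(data, q = 5, seed = 42)
  expect_length(folds, 5)
  expect_true(all(vapply(folds, function(f) length(f$test_users), 0L) == 2))
  expect_true(all(vapply(folds, function(f) length(f$test_items), 0L) == 2))
  expect_setequal(unlist(lapply(folds, `[[`, "test_users")), attr(data, "users"))
  expect_setequal(unlist(lapply(folds, `[[`, "test_items")), attr(data, "items"))
  expect_identical(folds, split_folds(data, q = 5, seed = 42))
  expect_false(identical(folds, split_folds(data, q = 5, seed = 43)))
  expect_error(split_folds(data, q = 11, seed = 1), "exceeds")
})

test_that("relevance is binary: any positive count is relevant, rating value ignored", {
  tr <- data.frame(item = c("a", "b"), rating = c(5, 1))
  expect_setequal(binarize_relevance(tr), c("a", "b"))
  expect_length(binarize_relevance(data.frame(item = character(0),
                                              rating = numeric(0))), 0)
  # swapping a 5 for a 1 changes no metric value
  ranked <- c("a", "c", "b")
  rel1 <- binarize_relevance(data.frame(item = c("a", "b"), rating = c(5, 1)))
  rel2 <- binarize_relevance(data.frame(item = c("a", "b"), rating = c(1, 5)))
  for (k in 1:3) {
    expect_equal(precision_at_k(ranked, rel1, k), precision_at_k(ranked, rel2, k))
    expect_equal(ndcg_at_k(ranked, rel1, k), ndcg_at_k(ranked, rel2, k))
  }
})

test_that("the metric formulas reproduce hand-worked examples", {
  ranked <- c("r1", "x", "x2", "r2", "x3")
  relevant <- c("r1", "r2")
  expect_equal(precision_at_k(ranked, relevant, 4), 0.5)
  expect_equal(recall_at_k(ranked, relevant, 4), 1)
  expect_equal(f_measure_at_k(0.5, 0.5), 0.5)
  expect_equal(f_measure_at_k(1, 0), 0)
  expect_equal(f_measure_at_k(0.4, 0.6), 0.48)
  expect_equal(mrr_at_k(list(c("x", "x2", "r1")), list("r1"), 3), 1 / 3)
  expect_equal(mrr_at_k(list(c("r1", "x"), c("x", "r1")),
                        list("r1", "r1"), 2), 0.75)
  expect_equal(mrr_at_k(list(c("x", "y")), list("r1"), 2), 0)
  # relevant at ranks 1 and 3 with k = 3
  got <- ndcg_at_k(c("r1", "x", "r2"), relevant, 3)
  expect_equal(got, (1 + 1 / log2(4)) / (1 + 1 / log2(3)), tolerance = 1e-12)
  expect_equal(round(got, 4), 0.9197)
  expect_equal(ndcg_at_k(c("r1", "r2", "x"), relevant, 3), 1)
  expect_equal(ndcg_at_k(c("x", "y", "z"), relevant, 3), 0)
})

test_that("scalar metric functions agree with the vectorized pass", {
  set.seed(31)
  for (rep in 1:25) {
    ranked <- sample(letters[1:10])
    relevant <- sample(letters[1:10], sample(1:5, 1))
    m <- ontorec:::ranking_metrics(ranked, relevant, 8)
    for (k in c(1, 4, 8)) {
      expect_equal(unname(m[k, "precision"]), precision_at_k(ranked, relevant, k))
      expect_equal(unname(m[k, "recall"]), recall_at_k(ranked, relevant, k))
      expect_equal(unname(m[k, "ndcg"]), ndcg_at_k(ranked, relevant, k))
      expect_equal(unname(m[k, "rr"]), mrr_at_k(list(ranked), list(relevant), k))
    }
    # recall is non-decreasing in k; nDCG stays within [0, 1]
    expect_true(all(diff(m[, "recall"]) >= 0))
    expect_true(all(m[, "ndcg"] >= 0 & m[, "ndcg"] <= 1))
    # precision * k counts hits: an integer no larger than min(k, |relevant|)
    hits <- m[, "precision"] * (1:8)
    expect_equal(hits, round(hits))
    expect_true(all(hits <= pmin(1:8, length(relevant))))
  }
})

test_that("nDCG is 1 exactly when relevant items fill the top ranks", {
  relevant <- c("a", "b", "c")
  expect_equal(ndcg_at_k(c("b", "c", "a", "x"), relevant, 4), 1)
  expect_lt(ndcg_at_k(c("b", "x", "a", "c"), relevant, 4), 1)
})

test_that("evaluate_run produces a deterministic, well-shaped report", {
  onto <- gen_ontology(60, seed = 2)
  data <- gen_ratings(onto, n_users = 15, n_items = 50,
                      min_items_per_user = 10, concentration = 0.8, seed = 2)
  rep1 <- evaluate_run("ONTO_LIN", data, onto, q = 3, seed = 5, k_max = 10)
  expect_s3_class(rep1, "eval_report")
  expect_setequal(unique(rep1$metric),
                  c("precision", "recall", "f_measure", "mrr", "ndcg"))
  expect_equal(max(rep1$k), 10)
  expect_true(all(rep1$value >= 0 & rep1$value <= 1))
  rep2 <- evaluate_run("ONTO_LIN", data, onto, q = 3, seed = 5, k_max = 10)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  expect_error(evaluate_run("ALS_ONTO_FOO_m1", data, onto), "valid names")
})

test_that("a hybrid with constant CB scores reports exactly the CF metrics", {
  onto <- gen_ontology(40, seed = 6)
  data <- gen_ratings(onto, n_users = 12, n_items = 35,
                      min_items_per_user = 8, concentration = 0.5, seed = 6)
  # degenerate store: every pairwise similarity identical -> constant ONTO score
  items <- attr(data, "items")
  ii <- rep.int(seq_along(items), times = length(items) - seq_along(items) + 1L)
  jj <- unlist(lapply(seq_along(items), function(i) seq.int(i, length(items))))
  flat <- ontorec:::new_sim_cache(items, data.frame(
    item_a = items[ii], item_b = items[jj],
    resnik = 0.4, lin = 0.4, jc = 0.4, stringsAsFactors = FALSE))
  base <- evaluate_run("ALS", data, q = 3, seed = 3, k_max = 8,
                       factors = 4, iterations = 5)
  for (alg in c("ALS_ONTO_LIN_m1", "ALS_ONTO_LIN_m2")) {
    hyb <- evaluate_run(alg, data, store = flat, q = 3, seed = 3, k_max = 8,
                        factors = 4, iterations = 5)
    expect_equal(hyb$value, base$value, tolerance = 1e-12)
  }
})

test_that("recall aggregates are non-decreasing in k", {
  onto <- gen_ontology(50, seed = 9)
  data <- gen_ratings(onto, n_users = 12, n_items = 40,
                      min_items_per_user = 8, concentration = 0.7, seed = 9)
  rep <- evaluate_run("ONTO_JC", data, onto, q = 3, seed = 1, k_max = 12)
  s <- attr(rep, "summary")
  rec <- s$value[s$metric == "recall"][order(s$k[s$metric == "recall"])]
  expect_true(all(diff(rec) >= -1e-12))
})
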