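#' Paired user-by-item cross-validation folds
#'
#' Splits users and items into `q` seeded random blocks each; fold `f`
#' pairs user-block `f` with item-block `f`. In fold `f` the test ratings
#' are the ratings of the fold's test users on the fold's test items; every
#' other rating is training data. For each test user the candidate universe
#' is the full test-item block — rated and unrated alike — so roughly a
#' fifth of the item universe must be ranked per user at `q = 5`.
#'
#' @param data A `"ratings"` object.
#' @param q Number of folds (default 5).
#' @param seed Integer seed for the two block permutations.
#' @return List of `q` fold specs: `fold`, `test_users`, `test_items`,
#'   `q`, `seed`. Across folds the user blocks partition the user set and
#'   the item blocks partition the item set.
#' @export
split_folds <- function(data, q = 5L, seed = 1L) {
  users <- attr(data, "users"); items <- attr(data, "items")
  if (q < 2L) stop("q must be at least 2")
  if (q > length(users)) stop("q exceeds the number of users (", length(users), ")")
  if (q > length(items)) stop("q exceeds the number of items (", length(items), ")")
  set.seed(seed)
  ublock <- block_assign(length(users), q)
  iblock <- block_assign(length(items), q)
  lapply(seq_len(q), function(f) {
    list(fold = f,
         test_users = users[ublock == f],
         test_items = items[iblock == f],
         q = q, seed = seed)
  })
}

# Seeded near-equal partition of n elements into q blocks.
block_assign <- function(n, q) {
  sizes <- diff(floor(seq(0, n, length.out = q + 1)))
  rep.int(seq_len(q), times = sizes)[sample.int(n)]
}

#' Binary relevance of a user's test ratings
#'
#' Under implicit feedback, any positive count marks an item as relevant —
#' an item with count 5 is not more relevant than one with count 1; unrated
#' candidates are treated as not relevant.
#'
#' @param test_ratings Data frame (or `"ratings"` subset) with columns
#'   `item` and `rating` for one user, or a named numeric vector.
#' @return Character vector of relevant item ids.
#' @export
binarize_relevance <- function(test_ratings) {
  if (is.numeric(test_ratings)) {
    return(names(test_ratings)[test_ratings > 0])
  }
  unique(test_ratings$item[test_ratings$rating > 0])
}

as_ranked_items <- function(ranked) {
  if (inherits(ranked, "ranked") || is.data.frame(ranked)) ranked$item else ranked
}

#' Top-k ranking quality metrics
#'
#' Standard top-k metrics under binary relevance for a single ranked list
#' (and, for `mrr_at_k()`, a set of per-user lists):
#' precision@k = hits in the top k divided by `k`; recall@k = hits divided
#' by the number of relevant items; F-measure = harmonic mean of the two
#' (0 when both are 0); MRR = mean over users of the reciprocal rank of
#' their first relevant item in the top k (0 when none appears); nDCG =
#' DCG with gain `1/log2(rank + 1)` for each relevant item, normalized by
#' the DCG of the ideal list that puts all relevant items first.
#'
#' @param ranked A `"ranked"` object (or character vector of item ids in
#'   rank order).
#' @param relevant Character vector of relevant item ids (non-empty for
#'   `recall_at_k()` / `ndcg_at_k()`).
#' @param k Cutoff, `k >= 1`.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' precision_at_k(c("a", "x", "b", "y"), c("a", "b"), k = 4)  # 0.5
#' ndcg_at_k(c("a", "x", "b"), c("a", "b"), k = 3)
#' @export
precision_at_k <- function(ranked, relevant, k) {
  stopifnot(k >= 1)
  ids <- as_ranked_items(ranked)
  sum(utils::head(ids, k) %in% relevant) / k
}

#' @rdname precision_at_k
#' @export
recall_at_k <- function(ranked, relevant, k) {
  stopifnot(k >= 1)
  if (!length(relevant)) stop("recall undefined for an empty relevant set")
  ids <- as_ranked_items(ranked)
  sum(utils::head(ids, k) %in% relevant) / length(relevant)
}

#' @rdname precision_at_k
#' @param p,r Precision and recall values in `[0, 1]`.
#' @export
f_measure_at_k <- function(p, r) {
  stopifnot(p >= 0, p <= 1, r >= 0, r <= 1)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' @rdname precision_at_k
#' @param ranked_lists List of ranked lists, one per user.
#' @param relevant_sets List of relevant-id vectors, parallel to
#'   `ranked_lists`.
#' @export
mrr_at_k <- function(ranked_lists, relevant_sets, k) {
  stopifnot(k >= 1, length(ranked_lists) == length(relevant_sets),
            length(ranked_lists) >= 1)
  rr <- mapply(function(ranked, relevant) {
    ids <- utils::head(as_ranked_items(ranked), k)
    hit <- which(ids %in% relevant)
    if (length(hit)) 1 / hit[1L] else 0
  }, ranked_lists, relevant_sets)
  mean(rr)
}

#' @rdname precision_at_k
#' @export
ndcg_at_k <- function(ranked, relevant, k) {
  stopifnot(k >= 1)
  if (!length(relevant)) stop("nDCG undefined for an empty relevant set")
  ids <- utils::head(as_ranked_items(ranked), k)
  gain <- as.numeric(ids %in% relevant)
  pos <- seq_along(gain)
  dcg <- sum(gain / log2(pos + 1))
  ideal_len <- min(k, length(relevant))
  idcg <- sum(1 / log2(seq_len(ideal_len) + 1))
  dcg / idcg
}

# All five metrics for k = 1..k_max in one pass (per user).
# Returns a k_max x 5 matrix: precision, recall, f_measure, rr, ndcg.
ranking_metrics <- function(ranked_items, relevant, k_max) {
  rel <- as.numeric(ranked_items %in% relevant)
  if (length(rel) < k_max) rel <- c(rel, numeric(k_max - length(rel)))
  rel <- rel[seq_len(k_max)]
  ks <- seq_len(k_max)
  hits <- cumsum(rel)
  precision <- hits / ks
  recall <- hits / length(relevant)
  f <- ifelse(precision + recall == 0, 0,
              2 * precision * recall / (precision + recall))
  first <- which(rel > 0)[1L]
  rr <- if (is.na(first)) numeric(k_max) else ifelse(ks >= first, 1 / first, 0)
  disc <- 1 / log2(ks + 1)
  dcg <- cumsum(rel * disc)
  idcg <- cumsum(ifelse(ks <= length(relevant), disc, 0))
  cbind(precision = precision, recall = recall, f_measure = f,
        rr = rr, ndcg = dcg / idcg)
}

#' Cross-validated top-k evaluation of recommendation algorithms
#'
#' Runs the full offline protocol for one or more algorithms over shared
#' folds: per fold, fit the collaborative filter on the training ratings
#' (when the algorithm has a CF part), score every candidate test item for
#' every test user, fuse and rank, and compute precision, recall,
#' F-measure, MRR and nDCG at `k = 1..k_max`. Metrics are macro-averaged:
#' mean over a fold's evaluable users, then mean over folds. Test users
#' with no relevant item in a fold (or that cannot be scored, e.g. no train
#' items left) are excluded from that fold's averages; exclusion counts are
#' attached to the report.
#'
#' Sharing folds and CF fits across algorithms makes comparisons paired:
#' `"ALS"` and `"ALS_ONTO_LIN_m2"` in the same call rank the exact same
#' candidate scores on the CF side.
#'
#' @param algorithms Character vector of [algorithm_names()].
#' @param data A `"ratings"` object.
#' @param onto An `"ontology"` (required when any algorithm has a
#'   content-based part and `store` is `NULL`).
#' @param store Optional prebuilt `"sim_cache"` over the item universe.
#' @param q,seed Fold count and seed for [split_folds()]; `seed` also seeds
#'   CF training.
#' @param k_max Largest list size evaluated.
#' @param n_most_similar ONTO neighborhood size.
#' @param factors,alpha,lambda,lr,epochs,iterations CF hyperparameters.
#' @param policy,bpr_shift,cb_only_fallback Scoring policy flags.
#' @param keep_recommendations If `TRUE`, attach per-user ranked lists
#'   (with score components) as attribute `"recommendations"`.
#' @return Object of class `"eval_report"`: long data frame
#'   `algorithm, fold, k, metric, value` with attributes `summary`
#'   (cross-fold means) and `excluded` (per-fold exclusion counts).
#' @export
evaluate_run <- function(algorithms, data, onto = NULL, store = NULL,
                         q = 5L, seed = 1L, k_max = 20L, n_most_similar = 5,
                         factors = 32L, alpha = 40, lambda = 0.01,
                         lr = 0.01, epochs = 100L, iterations = 15L,
                         policy = "exclude", bpr_shift = FALSE,
                         cb_only_fallback = FALSE,
                         keep_recommendations = FALSE) {
  specs <- lapply(algorithms, parse_algorithm)
  names(specs) <- algorithms
  need_cb <- any(!vapply(specs, function(s) is.null(s$measure), logical(1L)))
  if (need_cb && is.null(store)) {
    if (is.null(onto)) stop("content-based algorithms need an ontology or a store")
    store <- build_sim_cache(onto, compute_ic(onto), attr(data, "items"))
  }
  folds <- split_folds(data, q = q, seed = seed)
  metric_names <- c("precision", "recall", "f_measure", "mrr", "ndcg")
  rows <- list()
  excluded <- list()
  recs <- list()
  for (fs in folds) {
    in_test <- data$user %in% fs$test_users & data$item %in% fs$test_items
    train <- ratings_dataset(as.data.frame(data)[!in_test, , drop = FALSE])
    test <- as.data.frame(data)[in_test, , drop = FALSE]
    cf_fits <- list()
    for (cf in unique(unlist(lapply(specs, `[[`, "cf")))) {
      cf_fits[[cf]] <- if (cf == "ALS") {
        fit_als(train, factors = factors, alpha = alpha, lambda = lambda,
                iterations = iterations, seed = seed)
      } else {
        fit_bpr(train, factors = factors, lr = lr, lambda = lambda,
                epochs = epochs, seed = seed)
      }
    }
    train_items_of <- split(train$item, factor(train$user, levels = fs$test_users))
    relevant_of <- split(test$item[test$rating > 0],
                         factor(test$user[test$rating > 0], levels = fs$test_users))
    # per-user score vectors, computed once per side and reused by hybrids
    for (alg in algorithms) {
      spec <- specs[[alg]]
      acc <- matrix(0, k_max, 5L,
                    dimnames = list(NULL, c("precision", "recall", "f_measure",
                                            "rr", "ndcg")))
      n_eval <- 0L; n_skip <- 0L
      fold_recs <- list()
      for (u in fs$test_users) {
        relevant <- relevant_of[[u]]
        if (is.null(relevant) || !length(relevant)) { n_skip <- n_skip + 1L; next }
        s_cf <- s_cb <- NULL
        if (!is.null(spec$cf)) {
          if (!(u %in% rownames(cf_fits[[spec$cf]]$user_factors))) {
            n_skip <- n_skip + 1L; next
          }
          s_cf <- score_items_cf(cf_fits[[spec$cf]], u, fs$test_items,
                                 policy = policy, bpr_shift = bpr_shift)
        }
        if (!is.null(spec$measure)) {
          tr <- train_items_of[[u]]
          tr <- tr[tr %in% store$items]
          if (!length(tr)) { n_skip <- n_skip + 1L; next }
          cand <- fs$test_items[fs$test_items %in% store$items]
          s_cb <- suppressWarnings(
            onto_score_vector(store, tr, cand, spec$measure, n_most_similar))
        }
        combined <- if (!is.null(s_cf) && !is.null(s_cb)) {
          fuse_scores(s_cf, s_cb, spec$metric, cb_only_fallback)
        } else if (!is.null(s_cf)) s_cf else s_cb
        ranked <- rank_items(combined)
        acc <- acc + ranking_metrics(ranked$item, relevant, k_max)
        n_eval <- n_eval + 1L
        if (keep_recommendations) {
          rec <- ranked
          rec$user <- u
          rec$s_cf <- if (is.null(s_cf)) NA_real_ else unname(s_cf[rec$item])
          rec$s_cb <- if (is.null(s_cb)) NA_real_ else unname(s_cb[rec$item])
          rec$combined <- rec$score
          rec$algorithm <- alg
          fold_recs[[u]] <- as.data.frame(rec)[, c("user", "rank", "item",
                                                   "s_cf", "s_cb", "combined",
                                                   "algorithm")]
        }
      }
      if (n_eval == 0L) {
        warning("fold ", fs$fold, ", ", alg, ": no evaluable test user")
        next
      }
      m <- acc / n_eval
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, fold = fs$fold, k = rep(seq_len(k_max), 5L),
        metric = rep(metric_names, each = k_max),
        value = c(m[, "precision"], m[, "recall"], m[, "f_measure"],
                  m[, "rr"], m[, "ndcg"]),
        stringsAsFactors = FALSE)
      excluded[[length(excluded) + 1L]] <- data.frame(
        algorithm = alg, fold = fs$fold, users_evaluated = n_eval,
        users_excluded = n_skip, stringsAsFactors = FALSE)
      if (keep_recommendations) {
        recs[[paste(alg, fs$fold, sep = ".")]] <-
          do.call(rbind, c(fold_recs, list(make.row.names = FALSE)))
      }
    }
  }
  report <- do.call(rbind, rows)
  summary_df <- stats::aggregate(value ~ algorithm + k + metric, report, mean)
  summary_df <- summary_df[order(summary_df$algorithm, summary_df$metric,
                                 summary_df$k), , drop = FALSE]
  rownames(summary_df) <- NULL
  structure(report,
            summary = summary_df,
            excluded = do.call(rbind, excluded),
            recommendations = if (keep_recommendations) recs,
            class = c("eval_report", "data.frame"))
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Top-k evaluation report:", length(unique(x$algorithm)), "algorithm(s),",
      length(unique(x$fold)), "fold(s), k = 1..", max(x$k), "\n", sep = " ")
  show <- s[s$k %in% c(1, 5, 10, max(x$k)), ]
  wide <- stats::reshape(show, idvar = c("algorithm", "k"), timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Cross-fold mean of one metric at one cutoff
#'
#' @param report An `"eval_report"`.
#' @param algorithm,metric,k Selection.
#' @return Numeric scalar.
#' @export
report_value <- function(report, algorithm, metric, k) {
  s <- attr(report, "summary")
  v <- s$value[s$algorithm == algorithm & s$metric == metric & s$k == k]
  if (!length(v)) stop("no such cell in report: ", algorithm, "/", metric, "/k=", k)
  v
}
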