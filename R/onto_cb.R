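#' Content-based semantic score for candidate items
#'
#' The ONTO scorer rates each candidate (test) item for a user as the
#' arithmetic mean of its semantic similarities to the user's known (train)
#' items, optionally restricted to the `n` most similar of them. Because it
#' uses only the ontology and the user's own history, a candidate can be
#' scored even if nobody in the dataset ever rated it — content-based
#' scoring has no item cold-start. No rating of any candidate item is
#' consulted.
#'
#' With `n = 1` the score is the maximum similarity to the train set; with
#' `n = Inf` (or `"all"`) it is the plain mean over all train items. Ties at
#' the `n` cutoff are resolved by descending similarity then ascending item
#' id, so results are deterministic.
#'
#' @param store A `"sim_cache"` covering all train and test items.
#' @param train_items Non-empty character vector: the user's known items.
#' @param test_items Character vector of candidate items to score.
#' @param measure `"resnik"`, `"lin"` or `"jc"`.
#' @param n Number of most-similar train items to average
#'   (`>= 1`, `Inf`, or `"all"`). Default 5, the setting that performed best
#'   in ranked evaluation.
#' @return Data frame with one row per test item: `item`, `score`, `n_used`
#'   (the number of train items actually averaged) and `measure`.
#' @examples
#' toy <- fixture_toy()
#' ic <- compute_ic(toy$ontology)
#' store <- build_sim_cache(toy$ontology, ic, toy$ontology$ids)
#' score_items_onto(store, c("T:C", "T:B"), c("T:D", "T:A"), "lin", n = "all")
#' @export
score_items_onto <- function(store, train_items, test_items,
                             measure = c("resnik", "lin", "jc"), n = 5) {
  measure <- match.arg(measure)
  if (identical(n, "all") || identical(n, "ALL")) n <- Inf
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  train_items <- unique(train_items)
  if (!length(train_items)) stop("empty train set")
  known <- train_items %in% store$items
  if (any(!known)) {
    warning("train item(s) not in similarity store, dropped: ",
            paste(train_items[!known], collapse = ", "))
    train_items <- train_items[known]
    if (!length(train_items)) stop("empty train set after dropping unknown items")
  }
  ord0 <- order(train_items)   # ascending-id tie-break baseline
  train_items <- train_items[ord0]
  scores <- numeric(length(test_items))
  n_used <- integer(length(test_items))
  for (t in seq_along(test_items)) {
    sims <- get_similarity(store, test_items[t], train_items, measure)
    keep <- min(n, length(sims))
    # ties at the cutoff: descending similarity, then ascending item id
    # (train_items is sorted, so positional order is id order)
    top <- sims[order(-sims, seq_along(sims), method = "radix")[seq_len(keep)]]
    scores[t] <- mean(top)
    n_used[t] <- keep
  }
  data.frame(item = test_items, score = scores, n_used = n_used,
             measure = measure, stringsAsFactors = FALSE, row.names = NULL)
}

# Named-vector convenience used by the evaluation loop.
onto_score_vector <- function(store, train_items, test_items, measure, n) {
  sc <- score_items_onto(store, train_items, test_items, measure, n)
  stats::setNames(sc$score, sc$item)
}
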