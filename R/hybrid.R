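#' Hybrid score fusion rules
#'
#' Two weighted rules fuse a collaborative-filtering score and a
#' content-based score for the same candidate item: the product rule
#' (`combine_metric1`) multiplies them, letting an item that is outstanding
#' on either side surface, while the mean rule (`combine_metric2`) averages
#' them. The product rule is invariant to rescaling either side by a
#' positive constant; the mean rule is not, so a measure with large raw
#' magnitudes (e.g. unbounded Resnik scores versus sub-1 ALS scores)
#' dominates the mean.
#'
#' @param s_cf,s_cb Finite numeric score vectors (recycled).
#' @return Numeric vector of combined scores.
#' @examples
#' combine_metric1(0.5, 0.4)  # 0.2
#' combine_metric2(0.5, 0.4)  # 0.45
#' @export
combine_metric1 <- function(s_cf, s_cb) {
  stopifnot(all(is.finite(s_cf)), all(is.finite(s_cb)))
  s_cf * s_cb
}

#' @rdname combine_metric1
#' @export
combine_metric2 <- function(s_cf, s_cb) {
  stopifnot(all(is.finite(s_cf)), all(is.finite(s_cb)))
  (s_cf + s_cb) / 2
}

#' Rank scored items into a recommendation list
#'
#' Stable descending sort by score; exact ties are broken by ascending item
#' id so every ranking is reproducible.
#'
#' @param scores Named numeric vector (names are item ids).
#' @return Object of class `"ranked"`: data frame with `rank`, `item`,
#'   `score`, scores non-increasing down the list.
#' @export
rank_items <- function(scores) {
  stopifnot(all(is.finite(scores)))
  if (!length(scores)) {
    out <- data.frame(rank = integer(0), item = character(0), score = numeric(0))
    return(structure(out, class = c("ranked", "data.frame")))
  }
  o <- order(-scores, names(scores), method = "radix")
  out <- data.frame(rank = seq_along(o), item = names(scores)[o],
                    score = unname(scores[o]), stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, class = c("ranked", "data.frame"))
}

# Table-1 style algorithm vocabulary ------------------------------------

#' Algorithm names understood by the evaluation protocol
#'
#' The 17 evaluated variants: the two collaborative filters alone, the three
#' content-based scorers alone, and every CF x measure x fusion-rule hybrid.
#'
#' @return Character vector of valid algorithm names.
#' @export
algorithm_names <- function() {
  measures <- c("JC", "LIN", "RESNIK")
  c("ALS", "BPR",
    paste0("ONTO_", measures),
    as.vector(outer(
      as.vector(outer(c("ALS", "BPR"), paste0("ONTO_", measures), paste, sep = "_")),
      c("m1", "m2"), paste, sep = "_")))
}

#' Parse an algorithm name into its components
#'
#' @param name One algorithm name, e.g. `"ALS_ONTO_LIN_m2"`.
#' @return List with `cf` (`"ALS"`, `"BPR"` or `NULL`), `measure`
#'   (`"resnik"`, `"lin"`, `"jc"` or `NULL`) and `metric` (`"m1"`, `"m2"`
#'   or `NULL`).
#' @export
parse_algorithm <- function(name) {
  valid <- algorithm_names()
  if (length(name) != 1L || !(name %in% valid)) {
    stop("unknown algorithm '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  parts <- strsplit(name, "_", fixed = TRUE)[[1L]]
  cf <- if (parts[1L] %in% c("ALS", "BPR")) parts[1L] else NULL
  measure <- if ("ONTO" %in% parts) tolower(parts[which(parts == "ONTO") + 1L]) else NULL
  metric <- if (parts[length(parts)] %in% c("m1", "m2")) parts[length(parts)] else NULL
  list(cf = cf, measure = measure, metric = metric)
}

# Fuse named score vectors according to the hybrid metric; items scored by
# only one side are dropped unless cb_only_fallback keeps CB-only items.
fuse_scores <- function(s_cf, s_cb, metric, cb_only_fallback = FALSE) {
  common <- intersect(names(s_cf), names(s_cb))
  combined <- if (metric == "m1") {
    combine_metric1(s_cf[common], s_cb[common])
  } else {
    combine_metric2(s_cf[common], s_cb[common])
  }
  if (cb_only_fallback) {
    only_cb <- setdiff(names(s_cb), names(s_cf))
    combined <- c(combined, s_cb[only_cb])
  }
  combined
}

#' Fit a hybrid semantic recommender
#'
#' Convenience front end tying the modules together: fits the requested
#' collaborative filter on the ratings (when the algorithm has a CF part),
#' builds or reuses a pairwise similarity cache over the rated item universe
#' (when it has a content-based part), and returns a model whose
#' [predict.hybrid_recommender()] method produces a ranked recommendation
#' list for a user against a candidate set.
#'
#' @param data A `"ratings"` object.
#' @param onto An `"ontology"` object (required for content-based parts).
#' @param algorithm One of [algorithm_names()].
#' @param store Optional prebuilt `"sim_cache"`; built on demand otherwise.
#' @param n_most_similar ONTO neighborhood size.
#' @param factors,alpha,lambda,lr,epochs,iterations CF hyperparameters.
#' @param policy,bpr_shift,cb_only_fallback Scoring policy flags; see
#'   [score_items_cf()] and the fusion rules.
#' @param seed Integer seed for CF training.
#' @return Object of class `"hybrid_recommender"`.
#' @export
hybrid_recommender <- function(data, onto = NULL, algorithm = "ALS_ONTO_LIN_m2",
                               store = NULL, n_most_similar = 5,
                               factors = 32L, alpha = 40, lambda = 0.01,
                               lr = 0.01, epochs = 100L, iterations = 15L,
                               policy = "exclude", bpr_shift = FALSE,
                               cb_only_fallback = FALSE, seed = 1L) {
  spec <- parse_algorithm(algorithm)
  model <- NULL
  if (!is.null(spec$cf)) {
    model <- if (spec$cf == "ALS") {
      fit_als(data, factors = factors, alpha = alpha, lambda = lambda,
              iterations = iterations, seed = seed)
    } else {
      fit_bpr(data, factors = factors, lr = lr, lambda = lambda,
              epochs = epochs, seed = seed)
    }
  }
  if (!is.null(spec$measure)) {
    if (is.null(store)) {
      if (is.null(onto)) stop("content-based algorithms need an ontology or a store")
      ic <- compute_ic(onto)
      store <- build_sim_cache(onto, ic, attr(data, "items"))
    }
  }
  structure(list(algorithm = algorithm, spec = spec, data = data,
                 cf_model = model, store = store,
                 n_most_similar = n_most_similar, policy = policy,
                 bpr_shift = bpr_shift, cb_only_fallback = cb_only_fallback,
                 seed = seed),
            class = "hybrid_recommender")
}

#' @exportS3Method base::print
print.hybrid_recommender <- function(x, ...) {
  cat("Hybrid semantic recommender:", x$algorithm, "\n")
  if (!is.null(x$cf_model)) print(x$cf_model)
  if (!is.null(x$store)) print(x$store)
  invisible(x)
}

#' Ranked recommendations for one user
#'
#' @param object A `"hybrid_recommender"`.
#' @param user User id.
#' @param candidates Candidate item ids; defaults to every item the user has
#'   not rated.
#' @param ... Unused.
#' @return A `"ranked"` data frame (see [rank_items()]) with `s_cf` / `s_cb`
#'   columns where the algorithm has those parts.
#' @export
predict.hybrid_recommender <- function(object, user, candidates = NULL, ...) {
  data <- object$data
  if (is.null(candidates)) {
    rated <- data$item[data$user == user]
    candidates <- setdiff(attr(data, "items"), rated)
  }
  spec <- object$spec
  s_cf <- s_cb <- NULL
  if (!is.null(spec$cf)) {
    s_cf <- score_items_cf(object$cf_model, user, candidates,
                           policy = object$policy, bpr_shift = object$bpr_shift)
  }
  if (!is.null(spec$measure)) {
    train_items <- data$item[data$user == user & !(data$item %in% candidates)]
    if (!length(train_items)) train_items <- data$item[data$user == user]
    s_cb <- onto_score_vector(object$store, train_items, candidates,
                              spec$measure, object$n_most_similar)
  }
  combined <- if (!is.null(s_cf) && !is.null(s_cb)) {
    fuse_scores(s_cf, s_cb, spec$metric, object$cb_only_fallback)
  } else if (!is.null(s_cf)) s_cf else s_cb
  out <- rank_items(combined)
  if (!is.null(s_cf)) out$s_cf <- unname(s_cf[out$item])
  if (!is.null(s_cb)) out$s_cb <- unname(s_cb[out$item])
  out
}
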