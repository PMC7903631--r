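#' Generate a random ontology DAG
#'
#' Builds a single-root, acyclic `is_a` hierarchy emulating the shape of a
#' chemical-entity ontology: terms are created in order, and each non-root
#' term attaches to 1..`max_parents` previously created terms, with
#' attachment biased towards recent terms so the graph grows deep rather
#' than star-shaped. A fraction of terms receives a secondary accession
#' (`alt_id`), as real ontologies accumulate through term merges. Output is
#' fully determined by `seed`.
#'
#' @param n_terms Number of terms (`>= 2`).
#' @param max_parents Maximum parents per non-root term.
#' @param alt_id_frac Fraction of non-root terms given a secondary id.
#' @param seed Integer seed.
#' @return An `"ontology"` object; serialize with [obo_text()] /
#'   [write_obo()].
#' @export
gen_ontology <- function(n_terms, max_parents = 2L, alt_id_frac = 0.05,
                         seed = 1L) {
  stopifnot(n_terms >= 2L, max_parents >= 1L)
  set.seed(seed)
  ids <- sprintf("T:%04d", seq_len(n_terms))
  parents <- stats::setNames(rep(list(character(0)), n_terms), ids)
  for (i in 2:n_terms) {
    k <- sample.int(min(max_parents, i - 1L), 1L)
    # recency-weighted attachment -> deeper hierarchies
    w <- seq_len(i - 1L)
    parents[[i]] <- ids[sample.int(i - 1L, k, prob = w)]
  }
  alt <- character(0)
  n_alt <- round(alt_id_frac * (n_terms - 1L))
  if (n_alt > 0L) {
    carriers <- sample(ids[-1L], n_alt)
    alt[sprintf("S:%04d", seq_len(n_alt))] <- carriers
  }
  name <- stats::setNames(paste("term", seq_len(n_terms)), ids)
  synonyms <- stats::setNames(rep(list(character(0)), n_terms), ids)
  new_ontology(ids, name, parents, alt, synonyms)
}

#' Serialize an ontology to OBO text
#'
#' Deterministic OBO 1.2 output: terms in id order, tags in fixed order, so
#' equal ontologies serialize to identical bytes.
#'
#' @param onto An `"ontology"` object.
#' @return `obo_text()`: character vector of lines. `write_obo()` writes
#'   them to `path` and returns it invisibly.
#' @export
obo_text <- function(onto) {
  header <- c("format-version: 1.2", "")
  alt_by_term <- if (length(onto$alt)) {
    split(names(onto$alt), unname(onto$alt))
  } else list()
  blocks <- lapply(onto$ids, function(id) {
    c("[Term]",
      paste0("id: ", id),
      paste0("name: ", onto$name[[id]]),
      if (length(alt_by_term[[id]])) paste0("alt_id: ", sort(alt_by_term[[id]])),
      if (length(onto$synonyms[[id]])) {
        paste0("synonym: \"", onto$synonyms[[id]], "\" EXACT []")
      },
      if (length(onto$parents[[id]])) paste0("is_a: ", sort(onto$parents[[id]])),
      "")
  })
  c(header, unlist(blocks, use.names = FALSE))
}

#' @rdname obo_text
#' @param path Output file path.
#' @export
write_obo <- function(onto, path) {
  writeLines(obo_text(onto), path)
  invisible(path)
}

# Descendant-or-self id sets for every term (used for anchor subtrees).
descendant_sets <- function(onto) {
  idx <- stats::setNames(seq_along(onto$ids), onto$ids)
  dsets <- stats::setNames(vector("list", onto$n_terms), onto$ids)
  for (t in rev(onto$topo)) {
    ch <- onto$children[[t]]
    dsets[[t]] <- unique(c(t, unlist(dsets[ch], use.names = FALSE)))
  }
  dsets
}

#' Generate ontology-correlated implicit ratings
#'
#' Emulates the structure of a literature-derived implicit-feedback dataset:
#' every user rates at least `min_items_per_user` items (mirroring datasets
#' filtered to users with at least 20 rated items), ratings are small
#' positive counts dominated by 1s, item popularity is power-law skewed
#' (many items with a single rater, few popular ones), and each user's
#' interests are concentrated in an ontology subtree. A `concentration`
#' fraction of each user's items is drawn from their anchor subtree, the
#' rest from the popularity-skewed global pool; `concentration = 0` removes
#' all ontology signal (negative control), `1` confines users entirely to
#' their subtree.
#'
#' @param onto An `"ontology"` object.
#' @param n_users Number of users.
#' @param n_items Item universe size (`<= n_terms`); items are sampled from
#'   the ontology terms, root excluded.
#' @param min_items_per_user Minimum rated items per user (default 20).
#' @param concentration Fraction in `[0, 1]` of a user's items drawn from
#'   their anchor subtree.
#' @param skew Power-law exponent for global item popularity.
#' @param rating_probs Sampling weights for counts `1..length(rating_probs)`.
#' @param seed Integer seed.
#' @return A `"ratings"` object.
#' @export
gen_ratings <- function(onto, n_users, n_items = NULL,
                        min_items_per_user = 20L, concentration = 0.9,
                        skew = 1, rating_probs = c(0.55, 0.2, 0.12, 0.08, 0.05),
                        seed = 1L) {
  stopifnot(min_items_per_user >= 1L, concentration >= 0, concentration <= 1)
  set.seed(seed)
  pool <- setdiff(onto$ids, onto$roots)
  if (is.null(n_items)) n_items <- length(pool)
  stopifnot(n_items <= length(pool))
  universe <- sort(sample(pool, n_items))
  # power-law popularity over a random item order
  pop <- stats::setNames((seq_len(n_items))^(-skew), sample(universe))
  pop <- pop[universe]
  dsets <- descendant_sets(onto)
  subtree_items <- lapply(dsets, intersect, universe)
  users <- sprintf("U%03d", seq_len(n_users))
  out_user <- character(0); out_item <- character(0)
  for (u in users) {
    n_u <- min_items_per_user + stats::rpois(1L, 2)
    need_sub <- ceiling(concentration * n_u)
    # resample anchors until the subtree can supply the concentrated share
    anchors <- names(subtree_items)[lengths(subtree_items) >= max(need_sub, 2L)]
    anchor <- if (length(anchors)) sample(anchors, 1L) else
      names(which.max(lengths(subtree_items)))
    sub <- subtree_items[[anchor]]
    n_sub <- min(need_sub, length(sub))
    picked <- sample(sub, n_sub, prob = pop[sub])
    rest <- setdiff(universe, picked)
    n_glob <- min(n_u - n_sub, length(rest))
    if (n_glob > 0L) picked <- c(picked, sample(rest, n_glob, prob = pop[rest]))
    out_user <- c(out_user, rep(u, length(picked)))
    out_item <- c(out_item, picked)
  }
  rating <- sample.int(length(rating_probs), length(out_item),
                       replace = TRUE, prob = rating_probs)
  ratings_dataset(data.frame(user = out_user, item = out_item, rating = rating,
                             stringsAsFactors = FALSE))
}

#' Rank-one synthetic preference data
#'
#' Minimal dataset with a single latent axis: each item has a scalar
#' affinity and users pick their observed items with probability
#' proportional to a sharpened affinity, so the item ordering any good
#' ranker should recover is global. Used to exercise pairwise rankers.
#'
#' @param n_users,n_items Dimensions.
#' @param n_pos Observed items per user.
#' @param seed Integer seed.
#' @return List with `ratings` (a `"ratings"` object) and `affinity`
#'   (named numeric, the generating item scores).
#' @export
gen_rank1_ratings <- function(n_users = 30L, n_items = 40L, n_pos = 15L,
                              seed = 7L) {
  stopifnot(n_pos < n_items)
  set.seed(seed)
  items <- sprintf("I%03d", seq_len(n_items))
  users <- sprintf("U%03d", seq_len(n_users))
  affinity <- stats::setNames(stats::runif(n_items), items)
  w <- affinity^3   # sharpen so top items are consistently chosen
  out <- do.call(rbind, lapply(users, function(u) {
    picked <- sample(items, n_pos, prob = w)
    data.frame(user = u, item = picked,
               rating = sample.int(3L, n_pos, replace = TRUE,
                                   prob = c(0.7, 0.2, 0.1)),
               stringsAsFactors = FALSE)
  }))
  list(ratings = ratings_dataset(out), affinity = affinity)
}

#' Fixed toy fixture: five-term DAG and three-user ratings
#'
#' The diamond-free toy used throughout examples and tests: root `T:R`;
#' `T:A`, `T:B` children of the root; `T:C`, `T:D` children of `T:A`.
#' `T:C` carries the secondary id `S:C9`. Byte-stable across calls.
#'
#' @return List with `ontology` (an `"ontology"`) and `ratings`
#'   (a `"ratings"` object).
#' @examples
#' toy <- fixture_toy()
#' compute_ic(toy$ontology)[["T:R"]]  # 0
#' @export
fixture_toy <- function() {
  ids <- c("T:R", "T:A", "T:B", "T:C", "T:D")
  parents <- list(`T:R` = character(0), `T:A` = "T:R", `T:B` = "T:R",
                  `T:C` = "T:A", `T:D` = "T:A")
  name <- stats::setNames(c("root", "alpha", "beta", "gamma", "delta"), ids)
  synonyms <- stats::setNames(rep(list(character(0)), 5L), ids)
  onto <- new_ontology(ids, name, parents, alt = c(`S:C9` = "T:C"), synonyms)
  ratings <- ratings_dataset(data.frame(
    user = c("u1", "u1", "u1", "u2", "u2", "u3", "u3", "u3"),
    item = c("T:A", "T:C", "T:D", "T:B", "T:C", "T:A", "T:B", "T:D"),
    rating = c(2, 1, 1, 3, 1, 1, 1, 2),
    stringsAsFactors = FALSE))
  list(ontology = onto, ratings = ratings)
}
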