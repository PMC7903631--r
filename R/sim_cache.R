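#' Precompute all pairwise semantic similarities for an item universe
#'
#' Scoring a candidate item against a user's history needs thousands of
#' pairwise similarities; computing them on demand dominates runtime. This
#' builder computes Resnik, Lin and Jiang-Conrath for every unordered pair
#' of the item universe once (self-pairs included), optionally across
#' several worker processes, and returns an indexed in-memory store that
#' [write_sim_cache()] can persist to a single TSV file.
#'
#' Pairs are enumerated in a fixed canonical order (lexicographic, `item_a
#' <= item_b`) and partitioned deterministically across workers, and the
#' per-pair floating-point path does not depend on the partition, so the
#' resulting store is identical record-for-record for any `workers` value.
#'
#' @param onto An `"ontology"` object.
#' @param ic IC table from [compute_ic()].
#' @param items Character vector of item accessions (primary or secondary).
#' @param workers Number of worker processes (`>= 1`). Forked workers are
#'   used where the platform supports them; otherwise work runs serially,
#'   with identical results.
#' @param strict If `TRUE`, secondary accessions are not resolved.
#' @param on_unresolvable `"error"` (default) aborts naming the offending
#'   ids; `"skip"` drops them with a warning.
#' @param chunk_size Number of pairs per work unit.
#' @return An object of class `"sim_cache"`: item universe, canonical pair
#'   table with columns `item_a`, `item_b`, `resnik`, `lin`, `jc`, and a
#'   pair index for O(1) lookup.
#' @examples
#' toy <- fixture_toy()
#' ic <- compute_ic(toy$ontology)
#' store <- build_sim_cache(toy$ontology, ic, toy$ontology$ids)
#' get_similarity(store, "T:C", "T:D", "resnik")
#' @export
build_sim_cache <- function(onto, ic, items, workers = 1L, strict = FALSE,
                            on_unresolvable = c("error", "skip"),
                            chunk_size = 10000L) {
  on_unresolvable <- match.arg(on_unresolvable)
  stopifnot(workers >= 1L)
  items <- unique(items)
  ok <- vapply(items, function(i) {
    i %in% onto$ids || (!strict && i %in% names(onto$alt))
  }, logical(1L))
  if (any(!ok)) {
    msg <- paste("unresolvable item(s):", paste(items[!ok], collapse = ", "))
    if (on_unresolvable == "error") stop(msg)
    warning(msg, "; skipped")
    items <- items[ok]
  }
  primary <- resolve_id(onto, items, strict = strict)
  # store under the requested labels, computing on the resolved terms
  o <- order(items)
  items <- items[o]
  primary <- primary[o]
  u <- length(items)
  if (u < 1L) stop("empty item universe")
  anc <- ancestor_matrix(onto, primary)
  ic_terms <- ic[colnames(anc)]   # align IC with ancestor-matrix columns
  icv <- ic[primary]
  # canonical pair enumeration: (1,1),(1,2),...,(1,u),(2,2),...
  ii <- rep.int(seq_len(u), times = u - seq_len(u) + 1L)
  jj <- unlist(lapply(seq_len(u), function(i) seq.int(i, u)), use.names = FALSE)
  npair <- length(ii)
  compute_chunk <- function(rows) {
    res <- numeric(length(rows))
    for (r in seq_along(rows)) {
      a <- ii[rows[r]]; b <- jj[rows[r]]
      common <- anc[a, ] & anc[b, ]
      res[r] <- if (any(common)) max(ic_terms[common]) else 0
    }
    res
  }
  chunks <- split(seq_len(npair), ceiling(seq_len(npair) / chunk_size))
  use_fork <- workers > 1L && .Platform$OS.type == "unix"
  shared <- if (use_fork) {
    unlist(parallel::mclapply(chunks, compute_chunk, mc.cores = workers,
                              mc.preschedule = TRUE), use.names = FALSE)
  } else {
    unlist(lapply(chunks, compute_chunk), use.names = FALSE)
  }
  ica <- icv[ii]; icb <- icv[jj]
  denom <- ica + icb
  lin <- ifelse(denom == 0, ifelse(ii == jj, 1, 0), 2 * shared / denom)
  jc <- 1 / (1 + (ica + icb - 2 * shared))
  pairs <- data.frame(item_a = items[ii], item_b = items[jj],
                      resnik = shared, lin = as.numeric(lin),
                      jc = as.numeric(jc),
                      stringsAsFactors = FALSE, row.names = NULL)
  new_sim_cache(items, pairs, self_pairs = TRUE)
}

new_sim_cache <- function(items, pairs, self_pairs = TRUE) {
  structure(list(
    items = items,
    pairs = pairs,
    self_pairs = self_pairs,
    key = paste(pairs$item_a, pairs$item_b, sep = "\t")
  ), class = "sim_cache")
}

#' @exportS3Method base::print
print.sim_cache <- function(x, ...) {
  cat("Similarity cache:", length(x$items), "items,", nrow(x$pairs),
      "pair records (self-pairs", if (x$self_pairs) "included" else "excluded",
      "), measures: resnik, lin, jc\n")
  invisible(x)
}

#' Look up a stored pairwise similarity
#'
#' Symmetric lookup: `get_similarity(store, a, b, m)` equals
#' `get_similarity(store, b, a, m)`. A pair absent from the store is an
#' error (distinct from a stored value of 0). Vectorized over `a`/`b`.
#'
#' @param store A `"sim_cache"`.
#' @param a,b Item accessions (recycled against each other).
#' @param measure One of `"resnik"`, `"lin"`, `"jc"`.
#' @return Numeric vector of stored similarities.
#' @export
get_similarity <- function(store, a, b, measure = c("resnik", "lin", "jc")) {
  measure <- match.arg(measure)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\t")
  pos <- match(key, store$key)
  if (anyNA(pos)) {
    miss <- which(is.na(pos))[1L]
    stop("pair not in similarity store: (", a[miss], ", ", b[miss], ")")
  }
  store$pairs[[measure]][pos]
}

#' Persist / reload a similarity cache
#'
#' The store is a single self-describing TSV file: two comment lines record
#' the item universe and whether self-pairs are stored, followed by the
#' canonical pair table at full double precision.
#'
#' @param store A `"sim_cache"`.
#' @param path File path.
#' @return `write_sim_cache()` returns `path` invisibly; `read_sim_cache()`
#'   returns the reconstructed `"sim_cache"`.
#' @export
write_sim_cache <- function(store, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# items: ", paste(store$items, collapse = ",")),
    paste0("# self_pairs: ", store$self_pairs),
    "item_a\titem_b\tresnik\tlin\tjc"
  ), con)
  p <- store$pairs
  writeLines(paste(p$item_a, p$item_b,
                   formatC(p$resnik, digits = 17, format = "g"),
                   formatC(p$lin, digits = 17, format = "g"),
                   formatC(p$jc, digits = 17, format = "g"), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_sim_cache
#' @export
read_sim_cache <- function(path) {
  hdr <- readLines(path, n = 2L)
  items <- strsplit(sub("^# items: ", "", hdr[1L]), ",", fixed = TRUE)[[1L]]
  self_pairs <- as.logical(sub("^# self_pairs: ", "", hdr[2L]))
  pairs <- utils::read.delim(path, skip = 2L, header = TRUE,
                             colClasses = c("character", "character",
                                            "numeric", "numeric", "numeric"))
  new_sim_cache(items, pairs, self_pairs = self_pairs)
}

#' Latency speedup ratio between two implementations
#'
#' @param latency_baseline,latency_new Positive latencies in seconds.
#' @return `latency_baseline / latency_new`.
#' @examples
#' benchmark_speedup(2.0, 4.0)  # 0.5: the "new" system is slower
#' @export
benchmark_speedup <- function(latency_baseline, latency_new) {
  if (any(latency_baseline <= 0) || any(latency_new <= 0)) {
    stop("latencies must be positive")
  }
  latency_baseline / latency_new
}
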