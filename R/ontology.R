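#' Parse an OBO document into an ontology DAG
#'
#' Reads OBO 1.2/1.4 flat-file text and builds a directed acyclic graph of
#' terms connected by `is_a` edges. Only the tags `id`, `name`, `alt_id`,
#' `synonym`, `is_a` and `is_obsolete` are interpreted; everything else is
#' ignored. Obsolete terms are dropped, together with any `is_a` edge that
#' points at them. Secondary accessions (`alt_id`) are registered in a
#' secondary-to-primary map so that [resolve_id()] can translate them.
#'
#' @param text Character scalar (the whole document) or character vector of
#'   lines in OBO format.
#' @return An object of class `"ontology"`: a list with elements `ids`
#'   (primary term accessions), `name` (named character), `parents` and
#'   `children` (named lists of primary ids), `alt` (named character mapping
#'   secondary to primary ids), `synonyms` (named list), `roots`, `topo`
#'   (a topological order, parents before children) and `n_terms`.
#' @examples
#' obo <- c("[Term]", "id: T1", "name: root",
#'          "[Term]", "id: T2", "is_a: T1",
#'          "[Term]", "id: T3", "is_a: T2")
#' onto <- parse_obo(obo)
#' onto$n_terms
#' @seealso [read_obo()], [ancestors_or_self()], [compute_ic()]
#' @export
parse_obo <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  text <- sub("\r$", "", text)
  # stanza boundaries: lines like [Term], [Typedef], ...
  stanza_at <- grep("^\\[[A-Za-z]+\\]\\s*$", text)
  if (!length(stanza_at)) {
    stop("no [Term] stanzas found in OBO input")
  }
  bounds <- c(stanza_at, length(text) + 1L)
  terms <- list()
  for (s in seq_along(stanza_at)) {
    if (!identical(trimws(text[stanza_at[s]]), "[Term]")) next
    block <- text[seq.int(stanza_at[s] + 1L, bounds[s + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    tag <- sub(":.*$", "", block)
    val <- trimws(sub("^[^:]+:", "", block))
    # strip trailing OBO comments ("! ...") from tag values
    val <- trimws(sub("\\s*!.*$", "", val))
    id <- val[tag == "id"][1L]
    if (is.na(id) || !nzchar(id)) stop("[Term] stanza without an id line")
    if (any(tag == "is_obsolete") && tolower(val[tag == "is_obsolete"][1L]) == "true") {
      next
    }
    nm <- val[tag == "name"][1L]
    syn <- val[tag == "synonym"]
    # synonym values are quoted strings with trailing scope/type info
    syn <- sub('^"(.*)".*$', "\\1", syn)
    terms[[length(terms) + 1L]] <- list(
      id = id,
      name = if (is.na(nm)) id else nm,
      alt_ids = val[tag == "alt_id"],
      synonyms = syn,
      parents = val[tag == "is_a"]
    )
  }
  if (!length(terms)) stop("OBO input contains no non-obsolete [Term] stanzas")
  ids <- vapply(terms, `[[`, "", "id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate primary id(s) in OBO input: ", paste(unique(dup), collapse = ", "))
  }
  known <- ids
  parents <- stats::setNames(vector("list", length(ids)), ids)
  alt <- character(0)
  name <- stats::setNames(character(length(ids)), ids)
  synonyms <- stats::setNames(vector("list", length(ids)), ids)
  for (tm in terms) {
    pr <- tm$parents[nzchar(tm$parents)]
    bad <- setdiff(pr, known)
    if (length(bad)) {
      # is_a pointing at an obsolete (dropped) or undeclared term
      warning("dropping is_a edge(s) from ", tm$id, " to unknown/obsolete term(s): ",
              paste(bad, collapse = ", "))
      pr <- intersect(pr, known)
    }
    parents[[tm$id]] <- unique(pr)
    name[[tm$id]] <- tm$name
    synonyms[[tm$id]] <- tm$synonyms
    if (length(tm$alt_ids)) {
      alt[tm$alt_ids] <- tm$id
    }
  }
  clash <- intersect(names(alt), ids)
  if (length(clash)) {
    stop("alt_id(s) collide with primary id(s): ", paste(clash, collapse = ", "))
  }
  new_ontology(ids, name, parents, alt, synonyms)
}

#' @rdname parse_obo
#' @param path Path to an OBO file on disk.
#' @export
read_obo <- function(path) {
  parse_obo(readLines(path, warn = FALSE))
}

# Assemble and validate an ontology object; detects is_a cycles by Kahn's
# algorithm and reports one offending cycle on failure.
new_ontology <- function(ids, name, parents, alt, synonyms) {
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parents[[id]]) {
      children[[p]] <- c(children[[p]], id)
    }
  }
  # Kahn topological sort over child -> parent edges (parents first)
  n_out <- lengths(parents)   # unresolved parent count per term
  queue <- ids[n_out == 0L]
  topo <- character(0)
  n_left <- stats::setNames(n_out, ids)
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      n_left[[ch]] <- n_left[[ch]] - 1L
      if (n_left[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(ids)) {
    stuck <- setdiff(ids, topo)
    cyc <- find_cycle(stuck, parents)
    stop("is_a cycle detected: ", paste(cyc, collapse = " -> "))
  }
  structure(list(
    ids = ids,
    name = name,
    parents = parents,
    children = children,
    alt = alt,
    synonyms = synonyms,
    roots = ids[lengths(parents) == 0L],
    topo = topo,
    n_terms = length(ids)
  ), class = "ontology")
}

# Walk parent pointers from a stuck node until a node repeats.
find_cycle <- function(stuck, parents) {
  cur <- stuck[[1L]]
  seen <- character(0)
  while (!(cur %in% seen)) {
    seen <- c(seen, cur)
    nxt <- intersect(parents[[cur]], stuck)
    cur <- nxt[[1L]]
  }
  c(seen[which(seen == cur):length(seen)], cur)
}

#' @exportS3Method base::print
print.ontology <- function(x, ...) {
  cat("Ontology DAG:", x$n_terms, "terms,",
      sum(lengths(x$parents)), "is_a edges,",
      length(x$roots), "root(s),",
      length(x$alt), "secondary id(s)\n")
  invisible(x)
}

#' Resolve a primary or secondary accession to its primary id
#'
#' Ontologies carry secondary accessions (`alt_id`) left behind by term
#' merges. Tools that only accept primary ids silently fail on them; by
#' default this function translates a secondary accession to the primary
#' term that superseded it. `strict = TRUE` restricts resolution to primary
#' ids, so secondary accessions raise a not-found error — useful to expose
#' items that would be dropped by primary-id-only pipelines.
#'
#' @param onto An `"ontology"` object.
#' @param id Character vector of accessions (primary or secondary).
#' @param strict If `TRUE`, only primary ids resolve.
#' @return Character vector of primary ids.
#' @export
resolve_id <- function(onto, id, strict = FALSE) {
  out <- ifelse(id %in% onto$ids, id,
                if (strict) NA_character_ else unname(onto$alt[id]))
  if (anyNA(out)) {
    stop("id(s) not found in ontology: ", paste(id[is.na(out)], collapse = ", "))
  }
  out
}

#' Reflexive-transitive ancestor closure of a term
#'
#' @param onto An `"ontology"` object.
#' @param id A single accession (resolved via [resolve_id()]).
#' @param strict Passed to [resolve_id()].
#' @return Character vector of primary ids: the term itself plus every term
#'   reachable through `is_a` edges.
#' @export
ancestors_or_self <- function(onto, id, strict = FALSE) {
  id <- resolve_id(onto, id, strict = strict)
  out <- character(0)
  frontier <- id
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- setdiff(unique(unlist(onto$parents[frontier], use.names = FALSE)), out)
  }
  unique(out)
}

#' Intrinsic information content of every term
#'
#' The information content (IC) of a term is the negative log-probability of
#' meeting that term or one of its descendants in the ontology. With
#' `desc(t)` the number of strict descendants of `t` and `N` the number of
#' terms, `IC(t) = -log2((desc(t) + 1) / N)` in bits. A root subsuming the
#' whole ontology has IC 0; leaves carry the most information. Base-2
#' logarithms are used throughout, which matters downstream because Resnik
#' similarities (raw IC values) enter hybrid score fusion unnormalized.
#'
#' @param onto An `"ontology"` object.
#' @return Named numeric vector of IC values in bits, one per primary id.
#' @examples
#' onto <- fixture_toy()$ontology
#' compute_ic(onto)
#' @export
compute_ic <- function(onto) {
  ndesc <- descendant_counts(onto)
  ic <- -log2((ndesc + 1) / onto$n_terms)
  ic[ic < 0] <- 0   # guard against -0
  ic
}

# Strict-descendant counts via reverse topological accumulation of
# descendant sets (exact under multiple inheritance: sets, not counts,
# are propagated).
descendant_counts <- function(onto) {
  idx <- stats::setNames(seq_along(onto$ids), onto$ids)
  dsets <- vector("list", length(onto$ids))
  for (t in rev(onto$topo)) {
    i <- idx[[t]]
    ch <- onto$children[[t]]
    if (length(ch)) {
      dsets[[i]] <- unique(c(unlist(dsets[idx[ch]], use.names = FALSE), idx[ch]))
    } else {
      dsets[[i]] <- integer(0)
    }
  }
  stats::setNames(lengths(dsets), onto$ids)
}

# n_items x n_terms logical incidence matrix of ancestor-or-self sets;
# shared by the similarity routines and the cache builder.
ancestor_matrix <- function(onto, items) {
  idx <- stats::setNames(seq_along(onto$ids), onto$ids)
  m <- matrix(FALSE, nrow = length(items), ncol = onto$n_terms,
              dimnames = list(items, onto$ids))
  for (i in seq_along(items)) {
    m[i, idx[ancestors_or_self(onto, items[i])]] <- TRUE
  }
  m
}

#' Shared information content of two terms
#'
#' The IC of the most informative common ancestor (MICA): the maximum IC over
#' the intersection of the two terms' ancestor-or-self sets. Terms whose only
#' common ancestor is an all-subsuming root share 0 bits; terms in disjoint
#' components (no common ancestor at all) also share 0.
#'
#' @param onto An `"ontology"` object.
#' @param ic IC table from [compute_ic()].
#' @param a,b Accessions (primary or secondary).
#' @param strict Passed to [resolve_id()].
#' @return Non-negative numeric scalar (bits).
#' @export
shared_ic <- function(onto, ic, a, b, strict = FALSE) {
  common <- intersect(ancestors_or_self(onto, a, strict = strict),
                      ancestors_or_self(onto, b, strict = strict))
  if (!length(common)) return(0)
  max(ic[common])
}

#' Semantic similarity measures between two ontology terms
#'
#' Three IC-based measures:
#' \describe{
#'   \item{`sim_resnik()`}{IC of the most informative common ancestor.
#'     Non-negative and unbounded above (grows with ontology depth).}
#'   \item{`sim_lin()`}{`2 * IC(MICA) / (IC(a) + IC(b))`, in `[0, 1]`.
#'     When both terms have IC 0 (e.g. two roots) the ratio is undefined;
#'     the convention here is 1 for a term with itself and 0 otherwise.}
#'   \item{`sim_jc()`}{Jiang-Conrath is a distance,
#'     `d = IC(a) + IC(b) - 2 * IC(MICA)`, converted to a similarity as
#'     `1 / (1 + d)`, giving range `(0, 1]` with 1 exactly at distance 0.}
#' }
#' All three are symmetric in `a` and `b`.
#'
#' @inheritParams shared_ic
#' @return Numeric scalar.
#' @examples
#' toy <- fixture_toy()
#' ic <- compute_ic(toy$ontology)
#' sim_resnik(toy$ontology, ic, "T:C", "T:D")
#' sim_lin(toy$ontology, ic, "T:C", "T:D")
#' sim_jc(toy$ontology, ic, "T:C", "T:D")
#' @export
sim_resnik <- function(onto, ic, a, b, strict = FALSE) {
  shared_ic(onto, ic, a, b, strict = strict)
}

#' @rdname sim_resnik
#' @export
sim_lin <- function(onto, ic, a, b, strict = FALSE) {
  a <- resolve_id(onto, a, strict = strict)
  b <- resolve_id(onto, b, strict = strict)
  denom <- ic[[a]] + ic[[b]]
  if (denom == 0) return(if (a == b) 1 else 0)
  2 * shared_ic(onto, ic, a, b) / denom
}

#' @rdname sim_resnik
#' @export
sim_jc <- function(onto, ic, a, b, strict = FALSE) {
  a <- resolve_id(onto, a, strict = strict)
  b <- resolve_id(onto, b, strict = strict)
  d <- ic[[a]] + ic[[b]] - 2 * shared_ic(onto, ic, a, b)
  1 / (1 + d)
}
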