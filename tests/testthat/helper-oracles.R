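# Independent brute-force oracles, deliberately written against the raw
# parent lists rather than any package internals.

# Ancestor-or-self set by naive recursion over parent lists.
oracle_ancestors <- function(parents, id) {
  out <- id
  repeat {
    up <- unique(unlist(parents[out], use.names = FALSE))
    grown <- union(out, up)
    if (length(grown) == length(out)) return(out)
    out <- grown
  }
}

# IC by definition: count, for each term, how many OTHER terms have it in
# their ancestor set (i.e. its strict descendants), then -log2((d+1)/N).
oracle_ic <- function(parents) {
  ids <- names(parents)
  anc <- lapply(ids, function(t) oracle_ancestors(parents, t))
  names(anc) <- ids
  vapply(ids, function(t) {
    d <- sum(vapply(ids, function(o) o != t && t %in% anc[[o]], logical(1)))
    -log2((d + 1) / length(ids))
  }, numeric(1))
}

oracle_shared_ic <- function(parents, ic, a, b) {
  common <- intersect(oracle_ancestors(parents, a), oracle_ancestors(parents, b))
  if (!length(common)) 0 else max(ic[common])
}

oracle_sims <- function(parents, a, b) {
  ic <- oracle_ic(parents)
  s <- oracle_shared_ic(parents, ic, a, b)
  denom <- ic[[a]] + ic[[b]]
  lin <- if (denom == 0) (if (a == b) 1 else 0) else 2 * s / denom
  jc <- 1 / (1 + (denom - 2 * s))
  c(resnik = s, lin = lin, jc = jc)
}

# Random DAG as a bare parent-list (independent of gen_ontology): term i
# draws 1-2 parents uniformly among earlier terms.
random_parent_list <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  if (n >= 2) {
    for (i in 2:n) {
      k <- sample.int(min(2L, i - 1L), 1L)
      parents[[i]] <- ids[sample.int(i - 1L, k)]
    }
  }
  parents
}

# Convert a parent-list to an ontology via the package's OBO parser, so the
# comparison also exercises parsing.
ontology_from_parents <- function(parents) {
  lines <- unlist(lapply(names(parents), function(id) {
    c("[Term]", paste0("id: ", id),
      if (length(parents[[id]])) paste0("is_a: ", parents[[id]]))
  }), use.names = FALSE)
  parse_obo(lines)
}

# Reference top-k metrics, computed from first principles per k.
ref_metrics <- function(ranked, relevant, k) {
  topk <- ranked[seq_len(min(k, length(ranked)))]
  hits <- length(intersect(topk, relevant))
  p <- hits / k
  r <- hits / length(relevant)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  first <- match(TRUE, topk %in% relevant)
  rr <- if (is.na(first)) 0 else 1 / first
  dcg <- 0
  for (i in seq_along(topk)) {
    if (topk[i] %in% relevant) dcg <- dcg + 1 / log2(i + 1)
  }
  idcg <- 0
  for (i in seq_len(min(k, length(relevant)))) idcg <- idcg + 1 / log2(i + 1)
  c(precision = p, recall = r, f_measure = f, rr = rr, ndcg = dcg / idcg)
}

# The five-term toy DAG's exact similarity values, derived by hand:
# N = 5; IC(R) = 0, IC(A) = -log2(3/5), IC(B) = IC(C) = IC(D) = log2(5).
toy_expected <- local({
  icA <- -log2(3 / 5)
  icL <- log2(5)
  list(icA = icA, icL = icL,
       resnik_cd = icA,
       lin_cd = 2 * icA / (2 * icL),
       jc_cd = 1 / (1 + 2 * icL - 2 * icA),
       jc_cb = 1 / (1 + 2 * icL))
})
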