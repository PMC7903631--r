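#' End-to-end reproducible experiment run
#'
#' Ties the workflow together: load (or receive) an ontology and a ratings
#' table, build or load the pairwise similarity cache, evaluate the
#' requested algorithms under shared cross-validation folds, and write the
#' long-format report, the cross-fold summary, optional per-fold
#' recommendation lists, and a run manifest recording every parameter, seed
#' and input checksum needed to reproduce the outputs byte-for-byte.
#'
#' @param data A `"ratings"` object, or a path to a `user,item,rating` CSV.
#' @param onto An `"ontology"` object, or a path to an OBO file; optional
#'   when `store` is given or no algorithm has a content-based part.
#' @param algorithms Character vector of [algorithm_names()], or `"all"`
#'   for every variant.
#' @param outdir Output directory (created if missing); `NULL` writes no
#'   files and just returns the report.
#' @param store Optional `"sim_cache"` or path to one written by
#'   [write_sim_cache()].
#' @param write_recommendations Write per-fold, per-algorithm
#'   recommendation CSVs (`user,rank,item,s_cf,s_cb,combined,algorithm`).
#' @param ... Passed to [evaluate_run()] (q, k_max, n_most_similar, CF
#'   hyperparameters, policy flags).
#' @param seed Integer seed governing folding and CF training.
#' @return The `"eval_report"`, invisibly when `outdir` is set.
#' @export
run_experiment <- function(data, onto = NULL, algorithms = "all",
                           outdir = NULL, store = NULL,
                           write_recommendations = FALSE, seed = 1L, ...) {
  if (is.character(data)) data <- read_ratings_csv(data)
  if (is.character(onto)) onto <- read_obo(onto)
  if (is.character(store)) store <- read_sim_cache(store)
  if (identical(algorithms, "all")) algorithms <- algorithm_names()
  lapply(algorithms, parse_algorithm)   # validate names up front
  report <- evaluate_run(algorithms, data, onto = onto, store = store,
                         seed = seed,
                         keep_recommendations = write_recommendations, ...)
  if (is.null(outdir)) return(report)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(report), file.path(outdir, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(attr(report, "summary"), file.path(outdir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  if (write_recommendations) {
    for (nm in names(attr(report, "recommendations"))) {
      utils::write.csv(attr(report, "recommendations")[[nm]],
                       file.path(outdir, paste0("recommendations_", nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  manifest <- list(
    algorithms = algorithms,
    seed = seed,
    parameters = list(...),
    n_users = length(attr(data, "users")),
    n_items = length(attr(data, "items")),
    n_ratings = nrow(data),
    ratings_checksum = dataset_checksum(data),
    ontology_checksum = if (!is.null(onto)) ontology_checksum(onto)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

# Order-independent content checksums (no file needed): a digest of the
# serialized canonical representation via a small FNV-1a fold.
dataset_checksum <- function(data) {
  d <- as.data.frame(data)
  d <- d[order(d$user, d$item), ]
  text_checksum(paste(d$user, d$item, d$rating, sep = ",", collapse = ";"))
}

ontology_checksum <- function(onto) {
  text_checksum(paste(obo_text(onto), collapse = "\n"))
}

text_checksum <- function(s) {
  b <- as.integer(charToRaw(s))
  h <- 2166136261
  for (x in b) {
    h <- bitwXor(as.integer(h %% 2^31), x) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
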