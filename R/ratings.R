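#' Implicit-feedback ratings dataset
#'
#' Validates and wraps a `<user, item, rating>` triple table where ratings
#' are positive counts of interactions (for literature-derived data, the
#' number of articles a researcher wrote about a compound). Each
#' (user, item) pair may appear at most once.
#'
#' @param df Data frame with columns `user`, `item`, `rating`.
#' @return Object of class `"ratings"`: the validated data frame plus
#'   `users` and `items` index vectors as attributes.
#' @export
ratings_dataset <- function(df) {
  need <- c("user", "item", "rating")
  if (!all(need %in% names(df))) {
    stop("ratings table must have columns: ", paste(need, collapse = ", "))
  }
  df <- data.frame(user = as.character(df$user),
                   item = as.character(df$item),
                   rating = as.numeric(df$rating),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$rating)) || any(df$rating <= 0)) {
    stop("ratings must be positive finite counts")
  }
  key <- paste(df$user, df$item, sep = "\t")
  if (anyDuplicated(key)) {
    stop("duplicate (user, item) pair(s) in ratings table")
  }
  structure(df,
            users = sort(unique(df$user)),
            items = sort(unique(df$item)),
            class = c("ratings", "data.frame"))
}

#' @rdname ratings_dataset
#' @param path Path to a CSV file with header `user,item,rating`.
#' @export
read_ratings_csv <- function(path) {
  ratings_dataset(utils::read.csv(path, colClasses = c("character", "character", "numeric")))
}

#' @rdname ratings_dataset
#' @param x A `"ratings"` object.
#' @export
write_ratings_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("user", "item", "rating")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @exportS3Method base::print
print.ratings <- function(x, ...) {
  cat("Implicit ratings:", nrow(x), "triples,",
      length(attr(x, "users")), "users,",
      length(attr(x, "items")), "items\n")
  invisible(x)
}

# Sparse user x item count matrix (dgCMatrix) with dimnames.
ratings_matrix <- function(data) {
  users <- attr(data, "users")
  items <- attr(data, "items")
  Matrix::sparseMatrix(i = match(data$user, users),
                       j = match(data$item, items),
                       x = data$rating,
                       dims = c(length(users), length(items)),
                       dimnames = list(users, items))
}
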