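#' Alternating least squares for implicit feedback
#'
#' Factorizes the user-item interaction matrix under the confidence-weighted
#' model for implicit data: every cell carries a binary preference
#' `p_ui = 1` if the count `r_ui > 0` (else 0) and a confidence
#' `c_ui = 1 + alpha * r_ui`. The loss is
#' `sum_ui c_ui * (p_ui - x_u' y_i)^2 + lambda * (sum ||x_u||^2 + sum ||y_i||^2)`,
#' minimized by alternating exact least-squares solves for the user and item
#' factor matrices. Each full sweep can only decrease the objective.
#'
#' Users (or items) with no observed interactions get the zero vector from
#' their ridge-regularized solve. Initialization is uniform on
#' `(0, 1/sqrt(factors))` under the given seed, so runs are reproducible.
#'
#' @param data A `"ratings"` object.
#' @param factors Latent dimension (the reference configuration for
#'   literature-scale data is 150; scale down for small matrices).
#' @param alpha Confidence slope on raw counts.
#' @param lambda Ridge penalty (> 0).
#' @param iterations Number of full alternating sweeps.
#' @param seed Integer seed for initialization.
#' @return Object of class `c("als_model", "factor_model")` with
#'   `user_factors`, `item_factors` (dimnamed matrices), the hyperparameters
#'   and `objective`, the loss after each sweep.
#' @examples
#' toy <- fixture_toy()
#' m <- fit_als(toy$ratings, factors = 2, iterations = 5, seed = 1)
#' all(diff(m$objective) <= 1e-8)
#' @export
fit_als <- function(data, factors = 150L, alpha = 40, lambda = 0.01,
                    iterations = 15L, seed = 1L) {
  stopifnot(inherits(data, "ratings"), factors >= 1L, lambda > 0, iterations >= 1L)
  if (nrow(data) == 0L) stop("empty ratings dataset")
  R <- ratings_matrix(data)
  n_u <- nrow(R); n_i <- ncol(R); f <- as.integer(factors)
  set.seed(seed)
  X <- matrix(stats::runif(n_u * f, 0, 1 / sqrt(f)), n_u, f)
  Y <- matrix(stats::runif(n_i * f, 0, 1 / sqrt(f)), n_i, f)
  Rt <- Matrix::t(R)
  obj <- numeric(iterations)
  for (it in seq_len(iterations)) {
    X <- als_half_sweep(R, Y, alpha, lambda, f)
    Y <- als_half_sweep(Rt, X, alpha, lambda, f)
    obj[it] <- als_objective(R, X, Y, alpha, lambda)
    if (!is.finite(obj[it])) stop("non-finite objective at sweep ", it)
  }
  dimnames(X) <- list(rownames(R), NULL)
  dimnames(Y) <- list(colnames(R), NULL)
  structure(list(algorithm = "ALS", user_factors = X, item_factors = Y,
                 factors = f, alpha = alpha, lambda = lambda,
                 iterations = iterations, seed = seed, objective = obj),
            class = c("als_model", "factor_model"))
}

# Solve all rows of one side given the other side fixed.
# For row u with observed columns J and counts r:
#   (Y'Y + Y_J' diag(alpha r) Y_J + lambda I) x = Y_J' (1 + alpha r)
als_half_sweep <- function(R, Y, alpha, lambda, f) {
  YtY <- crossprod(Y)
  ridge <- diag(lambda, f)
  out <- matrix(0, nrow(R), f)
  for (u in seq_len(nrow(R))) {
    row <- R[u, ]
    j <- which(row != 0)
    if (!length(j)) next     # b = 0 => ridge solve yields the zero vector
    r <- row[j]
    Yj <- Y[j, , drop = FALSE]
    A <- YtY + crossprod(Yj, Yj * (alpha * r)) + ridge
    b <- crossprod(Yj, 1 + alpha * r)
    out[u, ] <- solve(A, b)
  }
  out
}

# Full confidence-weighted objective, including the c=1 term on every
# unobserved cell: ||X Y'||_F^2 is obtained from the factor Grams, then the
# observed cells are corrected to their weighted residuals.
als_objective <- function(R, X, Y, alpha, lambda) {
  base <- sum(crossprod(X) * crossprod(Y))   # sum over ALL cells of s_ui^2
  trip <- Matrix::summary(R)
  r <- trip$x
  s <- rowSums(X[trip$i, , drop = FALSE] * Y[trip$j, , drop = FALSE])
  base - sum(s^2) + sum((1 + alpha * r) * (1 - s)^2) +
    lambda * (sum(X^2) + sum(Y^2))
}

#' @exportS3Method base::print
print.factor_model <- function(x, ...) {
  cat(x$algorithm, "factor model:", nrow(x$user_factors), "users x",
      nrow(x$item_factors), "items,", x$factors, "factors\n")
  if (!is.null(x$objective)) {
    cat("final objective:", format(utils::tail(x$objective, 1)), "\n")
  }
  invisible(x)
}

#' Collaborative-filtering scores for one user
#'
#' Scores candidate items for a user as the dot product of the user and item
#' latent factors. Items absent from the training universe cannot be scored
#' by a factor model (the cold-start limitation of collaborative filtering):
#' policy `"exclude"` (default) drops them from the result, `"zero"` keeps
#' them with score 0 so a hybrid's content-based half can still rank them.
#' For BPR models, `bpr_shift = TRUE` adds 1 to every score, mirroring
#' implementations that offset ranking scores to be positive; this matters
#' only when scores are fused with a mean rule.
#'
#' @param model A `"factor_model"` (from [fit_als()] or [fit_bpr()]).
#' @param user A user id present in the model.
#' @param candidates Character vector of candidate item ids.
#' @param policy Unseen-item policy: `"exclude"` or `"zero"`.
#' @param bpr_shift Add 1 to every score (BPR models only).
#' @return Named numeric vector of scores over (a subset of) `candidates`.
#' @export
score_items_cf <- function(model, user, candidates,
                           policy = c("exclude", "zero"), bpr_shift = FALSE) {
  policy <- match.arg(policy)
  ui <- match(user, rownames(model$user_factors))
  if (is.na(ui)) {
    stop("cold start: user ", user, " was not in the training data")
  }
  known <- candidates %in% rownames(model$item_factors)
  scored <- candidates[known]
  s <- as.numeric(model$item_factors[scored, , drop = FALSE] %*%
                    model$user_factors[ui, ])
  names(s) <- scored
  if (bpr_shift) {
    if (!identical(model$algorithm, "BPR")) {
      stop("bpr_shift applies to BPR models only")
    }
    s <- s + 1
  }
  if (policy == "zero" && any(!known)) {
    z <- stats::setNames(numeric(sum(!known)), candidates[!known])
    s <- c(s, z)[candidates]   # preserve candidate order
  }
  s
}

#' @export
predict.factor_model <- function(object, user, candidates = NULL, ...) {
  if (is.null(candidates)) candidates <- rownames(object$item_factors)
  score_items_cf(object, user, candidates, ...)
}
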