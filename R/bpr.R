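#' Bayesian personalized ranking for implicit feedback
#'
#' Pairwise learning-to-rank for implicit data: rather than fitting the raw
#' counts, BPR posits that a user prefers any observed item over any
#' unobserved one, and maximizes
#' `sum ln sigma(x_u'(y_i - y_j)) - lambda * ||Theta||^2` over uniformly
#' sampled triplets (user, observed item i, unobserved item j) by stochastic
#' gradient ascent. Users whose observed items cover the whole item universe
#' admit no negative sample and are excluded from sampling with a warning.
#'
#' Sampling and initialization are driven entirely by `seed`, so two fits
#' with the same seed produce bit-identical factor matrices.
#'
#' @param data A `"ratings"` object.
#' @param factors Latent dimension.
#' @param lr Learning rate.
#' @param lambda L2 regularization applied to all touched parameters.
#' @param epochs Number of epochs; each draws as many triplets as there are
#'   observed ratings.
#' @param seed Integer seed.
#' @return Object of class `c("bpr_model", "factor_model")`.
#' @export
fit_bpr <- function(data, factors = 150L, lr = 0.01, lambda = 1e-4,
                    epochs = 100L, seed = 1L) {
  stopifnot(inherits(data, "ratings"), factors >= 1L, lr >= 0, epochs >= 0L)
  if (nrow(data) == 0L) stop("empty ratings dataset")
  users <- attr(data, "users"); items <- attr(data, "items")
  n_u <- length(users); n_i <- length(items); f <- as.integer(factors)
  pos <- split(match(data$item, items), factor(data$user, levels = users))
  eligible <- which(lengths(pos) >= 1L & lengths(pos) < n_i)
  saturated <- which(lengths(pos) == n_i)
  if (length(saturated)) {
    warning("user(s) with every item observed excluded from BPR sampling: ",
            paste(users[saturated], collapse = ", "))
  }
  if (!length(eligible)) stop("no user has both observed and unobserved items")
  set.seed(seed)
  X <- matrix(stats::runif(n_u * f, 0, 1 / sqrt(f)), n_u, f)
  Y <- matrix(stats::runif(n_i * f, 0, 1 / sqrt(f)), n_i, f)
  n_draw <- nrow(data)
  for (ep in seq_len(epochs)) {
    us <- eligible[sample.int(length(eligible), n_draw, replace = TRUE)]
    for (t in seq_len(n_draw)) {
      u <- us[t]
      pu <- pos[[u]]
      i <- pu[sample.int(length(pu), 1L)]
      repeat {                       # rejection-sample an unobserved item
        j <- sample.int(n_i, 1L)
        if (!(j %in% pu)) break
      }
      upd <- bpr_step(X[u, ], Y[i, ], Y[j, ], lr, lambda)
      X[u, ] <- upd$user
      Y[i, ] <- upd$item_pos
      Y[j, ] <- upd$item_neg
    }
  }
  dimnames(X) <- list(users, NULL)
  dimnames(Y) <- list(items, NULL)
  structure(list(algorithm = "BPR", user_factors = X, item_factors = Y,
                 factors = f, lr = lr, lambda = lambda, epochs = epochs,
                 seed = seed),
            class = c("bpr_model", "factor_model"))
}

# One SGD step on a (user, observed, unobserved) triplet.
# With xh = w' (hi - hj) and e = sigma(-xh), the gradient of
# ln sigma(xh) - lambda ||.||^2 gives:
#   w  <- w  + lr * (e * (hi - hj) - lambda * w)
#   hi <- hi + lr * (e * w         - lambda * hi)
#   hj <- hj + lr * (-e * w        - lambda * hj)
bpr_step <- function(w, hi, hj, lr, lambda) {
  xh <- sum(w * (hi - hj))
  e <- 1 / (1 + exp(xh))    # sigma(-xh)
  list(user = w + lr * (e * (hi - hj) - lambda * w),
       item_pos = hi + lr * (e * w - lambda * hi),
       item_neg = hj + lr * (-e * w - lambda * hj))
}

# Pairwise AUC of a factor model on given positive sets: for each user the
# fraction of (positive, negative) pairs ranked correctly (ties count 1/2),
# averaged over users. `positives` is a named list of item-id vectors;
# negatives are all other model items not in `exclude[[user]]`.
pairwise_auc <- function(model, positives, exclude = list()) {
  items <- rownames(model$item_factors)
  aucs <- c()
  for (u in names(positives)) {
    pos <- intersect(positives[[u]], items)
    neg <- setdiff(items, union(pos, exclude[[u]]))
    if (!length(pos) || !length(neg)) next
    s <- score_items_cf(model, u, c(pos, neg))
    sp <- s[pos]; sn <- s[neg]
    wins <- sum(outer(sp, sn, ">")) + 0.5 * sum(outer(sp, sn, "=="))
    aucs <- c(aucs, wins / (length(sp) * length(sn)))
  }
  mean(aucs)
}
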