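#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

softmax_rows <- function(score) {
  score <- score - apply(score, 1, max)
  e <- exp(score)
  e / rowSums(e)
}

decoder_scores <- function(model, H) {
  Hs <- sweep(sweep(H, 2, model$center), 2, model$scale, "/")
  cbind(1, Hs) %*% t(model$beta)
}

fit_multinom_l2 <- function(H, y, C) {
  df <- data.frame(y = y, H)
  fit <- nnet::multinom(
    y ~ ., data = df, decay = 1 / C, maxit = 1000,
    trace = FALSE, MaxNWts = 100000, reltol = 1e-10
  )
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1) # 2-class case
  # first (reference) outcome has implicit zero coefficients
  beta <- rbind(0, co)
  rownames(beta) <- levels(y)
  list(beta = beta, converged = fit$convergence == 0)
}

#' Train the regularized multinomial stimulus decoder
#'
#' Fits a softmax (multinomial logistic) model with an L2 penalty by a
#' quasi-Newton optimizer on the NMF activation coefficients, predicting
#' one stimulus feature's level per trial. The inverse regularization
#' strength `C` is chosen from `C_grid` by minimal mean cross-entropy over
#' stratified k-fold cross-validation on the training set, then the final
#' model is refit on the full training set at the chosen `C`. Coefficients
#' are fit on per-column standardized activations (centering/scaling stored
#' in the model and reapplied at prediction time).
#'
#' @param H_train Matrix (trials x K) of activation coefficients.
#' @param labels Feature levels, one per training trial (coerced to factor);
#'   every level must have at least `n_folds` trials.
#' @param C_grid Candidate inverse regularization strengths (default 7
#'   log-spaced values from 1e-3 to 1e3).
#' @param seed Integer seed (fold assignment).
#' @param n_folds Cross-validation folds (default 5, stratified).
#' @return Object of class `tactile_decoder`: `beta` (outcomes x (1+K),
#'   first column intercepts; reference outcome row is zero), `levels`,
#'   `C`, `cv` (tibble of C vs mean CV cross-entropy), `center`, `scale`,
#'   `train_loss`, `train_accuracy`, `converged`.
#' @export
train_decoder <- function(H_train, labels, C_grid = 10^seq(-3, 3, by = 1),
                          seed = 1L, n_folds = 5) {
  y <- factor(labels)
  if (nlevels(y) < 2) rlang::abort("need at least 2 outcome levels")
  if (min(table(y)) < n_folds) {
    rlang::abort(sprintf("every outcome level needs >= %d training trials", n_folds))
  }
  H_train <- as.matrix(H_train)
  center <- colMeans(H_train)
  scale <- apply(H_train, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Hs <- sweep(sweep(H_train, 2, center), 2, scale, "/")

  folds <- stratified_folds(as.integer(y), k = n_folds, seed = seed)
  cv_loss <- vapply(C_grid, function(C) {
    losses <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      fit <- withr::with_seed(
        derive_seed(seed, f, round(-log10(C) * 7 + 100)),
        fit_multinom_l2(Hs[tr, , drop = FALSE], y[tr], C)
      )
      score <- cbind(1, Hs[!tr, , drop = FALSE]) %*% t(fit$beta)
      p <- softmax_rows(score)
      p_true <- p[cbind(seq_len(sum(!tr)), as.integer(y[!tr]))]
      mean(-log(pmax(p_true, 1e-12)))
    }, numeric(1))
    mean(losses)
  }, numeric(1))
  C_best <- C_grid[which.min(cv_loss)]

  final <- withr::with_seed(
    derive_seed(seed, 991L),
    fit_multinom_l2(Hs, y, C_best)
  )
  score <- cbind(1, Hs) %*% t(final$beta)
  p <- softmax_rows(score)
  pred <- max.col(p, ties.method = "first")
  p_true <- p[cbind(seq_along(y), as.integer(y))]

  structure(
    list(
      beta = final$beta, levels = levels(y), C = C_best,
      cv = tibble::tibble(C = C_grid, cv_cross_entropy = cv_loss),
      center = center, scale = scale,
      train_loss = mean(-log(pmax(p_true, 1e-12))),
      train_accuracy = mean(pred == as.integer(y)),
      converged = final$converged
    ),
    class = "tactile_decoder"
  )
}

#' @export
print.tactile_decoder <- function(x, ...) {
  cat(sprintf(
    "<tactile_decoder> %d outcomes, K = %d, C = %g, train accuracy = %.2f\n",
    length(x$levels), ncol(x$beta) - 1, x$C, x$train_accuracy
  ))
  invisible(x)
}

#' Posterior probabilities of each stimulus level
#'
#' Softmax of the linear scores \eqn{\beta_s \cdot H_i}. The decoded level
#' is the argmax, with ties broken toward the lowest-index level.
#'
#' @param model A [train_decoder()] fit.
#' @param H Matrix (trials x K) or a single coefficient vector.
#' @return Matrix (trials x outcomes) of posterior probabilities; each row
#'   sums to 1. Column names are the outcome levels.
#' @export
posterior <- function(model, H) {
  stopifnot(inherits(model, "tactile_decoder"))
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  if (ncol(H) != ncol(model$beta) - 1) {
    rlang::abort("H must have K columns matching the decoder")
  }
  p <- softmax_rows(decoder_scores(model, as.matrix(H)))
  colnames(p) <- model$levels
  p
}

#' Decode stimulus levels
#' @param model A [train_decoder()] fit.
#' @param H Matrix (trials x K).
#' @return Factor of decoded levels (lowest-index tie-break).
#' @export
decode <- function(model, H) {
  p <- posterior(model, H)
  factor(model$levels[max.col(p, ties.method = "first")], levels = model$levels)
}

#' Confusion matrix of a decoder on held-out trials
#'
#' Counts of (presented, decoded) level pairs over the test trials: rows are
#' presented levels, columns decoded levels. Test trials must be disjoint
#' from the training trials.
#'
#' @param model A [train_decoder()] fit.
#' @param H_test Matrix (trials x K) of test activations.
#' @param labels_test Presented levels for the test trials.
#' @return An S x S integer matrix of class `confusion_matrix` (S = number
#'   of outcome levels), with dimnames `presented` x `decoded`.
#' @export
confusion_matrix <- function(model, H_test, labels_test) {
  pres <- factor(as.character(labels_test), levels = model$levels)
  if (anyNA(pres)) rlang::abort("test labels outside the decoder's outcome set")
  dec <- decode(model, H_test)
  cm <- table(presented = pres, decoded = dec)
  structure(
    matrix(as.integer(cm), nrow = nlevels(pres),
           dimnames = list(presented = model$levels, decoded = model$levels)),
    class = c("confusion_matrix", "matrix", "array")
  )
}

#' Tidy a decoder: coefficients in long form
#' @param x A `tactile_decoder`.
#' @param ... Unused.
#' @return Tibble with `outcome`, `term`, `estimate` (standardized scale).
#' @export
tidy.tactile_decoder <- function(x, ...) {
  terms <- c("(Intercept)", paste0("h", seq_len(ncol(x$beta) - 1)))
  tibble::tibble(
    outcome = rep(x$levels, times = ncol(x$beta)),
    term = rep(terms, each = nrow(x$beta)),
    estimate = as.vector(x$beta)
  )
}

#' One-row summary of a decoder
#' @param x A `tactile_decoder`.
#' @param ... Unused.
#' @return Tibble with `n_outcomes`, `K`, `C`, `train_loss`,
#'   `train_accuracy`, `converged`.
#' @export
glance.tactile_decoder <- function(x, ...) {
  tibble::tibble(
    n_outcomes = length(x$levels), K = ncol(x$beta) - 1, C = x$C,
    train_loss = x$train_loss, train_accuracy = x$train_accuracy,
    converged = x$converged
  )
}
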