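# Extreme learning machine: a single-hidden-layer network whose hidden layer
# is random (seed-controlled) and whose output weights are the ridge
# pseudo-inverse solution on one-hot class targets. Used as the wrapper
# classifier inside the gene-subset fitness.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train an extreme learning machine classifier
#'
#' Hidden weights and biases are drawn uniformly from `[-1, 1]` under the
#' given seed; output weights solve the ridge-regularized least-squares
#' system on one-hot targets via the normal equations.
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @param y class labels (factor or coercible), one per row of `X`.
#' @param H number of hidden units.
#' @param seed integer seed for the random hidden layer.
#' @param ridge ridge coefficient of the output solve.
#' @return an object of class `elm`.
#' @export
train_elm <- function(X, y, H = 100, seed = 1, ridge = 1e-6) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("parameter error: need at least one feature")
  if (H < 1) stop("parameter error: H must be >= 1")
  y <- factor(y)
  Fdim <- ncol(X)
  rand <- with_seed(as.integer(seed), {
    list(Win = matrix(stats::runif(Fdim * H, -1, 1), Fdim, H),
         bias = stats::runif(H, -1, 1))
  })
  Hmat <- sigmoid(sweep(X %*% rand$Win, 2L, rand$bias, "+"))
  Tmat <- matrix(0, nrow(X), nlevels(y))        # one-hot targets
  Tmat[cbind(seq_len(nrow(X)), as.integer(y))] <- 1
  beta <- solve(crossprod(Hmat) + diag(ridge, H), crossprod(Hmat, Tmat))
  structure(list(input_weights = rand$Win, biases = rand$bias,
                 output_weights = beta, levels = levels(y), H = H,
                 ridge = ridge, seed = as.integer(seed)),
            class = "elm")
}

#' Predict class labels with a trained ELM
#'
#' @param object an `elm` model.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return factor of predicted labels (levels of the training set).
#' @export
predict.elm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Hmat <- sigmoid(sweep(newdata %*% object$input_weights, 2L,
                        object$biases, "+"))
  scores <- Hmat %*% object$output_weights
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' Classification accuracy of an ELM on an evaluation set
#'
#' Exact ratio of correctly classified instances, times 100. Labels never
#' seen in training cannot be predicted and are counted as errors (with a
#' warning).
#'
#' @param model an `elm` model.
#' @param X samples x features evaluation matrix.
#' @param y true labels.
#' @return accuracy percentage in `[0, 100]`.
#' @export
classification_accuracy <- function(model, X, y) {
  if (length(y) == 0) stop("parameter error: empty evaluation set")
  y <- as.character(y)
  if (!all(y %in% model$levels)) {
    warning("labels unseen in training are counted as errors")
  }
  pred <- as.character(predict(model, X))
  100 * mean(pred == y)
}
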