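# Class prediction from two-window features: a small feed-forward network
# (ReLU hidden layers, softmax output) and a deterministic multinomial-
# logistic fallback sharing one train/test interface.

mlp_init <- function(sizes) {
  W <- list()
  b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    # He initialization for ReLU layers
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
      sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  acts <- list(X)
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% par$W[[l]] + matrix(par$b[[l]], nrow(X), length(par$b[[l]]),
      byrow = TRUE)
    acts[[l + 1]] <- if (l < L) pmax(Z, 0) else {
      # softmax with the usual max-shift for stability
      E <- exp(Z - apply(Z, 1, max))
      E / rowSums(E)
    }
  }
  acts
}

mlp_train <- function(X, y_onehot, hidden, epochs = 60, batch = 128, lr = 1e-3) {
  sizes <- c(ncol(X), hidden, ncol(y_onehot))
  par <- mlp_init(sizes)
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0)
  vW <- mW
  mb <- lapply(par$b, function(b) b * 0)
  vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1, n)]
      acts <- mlp_forward(par, X[idx, , drop = FALSE])
      delta <- (acts[[L + 1]] - y_onehot[idx, , drop = FALSE]) / length(idx)
      step <- step + 1
      for (l in rev(seq_len(L))) {
        gW <- t(acts[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(par$W[[l]])) * (acts[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mWh <- mW[[l]] / (1 - beta1^step)
        vWh <- vW[[l]] / (1 - beta2^step)
        mbh <- mb[[l]] / (1 - beta1^step)
        vbh <- vb[[l]] / (1 - beta2^step)
        par$W[[l]] <- par$W[[l]] - lr * mWh / (sqrt(vWh) + eps)
        par$b[[l]] <- par$b[[l]] - lr * mbh / (sqrt(vbh) + eps)
      }
    }
  }
  par
}

#' Train and evaluate a class predictor on two-window features
#'
#' Randomizes the rows with a fixed seed, splits into training and testing
#' groups, trains the chosen classifier on the training split only, and
#' reports accuracy on both splits plus the test confusion matrix. The
#' default classifier is a feed-forward network of seven ReLU hidden layers
#' (64, 24, 24, 12, 12, 10, 8 nodes) with a softmax output of one node per
#' class; `method = "multinom"` selects the deterministic
#' multinomial-logistic model instead, which is the reproducible surface
#' for acceptance checks.
#'
#' @param features Tibble of feature columns (non-numeric columns dropped).
#' @param labels Factor of class labels, one per row.
#' @param split_fraction Fraction of rows used for training (default 0.8).
#' @param seed Integer seed controlling the split (and network training).
#' @param method `"mlp"` (default) or `"multinom"`.
#' @param epochs,batch,lr Network training budget (mlp only).
#' @return A `class_fit` object; see [glance.class_fit()] for accuracies
#'   and [tidy.class_fit()] for the confusion matrix.
#' @export
train_eval <- function(features, labels, split_fraction = 0.8, seed = 1L,
                       method = c("mlp", "multinom"),
                       epochs = 60, batch = 128, lr = 1e-3) {
  method <- match.arg(method)
  num_cols <- vapply(features, is.numeric, logical(1))
  X <- as.matrix(features[, num_cols, drop = FALSE])
  labels <- droplevels(as.factor(labels))
  assert_that(nrow(X) == length(labels), "one label per feature row required")
  n <- nrow(X)
  idx_train <- with_stream(seed, "train_test_split", {
    sample.int(n, size = floor(split_fraction * n))
  })
  assert_that(nlevels(droplevels(labels[idx_train])) >= 2,
    "training split contains a single class")
  # standardize features on training statistics
  mu <- colMeans(X[idx_train, , drop = FALSE])
  sg <- apply(X[idx_train, , drop = FALSE], 2, sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  if (method == "multinom") {
    df_train <- data.frame(Xs[idx_train, , drop = FALSE])
    df_train$.y <- labels[idx_train]
    fit <- nnet::multinom(.y ~ ., data = df_train, trace = FALSE,
      maxit = 200, MaxNWts = 5000)
    predict_fun <- function(M) {
      predict(fit, newdata = data.frame(M), type = "class")
    }
  } else {
    y_onehot <- stats::model.matrix(~ 0 + labels)
    par <- with_stream(seed, "mlp_train", {
      mlp_train(Xs[idx_train, , drop = FALSE],
        y_onehot[idx_train, , drop = FALSE],
        hidden = c(64, 24, 24, 12, 12, 10, 8),
        epochs = epochs, batch = batch, lr = lr)
    })
    predict_fun <- function(M) {
      pr <- mlp_forward(par, M)[[length(par$W) + 1]]
      levels(labels)[max.col(pr, ties.method = "first")]
    }
  }
  pred_train <- factor(predict_fun(Xs[idx_train, , drop = FALSE]),
    levels = levels(labels))
  pred_test <- factor(predict_fun(Xs[-idx_train, , drop = FALSE]),
    levels = levels(labels))
  obs_test <- labels[-idx_train]
  structure(
    list(
      method = method,
      train_accuracy = mean(pred_train == labels[idx_train]),
      test_accuracy = mean(pred_test == obs_test),
      confusion = table(observed = obs_test, predicted = pred_test),
      idx_train = sort(idx_train),
      n_train = length(idx_train), n_test = n - length(idx_train),
      levels = levels(labels)
    ),
    class = "class_fit"
  )
}

#' @export
print.class_fit <- function(x, ...) {
  cat(sprintf(
    "<class_fit:%s> train accuracy %.3f (n=%d), test accuracy %.3f (n=%d)\n",
    x$method, x$train_accuracy, x$n_train, x$test_accuracy, x$n_test
  ))
  invisible(x)
}

#' Principal component analysis of the binned genome
#'
#' Thin wrapper over [stats::prcomp()] on the bin x attribute matrix
#' (centered and scaled); attribute correlations are read from the
#' loadings in the usual biplot sense.
#'
#' @param table A `genome_bins` table.
#' @param attrs Attribute columns to include.
#' @return The `prcomp` fit.
#' @export
pca_bins <- function(table, attrs) {
  M <- as.matrix(tibble::as_tibble(table)[, attrs, drop = FALSE])
  keep <- apply(M, 2, sd) > 0
  prcomp(M[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
}
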