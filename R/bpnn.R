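#' Backpropagation neural network classifier
#'
#' Fully connected feed-forward network for origin discrimination:
#' `hidden_layers` hidden layers of `neurons_per_layer` rectified-linear
#' units each, a softmax output over the origin classes, and cross-entropy
#' loss minimized by mini-batch Adam at the given learning rate. A
#' stratified 10% validation carve-out drives early stopping (the weights
#' of the best validation epoch are restored). Training is deterministic
#' under `seed`.
#'
#' The tunable ranges mirror the swarm search space: 1-5 hidden layers,
#' 2-40 neurons per layer, learning rate 0.001-0.1; values outside these
#' ranges are rejected.
#'
#' @param table Training chem table.
#' @param hidden_layers Number of hidden layers (integer in \[1, 5\]).
#' @param neurons_per_layer Width of each hidden layer (integer in
#'   \[2, 40\]).
#' @param learning_rate Adam step size (in \[0.001, 0.1\]).
#' @param max_epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param validation_fraction Stratified share held out for early stopping
#'   (0 disables early stopping).
#' @param patience Epochs without validation improvement before stopping.
#' @param standardize Z-score features on the training split.
#' @param group_by Label column.
#' @param seed Integer seed.
#' @return Object of class `c("origin_bpnn", "origin_classifier")`.
#' @export
train_bpnn <- function(table, hidden_layers = 3, neurons_per_layer = 31,
                       learning_rate = 0.001, max_epochs = 300,
                       batch_size = 32, validation_fraction = 0.1,
                       patience = 25, standardize = TRUE,
                       group_by = c("region", "country"), seed = 1) {
  group_by <- match.arg(group_by)
  if (hidden_layers < 1 || hidden_layers > 5 ||
      hidden_layers != round(hidden_layers)) {
    stop("'hidden_layers' must be an integer in [1, 5]", call. = FALSE)
  }
  if (neurons_per_layer < 2 || neurons_per_layer > 40 ||
      neurons_per_layer != round(neurons_per_layer)) {
    stop("'neurons_per_layer' must be an integer in [2, 40]", call. = FALSE)
  }
  if (learning_rate < 0.001 || learning_rate > 0.1) {
    stop("'learning_rate' must lie in [0.001, 0.1]", call. = FALSE)
  }
  table <- as_chem_table(table)
  y <- .training_labels(table, group_by)
  components <- chem_components(table)
  X <- .design_matrix(table, components)
  scaler <- if (standardize) .fit_scaler(X) else NULL
  X <- .apply_scaler(X, scaler)
  lev <- levels(y)
  K <- length(lev)
  Y <- diag(K)[as.integer(y), , drop = FALSE]

  set.seed(as.integer(seed))
  # stratified validation carve-out
  val_idx <- integer(0)
  if (validation_fraction > 0) {
    for (cl in lev) {
      idx <- which(y == cl)
      n_val <- floor(length(idx) * validation_fraction)
      if (n_val >= 1 && length(idx) - n_val >= 1) {
        val_idx <- c(val_idx, sample(idx, n_val))
      }
    }
  }
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
  if (!all(lev %in% y[tr_idx])) { # never let a class vanish from training
    val_idx <- integer(0); tr_idx <- seq_len(nrow(X))
  }

  sizes <- c(ncol(X), rep(neurons_per_layer, hidden_layers), K)
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {             # He initialization
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }

  forward <- function(Xb, W, b) {
    acts <- vector("list", L + 1)
    acts[[1]] <- Xb
    for (l in seq_len(L)) {
      z <- acts[[l]] %*% W[[l]] + matrix(b[[l]], nrow(Xb), sizes[l + 1],
                                         byrow = TRUE)
      acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
    }
    z <- acts[[L + 1]]
    z <- z - apply(z, 1, max)
    ez <- exp(z)
    list(acts = acts, probs = ez / rowSums(ez))
  }
  xent <- function(probs, Yb) {
    -mean(log(pmax(rowSums(probs * Yb), 1e-12)))
  }

  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
  best <- list(W = W, b = b, loss = Inf, epoch = 0)
  stall <- 0

  for (epoch in seq_len(max_epochs)) {
    perm <- sample(tr_idx)
    for (start in seq(1, length(perm), by = batch_size)) {
      bi <- perm[start:min(start + batch_size - 1, length(perm))]
      fw <- forward(X[bi, , drop = FALSE], W, b)
      delta <- (fw$probs - Y[bi, , drop = FALSE]) / length(bi)
      for (l in rev(seq_len(L))) {
        gW <- t(fw$acts[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * (fw$acts[[l]] > 0)
        }
        t_step_l <- t_step + 1
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^t_step_l)
        vhW <- vW[[l]] / (1 - beta2^t_step_l)
        mhb <- mb[[l]] / (1 - beta1^t_step_l)
        vhb <- vb[[l]] / (1 - beta2^t_step_l)
        W[[l]] <- W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
      }
      t_step <- t_step + 1
    }
    if (length(val_idx)) {
      vloss <- xent(forward(X[val_idx, , drop = FALSE], W, b)$probs,
                    Y[val_idx, , drop = FALSE])
      if (vloss < best$loss - 1e-6) {
        best <- list(W = W, b = b, loss = vloss, epoch = epoch)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= patience) break
      }
    }
  }
  if (length(val_idx) && is.finite(best$loss)) {
    W <- best$W; b <- best$b
  }

  structure(list(algorithm = "BPNN", W = W, b = b, sizes = sizes,
                 hidden_layers = hidden_layers,
                 neurons_per_layer = neurons_per_layer,
                 learning_rate = learning_rate,
                 epochs_run = if (length(val_idx)) best$epoch else max_epochs,
                 scaler = scaler, components = components, levels = lev,
                 group_by = group_by, n_train = nrow(X),
                 class_support = as.vector(table(y)), seed = seed),
            class = c("origin_bpnn", "origin_classifier"))
}

#' Predict origins with a fitted BPNN
#'
#' @param object Fitted model from [train_bpnn()].
#' @param newdata Chem table with the training components.
#' @param type `"class"` or `"scores"` (softmax class probabilities).
#' @param ... Unused.
#' @return Factor of labels or a probability matrix.
#' @export
predict.origin_bpnn <- function(object, newdata,
                                type = c("class", "scores"), ...) {
  type <- match.arg(type)
  Xnew <- .apply_scaler(.design_matrix(newdata, object$components),
                        object$scaler)
  L <- length(object$W)
  A <- Xnew
  for (l in seq_len(L)) {
    z <- A %*% object$W[[l]] +
      matrix(object$b[[l]], nrow(A), length(object$b[[l]]), byrow = TRUE)
    A <- if (l < L) pmax(z, 0) else z
  }
  A <- A - apply(A, 1, max)
  probs <- exp(A) / rowSums(exp(A))
  colnames(probs) <- object$levels
  if (type == "scores") return(probs)
  factor(object$levels[max.col(probs, ties.method = "first")],
         levels = object$levels)
}
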