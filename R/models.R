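# Uniform train/predict contract over three classifier families: random
# forest (ranger backend), gradient-boosted trees (xgboost backend) and a
# feed-forward neural network implemented here (input -> 500 -> 200 ->
# softmax with dropout, trained by Adam on the cross-entropy loss).

#' Model configuration
#'
#' Hyperparameters for the three families. The shipped YAML files under
#' `inst/configs/` mirror the study-scale settings per task (random forest
#' n_estimators 1200-1800 with max_depth 100-420, min_samples_leaf 2 and
#' sqrt feature sampling; XGBoost max_depth 20 with mostly default
#' boosting settings; ANN hidden layers 500/200, dropout 0.05,
#' cross-entropy loss). Desk-scale defaults here are smaller so the whole
#' stack runs in seconds; training contracts are identical.
#'
#' The optimizer name `"adam"` (learning rate 1e-3) is the default for the
#' ANN; `"adagrad"` is selectable. Epoch budget and early-stopping patience
#' are configurable; study-scale training runs for thousands of epochs.
#'
#' @param family `"rf"`, `"gbdt"` or `"ann"`.
#' @param n_estimators Trees (rf) or boosting rounds (gbdt).
#' @param max_depth Maximal tree depth; `NULL` = unlimited (rf) / backend
#'   default (gbdt uses 20, the study value).
#' @param min_samples_leaf Minimal samples per leaf (rf).
#' @param max_features `"sqrt"` or an integer mtry (rf).
#' @param eta Learning rate (gbdt).
#' @param eval_metric Optional evaluation metric name (gbdt).
#' @param hidden Hidden layer sizes (ann).
#' @param dropout Dropout rate in [0, 1) applied at each hidden layer (ann).
#' @param lr Learning rate (ann).
#' @param optimizer `"adam"` or `"adagrad"` (ann).
#' @param epochs Maximal training epochs (ann).
#' @param patience Early-stopping patience in epochs on the training loss;
#'   `Inf` disables early stopping.
#' @param seed Integer seed making training reproducible (single-threaded
#'   deterministic mode for all families).
#' @return A `model_config` list.
#' @export
model_config <- function(family = c("rf", "gbdt", "ann"),
                         n_estimators = NULL, max_depth = NULL,
                         min_samples_leaf = 2L, max_features = "sqrt",
                         eta = 0.3, eval_metric = NULL,
                         hidden = c(500L, 200L), dropout = 0.05,
                         lr = 1e-3, optimizer = c("adam", "adagrad"),
                         epochs = 200L, patience = 25L, seed = 1L) {
  family <- match.arg(family)
  optimizer <- match.arg(optimizer)
  if (is.null(n_estimators)) {
    n_estimators <- switch(family, rf = 300L, gbdt = 100L, ann = NA_integer_)
  }
  stopifnot(dropout >= 0, dropout < 1, eta > 0, eta <= 1)
  structure(list(family = family, n_estimators = n_estimators,
                 max_depth = max_depth, min_samples_leaf = min_samples_leaf,
                 max_features = max_features, eta = eta,
                 eval_metric = eval_metric, hidden = hidden,
                 dropout = dropout, lr = lr, optimizer = optimizer,
                 epochs = as.integer(epochs), patience = patience,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Load a model configuration from YAML
#'
#' @param path YAML file with a `family` key and any [model_config()]
#'   fields. Package-shipped configs live under
#'   `system.file("configs", package = "ohecc")`.
#' @return A `model_config`.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(model_config, y)
}

check_training_input <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || !all(is.finite(x))) stop("features must be finite (no NaN/NA)")
  y <- as.factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  if (length(y) != nrow(x)) stop("nrow(features) must equal length(labels)")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  list(x = x, y = y)
}

#' Train a classifier
#'
#' Fits the configured family on a feature matrix (rows = molecules,
#' typically flattened OHECC vectors) and a label vector. All families run
#' single-threaded and are deterministic under a fixed config seed.
#'
#' @param x Numeric feature matrix.
#' @param y Labels (factor or coercible); at least two classes.
#' @param config A [model_config()].
#' @return An `ohecc_model` exposing [predict.ohecc_model()].
#' @export
train_model <- function(x, y, config = model_config("rf")) {
  inp <- check_training_input(x, y)
  x <- inp$x; y <- inp$y
  fit <- switch(
    config$family,
    rf = {
      mtry <- if (identical(config$max_features, "sqrt")) {
        max(1L, floor(sqrt(ncol(x))))
      } else as.integer(config$max_features)
      ranger::ranger(
        x = x, y = y, num.trees = config$n_estimators, mtry = mtry,
        min.node.size = config$min_samples_leaf,
        max.depth = if (is.null(config$max_depth)) 0L else config$max_depth,
        seed = config$seed, num.threads = 1L)
    },
    gbdt = {
      k <- nlevels(y)
      params <- list(
        max_depth = if (is.null(config$max_depth)) 20L else config$max_depth,
        eta = config$eta, nthread = 1L,
        objective = if (k == 2L) "binary:logistic" else "multi:softprob")
      if (k > 2L) params$num_class <- k
      if (!is.null(config$eval_metric)) params$eval_metric <- config$eval_metric
      set.seed(config$seed)
      xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L),
        nrounds = config$n_estimators, verbose = 0)
    },
    ann = ann_train(x, y, config)
  )
  structure(list(family = config$family, fit = fit, classes = levels(y),
                 n_features = ncol(x), feature_names = colnames(x),
                 config = config),
            class = "ohecc_model")
}

#' @export
print.ohecc_model <- function(x, ...) {
  cat("<ohecc_model ", x$family, ": ", length(x$classes), " classes (",
      paste(x$classes, collapse = "/"), "), ", x$n_features,
      " features>\n", sep = "")
  invisible(x)
}

#' Predict with a fitted classifier
#'
#' @param object An `ohecc_model`.
#' @param x Feature matrix with the training feature width.
#' @param type `"class"` for labels (factor over the training classes) or
#'   `"prob"` for a class-probability matrix (rows sum to 1). For random
#'   forests the label is the majority vote of the trees and the
#'   probabilities are the per-class vote shares.
#' @param ... Unused.
#' @return Factor of labels or numeric probability matrix.
#' @export
predict.ohecc_model <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != object$n_features) {
    stop("feature width ", ncol(x), " does not match training width ",
         object$n_features)
  }
  colnames(x) <- object$feature_names
  k <- length(object$classes)
  prob <- switch(
    object$family,
    rf = {
      votes <- predict_votes(object, x)
      t(apply(votes, 2L, function(v) {
        tabulate(v, nbins = k) / length(v)
      }))
    },
    gbdt = {
      p <- predict(object$fit, xgboost::xgb.DMatrix(x))
      if (k == 2L) cbind(1 - p, p)
      else if (is.matrix(p)) p
      else matrix(p, ncol = k, byrow = TRUE)
    },
    ann = ann_predict_prob(object$fit, x)
  )
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}

#' Per-tree votes of a random forest
#'
#' Exposes the individual tree predictions behind the ensemble so the
#' majority-vote contract (the returned label is the class predicted by
#' the most trees) can be verified directly.
#'
#' @param object An `ohecc_model` with `family = "rf"`.
#' @param x Feature matrix.
#' @return Integer matrix, trees x samples, of class indices into
#'   `object$classes`.
#' @export
predict_votes <- function(object, x) {
  stopifnot(object$family == "rf")
  x <- as.matrix(x)
  colnames(x) <- object$feature_names
  p <- predict(object$fit, data = x, predict.all = TRUE,
               num.threads = 1L)$predictions
  t(p)   # ranger returns samples x trees
}

## ---- feed-forward neural network --------------------------------------

# He-initialized fully connected net, ReLU hidden activations, inverted
# dropout, softmax + cross-entropy, full-batch Adam or Adagrad.

ann_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L], 0,
                                 sqrt(2 / sizes[i])),
                    sizes[i], sizes[i + 1L]),
         b = rep(0, sizes[i + 1L]))
  })
}

ann_forward <- function(layers, x, dropout = 0, train = FALSE) {
  a <- x
  acts <- list(a)
  masks <- list()
  nl <- length(layers)
  for (i in seq_len(nl)) {
    z <- sweep(a %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    if (i < nl) {
      a <- pmax(z, 0)
      if (train && dropout > 0) {
        m <- matrix(stats::rbinom(length(a), 1L, 1 - dropout) / (1 - dropout),
                    nrow(a), ncol(a))
        a <- a * m
        masks[[i]] <- m
      }
      acts[[i + 1L]] <- a
    } else {
      z <- z - apply(z, 1L, max)
      e <- exp(z)
      acts[[i + 1L]] <- e / rowSums(e)
    }
  }
  list(acts = acts, masks = masks)
}

ann_train <- function(x, y, config) {
  set.seed(config$seed)
  k <- nlevels(y)
  sizes <- c(ncol(x), config$hidden, k)
  layers <- ann_init(sizes)
  nl <- length(layers)
  yi <- as.integer(y)
  n <- nrow(x)
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), yi)] <- 1
  # optimizer state
  state <- lapply(layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- Inf; wait <- 0; t_step <- 0
  loss_trace <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    fw <- ann_forward(layers, x, dropout = config$dropout, train = TRUE)
    p <- fw$acts[[nl + 1L]]
    loss <- -mean(log(pmax(p[cbind(seq_len(n), yi)], 1e-12)))
    loss_trace[epoch] <- loss
    # backprop
    delta <- (p - onehot) / n
    t_step <- t_step + 1
    for (i in rev(seq_len(nl))) {
      a_prev <- fw$acts[[i]]
      gW <- crossprod(a_prev, delta)
      gb <- colSums(delta)
      if (i > 1L) {
        delta <- tcrossprod(delta, layers[[i]]$W)
        delta <- delta * (fw$acts[[i]] > 0)
        if (config$dropout > 0 && length(fw$masks) >= i - 1L &&
            !is.null(fw$masks[[i - 1L]])) {
          delta <- delta * fw$masks[[i - 1L]]
        }
      }
      st <- state[[i]]
      if (config$optimizer == "adam") {
        st$mW <- beta1 * st$mW + (1 - beta1) * gW
        st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
        st$mb <- beta1 * st$mb + (1 - beta1) * gb
        st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
        mhW <- st$mW / (1 - beta1^t_step); vhW <- st$vW / (1 - beta2^t_step)
        mhb <- st$mb / (1 - beta1^t_step); vhb <- st$vb / (1 - beta2^t_step)
        layers[[i]]$W <- layers[[i]]$W - config$lr * mhW / (sqrt(vhW) + eps)
        layers[[i]]$b <- layers[[i]]$b - config$lr * mhb / (sqrt(vhb) + eps)
      } else {   # adagrad
        st$vW <- st$vW + gW^2
        st$vb <- st$vb + gb^2
        layers[[i]]$W <- layers[[i]]$W - config$lr * gW / (sqrt(st$vW) + eps)
        layers[[i]]$b <- layers[[i]]$b - config$lr * gb / (sqrt(st$vb) + eps)
      }
      state[[i]] <- st
    }
    if (loss < best - 1e-6) { best <- loss; wait <- 0 } else wait <- wait + 1
    if (wait >= config$patience) break
  }
  list(layers = layers, loss_trace = loss_trace, epochs_run = epoch)
}

ann_predict_prob <- function(fit, x) {
  nl <- length(fit$layers)
  ann_forward(fit$layers, x, dropout = 0, train = FALSE)$acts[[nl + 1L]]
}
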