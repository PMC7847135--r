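#' Train/validation split with forced validation cases
#'
#' Per-group random split: `train_frac` of each group (rounded to the
#' nearest integer) is assigned to training, the rest to validation.
#' Specimens in `forced_validation_ids` are reserved for validation before
#' sampling — the protocol used to stress-test the network on the cases the
#' discriminant analysis got wrong. If the forced cases exceed a group's
#' validation quota the quota is expanded with a warning.
#'
#' @param labels group labels, one per specimen.
#' @param ids specimen identifiers; default the row positions.
#' @param train_frac training fraction per group.
#' @param forced_validation_ids ids that must end up in validation.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return a `split_plan` list: `train_ids`, `validation_ids`,
#'   `forced_validation_ids`, `seed`.
#' @export
make_split <- function(labels, ids = seq_along(labels), train_frac = 0.6,
                       forced_validation_ids = NULL, seed = 1L) {
  stopifnot(length(ids) == length(labels), train_frac > 0, train_frac < 1)
  if (!all(forced_validation_ids %in% ids))
    stop("forced_validation_ids contains unknown ids")
  set.seed(seed)
  train <- c()
  g <- factor(labels)
  for (lev in levels(g)) {
    gid <- ids[g == lev]
    n_train <- round(train_frac * length(gid))
    pool <- setdiff(gid, forced_validation_ids)
    if (n_train > length(pool)) {
      warning("group ", lev, ": forced validation cases exceed the ",
              "validation quota; training set reduced to ", length(pool))
      n_train <- length(pool)
    }
    train <- c(train, sample(pool, n_train))
  }
  structure(list(train_ids = train,
                 validation_ids = setdiff(ids, train),
                 forced_validation_ids = forced_validation_ids,
                 seed = seed),
            class = "split_plan")
}

#' Multilayer-perceptron configuration
#'
#' Single hidden layer; logistic softmax-normalized outputs; full-batch
#' quasi-Newton (BFGS) optimization. `sine` hidden activation mirrors the
#' original protocol's best network but is brittle to optimize (periodic);
#' `tanh` is the default.
#'
#' @param hidden_units neurons in the hidden layer.
#' @param hidden_activation "tanh", "logistic" or "sine".
#' @param loss "cross_entropy" (entropy error) or "sum_of_squares".
#' @param max_epochs BFGS iteration cap.
#' @param weight_decay L2 penalty on the weights.
#' @param seed integer seed for weight initialization.
#' @return an `mlp_config` list.
#' @export
mlp_config <- function(hidden_units = 20L,
                       hidden_activation = c("tanh", "logistic", "sine"),
                       loss = c("cross_entropy", "sum_of_squares"),
                       max_epochs = 200L, weight_decay = 1e-4, seed = 1L) {
  hidden_activation <- match.arg(hidden_activation)
  loss <- match.arg(loss)
  stopifnot(hidden_units >= 1L, max_epochs >= 1L, weight_decay >= 0)
  structure(list(hidden_units = as.integer(hidden_units),
                 hidden_activation = hidden_activation, loss = loss,
                 max_epochs = as.integer(max_epochs),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "mlp_config")
}

#' Train the multilayer-perceptron classifier
#'
#' Inputs are z-scored with the training rows only; the network is trained
#' full-batch with BFGS (analytic gradients) to convergence or
#' `cfg$max_epochs`. Fully reproducible given (`cfg$seed`, `split`).
#'
#' @param features data.frame with the predictor columns.
#' @param labels group labels, one per row.
#' @param split a `split_plan` over row ids (positions).
#' @param cfg an [mlp_config()].
#' @param columns predictor columns.
#' @return an `mlp_model`: weights, scaling, confusion matrices and
#'   accuracies (percent) for training and validation, convergence info.
#' @export
train_mlp <- function(features, labels, split, cfg = mlp_config(),
                      columns = intersect(feature_columns(), names(features))) {
  x <- as.matrix(features[, columns, drop = FALSE])
  g <- factor(labels)
  stopifnot(nrow(x) == length(g))
  tr <- split$train_ids
  va <- split$validation_ids
  ctr <- colMeans(x[tr, , drop = FALSE])
  scl <- apply(x[tr, , drop = FALSE], 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  k <- nlevels(g)
  Y <- diag(k)[as.integer(g), , drop = FALSE]

  p <- ncol(x); H <- cfg$hidden_units
  npar <- (p + 1) * H + (H + 1) * k
  set.seed(cfg$seed)
  par0 <- stats::runif(npar, -0.5, 0.5) / sqrt(p + 1)

  obj <- mlp_objective(xs[tr, , drop = FALSE], Y[tr, , drop = FALSE], p, H, k, cfg)
  opt <- stats::optim(par0, fn = obj$fn, gr = obj$gr, method = "BFGS",
                      control = list(maxit = cfg$max_epochs, reltol = 1e-10))
  if (!is.finite(opt$value))
    stop("non-finite loss after optimization; loss = ", opt$value,
         ", activation = ", cfg$hidden_activation)

  model <- structure(list(
    par = opt$par, p = p, hidden = H, k = k, cfg = cfg,
    columns = columns, center = ctr, scale = scl, levels = levels(g),
    converged = opt$convergence == 0L, final_loss = opt$value,
    split = split
  ), class = "mlp_model")

  pred_tr <- predict(model, features[tr, , drop = FALSE])
  pred_va <- predict(model, features[va, , drop = FALSE])
  model$confusion_train <- table(truth = g[tr], predicted = pred_tr)
  model$confusion_validation <- table(truth = g[va], predicted = pred_va)
  model$accuracy_train <- 100 * mean(pred_tr == g[tr])
  model$accuracy_validation <- 100 * mean(pred_va == g[va])
  vl <- mlp_objective(xs[va, , drop = FALSE], Y[va, , drop = FALSE],
                      p, H, k, cfg)$fn(opt$par)
  model$validation_loss <- vl
  model
}

#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, object$columns, drop = FALSE])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  P <- mlp_forward(object$par, xs, object$p, object$hidden, object$k,
                   object$cfg$hidden_activation)$P
  if (type == "prob") {
    colnames(P) <- object$levels
    return(P)
  }
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("MLP %d-%d-%d (%s hidden, %s loss)\n", x$p, x$hidden, x$k,
              x$cfg$hidden_activation, x$cfg$loss))
  cat(sprintf("  accuracy: %.1f%% training, %.1f%% validation\n",
              x$accuracy_train, x$accuracy_validation))
  invisible(x)
}

mlp_unpack <- function(par, p, H, k) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(p * H)], p, H); i <- i + p * H
  b1 <- par[i + seq_len(H)]; i <- i + H
  W2 <- matrix(par[i + seq_len(H * k)], H, k); i <- i + H * k
  b2 <- par[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward <- function(par, X, p, H, k, act) {
  w <- mlp_unpack(par, p, H, k)
  Z1 <- sweep(X %*% w$W1, 2, w$b1, "+")
  A1 <- switch(act, tanh = tanh(Z1),
               logistic = 1 / (1 + exp(-Z1)),
               sine = sin(Z1))
  Z2 <- sweep(A1 %*% w$W2, 2, w$b2, "+")
  Z2 <- Z2 - apply(Z2, 1, max)
  E <- exp(Z2)
  P <- E / rowSums(E)
  list(w = w, Z1 = Z1, A1 = A1, P = P)
}

mlp_objective <- function(X, Y, p, H, k, cfg) {
  act <- cfg$hidden_activation
  lambda <- cfg$weight_decay
  fn <- function(par) {
    f <- mlp_forward(par, X, p, H, k, act)
    loss <- if (cfg$loss == "cross_entropy") {
      -sum(Y * log(pmax(f$P, 1e-12)))
    } else {
      sum((f$P - Y)^2)
    }
    loss + lambda * sum(par^2)
  }
  gr <- function(par) {
    f <- mlp_forward(par, X, p, H, k, act)
    d2 <- if (cfg$loss == "cross_entropy") {
      f$P - Y
    } else {
      dP <- 2 * (f$P - Y)
      f$P * (dP - rowSums(dP * f$P))
    }
    gW2 <- crossprod(f$A1, d2)
    gb2 <- colSums(d2)
    dA1 <- d2 %*% t(f$w$W2)
    d1 <- dA1 * switch(act, tanh = 1 - f$A1^2,
                       logistic = f$A1 * (1 - f$A1),
                       sine = cos(f$Z1))
    gW1 <- crossprod(X, d1)
    gb1 <- colSums(d1)
    c(as.numeric(gW1), gb1, as.numeric(gW2), gb2) + 2 * lambda * par
  }
  list(fn = fn, gr = gr)
}

#' Automated topology search
#'
#' Trains one network per configuration on the same split and ranks them by
#' validation accuracy; ties broken by fewer hidden units, then lower
#' validation loss. Configurations that fail to train are skipped and
#' logged.
#'
#' @inheritParams train_mlp
#' @param hidden_grid hidden-layer sizes to try.
#' @param activations hidden activations to try.
#' @param losses loss functions to try.
#' @param seed seed applied to every configuration.
#' @return list: `best` (an `mlp_model`), `leaderboard` (data.frame).
#' @export
search_topology <- function(features, labels, split,
                            hidden_grid = seq(5L, 25L, by = 5L),
                            activations = "tanh",
                            losses = "cross_entropy",
                            seed = 1L, max_epochs = 200L,
                            columns = intersect(feature_columns(),
                                                names(features))) {
  if (length(hidden_grid) == 0L) stop("empty topology grid")
  grid <- expand.grid(hidden = hidden_grid, activation = activations,
                      loss = losses, stringsAsFactors = FALSE)
  models <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- mlp_config(hidden_units = grid$hidden[i],
                      hidden_activation = grid$activation[i],
                      loss = grid$loss[i], max_epochs = max_epochs,
                      seed = seed)
    m <- tryCatch(train_mlp(features, labels, split, cfg, columns = columns),
                  error = function(e) {
                    message("topology ", grid$hidden[i], "/",
                            grid$activation[i], " failed: ",
                            conditionMessage(e))
                    NULL
                  })
    models[[i]] <<- m
    if (is.null(m)) return(NULL)
    data.frame(hidden = grid$hidden[i], activation = grid$activation[i],
               loss = grid$loss[i],
               accuracy_train = m$accuracy_train,
               accuracy_validation = m$accuracy_validation,
               validation_loss = m$validation_loss,
               stringsAsFactors = FALSE)
  })
  lb <- do.call(rbind, rows)
  if (is.null(lb)) stop("all topologies failed to train")
  ord <- order(-lb$accuracy_validation, lb$hidden, lb$validation_loss)
  lb <- lb[ord, ]
  best_i <- which(vapply(models, function(m) {
    !is.null(m) && m$hidden == lb$hidden[1] &&
      m$cfg$hidden_activation == lb$activation[1] && m$cfg$loss == lb$loss[1]
  }, logical(1)))[1]
  list(best = models[[best_i]], leaderboard = lb)
}

#' Permutation variable importance
#'
#' For each predictor, the evaluation-set error after permuting that column,
#' divided by the baseline error, averaged over `reps` permutations. Values
#' near 1 mean the variable is uninformative; larger values mean the model
#' relies on it. Errors are add-one smoothed, (misclassified + 1) / (n + 1),
#' so the ratio stays defined when the baseline error is zero.
#'
#' @param model a fitted `mlp_model` (or any model with a class `predict`
#'   method over `columns`).
#' @param features data.frame of predictors.
#' @param labels true labels.
#' @param eval_ids row positions to evaluate on; defaults to the model's
#'   validation split.
#' @param reps permutations per variable.
#' @param seed integer seed.
#' @return data.frame: variable, importance; attribute `baseline_error`.
#' @export
permutation_importance <- function(model, features, labels,
                                   eval_ids = model$split$validation_ids,
                                   reps = 50L, seed = 1L) {
  stopifnot(reps >= 1L)
  columns <- model$columns
  g <- factor(labels, levels = model$levels)
  xe <- features[eval_ids, , drop = FALSE]
  ge <- g[eval_ids]
  n <- length(eval_ids)
  err <- function(pred) (sum(pred != ge) + 1) / (n + 1)
  base <- err(predict(model, xe))
  set.seed(seed)
  imp <- vapply(columns, function(col) {
    ratios <- vapply(seq_len(reps), function(r) {
      xp <- xe
      xp[[col]] <- xp[[col]][sample.int(n)]
      err(predict(model, xp)) / base
    }, numeric(1))
    mean(ratios)
  }, numeric(1))
  out <- data.frame(variable = columns, importance = unname(imp),
                    stringsAsFactors = FALSE)
  attr(out, "baseline_error") <- base
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  out[order(-out$importance), ]
}
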