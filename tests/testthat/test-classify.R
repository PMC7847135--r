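test_that("stepwise LDA picks the separating variable and drops pure noise", {
  set.seed(5)
  n <- 30
  f <- data.frame(A = c(stats::rnorm(n), stats::rnorm(n, 10)),
                  B = stats::rnorm(2 * n))
  g <- rep(c("g1", "g2"), each = n)
  fit <- stepwise_lda(f, g, columns = c("A", "B"))
  expect_identical(fit$selected_vars, "A")
  expect_equal(fit$accuracy_resub, 100)
})

test_that("three groups with >= 2 selected variables yield 2 canonical axes", {
  f <- sim_features(n_per_group = 20, sep = 3, seed = 8)
  fit <- stepwise_lda(f, f$group, columns = grep("^inf|^noise", names(f),
                                                 value = TRUE))
  expect_gte(length(fit$selected_vars), 2L)
  expect_equal(ncol(fit$scores), 2L)
  expect_equal(sum(fit$confusion_resub), nrow(f))
  expect_equal(unname(rowSums(fit$confusion_resub)), rep(20, 3))
})

test_that("stepwise trace is reproducible and scores survive rescaling", {
  f <- sim_features(n_per_group = 15, sep = 2.5, seed = 12)
  cols <- grep("^inf|^noise", names(f), value = TRUE)
  fit1 <- stepwise_lda(f, f$group, columns = cols)
  fit2 <- stepwise_lda(f, f$group, columns = cols)
  expect_identical(fit1$step_trace$variable, fit2$step_trace$variable)
  # affine rescaling of one input feature: same selection, same scores up
  # to axis sign
  f3 <- f; f3$inf1 <- f3$inf1 * 100 - 7
  fit3 <- stepwise_lda(f3, f3$group, columns = cols)
  expect_identical(fit3$selected_vars, fit1$selected_vars)
  for (ax in seq_len(ncol(fit1$scores)))
    expect_equal(abs(fit3$scores[, ax]), abs(fit1$scores[, ax]),
                 tolerance = 1e-6)
})

test_that("no discriminative variables raises an error", {
  set.seed(3)
  f <- data.frame(A = stats::rnorm(20), B = stats::rnorm(20))
  g <- rep(c("x", "y"), each = 10)
  expect_error(suppressWarnings(stepwise_lda(f, g, columns = c("A", "B"),
                                             f_enter = 1e6)),
               "no discriminative variables")
})

test_that("make_split reproduces the 60% per-group sizes and forcing rule", {
  labels <- rep(c("H1", "H2", "H3"), c(39, 23, 39))
  s <- make_split(labels, seed = 7)
  expect_equal(as.integer(table(labels[s$train_ids])), c(23L, 14L, 23L))
  expect_length(intersect(s$train_ids, s$validation_ids), 0)
  expect_setequal(c(s$train_ids, s$validation_ids), seq_along(labels))
  for (sd in 1:25) {
    sf <- make_split(labels, forced_validation_ids = c(4L, 50L), seed = sd)
    expect_true(all(c(4L, 50L) %in% sf$validation_ids))
  }
  expect_identical(make_split(labels, seed = 99), make_split(labels, seed = 99))
})

test_that("MLP gradients match finite differences", {
  set.seed(2)
  X <- matrix(stats::rnorm(40), 10, 4)
  Y <- diag(3)[sample(1:3, 10, replace = TRUE), ]
  for (act in c("tanh", "logistic", "sine"))
    for (loss in c("cross_entropy", "sum_of_squares")) {
      cfg <- mlp_config(hidden_units = 3, hidden_activation = act, loss = loss)
      obj <- spotmorph:::mlp_objective(X, Y, 4, 3, 3, cfg)
      par <- stats::rnorm(3 * 4 + 3 + 3 * 3 + 3, sd = 0.3)
      ga <- obj$gr(par)
      gn <- vapply(seq_along(par), function(i) {
        e <- rep(0, length(par)); e[i] <- 1e-5
        (obj$fn(par + e) - obj$fn(par - e)) / 2e-5
      }, numeric(1))
      expect_equal(ga, gn, tolerance = 1e-5)
    }
})

test_that("MLP fits separable data, is deterministic, and chance on permuted labels", {
  set.seed(44)
  n <- 25
  f <- data.frame(x1 = c(stats::rnorm(n), stats::rnorm(n, 8)),
                  x2 = stats::rnorm(2 * n))
  g <- rep(c("a", "b"), each = n)
  sp <- make_split(g, seed = 1)
  m1 <- train_mlp(f, g, sp, mlp_config(hidden_units = 10, seed = 2),
                  columns = c("x1", "x2"))
  expect_equal(m1$accuracy_train, 100)
  m2 <- train_mlp(f, g, sp, mlp_config(hidden_units = 10, seed = 2),
                  columns = c("x1", "x2"))
  expect_identical(m1$par, m2$par)
  expect_identical(m1$confusion_validation, m2$confusion_validation)
  # permuted labels: validation accuracy within the 95% binomial band of chance
  set.seed(9)
  gp <- sample(g)
  sp2 <- make_split(gp, seed = 3)
  mp <- train_mlp(f, gp, sp2, mlp_config(hidden_units = 10, seed = 2),
                  columns = c("x1", "x2"))
  nv <- length(sp2$validation_ids)
  band <- stats::qbinom(c(0.025, 0.975), nv, 0.5) / nv * 100
  expect_gte(mp$accuracy_validation, band[1])
  expect_lte(mp$accuracy_validation, band[2])
})

test_that("MLP agrees with an established single-hidden-layer fit on easy data", {
  skip_if_not_installed("nnet")
  f <- sim_features(n_per_group = 20, sep = 4, seed = 21)
  cols <- grep("^inf", names(f), value = TRUE)
  sp <- make_split(f$group, seed = 2)
  ours <- train_mlp(f, f$group, sp,
                    mlp_config(hidden_units = 8, hidden_activation = "logistic",
                               seed = 3), columns = cols)
  xs <- scale(as.matrix(f[sp$train_ids, cols]))
  set.seed(3)
  ref <- nnet::nnet(x = xs, y = class.ind2 <- diag(3)[as.integer(factor(f$group[sp$train_ids])), ],
                    size = 8, softmax = TRUE, trace = FALSE, maxit = 300)
  ref_acc <- 100 * mean(max.col(ref$fitted.values) ==
                          as.integer(factor(f$group[sp$train_ids])))
  expect_equal(ours$accuracy_train, 100)
  expect_equal(ref_acc, 100)
})

test_that("topology search ranks by validation accuracy with the tie-breaks", {
  f <- sim_features(n_per_group = 15, sep = 4, seed = 17)
  sp <- make_split(f$group, seed = 5)
  cols <- grep("^inf", names(f), value = TRUE)
  res <- search_topology(f, f$group, sp, hidden_grid = c(5L, 20L), seed = 4,
                         columns = cols)
  # both reach the same validation accuracy on easy data: fewer units win
  if (length(unique(res$leaderboard$accuracy_validation)) == 1L)
    expect_equal(res$best$hidden, 5L)
  expect_equal(res$leaderboard$accuracy_validation,
               sort(res$leaderboard$accuracy_validation, decreasing = TRUE))
  res2 <- search_topology(f, f$group, sp, hidden_grid = c(5L, 20L), seed = 4,
                          columns = cols)
  expect_identical(res$leaderboard, res2$leaderboard)
  one <- search_topology(f, f$group, sp, hidden_grid = 7L, seed = 4,
                         columns = cols)
  expect_equal(one$best$hidden, 7L)
})

test_that("permutation importance flags the informative variable", {
  set.seed(31)
  n <- 30
  f <- data.frame(signal = c(stats::rnorm(n), stats::rnorm(n, 6)),
                  junk = stats::rnorm(2 * n))
  g <- rep(c("a", "b"), each = n)
  sp <- make_split(g, seed = 1)
  m <- train_mlp(f, g, sp, mlp_config(hidden_units = 6, seed = 2),
                 columns = c("signal", "junk"))
  imp <- permutation_importance(m, f, g, reps = 50, seed = 8)
  expect_gt(imp$importance[imp$variable == "signal"],
            imp$importance[imp$variable == "junk"])
  expect_gte(imp$importance[imp$variable == "junk"], 0.8)
  expect_lte(imp$importance[imp$variable == "junk"], 1.2)
  imp2 <- permutation_importance(m, f, g, reps = 50, seed = 8)
  expect_identical(imp, imp2)
})

test_that("leave-one-out accuracy does not beat resubstitution on average", {
  accs <- vapply(1:12, function(s) {
    f <- sim_features(n_per_group = 12, sep = 1.2, seed = 100 + s)
    fit <- tryCatch(
      stepwise_lda(f, f$group, columns = grep("^inf|^noise", names(f),
                                              value = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) return(c(NA_real_, NA_real_))
    c(fit$accuracy_resub, fit$accuracy_loo)
  }, numeric(2))
  ok <- !is.na(accs[1, ])
  expect_gte(mean(accs[1, ok]), mean(accs[2, ok]))
})
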