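# Naive Bayes, metrics, cross-validation and ROC; oracles are brute-force
# plain-arithmetic Bayes computations independent of the log-space
# implementation.

brute_force_posterior <- function(x_train, y_train, x_new, alpha) {
  classes <- sort(unique(y_train))
  V <- ncol(x_train)
  unnorm <- numeric(length(classes))
  names(unnorm) <- classes
  for (cl in classes) {
    prior <- mean(y_train == cl)
    counts <- colSums(x_train[y_train == cl, , drop = FALSE])
    theta <- (counts + alpha) / (sum(counts) + alpha * V)
    unnorm[cl] <- prior * prod(theta ^ x_new)
  }
  unnorm / sum(unnorm)
}

random_instance <- function(n_docs, V) {
  x <- matrix(rpois(n_docs * V, 2), nrow = n_docs,
              dimnames = list(NULL, paste0("g", seq_len(V))))
  y <- factor(c("neg", "pos")[c(1, 2, sample(1:2, n_docs - 2, replace = TRUE))])
  list(x = x, y = y)
}

test_that("training matches hand-computed Laplace-smoothed likelihoods", {
  # 2 documents, 2 words: doc1 = (3, 0) labeled A, doc2 = (1, 2) labeled B
  x <- matrix(c(3, 1, 0, 2), nrow = 2, dimnames = list(NULL, c("w1", "w2")))
  m <- train_nb(x, c("A", "B"), alpha = 1)
  expect_equal(exp(m$log_lik["A", "w1"]), (3 + 1) / (3 + 2))
  expect_equal(exp(m$log_lik["A", "w2"]), (0 + 1) / (3 + 2))
  expect_equal(exp(m$log_lik["B", "w1"]), (1 + 1) / (3 + 2))
  expect_equal(exp(m$log_lik["B", "w2"]), (2 + 1) / (3 + 2))
  expect_equal(unname(exp(m$log_prior)), c(0.5, 0.5))
  # model invariants: priors and per-class likelihoods sum to one
  expect_equal(sum(exp(m$log_prior)), 1)
  expect_equal(unname(rowSums(exp(m$log_lik))), c(1, 1))
  expect_error(train_nb(x, c("A", "B"), alpha = 0), "alpha")
  expect_error(train_nb(x, c("A", "A")), "two classes")
})

test_that("prediction ties resolve to the first (negative) class", {
  x <- matrix(c(2, 0, 0, 2), nrow = 2, dimnames = list(NULL, c("w1", "w2")))
  m <- train_nb(x, factor(c("neg", "pos"), levels = c("neg", "pos")))
  p <- predict_nb(m, c(w1 = 1, w2 = 1))
  expect_equal(unname(p$posterior), c(0.5, 0.5))
  expect_equal(p$label, "neg")
  # all-zero vector falls back to the prior arg-max
  m2 <- train_nb(rbind(x, c(1, 1)), factor(c("neg", "pos", "pos")))
  expect_equal(predict_nb(m2, c(w1 = 0, w2 = 0))$label, "pos")
})

test_that("vocabulary mismatches are rejected", {
  x <- matrix(1:4, nrow = 2, dimnames = list(NULL, c("w1", "w2")))
  m <- train_nb(x, c("A", "B"))
  expect_error(predict_nb(m, c(a = 1)), "vocabulary")
  expect_error(predict_nb(m, c(w2 = 1, w1 = 0)), "vocabulary")
})

test_that("posteriors equal brute-force Bayes on random toy instances", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      n_docs <- sample(3:5, 1)
      V <- sample(2:4, 1)
      inst <- random_instance(n_docs, V)
      m <- train_nb(inst$x, inst$y, alpha = 1)
      x_new <- rpois(V, 2)
      names(x_new) <- colnames(inst$x)
      p <- predict_nb(m, x_new)
      oracle <- brute_force_posterior(inst$x, as.character(inst$y), x_new, 1)
      expect_equal(unname(p$posterior), unname(oracle[m$classes]),
                   tolerance = 1e-10)
    }
  })
})

test_that("metrics satisfy the precision/recall/F definitions", {
  ev <- evaluate_predictions(c("p", "p", "p", "p", "n"),
                             c("p", "p", "p", "n", "p"), "p")
  expect_equal(ev$tp, 3); expect_equal(ev$fp, 1); expect_equal(ev$fn, 1)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  expect_equal(ev$f_score, 0.75)
  perfect <- evaluate_predictions(c("p", "n"), c("p", "n"), "p")
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f_score, 1)
  expect_equal(perfect$accuracy, 1)
  # no positives predicted while positives exist: P undefined, R = 0
  none <- evaluate_predictions(c("p", "n"), c("n", "n"), "p")
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  expect_error(evaluate_predictions(c("p"), c("p", "n"), "p"), "length")
})

test_that("metrics match confusion-matrix substitution on random counts", {
  withr::with_seed(7, {
    for (rep in 1:1000) {
      tp <- sample(0:20, 1); fp <- sample(0:20, 1)
      fn <- sample(0:20, 1); tn <- sample(0:20, 1)
      if (tp + fp + fn + tn == 0) next
      truth <- c(rep("p", tp), rep("n", fp), rep("p", fn), rep("n", tn))
      pred <- c(rep("p", tp), rep("p", fp), rep("n", fn), rep("n", tn))
      ev <- evaluate_predictions(truth, pred, "p")
      P <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      R <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      expect_identical(ev$precision, P)
      expect_identical(ev$recall, R)
      if (!is.na(P) && !is.na(R) && P + R > 0) {
        expect_equal(ev$f_score, 2 * P * R / (P + R))
        # harmonic-mean property
        expect_gte(ev$f_score, min(P, R) - 1e-12)
        expect_lte(ev$f_score, max(P, R) + 1e-12)
      }
      expect_equal(ev$accuracy, (tp + tn) / (tp + fp + fn + tn))
    }
  })
})

test_that("metrics are invariant to permutation of example order", {
  withr::with_seed(11, {
    truth <- sample(c("p", "n"), 40, replace = TRUE)
    pred <- sample(c("p", "n"), 40, replace = TRUE)
    ev1 <- evaluate_predictions(truth, pred, "p")
    perm <- sample(40)
    ev2 <- evaluate_predictions(truth[perm], pred[perm], "p")
    expect_equal(ev1[c("tp", "fp", "fn", "tn", "precision", "recall",
                       "f_score", "accuracy")],
                 ev2[c("tp", "fp", "fn", "tn", "precision", "recall",
                       "f_score", "accuracy")])
  })
})

test_that("token agreement reproduces the positional worked example", {
  expect_identical(token_agreement_score(c("n", "y", "n", "a"),
                                         c("n", "n", "n", "a")), 0.75)
  expect_identical(token_agreement_score(c("y", "a"), c("y", "a")), 1.0)
  expect_identical(token_agreement_score(c("y", "n"), c("n", "y")), 0.0)
  expect_error(token_agreement_score(c("y"), c("y", "n")), "length")
  expect_error(token_agreement_score(c("x"), c("y")), "\\{n, y, a\\}")
})

test_that("stratified cross-validation partitions every example once", {
  withr::with_seed(5, {
    x <- matrix(rpois(10 * 3, 2), nrow = 10,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- factor(rep(c("neg", "pos"), 5))
    cv <- cross_validate(x, y, k = 10, seed = 3)
    expect_equal(sort(unique(cv$fold_assignment)), 1:10)
    expect_equal(as.integer(table(cv$fold_assignment)), rep(1L, 10))
    expect_equal(cv$pooled$tp + cv$pooled$fp + cv$pooled$fn + cv$pooled$tn,
                 10)
    # same seed -> identical fold assignment
    cv2 <- cross_validate(x, y, k = 10, seed = 3)
    expect_identical(cv2$fold_assignment, cv$fold_assignment)
  })
})

test_that("split validation respects the training fraction and strata", {
  withr::with_seed(6, {
    x <- matrix(rpois(20 * 3, 2), nrow = 20,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- factor(rep(c("neg", "pos"), 10))
    res <- split_validate(x, y, train_frac = 0.4, seed = 2)
    expect_length(res$test_idx, 12)  # 60% of each class tested
    res5 <- split_validate(x, y, train_frac = 0.5, seed = 2)
    expect_length(res5$test_idx, 10)
  })
})

test_that("ROC sweeps thresholds from (0,0) to (1,1) with the right AUC", {
  roc <- roc_curve(c("p", "p", "n", "n"), c(0.9, 0.8, 0.2, 0.1), "p")
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # perfect separation
  expect_equal(attr(roc, "auc"), 1)
  # identical posteriors: a single step, AUC = 0.5
  flat <- roc_curve(c("p", "n", "p", "n"), rep(0.5, 4), "p")
  expect_equal(attr(flat, "auc"), 0.5)
  expect_error(roc_curve(c("p", "p"), c(0.1, 0.2), "p"), "both classes")
  expect_error(roc_curve(c("p", "n"), c(1.2, 0.1), "p"), "\\[0, 1\\]")
})

test_that("AUC equals the brute-force pairwise concordance count", {
  concordance <- function(truth, post, positive) {
    pos <- post[truth == positive]
    neg <- post[truth != positive]
    total <- 0
    for (a in pos) for (b in neg) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
    total / (length(pos) * length(neg))
  }
  withr::with_seed(13, {
    for (rep in 1:25) {
      n <- sample(6:15, 1)
      truth <- c("p", "n", sample(c("p", "n"), n - 2, replace = TRUE))
      post <- round(runif(n), 2)
      roc <- roc_curve(truth, post, "p")
      expect_equal(attr(roc, "auc"), concordance(truth, post, "p"),
                   tolerance = 1e-12)
    }
  })
})

test_that("cross-validation AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    truth <- sample(c("neg", "pos"), 50, replace = TRUE)
    post <- runif(50)
    roc <- roc_curve(truth, post, "pos")
    ref <- suppressMessages(pROC::auc(pROC::roc(truth, post,
                                                levels = c("neg", "pos"),
                                                direction = "<")))
    expect_equal(attr(roc, "auc"), as.numeric(ref), tolerance = 1e-12)
  })
})

test_that("model JSON serialization round-trips predictions", {
  x <- matrix(rpois(8, 3), nrow = 4, dimnames = list(NULL, c("a", "b")))
  x[1, 1] <- x[1, 1] + 1
  m <- train_nb(x, factor(c("neg", "pos", "neg", "pos")))
  path <- tempfile(fileext = ".json")
  write_nb_model(m, path)
  m2 <- read_nb_model(path)
  expect_equal(m2$classes, m$classes)
  expect_equal(m2$log_lik, m$log_lik)
  p1 <- predict_nb(m, c(a = 2, b = 1))
  p2 <- predict_nb(m2, c(a = 2, b = 1))
  expect_equal(p1$posterior, p2$posterior)
  expect_equal(p1$label, p2$label)
})
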