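# small helper: gaussian two-class feature matrix with mean shift `sep`
sim_features <- function(n_per_class, p = 10, sep = 0, seed = 1) {
  with_seed <- function(s, expr) { set.seed(s); expr }
  with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p, mean = sep), n_per_class, p),
               matrix(rnorm(n_per_class * p), n_per_class, p))
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, y = rep(c(1L, 0L), each = n_per_class))
  })
}

test_that("metrics reproduce confusion-matrix arithmetic on hand cases", {
  # perfect classifier
  r <- compute_metrics(rep(c(1, 0), each = 64),
                       rep(c(0.9, 0.1), each = 64))
  expect_equal(r$TP, 64L); expect_equal(r$TN, 64L)
  expect_equal(r$FP, 0L); expect_equal(r$FN, 0L)
  expect_equal(c(r$Sn, r$Sp, r$ACC, r$MCC, r$AUROC), rep(1, 5))

  # all-tied scores: AUROC is exactly 1/2
  tied <- compute_metrics(c(1, 1, 0, 0), rep(0.3, 4))
  expect_equal(tied$AUROC, 0.5)

  # degenerate MCC flagged as zero
  allpos <- compute_metrics(c(1, 1, 0), c(0.9, 0.8, 0.7))
  expect_true(allpos$mcc_degenerate)
  expect_equal(allpos$MCC, 0)

  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("metrics agree with brute-force oracles on random instances", {
  set.seed(55)
  for (rep in 1:300) {
    n <- sample(4:50, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    scores <- round(runif(n), sample(1:3, 1)) # coarse rounding forces ties
    got <- compute_metrics(truth, scores)
    want <- o_metrics(truth, scores)
    expect_equal(got[c("TP", "FP", "TN", "FN")],
                 want[c("TP", "FP", "TN", "FN")], ignore_attr = TRUE)
    expect_equal(got$MCC, want$MCC, tolerance = 1e-12)
    expect_equal(got$Sn, want$Sn)
    expect_equal(got$Sp, want$Sp)
    expect_equal(got$ACC, want$ACC)
    expect_equal(got$AUROC, o_auroc(truth, scores), tolerance = 1e-12)
  }
})

test_that("package AUROC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (rep in 1:20) {
    truth <- c(0, 1, rbinom(38, 1, 0.5))
    scores <- runif(40)
    expect_equal(auroc(truth, scores),
                 as.numeric(pROC::auc(pROC::roc(truth, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(3)
  truth <- rbinom(60, 1, 0.5); truth[1:2] <- c(0, 1)
  scores <- rnorm(60)
  a <- auroc(truth, scores)
  expect_equal(auroc(truth, exp(scores)), a)
  expect_equal(auroc(truth, 3 * scores - 10), a)
  expect_equal(auroc(truth, rank(scores)), a)
})

test_that("MCC flips sign when all calls are inverted on balanced classes", {
  set.seed(12)
  truth <- rep(c(0, 1), 25)
  scores <- runif(50)
  m1 <- compute_metrics(truth, scores)$MCC
  m2 <- compute_metrics(truth, 1 - scores,
                        threshold = 0.5 + 1e-12)$MCC  # flip every call
  expect_equal(m2, -m1, tolerance = 1e-12)
})

test_that("training is deterministic and interpolates separable data", {
  d <- sim_features(30, sep = 3, seed = 4)
  for (fam in c("random_forest", "gradient_boosting", "decision_tree",
                "logistic_regression", "svm")) {
    spec <- classifier_spec(fam, seed = 9)
    m1 <- train_classifier(spec, d$x, d$y)
    m2 <- train_classifier(spec, d$x, d$y)
    expect_equal(predict_scores(m1, d$x), predict_scores(m2, d$x),
                 label = fam)
  }
  rf <- train_classifier(classifier_spec("random_forest", seed = 9), d$x, d$y)
  train_acc <- compute_metrics(d$y, predict_scores(rf, d$x))$ACC
  expect_equal(train_acc, 1)
  expect_error(train_classifier(classifier_spec("random_forest"),
                                d$x, rep(1L, nrow(d$x))), "both classes")
})

test_that("held-out AUROC on label-free noise stays near one half", {
  aucs <- vapply(1:20, function(s) {
    d <- sim_features(40, sep = 0, seed = 100 + s)
    tr <- c(1:20, 41:60); te <- setdiff(1:80, tr)
    spec <- classifier_spec("random_forest", seed = s,
                            params = list(num_trees = 100))
    model <- train_classifier(spec, d$x[tr, ], d$y[tr])
    auroc(d$y[te], predict_scores(model, d$x[te, ]))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("cross-validation folds are a stratified seeded partition", {
  d <- sim_features(25, sep = 1, seed = 6)
  spec <- classifier_spec("random_forest", seed = 2,
                          params = list(num_trees = 100))
  cv <- cross_validate(spec, d$x, d$y, k = 10, seed = 2)
  # every sample in exactly one test fold
  expect_equal(sort(unique(cv$fold_id)), 1:10)
  expect_length(cv$fold_id, 50)
  # per-class fold sizes differ by at most one
  for (cl in 0:1) {
    sizes <- table(cv$fold_id[d$y == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  cv2 <- cross_validate(spec, d$x, d$y, k = 10, seed = 2)
  expect_equal(cv$scores, cv2$scores)
  expect_s3_class(cv$pooled, "evaluation_report")
  expect_length(cv$folds, 10)
  expect_named(cv$fold_mean, c("Sn", "Sp", "ACC", "MCC", "AUROC"))

  expect_error(cross_validate(spec, d$x, d$y, k = 1), "at least 2")
  expect_error(cross_validate(spec, d$x[1:12, ], d$y[1:12], k = 10),
               "at least k")
})

test_that("leave-pair-out (k equal to class size) still partitions correctly", {
  d <- sim_features(8, sep = 2, seed = 10)
  spec <- classifier_spec("random_forest", seed = 1,
                          params = list(num_trees = 50))
  cv <- cross_validate(spec, d$x, d$y, k = 8, seed = 1)
  expect_equal(as.vector(table(cv$fold_id)), rep(2L, 8))
  for (f in 1:8) expect_setequal(d$y[cv$fold_id == f], c(0L, 1L))
})

test_that("benchmark report has the expected structure and is reproducible", {
  ps <- generate_peptides(15, delta = 0.4, seed = 31)
  specs <- list(classifier_spec("random_forest", seed = 1,
                                params = list(num_trees = 100)),
                classifier_spec("decision_tree", seed = 1))
  b1 <- run_benchmark(ps, specs = specs, seed = 5, k = 3)
  # 10 single-feature rows + one fusion row per spec, per evaluation mode
  expect_equal(nrow(b1$report), 2 * (10 + length(specs)))
  expect_setequal(unique(b1$report$mode), c("cv", "independent"))
  expect_equal(sum(b1$report$feature == "Fusion"), 4)
  expect_true(all(b1$report$AUROC >= 0 & b1$report$AUROC <= 1))
  b2 <- run_benchmark(ps, specs = specs, seed = 5, k = 3)
  expect_identical(b1$report, b2$report)
})

test_that("the prediction pipeline embeds the schema and scores new peptides", {
  ps <- generate_peptides(20, delta = 0.4, seed = 17)
  pipe <- train_pipeline(ps, spec = classifier_spec("random_forest", seed = 3,
                                                    params = list(num_trees = 100)))
  newps <- generate_peptides(5, delta = 0.4, seed = 99)
  pred <- predict(pipe, newps)
  expect_named(pred, c("id", "score", "call"))
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_true(all(pred$call %in% 0:1))
})
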