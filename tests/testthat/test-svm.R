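test_that("polynomial kernel matches its closed form and is symmetric", {
  expect_equal(polynomial_kernel(c(0, 0), c(0, 0), degree = 4), 1)
  expect_equal(polynomial_kernel(c(1, 1), c(1, 1), degree = 2), 9)
  for (i in 1:10) {
    v <- with_test_seed(i, list(x = rnorm(6), y = rnorm(6)))
    d <- sample(1:4, 1)
    expect_identical(polynomial_kernel(v$x, v$y, d),
                     polynomial_kernel(v$y, v$x, d))
  }
  expect_error(polynomial_kernel(1:3, 1:4, 2), "equal dimension")
  expect_error(polynomial_kernel(1:3, 1:3, 0), "positive integer")
})

test_that("config validates degree and penalty", {
  expect_error(svm_config(degree = 0), "1..10")
  expect_error(svm_config(degree = 11), "1..10")
  expect_error(svm_config(C = -1), "positive")
  cfg <- svm_config()
  expect_equal(cfg$degree, 4L)
  expect_equal(cfg$C, 1.0)
  expect_true(cfg$standardize)
})

test_that("separable clusters train to 100% accuracy with valid duals", {
  dat <- make_separable_data()
  m <- svm_train(dat$x, dat$y, svm_config(degree = 1))
  expect_equal(predict(m, dat$x), dat$y, ignore_attr = TRUE)
  expect_lt(abs(sum(m$alphas * m$support_labels)), 1e-6)
  expect_true(all(m$alphas >= 0 & m$alphas <= m$config$C + 1e-9))
})

test_that("quadratic kernel separates XOR-patterned data", {
  dat <- make_xor_data()
  m <- svm_train(dat$x, dat$y, svm_config(degree = 2))
  expect_equal(mean(predict(m, dat$x) == dat$y), 1)
  # dual feasibility on this model too
  expect_lt(abs(sum(m$coefs)), 1e-6)
  expect_true(all(m$alphas <= m$config$C + 1e-9))
})

test_that("own decision function reproduces the backend's predictions", {
  dat <- make_xor_data(noise = 0.25, seed = 8)
  for (deg in 2:4) {
    cfg <- svm_config(degree = deg)
    m <- svm_train(dat$x, dat$y, cfg)
    xs <- sweep(sweep(dat$x, 2, m$center, "-"), 2, m$scale, "/")
    fit <- e1071::svm(xs, factor(dat$y, levels = c(-1, 1)),
                      type = "C-classification", kernel = "polynomial",
                      degree = deg, gamma = 1, coef0 = 1, cost = cfg$C,
                      scale = FALSE)
    expect_equal(predict(m, dat$x),
                 as.integer(as.character(predict(fit, xs))),
                 ignore_attr = TRUE)
    # decision values agree up to the backend's sign convention
    dv_backend <- attr(predict(fit, xs, decision.values = TRUE),
                       "decision.values")[, 1]
    lab <- if (colnames(attr(predict(fit, xs, decision.values = TRUE),
                             "decision.values")) == "-1/1") -1 else 1
    expect_equal(decision_values(m, dat$x), lab * dv_backend,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("training rejects degenerate inputs", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(svm_train(x, rep(1, 5)), "both classes")
  expect_error(svm_train(x, c(1, 1, -1, -1, 2)), "\\+1 or -1")
  x[1, 1] <- NA
  expect_error(svm_train(x, c(1, 1, -1, -1, 1)), "non-finite")
  expect_error(predict(svm_train(make_xor_data()$x, make_xor_data()$y),
                       c(1, 2, 3)), "dimension")
})

test_that("prediction is invariant to training-sample order", {
  dat <- make_xor_data(seed = 13)
  probe <- matrix(with_test_seed(99, runif(20, -0.5, 1.5)), ncol = 2)
  m1 <- svm_train(dat$x, dat$y)
  perm <- with_test_seed(5, sample(nrow(dat$x)))
  m2 <- svm_train(dat$x[perm, ], dat$y[perm])
  expect_equal(predict(m1, probe), predict(m2, probe))
  # decision values agree up to the dual solver's termination tolerance
  expect_equal(decision_values(m1, probe), decision_values(m2, probe),
               tolerance = 1e-2)
})

test_that("duplicating every sample leaves the separable boundary unchanged", {
  dat <- make_separable_data()
  probe <- matrix(seq(-3, 3, length.out = 13), ncol = 1)
  m1 <- svm_train(dat$x, dat$y, svm_config(degree = 1, standardize = FALSE))
  m2 <- svm_train(rbind(dat$x, dat$x), c(dat$y, dat$y),
                  svm_config(degree = 1, standardize = FALSE))
  expect_equal(predict(m1, probe), predict(m2, probe))
})

test_that("metric identities hold exactly on constructed prediction tables", {
  truth <- c(rep(1, 7), rep(-1, 5))
  pred <- truth
  pred[3] <- -1  # one positive missed
  m <- classification_metrics(truth, pred)
  expect_equal(m$ccr, 11 / 12)
  expect_equal(m$sensitivity, 6 / 7)
  expect_equal(m$specificity, 1)
  expect_equal(m$ccr * m$n, 11)          # ccr * total == correct count
  expect_equal(m$sensitivity * 7, 6)     # sensitivity * P == correct positives
  expect_equal(m$ccr_std, stats::sd(as.numeric(truth == pred)))
  # metrics depend only on the multiset of outcomes, not their order
  perm <- c(12:1)
  mp <- classification_metrics(truth[perm], pred[perm])
  expect_identical(mp[c("ccr", "sensitivity", "specificity")],
                   m[c("ccr", "sensitivity", "specificity")])
})

test_that("LOOCV predicts separable data perfectly and reports per-fold table", {
  x <- with_test_seed(17, rbind(matrix(rnorm(20, -3, 0.3), 10, 2),
                                matrix(rnorm(20, 3, 0.3), 10, 2)))
  y <- c(rep(-1, 10), rep(1, 10))
  rep <- evaluate_loocv(x, y, svm_config(degree = 4))
  expect_equal(rep$ccr, 1)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_equal(rep$ccr_std, 0)
  expect_equal(nrow(rep$per_fold), 20L)
  expect_identical(
    classification_metrics(rep$per_fold$truth, rep$per_fold$predicted)$ccr,
    rep$ccr)
  expect_error(evaluate_loocv(x, c(rep(-1, 19), 1)), "insufficient data")
})

test_that("fold standardization uses the training split only", {
  x <- with_test_seed(23, rbind(matrix(rnorm(12, -1), 6, 2),
                                matrix(rnorm(12, 1), 6, 2)))
  x[1, ] <- c(50, -50)  # extreme held-out point must not shift fold scaling
  y <- c(rep(-1, 6), rep(1, 6))
  m <- svm_train(x[-1, ], y[-1])
  expect_equal(m$center, colMeans(x[-1, ]), ignore_attr = TRUE)
  expect_equal(m$scale, apply(x[-1, ], 2, sd), ignore_attr = TRUE)
  # and LOOCV's fold-1 prediction equals the manual leave-out model's
  rep <- evaluate_loocv(x, y)
  expect_identical(rep$per_fold$predicted[1], predict(m, x[1, ]))
})

test_that("models serialize to JSON and restore with identical predictions", {
  dat <- make_xor_data(seed = 21)
  m <- svm_train(dat$x, dat$y, svm_config(degree = 3))
  p <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, p)
  m2 <- read_model_json(p)
  expect_equal(decision_values(m2, dat$x), decision_values(m, dat$x),
               tolerance = 1e-12)
})
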