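test_that("the architecture has the expected trainable parameter count", {
  # layer-shape arithmetic: conv f*(27c+1), BN 2f, FC in*out+out
  conv <- function(f, c) f * (27 * c + 1)
  bn <- function(f) 2 * f
  fc <- function(i, o) i * o + o
  want1 <- conv(32, 1) + conv(64, 32) + conv(128, 64) +
    bn(32) + bn(64) + bn(128) +
    fc(8192, 128) + fc(128, 128) + fc(128, 2)
  expect_equal(want1, 1343490)
  expect_equal(n_params(build_model(1L, seed = 1)), want1)
  want2 <- want1 - conv(32, 1) + conv(32, 2)
  expect_equal(n_params(build_model(2L, seed = 1)), want2)
  expect_error(build_model(3L), "1 or 2")
})

test_that("weight initialisation is N(0, 0.1) and seed-reproducible", {
  m1 <- build_model(1L, seed = 7)
  m2 <- build_model(1L, seed = 7)
  expect_identical(m1$params, m2$params)
  w <- c(m1$params$W2, m1$params$Wf1)
  expect_equal(mean(w), 0, tolerance = 5e-4)
  expect_equal(sd(w), 0.1, tolerance = 2e-3)
  m3 <- build_model(1L, seed = 8)
  expect_false(identical(m1$params$W1, m3$params$W1))
})

test_that("forward pass yields a proper softmax and batch consistency", {
  m <- build_model(1L, seed = 3)
  xs <- c(list(const_input(0)),
          lapply(1:3, function(i) {
            set.seed(i); const_input(runif(1))
          }),
          list(const_input(0)))  # duplicate of the first
  p <- cnn_predict(m, xs)
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-5)
  expect_equal(p[1, ], p[5, ], tolerance = 1e-7)  # identical inputs
  p2 <- cnn_predict(m, xs)
  expect_identical(p, p2)                         # deterministic
  expect_error(cnn_predict(build_model(2L, seed = 1), xs), "channels")
})

test_that("training separates a trivially separable toy cohort", {
  inputs <- separable_inputs(10L)
  m <- build_model(1L, seed = 4)
  fr <- cnn_train(m, inputs, train_config(iterations = 60L, batch = 8L,
                                          seed = 5))
  expect_s3_class(fr, "fold_result")
  expect_equal(nrow(fr$history), 60L)
  # converging loss: late moving average below early moving average
  expect_lt(mean(tail(fr$history$loss, 20)), mean(head(fr$history$loss, 20)))
  expect_gte(mean(tail(fr$history$accuracy, 10)), 0.95)
  p <- cnn_predict(fr$model, inputs)
  lab <- vapply(inputs, function(x) x$label, "")
  expect_equal(mean((p[, "COPD"] >= 0.5) == (lab == "COPD")), 1.0)
  # training is reproducible under the same seed
  fr2 <- cnn_train(build_model(1L, seed = 4), inputs,
                   train_config(iterations = 60L, batch = 8L, seed = 5))
  expect_identical(fr$history, fr2$history)
})

test_that("training rejects degenerate datasets", {
  m <- build_model(1L, seed = 1)
  expect_error(cnn_train(m, list()), "empty")
  one_class <- lapply(1:6, function(i) const_input(i / 10, label = "COPD"))
  expect_error(cnn_train(m, one_class), "both classes")
})

test_that("stratified folds form a disjoint cover within one subject", {
  lab <- rep(c("COPD", "non-COPD"), c(204, 392))
  fold <- make_folds(lab, k = 5, seed = 20)
  expect_identical(sort(unique(fold)), 1:5)
  sizes <- table(fold)
  expect_true(all(sizes %in% c(119L, 120L)))
  expect_identical(sum(sizes), 596L)          # every subject exactly once
  per_class <- table(fold, lab)
  expect_true(all(abs(per_class[, "COPD"] - 204 / 5) <= 1))
  expect_true(all(abs(per_class[, "non-COPD"] - 392 / 5) <= 1))
  expect_error(make_folds(lab, k = 1), ">= 2")
  expect_error(make_folds(rep(c("COPD", "non-COPD"), c(3, 10)), k = 5),
               "fewer than k")
})

test_that("cross-validation tests each subject once and pools perfectly
           separable data to accuracy 1", {
  inputs <- separable_inputs(8L)
  cv <- cross_validate(inputs, k = 2L,
                       cfg = train_config(iterations = 40L, batch = 8L),
                       seed = 21)
  expect_equal(sort(unlist(lapply(cv$fold_results, function(f)
    f$test_index))), seq_along(inputs))
  expect_false(anyNA(cv$predictions$p_copd))
  expect_equal(unname(cv$report$metrics["accuracy"]), 1.0)
  expect_equal(cv$report$auc, 1.0)
  cv2 <- cross_validate(inputs, k = 2L,
                        cfg = train_config(iterations = 40L, batch = 8L),
                        seed = 21)
  expect_identical(cv$predictions, cv2$predictions)
})
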