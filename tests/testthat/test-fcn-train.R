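test_that("analytic gradients agree with finite differences", {
  # directional derivative of the training-mode loss vs the backward pass,
  # on a tiny network (float arithmetic, hence the loose tolerance)
  set.seed(31)
  spec <- tiny_spec(input_len = 12L, filters = 3L, n_blocks = 2L)
  x <- matrix(rnorm(5 * 12), 5, 12)
  y <- c(0L, 1L, 0L, 1L, 1L)
  w <- edanet:::cpp_fcn_init(1L, 3L, 3L, 2L, 2L, 99L)
  g <- edanet:::cpp_fcn_loss_grad(w, x, y)
  flat_names <- c("W", "b", "gamma", "beta")
  rand_like <- function(a) { a[] <- rnorm(length(a)); a }
  for (trial in 1:3) {
    d <- w
    dot <- 0
    for (bi in seq_along(w$blocks)) {
      for (nm in flat_names) {
        d$blocks[[bi]][[nm]] <- rand_like(w$blocks[[bi]][[nm]])
        dot <- dot + sum(d$blocks[[bi]][[nm]] * g$blocks[[bi]][[nm]])
      }
    }
    for (nm in c("W", "b")) {
      d$dense[[nm]] <- rand_like(w$dense[[nm]])
      dot <- dot + sum(d$dense[[nm]] * g$dense[[nm]])
    }
    h <- 1e-3
    perturb <- function(sgn) {
      wp <- w
      for (bi in seq_along(w$blocks)) {
        for (nm in flat_names) {
          wp$blocks[[bi]][[nm]] <- w$blocks[[bi]][[nm]] +
            sgn * h * d$blocks[[bi]][[nm]]
        }
      }
      wp$dense$W <- w$dense$W + sgn * h * d$dense$W
      wp$dense$b <- w$dense$b + sgn * h * d$dense$b
      wp
    }
    fd <- (edanet:::cpp_fcn_loss(perturb(1), x, y) -
             edanet:::cpp_fcn_loss(perturb(-1), x, y)) / (2 * h)
    expect_equal(fd, dot, tolerance = 0.02)
  }
})

test_that("linearly separable toy data reach full training accuracy fast", {
  toy <- toy_separable(n = 60, len = 60)
  # mean level carries the class here, so keep the raw scale
  fit <- fcn_train(toy$x, toy$y, spec = tiny_spec(), epochs = 5,
                   batch_size = 16, seed = 1, normalize = "none")
  expect_gte(max(fit$history$accuracy), 1 - 1e-9)
  expect_lte(nrow(fit$history), 5)
  pred <- predict(fit, toy$x)
  expect_gte(mean(pred == toy$y), 0.95)
})

test_that("probability rows sum to one and agree with the hard labels", {
  toy <- toy_separable(n = 30, len = 60, seed = 2)
  fit <- fcn_train(toy$x, toy$y, spec = tiny_spec(), epochs = 2,
                   batch_size = 16, seed = 3)
  p <- predict(fit, toy$x, type = "prob")
  expect_identical(colnames(p), c("neutral", "active"))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_identical(predict(fit, toy$x), as.integer(max.col(p) - 1L))
  # empty input gives empty output
  empty <- predict(fit, toy$x[0, , drop = FALSE])
  expect_length(empty, 0L)
  expect_identical(nrow(predict(fit, toy$x[0, , drop = FALSE], type = "prob")),
                   0L)
  # length mismatch is refused
  expect_error(predict(fit, toy$x[, 1:10]), "expects")
})

test_that("the stratified split hits the requested sizes per class", {
  y <- rep(c(0L, 1L), c(200, 200))
  sp <- edanet:::stratified_split(y, 0.2, seed = 5)
  expect_length(sp$val, 80L)
  expect_length(sp$train, 320L)
  expect_identical(sum(y[sp$val] == 0L), 40L)
  expect_identical(intersect(sp$train, sp$val), integer(0))
  # 40,000 at 20% validation would leave 32,000 for training
  y_big <- rep(c(0L, 1L), c(20000, 20000))
  sp_big <- edanet:::stratified_split(y_big, 0.2, seed = 1)
  expect_length(sp_big$train, 32000L)
  expect_length(sp_big$val, 8000L)
})

test_that("single-class data and malformed labels are refused", {
  x <- matrix(rnorm(10 * 60), 10, 60)
  expect_error(fcn_train(x, rep(0L, 10), spec = tiny_spec()), "single class")
  expect_error(fcn_train(x, rep(2L, 10), spec = tiny_spec()), "labels")
  expect_error(fcn_train(x, rep(0:1, 5), spec = tiny_spec(input_len = 30L)),
               "input_len")
  expect_error(fcn_train(x, rep(0:1, 5), spec = tiny_spec(),
                         val_fraction = 1), "val_fraction")
})

test_that("training is reproducible under a fixed seed", {
  toy <- toy_separable(n = 30, len = 60, seed = 4)
  f1 <- fcn_train(toy$x, toy$y, spec = tiny_spec(), epochs = 2,
                  batch_size = 16, seed = 7)
  f2 <- fcn_train(toy$x, toy$y, spec = tiny_spec(), epochs = 2,
                  batch_size = 16, seed = 7)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("fitted models survive a JSON round trip", {
  toy <- toy_separable(n = 20, len = 60, seed = 5)
  fit <- fcn_train(toy$x, toy$y, spec = tiny_spec(), epochs = 1,
                   batch_size = 10, seed = 2)
  path <- file.path(withr::local_tempdir(), "model.json")
  save_fcn_classifier(fit, path)
  back <- load_fcn_classifier(path)
  expect_equal(predict(back, toy$x, type = "prob"),
               predict(fit, toy$x, type = "prob"), tolerance = 1e-6)
  expect_identical(back$spec, fit$spec)
})
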