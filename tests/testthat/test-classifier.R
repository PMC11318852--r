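# Masked LSTM classifier: analytic gradients, masking semantics, seeded
# determinism, and separability on constructed fixtures.

make_window <- function(mat, target, id = "w") {
  structure(list(matrix = mat, end_hour = 4L, target = target,
                 patient_id = id), class = "feature_window")
}

separable_windows <- function(n_each = 25) {
  pos <- lapply(seq_len(n_each), function(i)
    make_window(matrix(5, 4, 21), 1, sprintf("p%d", i)))
  neg <- lapply(seq_len(n_each), function(i)
    make_window(matrix(1, 4, 21), 0, sprintf("n%d", i)))
  c(pos, neg)
}

test_that("analytic gradients match finite differences", {
  set.seed(31)
  B <- 4; T_ <- 4; F_ <- 5
  x <- array(runif(B * T_ * F_, 1, 5), c(B, T_, F_))
  x[2, 3, ] <- -1  # include a masked timestep
  y <- c(1, 0, 0, 1)
  cfg <- model_config(hidden_units = 5, dense_units = 3, seed = 2)
  params <- sepsiswatch:::with_seed(2, sepsiswatch:::init_params(F_, cfg))
  fw <- sepsiswatch:::lstm_forward(params, x, -1, keep_cache = TRUE)
  gr <- sepsiswatch:::lstm_backward(params, x, y, fw, -1)
  loss_at <- function(p)
    sepsiswatch:::bce_loss(sepsiswatch:::lstm_forward(p, x, -1)$p, y)
  eps <- 1e-6
  for (nm in names(params)) {
    num <- params[[nm]] * 0
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num[i] <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    }
    expect_lt(max(abs(num - gr[[nm]])) / max(1e-8, max(abs(num))), 1e-5,
              label = sprintf("gradient of %s", nm))
  }
})

test_that("a separable fixture is fit to 100% training accuracy", {
  wins <- separable_windows()
  model <- train_sepsis_model(wins, model_config(hidden_units = 8,
                                                 dense_units = 4,
                                                 epochs = 30, batch_size = 16,
                                                 seed = 9))
  data <- stack_windows(wins)
  p <- vapply(seq_along(wins), function(i) predict_window(model, wins[[i]]),
              numeric(1))
  expect_equal(mean((p > 0.5) == (data$y == 1)), 1)
  expect_gt(predict_window(model, matrix(5, 4, 21)),
            predict_window(model, matrix(1, 4, 21)))
  expect_true(all(is.finite(model$history)))
})

test_that("training is exactly reproducible from the seed", {
  wins <- separable_windows(10)
  cfg <- model_config(hidden_units = 6, dense_units = 3, epochs = 5,
                      batch_size = 8, seed = 77)
  a <- train_sepsis_model(wins, cfg)
  b <- train_sepsis_model(wins, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
})

test_that("training rejects single-class input and bad shapes error", {
  wins <- separable_windows(5)
  pos_only <- wins[vapply(wins, `[[`, numeric(1), "target") == 1]
  expect_error(train_sepsis_model(pos_only), "both classes")
  model <- train_sepsis_model(wins, model_config(hidden_units = 4,
                                                 dense_units = 2, epochs = 2,
                                                 batch_size = 8, seed = 1))
  expect_error(predict_window(model, matrix(1, 4, 7)), "shape mismatch")
})

test_that("a masked timestep is equivalent to deleting it, and all-mask windows score safely", {
  cfg <- model_config(hidden_units = 7, dense_units = 4, seed = 13)
  params <- sepsiswatch:::with_seed(13, sepsiswatch:::init_params(6, cfg))
  set.seed(5)
  base <- matrix(runif(3 * 6, 1, 5), 3, 6)
  # insert a masked hour in the middle vs the 3-hour sequence alone
  with_mask <- rbind(base[1:2, ], rep(-1, 6), base[3, ])
  x1 <- array(with_mask, c(1, 4, 6))
  x2 <- array(base, c(1, 3, 6))
  p1 <- sepsiswatch:::lstm_forward(params, x1, -1)$p
  p2 <- sepsiswatch:::lstm_forward(params, x2, -1)$p
  expect_equal(p1, p2, tolerance = 1e-12)

  all_mask <- array(-1, c(1, 4, 6))
  p <- sepsiswatch:::lstm_forward(params, all_mask, -1)$p
  expect_true(is.finite(p) && p >= 0 && p <= 1)
})

test_that("patient-level prediction yields one probability per end hour", {
  cohort <- small_cohort()
  procs <- lapply(cohort$records, preprocess_record)
  wins <- unlist(lapply(procs, build_windows), recursive = FALSE)
  model <- memo("small_model", train_sepsis_model(
    undersample_negatives(wins, 1, seed = 2),
    model_config(hidden_units = 16, dense_units = 8, epochs = 10, seed = 4)))

  ten <- preprocess_record(toy_record(10, list(HR = rep(80, 10))))
  p <- predict_patient(model, ten)
  expect_length(p, 7)
  expect_equal(attr(p, "hours"), 4:10)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict_patient(model, ten))
})

test_that("probabilities rise approaching onset on a drifting septic patient", {
  cohort <- small_cohort()
  procs <- lapply(cohort$records, preprocess_record)
  wins <- unlist(lapply(procs, build_windows), recursive = FALSE)
  model <- memo("small_model", train_sepsis_model(
    undersample_negatives(wins, 1, seed = 2),
    model_config(hidden_units = 16, dense_units = 8, epochs = 10, seed = 4)))

  sep <- cohort$truth[cohort$truth$is_septic & !is.na(cohort$truth$onset_hour) &
                        cohort$truth$onset_hour >= 16, ]
  expect_gt(nrow(sep), 0)
  pre_vs_early <- vapply(sep$patient_id, function(id) {
    p <- predict_patient(model, procs[[id]])
    hrs <- attr(p, "hours")
    onset <- sep$onset_hour[sep$patient_id == id]
    mean(p[hrs > onset - 6 & hrs <= onset]) - mean(p[hrs <= 9])
  }, numeric(1))
  expect_gt(mean(pre_vs_early), 0)
})

test_that("a model archive round-trips through save/load", {
  wins <- separable_windows(5)
  model <- train_sepsis_model(wins, model_config(hidden_units = 4,
                                                 dense_units = 2, epochs = 2,
                                                 batch_size = 8, seed = 1))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  reloaded <- load_model(f)
  expect_identical(reloaded$params, model$params)
  expect_equal(predict_window(reloaded, matrix(3, 4, 21)),
               predict_window(model, matrix(3, 4, 21)))
})
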