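make_clouds <- function(n, sep = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * 2), ncol = 2),
             matrix(rnorm(n * 2, mean = sep), ncol = 2))
  list(X = X, y = rep(c("RELAX", "IMAGINE"), each = n))
}

test_that("the SVM separates well-separated clouds and is honest on noise", {
  cl <- make_clouds(100)
  m <- train_model(cl$X, cl$y)
  expect_gte(m$training_accuracy, 0.95)
  expect_equal(predict(m, matrix(c(0, 0, 3, 3), 2, byrow = TRUE)),
               c("RELAX", "IMAGINE"))

  # pure noise, random labels: held-out accuracy is at chance
  set.seed(13)
  Xtr <- matrix(rnorm(400 * 4), ncol = 4)
  ytr <- sample(c("RELAX", "IMAGINE"), 400, replace = TRUE)
  Xte <- matrix(rnorm(800 * 4), ncol = 4)
  yte <- sample(c("RELAX", "IMAGINE"), 800, replace = TRUE)
  m2 <- train_model(Xtr, ytr)
  expect_equal(mean(predict(m2, Xte) == yte), 0.5, tolerance = 0.05)
})

test_that("training is deterministic and invariant to duplicating the data", {
  cl <- make_clouds(60, sep = 2, seed = 3)
  grid <- as.matrix(expand.grid(seq(-2, 4, 0.5), seq(-2, 4, 0.5)))
  m1 <- train_model(cl$X, cl$y)
  m2 <- train_model(cl$X, cl$y)
  expect_identical(predict(m1, grid), predict(m2, grid))
  # duplicating every point doubles the loss term, so halving C keeps the
  # objective (and hence the decision function) unchanged up to solver slack
  mdup <- train_model(rbind(cl$X, cl$X), c(cl$y, cl$y), C = 0.5,
                      kernel_width = m1$kernel_width)
  expect_equal(mean(predict(mdup, grid) == predict(m1, grid)), 1,
               tolerance = 0.02)
})

test_that("degenerate training inputs are rejected", {
  expect_error(train_model(matrix(1:10, 5), rep("RELAX", 5)), "both task")
  expect_error(train_model(matrix(c(1, Inf, 3, 4), 2),
                           c("RELAX", "IMAGINE")), "finite")
})

test_that("real-time accuracy is the percentage of correct epoch classifications", {
  df <- data.frame(correct = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(realtime_accuracy(df), 75)
  expect_equal(realtime_accuracy(data.frame(correct = rep(TRUE, 8))), 100)
  expect_error(realtime_accuracy(data.frame(correct = logical(0))), "empty")

  # invariant under relabeling truths and predictions together
  set.seed(2)
  truth <- sample(c("RELAX", "IMAGINE"), 200, replace = TRUE)
  pred <- sample(c("RELAX", "IMAGINE"), 200, replace = TRUE)
  flip <- function(x) ifelse(x == "RELAX", "IMAGINE", "RELAX")
  expect_equal(realtime_accuracy(data.frame(correct = pred == truth)),
               realtime_accuracy(data.frame(correct = flip(pred) == flip(truth))))
})

test_that("the online session produces one record per evaluation epoch", {
  spec <- protocol_spec(tasks_per_type_per_trial = 2, trials_per_session = 6,
                        training_trials = 4)
  rec <- generate_session(subject_profile(erd_power_fraction = 0.4),
                          spec, day = 1, seed = 15)
  model <- train_session_model(rec, spec)
  stream <- run_online_session(rec, model, spec)

  n_eval_tasks <- 2 * spec$tasks_per_type_per_trial *
    (spec$trials_per_session - spec$training_trials)
  expect_equal(nrow(stream$records), n_eval_tasks * epochs_per_task(spec))
  expect_setequal(unique(stream$records$trial), 5:6)
  # predictions are spaced one epoch shift apart within a task
  within <- split(stream$records$epoch_start_s, stream$records$task_id)
  expect_true(all(vapply(within, function(s) all(abs(diff(s) - 0.2) < 1e-9),
                         logical(1))))
  # feedback counters: bar sizes count exactly the correct detections
  expect_equal(sum(stream$feedback$bar_size), sum(stream$records$correct))
  expect_true(all(stream$feedback$n_epochs == epochs_per_task(spec)))

  # end-to-end determinism
  stream2 <- run_online_session(rec, model, spec)
  expect_identical(stream$records, stream2$records)
})

test_that("a trained model survives the JSON round trip with identical predictions", {
  spec <- small_spec()
  rec <- generate_session(subject_profile(erd_power_fraction = 0.4), spec,
                          day = 1, seed = 20)
  model <- train_session_model(rec, spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$map$frequency_hz, model$map$frequency_hz)
  ep <- preprocess_session(rec, spec, trials = 5)
  feats <- extract_features(normalize_powers(power_table(ep)), model$map)
  expect_identical(predict(back, feats), predict(model, feats))
})

test_that("montage mismatches are rejected before classification", {
  spec <- small_spec()
  rec <- generate_session(subject_profile(), spec, day = 1, seed = 4)
  model <- train_session_model(rec, spec)
  rec$channel_labels <- sub("CZ", "XX", rec$channel_labels)
  rownames(rec$samples) <- rec$channel_labels
  expect_error(run_online_session(rec, model, spec), "montage")
})
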