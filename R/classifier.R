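#' Train the RBF-SVM task classifier
#'
#' Standardizes the training features (center/scale estimated from the
#' training data only) and fits a binary support vector machine with a radial
#' basis function kernel separating Relax from Imagine epochs. The kernel
#' width defaults to the median heuristic — the median pairwise Euclidean
#' distance between standardized training points — giving a reproducible,
#' scale-appropriate default; `C` defaults to 1.
#'
#' @param features Numeric matrix, epochs x features (finite values).
#' @param labels Character/factor of task labels (`"RELAX"`/`"IMAGINE"`),
#'   one per epoch; both classes must be present.
#' @param C Soft-margin cost.
#' @param kernel_width RBF width `sigma` (kernel
#'   `exp(-||u - v||^2 / (2 sigma^2))`); `NULL` for the median heuristic.
#' @param map Optional [select_optimal_frequencies()] map to attach, so the
#'   model carries the frequencies its features were extracted at.
#' @return An object of class `trained_model` with the fitted SVM, scaling
#'   parameters, hyperparameters, attached map and training accuracy.
#' @export
train_model <- function(features, labels, C = 1, kernel_width = NULL,
                        map = NULL) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite", call. = FALSE)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("both task classes are required to train", call. = FALSE)
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0] <- 1
  X <- sweep(sweep(features, 2, center), 2, scale, "/")
  if (is.null(kernel_width)) kernel_width <- median_heuristic_width(X)
  gamma <- 1 / (2 * kernel_width^2)
  y <- factor(labels, levels = TASK_LABELS)
  fit <- e1071::svm(x = X, y = y, scale = FALSE, kernel = "radial",
                    cost = C, gamma = gamma)
  train_acc <- mean(as.character(stats::predict(fit, X)) == labels)
  structure(list(svm = fit, center = center, scale = scale, C = C,
                 kernel_width = kernel_width, gamma = gamma, map = map,
                 training_accuracy = train_acc,
                 feature_names = colnames(features)),
            class = "trained_model")
}

# Median pairwise distance between rows (subsampled for large n).
median_heuristic_width <- function(X, max_rows = 500L) {
  n <- nrow(X)
  if (n > max_rows) X <- X[round(seq(1, n, length.out = max_rows)), , drop = FALSE]
  w <- stats::median(stats::dist(X))
  if (!is.finite(w) || w <= 0) 1 else w
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model: RBF-SVM, %d features, C = %g, sigma = %.3g, training accuracy %.1f%%\n",
              length(x$center), x$C, x$kernel_width,
              100 * x$training_accuracy))
  invisible(x)
}

#' Predict task labels for feature rows
#'
#' Applies the model's standardization and SVM decision function.
#'
#' @param object A `trained_model` (from [train_model()] or [read_model()]).
#' @param features Numeric matrix, epochs x features.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.trained_model <- function(object, features, ...) {
  X <- sweep(sweep(as.matrix(features), 2, object$center), 2, object$scale, "/")
  if (!is.null(object$svm))
    return(as.character(stats::predict(object$svm, X)))
  # deserialized model: evaluate the RBF decision function directly
  K <- exp(-object$gamma * outer(rowSums(X^2), rowSums(object$sv^2), "+") +
             2 * object$gamma * tcrossprod(X, object$sv))
  f <- drop(K %*% object$sv_coefs) - object$rho
  ifelse(f > 0, object$decision_levels[1], object$decision_levels[2])
}

#' Train a session model from raw EEG
#'
#' End-to-end training stage of the online system: preprocess the training
#' trials (epoching, filter chain, Laplacian, electrode selection), compute
#' normalized Burg spectra, pick each electrode's optimal frequency, extract
#' the per-epoch features and fit the RBF-SVM.
#'
#' @param rec A `session_recording`.
#' @param spec The [protocol_spec()] of the recording; trials
#'   `1..spec$training_trials` are used.
#' @param cfg A [filter_chain_config()].
#' @param electrodes Electrodes used for classification.
#' @param ar_order Burg AR order.
#' @param C,kernel_width SVM hyperparameters (see [train_model()]).
#' @return A `trained_model` with the optimal-frequency map attached.
#' @export
train_session_model <- function(rec, spec = protocol_spec(),
                                cfg = filter_chain_config(),
                                electrodes = motor_electrodes(),
                                ar_order = 16, C = 1, kernel_width = NULL) {
  ep <- preprocess_session(rec, spec, cfg,
                           trials = seq_len(spec$training_trials),
                           electrodes = electrodes)
  pt <- normalize_powers(power_table(ep, ar_order = ar_order))
  map <- select_optimal_frequencies(pt)
  feats <- extract_features(pt, map)
  model <- train_model(feats, pt$labels, C = C, kernel_width = kernel_width,
                       map = map)
  model$electrodes <- electrodes
  model$ar_order <- ar_order
  model$cfg <- cfg
  model
}

#' Run the online classifier over the evaluation trials
#'
#' Streams through every evaluation epoch exactly as the online system does:
#' slice the 1 s window, temporal filters, Laplacian, electrode selection,
#' Burg spectrum, normalization, feature extraction at the model's optimal
#' frequencies, standardization and SVM classification — one prediction
#' every epoch shift (200 ms by default). Feedback is accounted per task
#' cue: the cue's "bar size" is its number of correct detections.
#'
#' @param rec A `session_recording` (same montage as the model).
#' @param model A `trained_model` from [train_session_model()].
#' @param spec The [protocol_spec()] of the recording.
#' @param cfg A [filter_chain_config()]; defaults to the model's.
#' @param trials Trials to evaluate (default: all after the training trials).
#' @return An object of class `prediction_stream`: list with `records` (data
#'   frame: `trial`, `task_id`, `epoch_start_s`, `true_label`,
#'   `predicted_label`, `correct`) and `feedback` (data frame per task cue:
#'   `task_id`, `trial`, `label`, `bar_size`, `n_epochs`).
#' @export
run_online_session <- function(rec, model, spec = protocol_spec(),
                               cfg = NULL, trials = NULL) {
  stopifnot(inherits(model, "trained_model"))
  if (is.null(cfg)) cfg <- model$cfg %||% filter_chain_config()
  if (is.null(trials))
    trials <- (spec$training_trials + 1L):spec$trials_per_session
  electrodes <- model$electrodes %||% motor_electrodes()
  if (!all(toupper(electrodes) %in% toupper(rec$channel_labels)))
    stop("recording montage does not cover the model's electrodes",
         call. = FALSE)
  ep <- preprocess_session(rec, spec, cfg, trials = trials,
                           electrodes = electrodes)
  pt <- normalize_powers(power_table(ep, ar_order = model$ar_order %||% 16))
  feats <- extract_features(pt, model$map)
  pred <- predict(model, feats)
  npt <- epochs_per_task(spec)
  task_id <- rep(seq_len(length(ep$labels) / npt), each = npt)
  records <- data.frame(trial = ep$trial %||% NA_integer_,
                        task_id = task_id,
                        epoch_start_s = ep$epoch_start_s,
                        true_label = ep$labels,
                        predicted_label = pred,
                        correct = pred == ep$labels,
                        stringsAsFactors = FALSE)
  feedback <- do.call(rbind, lapply(split(records, records$task_id), function(g)
    data.frame(task_id = g$task_id[1], trial = g$trial[1],
               label = g$true_label[1], bar_size = sum(g$correct),
               n_epochs = nrow(g), stringsAsFactors = FALSE)))
  feedback <- feedback[order(feedback$task_id), ]
  rownames(feedback) <- NULL
  structure(list(records = records, feedback = feedback),
            class = "prediction_stream")
}

#' @export
print.prediction_stream <- function(x, ...) {
  cat(sprintf("prediction_stream: %d epochs over %d task cues, real-time accuracy %.1f%%\n",
              nrow(x$records), nrow(x$feedback), realtime_accuracy(x)))
  invisible(x)
}

#' Real-time detection accuracy
#'
#' Percentage of correctly classified epochs among all classified epochs:
#' `100 * correct / total`.
#'
#' @param stream A `prediction_stream`, or a data frame with a logical
#'   `correct` column.
#' @return Accuracy in percent.
#' @export
realtime_accuracy <- function(stream) {
  records <- if (inherits(stream, "prediction_stream")) stream$records else stream
  if (is.null(records$correct) || nrow(records) == 0)
    stop("empty prediction stream", call. = FALSE)
  100 * sum(records$correct) / nrow(records)
}

#' Serialize / restore a trained model as JSON
#'
#' `write_model()` stores scaling parameters, hyperparameters, the
#' optimal-frequency map and the SVM's support vectors, coefficients and
#' bias; `read_model()` restores a model whose [predict.trained_model()]
#' evaluates the RBF decision function from those stored quantities.
#'
#' @param model A `trained_model`.
#' @param path JSON file path.
#' @return `write_model()`: the path, invisibly; `read_model()`: a
#'   `trained_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  fit <- model$svm
  doc <- list(center = model$center, scale = model$scale, C = model$C,
              kernel_width = model$kernel_width, gamma = model$gamma,
              electrodes = model$electrodes, ar_order = model$ar_order,
              map = as.data.frame(model$map),
              training_accuracy = model$training_accuracy,
              sv = unname(as.matrix(fit$SV)),
              sv_coefs = as.numeric(fit$coefs),
              rho = as.numeric(fit$rho),
              decision_levels = fit$levels[fit$labels])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  map <- doc$map
  class(map) <- c("optimal_frequency_map", "data.frame")
  structure(list(svm = NULL, center = unlist(doc$center),
                 scale = unlist(doc$scale), C = doc$C,
                 kernel_width = doc$kernel_width, gamma = doc$gamma,
                 electrodes = doc$electrodes, ar_order = doc$ar_order,
                 map = map, training_accuracy = doc$training_accuracy,
                 sv = as.matrix(doc$sv), sv_coefs = as.numeric(doc$sv_coefs),
                 rho = as.numeric(doc$rho),
                 decision_levels = doc$decision_levels),
            class = "trained_model")
}
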