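# Random-forest classification of histosketch S-vectors, including
# streaming prediction that signals stream termination once a probability
# threshold is reached.

#' Feature matrix from histosketches
#'
#' Features use only the sketch bin identifiers `S`, never the hash values
#' `A`.  The default `"raw"` encoding passes the Z-slot S-vector directly
#' (one column per slot).  The `"frequency"` encoding counts how often each
#' vocabulary bin occurs across a sketch's slots, which is insensitive to
#' slot order and to the arbitrary numeric magnitude of bin identifiers.
#'
#' @param sketches list of comparable `histosketch` objects.
#' @param encoding `"raw"` or `"frequency"`.
#' @param vocabulary for `"frequency"`: the bin vocabulary (defaults to all
#'   bins observed across `sketches`); prediction must reuse the training
#'   vocabulary.
#' @return numeric matrix, one row per sketch.
#' @export
sketch_feature_matrix <- function(sketches, encoding = c("raw", "frequency"),
                                  vocabulary = NULL) {
  encoding <- match.arg(encoding)
  cfg <- sketches[[1L]]$config
  for (s in sketches) assert_comparable(cfg, s$config)
  S <- t(vapply(sketches, `[[`, integer(cfg$sketch_size), "S"))
  if (encoding == "raw") {
    colnames(S) <- paste0("slot_", seq_len(ncol(S)))
    return(S * 1.0)
  }
  if (is.null(vocabulary)) vocabulary <- sort(unique(as.vector(S)))
  m <- t(apply(S, 1L, function(row)
    tabulate(match(row, vocabulary), nbins = length(vocabulary))))
  colnames(m) <- paste0("bin_", vocabulary)
  attr(m, "vocabulary") <- vocabulary
  m
}

# stratified assignment of samples to `folds` groups (fold 0/1 for a split)
stratified_folds <- function(labels, folds) {
  out <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

classification_metrics <- function(truth, pred, classes) {
  tab <- table(factor(truth, classes), factor(pred, classes))
  prec <- diag(tab) / pmax(colSums(tab), 1)
  rec <- diag(tab) / pmax(rowSums(tab), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = mean(truth == pred),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

#' Train a random-forest classifier on histosketches
#'
#' Fits a forest of bootstrapped trees (1000 by default) on a stratified 80%
#' of the samples, reports accuracy/precision/recall/F1 on the held-out 20%,
#' and summarises a stratified ten-fold cross-validation over all samples.
#' The model carries the sketch comparability header, so predictions on
#' sketches from a different configuration are refused.
#'
#' @param sketches list of comparable `histosketch` objects.
#' @param labels class label per sketch (>= 2 classes, >= 10 samples).
#' @param seed RNG seed governing the split, the folds and the forest.
#' @param ntree number of trees.
#' @param split training fraction (default 0.8).
#' @param cv_folds cross-validation folds (default 10).
#' @param encoding feature encoding, see [sketch_feature_matrix()].
#' @return an object of class `sketch_classifier` with elements `forest`,
#'   `metrics` (held-out), `cv` (per-fold accuracies) and `header`.
#' @export
train_sketch_classifier <- function(sketches, labels, seed = 1L,
                                    ntree = 1000L, split = 0.8,
                                    cv_folds = 10L,
                                    encoding = c("raw", "frequency")) {
  encoding <- match.arg(encoding)
  labels <- as.character(labels)
  if (length(sketches) != length(labels)) stopf("need one label per sketch")
  if (length(sketches) < 10L) stopf("need >= 10 samples")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stopf("need >= 2 classes")
  if (min(table(labels)) < 2L) stopf("every class needs >= 2 samples")
  features <- sketch_feature_matrix(sketches, encoding)
  vocabulary <- attr(features, "vocabulary")
  y <- factor(labels, classes)
  with_seed(seed, {
    # stratified 80/20 split
    test <- stratified_folds(labels, round(1 / (1 - split))) == 1L
    forest <- randomForest::randomForest(
      x = features[!test, , drop = FALSE], y = y[!test], ntree = ntree)
    held_pred <- as.character(predict(forest, features[test, , drop = FALSE]))
    metrics <- classification_metrics(labels[test], held_pred, classes)
    # stratified k-fold cross-validation over all samples
    folds <- stratified_folds(labels, cv_folds)
    cv <- vapply(seq_len(cv_folds), function(f) {
      in_fold <- folds == f
      if (!any(in_fold) || length(unique(y[!in_fold])) < 2L) return(NA_real_)
      rf <- randomForest::randomForest(
        x = features[!in_fold, , drop = FALSE], y = y[!in_fold],
        ntree = ntree)
      mean(as.character(predict(rf, features[in_fold, , drop = FALSE])) ==
             labels[in_fold])
    }, numeric(1))
    structure(list(forest = forest, classes = classes,
                   header = sketches[[1L]]$config[comparability_fields],
                   metrics = metrics,
                   cv = list(folds = cv_folds,
                             accuracy = cv[!is.na(cv)],
                             mean_accuracy = mean(cv, na.rm = TRUE)),
                   encoding = encoding, vocabulary = vocabulary,
                   ntree = ntree, split = split, seed = seed),
              class = "sketch_classifier")
  })
}

#' @export
print.sketch_classifier <- function(x, ...) {
  cat(sprintf(
    paste0("<sketch_classifier> %d classes, %d trees (%s encoding)\n",
           "  held-out: accuracy %.3f, F1 %.3f; %d-fold CV accuracy %.3f\n"),
    length(x$classes), x$ntree, x$encoding, x$metrics$accuracy,
    x$metrics$f1, x$cv$folds, x$cv$mean_accuracy))
  invisible(x)
}

#' Predict classes or probabilities for histosketches
#'
#' @param object a [train_sketch_classifier()] model.
#' @param sketches list of comparable `histosketch` objects (or a single
#'   one).
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return character vector of classes, or a matrix of per-class
#'   probabilities (rows sum to 1).
#' @export
predict.sketch_classifier <- function(object, sketches, type = c("class",
                                                                 "prob"),
                                      ...) {
  type <- match.arg(type)
  if (inherits(sketches, "histosketch")) sketches <- list(sketches)
  for (s in sketches)
    assert_comparable(object$header, s$config, what = "model and sketch")
  features <- sketch_feature_matrix(sketches, object$encoding,
                                    object$vocabulary)
  if (type == "class")
    return(as.character(predict(object$forest, features)))
  p <- predict(object$forest, features, type = "prob")
  p[, object$classes, drop = FALSE]
}

#' Classify a stream of histosketch snapshots
#'
#' Consumes interval snapshots (as produced by [sketch_stream()]) in order,
#' predicting class probabilities on each; returns as soon as the maximal
#' class probability reaches `prob_threshold`, signalling that the upstream
#' sketching of this sample can stop.  If the stream ends first, the final
#' snapshot's prediction is returned flagged `below_threshold = TRUE`.
#'
#' @param model a [train_sketch_classifier()] model.
#' @param snapshots list of comparable `histosketch` snapshots.
#' @param prob_threshold probability needed to terminate early (in
#'   (0.5, 1\]).
#' @return list with `label`, `probability`, `snapshots_consumed` and
#'   `below_threshold`.
#' @export
classify_stream <- function(model, snapshots, prob_threshold = 0.9) {
  assert_scalar_number(prob_threshold, "prob_threshold", 0.5, 1,
                       open_lower = TRUE)
  if (length(snapshots) == 0L) stopf("empty snapshot stream")
  for (i in seq_along(snapshots)) {
    p <- predict(model, snapshots[[i]], type = "prob")
    best <- which.max(p[1L, ])
    if (p[1L, best] >= prob_threshold)
      return(list(label = colnames(p)[best], probability = unname(p[1L, best]),
                  snapshots_consumed = i, below_threshold = FALSE))
  }
  list(label = colnames(p)[best], probability = unname(p[1L, best]),
       snapshots_consumed = length(snapshots), below_threshold = TRUE)
}

#' Save / load a trained sketch classifier
#'
#' The model is serialized with [saveRDS()]; a JSON sidecar
#' (`<path>.json`) records the training report (held-out metrics,
#' cross-validation accuracies and the comparability header) for
#' inspection without loading the forest.
#'
#' @param model a `sketch_classifier`.
#' @param path file path.
#' @return `path` invisibly (save) or the restored model (load).
#' @export
save_sketch_classifier <- function(model, path) {
  saveRDS(model, path)
  report <- list(classes = model$classes, ntree = model$ntree,
                 split = model$split, seed = model$seed,
                 encoding = model$encoding, metrics = model$metrics,
                 cv = model$cv, header = model$header)
  jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_sketch_classifier
#' @export
load_sketch_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sketch_classifier"))
    stopf("not a sketch_classifier file: %s", path)
  model
}
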