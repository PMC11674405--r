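#' Subject-level hold-out dataset for node classification
#'
#' Splits the subjects (never individual nodes) into train and test sets,
#' then stacks every subject's node coordinates into row matrices: with S
#' subjects and n nodes per subject, a (train_subjects x n) x p train
#' matrix and a (test_subjects x n) x p test matrix (70/30 of 100 subjects
#' with 219 nodes give 15,330 and 6,570 rows). Labels are the
#' parcellation's node superclasses, identical across subjects.
#'
#' @param embeddings named list of [property_matrix()] objects.
#' @param parcellation a [parcellation()] aligned with the node order.
#' @param split integer vector `c(train, test)` summing to the subject
#'   count, or fractions summing to 1.
#' @param seed RNG seed for the random subject split.
#' @return list of class `graphspace_dataset`: `train_x`, `train_y`,
#'   `test_x`, `test_y`, `train_subjects`, `test_subjects`,
#'   `property_names`.
#' @export
prepare_dataset <- function(embeddings, parcellation, split = c(70, 30),
                            seed = 1L) {
  s <- length(embeddings)
  if (s < 2L) stop("need at least 2 subjects")
  ids <- names(embeddings) %||% sprintf("s%03d", seq_len(s))
  if (length(split) != 2L) stop("`split` must have 2 entries")
  if (isTRUE(all.equal(sum(split), 1))) split <- round_half_up(split * s)
  if (sum(split) != s) {
    stop(sprintf("split (%s) must sum to the subject count %d",
                 paste(split, collapse = ", "), s))
  }
  mats <- lapply(embeddings, coords_of)
  n <- nrow(mats[[1L]])
  if (nrow(parcellation) != n) {
    stop("parcellation does not match the embeddings' node count")
  }
  labels <- factor(parcellation$superclass)
  train_subj <- sort(with_seed(seed, sample.int(s, split[1L])))
  test_subj <- setdiff(seq_len(s), train_subj)
  stack <- function(idx) {
    x <- do.call(rbind, mats[idx])
    rownames(x) <- paste(rep(ids[idx], each = n),
                         rep(parcellation$node_id, length(idx)), sep = "|")
    x
  }
  train_y <- factor(rep(labels, length(train_subj)), levels = levels(labels))
  if (nlevels(droplevels(train_y)) < 2L) {
    stop("a superclass is absent from the training set")
  }
  structure(
    list(train_x = stack(train_subj), train_y = train_y,
         test_x = stack(test_subj),
         test_y = factor(rep(labels, length(test_subj)),
                         levels = levels(labels)),
         train_subjects = ids[train_subj], test_subjects = ids[test_subj],
         property_names = colnames(mats[[1L]]), seed = seed),
    class = "graphspace_dataset"
  )
}

#' Train and evaluate one node-superclass classifier
#'
#' Three classifier families are available: `"svm"` (linear-kernel support
#' vector machine), `"gaussian_kernel"` (RBF-kernel SVM), and `"linear"`
#' (logistic regression). For the SVM families a small hyperparameter grid
#' (cost, and kernel scale for the RBF) is selected by internal 5-fold
#' cross-validation on the training side only, with deterministic fold
#' assignment under `seed`; the grid and the chosen values are recorded in
#' the report. Accuracy is the fraction of correctly classified node rows;
#' the AUC comes from the decision scores on the test side.
#'
#' @param data a `graphspace_dataset` from [prepare_dataset()].
#' @param classifier `"gaussian_kernel"`, `"svm"` or `"linear"`.
#' @param features property names (columns) to use; `NULL` means all.
#' @param tune run the internal grid search (default); `FALSE` uses fixed
#'   defaults (cost 1, gamma 1/p), useful for large sweeps.
#' @param seed RNG seed for fold assignment.
#' @return list of class `classifier_report`: `classifier`, `features`,
#'   `dimension`, `train_accuracy`, `test_accuracy`, `auc`, `seed`,
#'   `hyperparameters`, `n_train`, `n_test`.
#' @export
train_eval <- function(data, classifier = c("gaussian_kernel", "svm",
                                            "linear"),
                       features = NULL, tune = TRUE, seed = 1L) {
  stopifnot(inherits(data, "graphspace_dataset"))
  classifier <- match.arg(classifier)
  features <- features %||% data$property_names
  if (length(features) == 0L) stop("`features` must be non-empty")
  bad <- setdiff(features, data$property_names)
  if (length(bad) > 0L) {
    stop("unknown features: ", paste(bad, collapse = ", "))
  }
  tr_x <- data$train_x[, features, drop = FALSE]
  te_x <- data$test_x[, features, drop = FALSE]
  tr_y <- data$train_y
  te_y <- data$test_y
  if (nlevels(droplevels(tr_y)) < 2L) {
    stop("training labels contain a single class")
  }
  p <- length(features)

  fit_fn <- function(xm, y, par) {
    switch(classifier,
      linear = suppressWarnings(
        stats::glm.fit(cbind(1, xm), y == levels(y)[2L],
                       family = stats::binomial())
      ),
      svm = e1071::svm(xm, y, kernel = "linear", cost = par$cost,
                       scale = FALSE),
      gaussian_kernel = e1071::svm(xm, y, kernel = "radial",
                                   cost = par$cost, gamma = par$gamma,
                                   scale = FALSE)
    )
  }
  score_fn <- function(fit, xm) {
    if (classifier == "linear") {
      as.vector(cbind(1, xm) %*% fit$coefficients)
    } else {
      pr <- stats::predict(fit, xm, decision.values = TRUE)
      as.vector(attr(pr, "decision.values"))
    }
  }
  pred_fn <- function(fit, xm, y_levels) {
    if (classifier == "linear") {
      factor(y_levels[1L + (score_fn(fit, xm) > 0)], levels = y_levels)
    } else {
      stats::predict(fit, xm)
    }
  }

  grid <- switch(classifier,
    linear = list(list()),
    svm = lapply(10^(-1:1), function(co) list(cost = co)),
    gaussian_kernel = {
      g <- expand.grid(cost = 10^(-1:1), gamma = c(0.5, 1, 2) / p)
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    }
  )
  if (!tune || length(grid) == 1L) {
    best <- switch(classifier,
                   linear = list(),
                   svm = list(cost = 1),
                   gaussian_kernel = list(cost = 1, gamma = 1 / p))
  } else {
    folds <- with_seed(seed, sample(rep_len(1:5, nrow(tr_x))))
    cv_acc <- vapply(grid, function(par) {
      accs <- vapply(1:5, function(f) {
        in_tr <- folds != f
        if (nlevels(droplevels(tr_y[in_tr])) < 2L) return(NA_real_)
        fit <- fit_fn(tr_x[in_tr, , drop = FALSE], tr_y[in_tr], par)
        mean(pred_fn(fit, tr_x[!in_tr, , drop = FALSE], levels(tr_y)) ==
               tr_y[!in_tr])
      }, numeric(1L))
      mean(accs, na.rm = TRUE)
    }, numeric(1L))
    best <- grid[[which.max(cv_acc)]]  # first maximum: deterministic ties
  }

  fit <- fit_fn(tr_x, tr_y, best)
  train_acc <- mean(pred_fn(fit, tr_x, levels(tr_y)) == tr_y)
  test_acc <- mean(pred_fn(fit, te_x, levels(tr_y)) == te_y)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = te_y, predictor = score_fn(fit, te_x),
    levels = levels(te_y), quiet = TRUE
  )))
  structure(
    list(classifier = classifier, features = features, dimension = p,
         train_accuracy = train_acc, test_accuracy = test_acc, auc = auc,
         seed = seed, hyperparameters = best,
         n_train = nrow(tr_x), n_test = nrow(te_x)),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> %s on %dD (%s): train %.3f, test %.3f, AUC %.3f\n",
    x$classifier, x$dimension, paste(x$features, collapse = "+"),
    x$train_accuracy, x$test_accuracy, x$auc
  ))
  invisible(x)
}

report_row <- function(r, combo) {
  data.frame(dimension = r$dimension, combo = combo,
             features = paste(r$features, collapse = "+"),
             train_accuracy = r$train_accuracy,
             test_accuracy = r$test_accuracy, auc = r$auc,
             stringsAsFactors = FALSE)
}

sample_subsets <- function(p, size, n_subsets) {
  total <- choose(p, size)
  if (n_subsets >= total) {
    cmb <- utils::combn(p, size)
    return(lapply(seq_len(ncol(cmb)), function(k) cmb[, k]))
  }
  seen <- character(0L)
  out <- list()
  while (length(out) < n_subsets) {
    s <- sort(sample.int(p, size))
    key <- paste(s, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- s
    }
  }
  out
}

#' Accuracy across graph-space dimensionalities
#'
#' For each dimension d, trains classifiers on `combos_per_dim` distinct
#' random d-subsets of the available properties (sampled without
#' replacement; when d equals the property count the single full set is
#' used) and evaluates train/test accuracy, tracing the
#' information-versus-dimension curve. One subject split (under `seed`) is
#' shared by all classifiers in the sweep; the sampled subsets are
#' reproducible across runs for a fixed seed.
#'
#' @inheritParams prepare_dataset
#' @param dims dimensions to sweep (subset of 2..p).
#' @param combos_per_dim random property subsets per dimension (default 5).
#' @param classifier,tune passed to [train_eval()].
#' @return data.frame with one row per trained classifier: `dimension`,
#'   `combo`, `features`, `train_accuracy`, `test_accuracy`, `auc`.
#' @export
dimension_sweep <- function(embeddings, parcellation, dims = NULL,
                            combos_per_dim = 5L,
                            classifier = "gaussian_kernel",
                            split = c(70, 30), seed = 1L, tune = TRUE) {
  data <- prepare_dataset(embeddings, parcellation, split = split,
                          seed = seed)
  p <- length(data$property_names)
  dims <- dims %||% seq(2L, p)
  if (any(dims < 2L | dims > p)) stop("`dims` must lie in 2..", p)
  rows <- list()
  for (d in dims) {
    subsets <- if (d == p) {
      list(seq_len(p))
    } else {
      with_seed(seed + d, sample_subsets(p, d, combos_per_dim))
    }
    for (k in seq_along(subsets)) {
      feats <- data$property_names[subsets[[k]]]
      rep_k <- train_eval(data, classifier = classifier, features = feats,
                          tune = tune, seed = seed)
      rows[[length(rows) + 1L]] <- report_row(rep_k, k)
    }
  }
  do.call(rbind, rows)
}

#' Exhaustive feature-subset sweep
#'
#' Trains one classifier per subset of exactly `k` properties (all
#' C(p, k) subsets; with the canonical 10 properties: 45 in 2D, 120 in 3D,
#' 210 in 4D, 252 in 5D, ..., 1 in 10D). `k = "all"` sweeps every
#' dimension from 2 to p.
#'
#' @inheritParams dimension_sweep
#' @param k subset size in 2..p, or `"all"`.
#' @return data.frame with one row per subset, as in [dimension_sweep()].
#' @export
combo_sweep <- function(embeddings, parcellation, k,
                        classifier = "gaussian_kernel", split = c(70, 30),
                        seed = 1L, tune = TRUE) {
  data <- prepare_dataset(embeddings, parcellation, split = split,
                          seed = seed)
  p <- length(data$property_names)
  ks <- if (identical(k, "all")) seq(2L, p) else as.integer(k)
  if (any(ks < 2L | ks > p)) stop("`k` must lie in 2..", p)
  rows <- list()
  for (kk in ks) {
    cmb <- utils::combn(p, kk)
    for (c_i in seq_len(ncol(cmb))) {
      feats <- data$property_names[cmb[, c_i]]
      rep_k <- train_eval(data, classifier = classifier, features = feats,
                          tune = tune, seed = seed)
      rows[[length(rows) + 1L]] <- report_row(rep_k, c_i)
    }
  }
  do.call(rbind, rows)
}
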