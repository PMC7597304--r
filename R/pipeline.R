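#' Labelled feature dataset of antifragility difference curves
#'
#' Rows are 30-point difference curves (one per original/mutant pair),
#' labels are the four robustness/evolvability classes, and `group`
#' identifies the source network of each row (useful for group-aware
#' splitting).
#'
#' @param features numeric matrix, one row per comparison.
#' @param labels factor or character over [robustness_classes()].
#' @param group character vector of source-network identifiers.
#' @return an object of class `feature_dataset`.
#' @export
feature_dataset <- function(features, labels, group = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  labels <- factor(as.character(labels), levels = robustness_classes())
  if (anyNA(labels)) stop("unknown class label")
  if (length(labels) != n) stop("labels length must match feature rows")
  if (is.null(group)) group <- rep(NA_character_, n)
  if (length(group) != n) stop("group length must match feature rows")
  structure(list(features = features, labels = labels,
                 group = as.character(group)),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("Feature dataset: %d rows x %d features\n",
              nrow(x$features), ncol(x$features)))
  print(table(x$labels))
  invisible(x)
}

fd_nrow <- function(data) nrow(data$features)

fd_subset <- function(data, idx) {
  feature_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
                  data$group[idx])
}

fd_rbind <- function(a, b) {
  feature_dataset(rbind(a$features, b$features),
                  c(as.character(a$labels), as.character(b$labels)),
                  c(a$group, b$group))
}

#' Assemble a feature dataset from difference curves
#'
#' @param curves list of [difference_curve()] objects (each of length 30).
#' @param labels per-curve robustness/evolvability class.
#' @param groups per-curve source-network identifier.
#' @return a [feature_dataset()] with width exactly 30; row order is
#'   preserved.
#' @export
build_dataset <- function(curves, labels, groups = NULL) {
  if (length(curves) == 0L)
    return(feature_dataset(matrix(numeric(0), 0L, 30L), character(0),
                           character(0)))
  lens <- vapply(curves, function(cu) length(cu$values), integer(1))
  if (any(lens != 30L))
    stop(sprintf("difference curve %d has length %d, expected 30",
                 which(lens != 30L)[1], lens[lens != 30L][1]))
  feats <- do.call(rbind, lapply(curves, function(cu) cu$values))
  colnames(feats) <- paste0("d", seq_len(30L))
  feature_dataset(feats, labels, groups)
}

# ---- oversampling --------------------------------------------------------

# synthesise n_new points for one class by convex combination of a class
# member and one of its k nearest same-class neighbours
synth_points <- function(Xc, n_new, k) {
  nc <- nrow(Xc)
  k_eff <- min(k, nc - 1L)
  D <- as.matrix(stats::dist(Xc))
  diag(D) <- Inf
  nn <- t(apply(D, 1L, function(r) order(r)[seq_len(k_eff)]))
  base <- sample.int(nc, n_new, replace = TRUE)
  nb <- nn[cbind(base, sample.int(k_eff, n_new, replace = TRUE))]
  gap <- stats::runif(n_new)
  Xc[base, , drop = FALSE] +
    gap * (Xc[nb, , drop = FALSE] - Xc[base, , drop = FALSE])
}

#' Balance a training set by SMOTE or ADASYN oversampling
#'
#' Both methods append synthetic minority-class samples, each a convex
#' combination of a minority point and one of its `k` nearest same-class
#' neighbours; original rows are always retained unchanged (synthetic rows
#' carry `NA` group). SMOTE brings every class exactly up to the majority
#' count; ADASYN allocates the synthetic budget per minority point in
#' proportion to the fraction of its `k` nearest neighbours (in the whole
#' data) belonging to other classes, so harder-to-learn regions receive more
#' synthesis and class counts become only approximately equal.
#'
#' @param data a [feature_dataset()] with at least 2 classes present.
#' @param method `"smote"` or `"adasyn"`.
#' @param seed integer seed.
#' @param k neighbourhood size (default 5).
#' @return a balanced [feature_dataset()].
#' @export
oversample <- function(data, method = c("smote", "adasyn"), seed = 1L, k = 5L) {
  method <- match.arg(method)
  counts <- table(droplevels(data$labels))
  if (length(counts) < 2L) stop("need at least 2 classes to balance")
  target <- max(counts)
  withr::with_seed(as.integer(seed), {
    new_feats <- list(); new_labels <- character(0)
    for (cl in names(counts)) {
      nc <- counts[[cl]]
      if (nc == target) next
      if (nc < 2L)
        stop(sprintf(
          "class '%s' has %d member(s); neighbour-based synthesis needs >= 2 (fall back to duplication)",
          cl, nc))
      G <- target - nc
      in_cl <- which(data$labels == cl)
      Xc <- data$features[in_cl, , drop = FALSE]
      if (method == "smote") {
        synth <- synth_points(Xc, G, k)
      } else {
        # ADASYN density criterion over the whole dataset
        k2 <- min(k, fd_nrow(data) - 1L)
        D <- as.matrix(stats::dist(data$features))
        diag(D) <- Inf
        r <- vapply(in_cl, function(i) {
          nn <- order(D[i, ])[seq_len(k2)]
          mean(data$labels[nn] != cl)
        }, numeric(1))
        w <- if (sum(r) == 0) rep(1 / nc, nc) else r / sum(r)
        g <- floor(w * G)
        short <- G - sum(g)
        if (short > 0L) {
          bump <- order(w * G - g, decreasing = TRUE)[seq_len(short)]
          g[bump] <- g[bump] + 1L
        }
        base <- rep(seq_len(nc), times = g)
        k_eff <- min(k, nc - 1L)
        Dc <- as.matrix(stats::dist(Xc)); diag(Dc) <- Inf
        nn <- t(apply(Dc, 1L, function(rr) order(rr)[seq_len(k_eff)]))
        nb <- nn[cbind(base, sample.int(k_eff, length(base), replace = TRUE))]
        gap <- stats::runif(length(base))
        synth <- Xc[base, , drop = FALSE] +
          gap * (Xc[nb, , drop = FALSE] - Xc[base, , drop = FALSE])
      }
      new_feats[[length(new_feats) + 1L]] <- synth
      new_labels <- c(new_labels, rep(cl, nrow(synth)))
    }
    if (length(new_feats) == 0L) return(data)
    synth_fd <- feature_dataset(do.call(rbind, new_feats), new_labels)
    fd_rbind(data, synth_fd)
  })
}

# ---- metrics -------------------------------------------------------------

#' Precision-recall curve and average precision
#'
#' Standard step-wise average precision: `AP = sum((R_n - R_{n-1}) * P_n)`
#' over descending score thresholds (no precision-envelope interpolation).
#' For a scorer independent of the labels, AP concentrates around the
#' positive-class prevalence.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 (or logical) ground truth.
#' @return a list with `precision`, `recall`, `thresholds` and `ap`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  npos <- sum(labels)
  if (npos == 0L) stop("no positive examples")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / npos
  list(precision = precision, recall = recall, thresholds = s[keep],
       ap = sum(diff(c(0, recall)) * precision))
}

#' One-vs-rest ROC AUC of multiclass probabilities
#'
#' Per-class AUC by the rank (Mann-Whitney) statistic; `"macro"` averages
#' the per-class AUCs over classes present in the labels, `"micro"` pools
#' all binarized (example, class) decisions into one AUC.
#'
#' @param probs `n x n_classes` probability matrix.
#' @param labels factor or integer class labels.
#' @param average `"macro"` or `"micro"`.
#' @return a single AUC in `[0, 1]`.
#' @export
ovr_auc <- function(probs, labels, average = c("macro", "micro")) {
  average <- match.arg(average)
  y <- label_index(labels, ncol(probs))
  binary_auc <- function(s, pos) {
    npos <- sum(pos); nneg <- sum(!pos)
    if (npos == 0L || nneg == 0L) return(NA_real_)
    r <- rank(s)
    (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  if (average == "macro") {
    aucs <- vapply(seq_len(ncol(probs)), function(cl)
      binary_auc(probs[, cl], y == cl), numeric(1))
    mean(aucs, na.rm = TRUE)
  } else {
    pos <- as.vector(vapply(seq_len(ncol(probs)), function(cl) y == cl,
                            logical(length(y))))
    binary_auc(as.vector(probs), pos)
  }
}

#' AP of a random classifier under class imbalance
#'
#' For a scorer carrying no information, the average precision for a class
#' equals that class's prevalence, `positives / (positives + negatives)`.
#'
#' @param class_counts named nonnegative counts per class.
#' @return named per-class baseline AP values.
#' @export
random_baseline_ap <- function(class_counts) {
  counts <- as.numeric(class_counts)
  if (sum(counts) <= 0) stop("class counts must have a positive total")
  out <- counts / sum(counts)
  names(out) <- names(class_counts)
  out
}

#' Evaluate a trained classifier on a held-out dataset
#'
#' Computes the test accuracy, the row-normalized confusion matrix (rows =
#' actual classes), per-class one-vs-rest precision-recall curves with
#' average precision, and the micro-averaged PR curve over all binarized
#' (example, class) decisions. The held-out data is used as-is — never
#' resampled — so the metrics reflect the original imbalanced class
#' distribution.
#'
#' @param model a trained [build_cnn()] model.
#' @param test a [feature_dataset()].
#' @return an object of class `evaluation_report`: `accuracy`, `confusion`
#'   (4 x 4, rows summing to 1 for classes present), `per_class` (PR curve +
#'   AP per class), `micro` (micro-averaged PR + AP), `macro_auc`,
#'   `class_counts`.
#' @export
evaluate <- function(model, test) {
  if (fd_nrow(test) == 0L) stop("empty test set")
  probs <- predict_proba(model, test$features)
  y <- as.integer(test$labels)
  pred <- max.col(probs, ties.method = "first")
  classes <- robustness_classes()
  conf <- matrix(0, 4L, 4L, dimnames = list(actual = classes,
                                            predicted = classes))
  for (i in seq_along(y)) conf[y[i], pred[i]] <- conf[y[i], pred[i]] + 1
  rs <- rowSums(conf)
  conf_norm <- conf / ifelse(rs > 0, rs, NA_real_)
  per_class <- lapply(seq_len(4L), function(cl) {
    if (!any(y == cl)) return(NULL)
    pr_curve(probs[, cl], y == cl)
  })
  names(per_class) <- classes
  pos <- as.vector(vapply(seq_len(4L), function(cl) y == cl,
                          logical(length(y))))
  micro <- pr_curve(as.vector(probs), as.integer(pos))
  structure(list(accuracy = mean(pred == y), confusion = conf_norm,
                 per_class = per_class, micro = micro,
                 macro_auc = ovr_auc(probs, y, "macro"),
                 class_counts = table(test$labels), n = length(y)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d examples: accuracy %.4f, micro-AP %.4f\n",
              x$n, x$accuracy, x$micro$ap))
  aps <- vapply(x$per_class, function(p)
    if (is.null(p)) NA_real_ else p$ap, numeric(1))
  for (i in seq_along(aps))
    cat(sprintf("  %-26s AP = %s\n", names(aps)[i],
                ifelse(is.na(aps[i]), "NA", sprintf("%.4f", aps[i]))))
  invisible(x)
}

# ---- cross-validation ----------------------------------------------------

#' The 12-point hyperparameter grid
#'
#' Batch size x balancing method x CNN architecture, each trained for a
#' fixed number of epochs. The default reproduces the standard 12-set grid
#' (3 batch sizes x 2 balancers x 2 architectures, 128 epochs); smaller
#' grids/epochs are useful for smoke runs.
#'
#' @param batch_size candidate minibatch sizes.
#' @param balancing candidate oversamplers.
#' @param architecture candidate CNN architectures.
#' @param epochs training epochs for every set.
#' @return a data frame with columns `set`, `epochs`, `batch_size`,
#'   `balancing`, `architecture`.
#' @export
hyperparameter_grid <- function(batch_size = c(32L, 64L, 128L),
                                balancing = c("smote", "adasyn"),
                                architecture = c("simple", "complex"),
                                epochs = 128L) {
  g <- expand.grid(batch_size = as.integer(batch_size),
                   architecture = architecture, balancing = balancing,
                   stringsAsFactors = FALSE)
  data.frame(set = paste0("hyp", seq_len(nrow(g))), epochs = as.integer(epochs),
             batch_size = g$batch_size, balancing = g$balancing,
             architecture = g$architecture, stringsAsFactors = FALSE)
}

# stratified assignment of indices to k folds (or to a held-out fraction)
stratified_split <- function(labels, frac) {
  idx <- integer(0)
  for (cl in levels(droplevels(labels))) {
    in_cl <- which(labels == cl)
    n_take <- round(length(in_cl) * frac)
    if (n_take > 0L)
      idx <- c(idx, sample(in_cl, n_take))
  }
  sort(idx)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(droplevels(labels))) {
    in_cl <- sample(which(labels == cl))
    fold[in_cl] <- rep_len(seq_len(k), length(in_cl))
  }
  fold
}

#' Nested k-fold cross-validation for hyperparameter selection
#'
#' The data is split 75/25 (stratified) into a training portion and a
#' held-out test portion. The training portion is divided into `k = 4`
#' stratified outer folds. For each fold, the fold-training data (the other
#' folds) is balanced with the candidate oversampler and split 67/33 three
#' times; every hyperparameter set is trained on the 67% part and scored by
#' one-vs-rest AUC on the 33% part. The selection score of a set is the mean
#' AUC over the 3 inner rows and then over the 4 folds; the argmax wins.
#' Finally, one model per fold is retrained with the winning set on the
#' balanced fold-training data and evaluated on the untouched, imbalanced
#' test portion.
#'
#' Balancing the fold-training data *before* the 67/33 split replicates the
#' original protocol but lets synthetic neighbours leak across the inner
#' split; set `balance_before_split = FALSE` to balance only the 67% part.
#'
#' @param data a [feature_dataset()] containing all four classes (or at
#'   least two when `allow_missing_classes = TRUE`).
#' @param grid a [hyperparameter_grid()].
#' @param seed master seed; the whole selection is a pure function of
#'   `(data, grid, seed)`.
#' @param k number of outer folds.
#' @param test_frac held-out fraction of the data.
#' @param inner_splits number of inner 67/33 splits per fold.
#' @param inner_frac inner-loop training fraction.
#' @param lr Adam learning rate.
#' @param auc_average `"macro"` (default) or `"micro"` AUC for selection.
#' @param balance_before_split balance before (TRUE, replicating the
#'   original protocol) or after the inner split.
#' @param allow_missing_classes accept datasets lacking some of the four
#'   classes (used by smoke experiments on tiny cohorts).
#' @param smote_k oversampling neighbourhood size.
#' @return an object of class `nested_cv`: `best` (winning grid row),
#'   `auc_table` (selection AUC per set), `fold_reports` (one
#'   [evaluate()] report per fold on the test portion), `mean_accuracy`,
#'   `test_idx`.
#' @export
nested_cross_validation <- function(data, grid = hyperparameter_grid(),
                                    seed = 1L, k = 4L, test_frac = 0.25,
                                    inner_splits = 3L, inner_frac = 0.67,
                                    lr = 1e-3,
                                    auc_average = c("macro", "micro"),
                                    balance_before_split = TRUE,
                                    allow_missing_classes = FALSE,
                                    smote_k = 5L) {
  auc_average <- match.arg(auc_average)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  present <- levels(droplevels(data$labels))
  if (!allow_missing_classes && length(present) < 4L)
    stop("stratification error: all four classes must be present ",
         "(set allow_missing_classes = TRUE to override)")
  if (length(present) < 2L)
    stop("stratification error: need at least two classes")
  withr::with_seed(as.integer(seed), {
    n <- fd_nrow(data)
    test_idx <- stratified_split(data$labels, test_frac)
    train_idx <- setdiff(seq_len(n), test_idx)
    train <- fd_subset(data, train_idx)
    test <- fd_subset(data, test_idx)
    fold <- stratified_folds(train$labels, k)
    for (f in seq_len(k)) {
      tr_lab <- droplevels(train$labels[fold != f])
      if (!setequal(levels(tr_lab), present))
        stop(sprintf("stratification error: fold %d training data lacks a class", f))
    }
    auc_mat <- matrix(NA_real_, nrow(grid), k,
                      dimnames = list(grid$set, paste0("fold", seq_len(k))))
    for (f in seq_len(k)) {
      fold_train <- fd_subset(train, which(fold != f))
      for (h in seq_len(nrow(grid))) {
        hyp <- grid[h, ]
        pool <- if (balance_before_split)
          oversample(fold_train, hyp$balancing,
                     seed = derive_seed(seed, "balance", f, h), k = smote_k)
        else fold_train
        aucs <- numeric(inner_splits)
        for (r in seq_len(inner_splits)) {
          sub_idx <- stratified_split(pool$labels, 1 - inner_frac)
          inner_val <- fd_subset(pool, sub_idx)
          inner_train <- fd_subset(pool, setdiff(seq_len(fd_nrow(pool)),
                                                 sub_idx))
          if (!balance_before_split)
            inner_train <- oversample(inner_train, hyp$balancing,
                                      seed = derive_seed(seed, "bal2", f, h, r),
                                      k = smote_k)
          model <- build_cnn(hyp$architecture, input_len = ncol(data$features),
                             seed = derive_seed(seed, "init", f, h, r))
          model <- train_cnn(model, inner_train$features, inner_train$labels,
                             epochs = hyp$epochs, batch_size = hyp$batch_size,
                             lr = lr,
                             seed = derive_seed(seed, "train", f, h, r))
          probs <- predict_proba(model, inner_val$features)
          aucs[r] <- ovr_auc(probs, inner_val$labels, auc_average)
        }
        auc_mat[h, f] <- mean(aucs)
      }
    }
    auc_final <- rowMeans(auc_mat)
    best_h <- which.max(auc_final)
    best <- grid[best_h, ]
    fold_reports <- vector("list", k)
    for (f in seq_len(k)) {
      fold_train <- fd_subset(train, which(fold != f))
      balanced <- oversample(fold_train, best$balancing,
                             seed = derive_seed(seed, "final-bal", f),
                             k = smote_k)
      model <- build_cnn(best$architecture, input_len = ncol(data$features),
                         seed = derive_seed(seed, "final-init", f))
      model <- train_cnn(model, balanced$features, balanced$labels,
                         epochs = best$epochs, batch_size = best$batch_size,
                         lr = lr, seed = derive_seed(seed, "final-train", f))
      fold_reports[[f]] <- evaluate(model, test)
    }
    structure(list(best = best, auc_table = auc_final, auc_by_fold = auc_mat,
                   fold_reports = fold_reports,
                   mean_accuracy = mean(vapply(fold_reports, `[[`, numeric(1),
                                               "accuracy")),
                   final_model = model, test_idx = test_idx),
              class = "nested_cv")
  })
}

#' @export
print.nested_cv <- function(x, ...) {
  cat("Nested cross-validation\n")
  cat(sprintf("  best set: %s (epochs=%d, batch=%d, %s, %s)\n", x$best$set,
              x$best$epochs, x$best$batch_size, x$best$balancing,
              x$best$architecture))
  cat(sprintf("  selection AUC: %s\n",
              paste(sprintf("%s=%.3f", names(x$auc_table), x$auc_table),
                    collapse = ", ")))
  cat(sprintf("  mean test accuracy over folds: %.4f\n", x$mean_accuracy))
  invisible(x)
}
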