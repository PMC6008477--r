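# Leave-one-subject-out evaluation of the kernel-SVM and random-forest
# classifiers, with per-recording majority voting and the standard
# SE/SP/ACC and F1 metrics.

feature_columns <- function(table) {
  setdiff(colnames(table), c("subject_id", "label", "episode"))
}

#' Leave-one-subject-out folds of a feature table
#'
#' One fold per subject: all of that subject's segments form the test
#' set, everything else trains. No subject ever appears on both sides,
#' and the test sets partition the table.
#'
#' @param table A feature table from [extract_features()].
#' @return A named list of `list(train, test)` row-index pairs.
#' @export
loocv_split <- function(table) {
  subjects <- unique(table$subject_id)
  if (length(subjects) < 2)
    stop("leave-one-subject-out needs at least 2 subjects")
  folds <- lapply(subjects, function(s) {
    test <- which(table$subject_id == s)
    list(train = setdiff(seq_len(nrow(table)), test), test = test)
  })
  names(folds) <- subjects
  folds
}

#' Train on one fold and predict its test segments
#'
#' Features are z-scored with training-fold statistics only
#' (zero-variance columns pass through unscaled). `"ksvm"` is a
#' one-vs-one RBF-kernel SVM solved as a dual quadratic program,
#' default `C = 10` and `gamma = 1/p` (optionally grid-searched by
#' 3-fold inner CV when `config$svm$tune` is set); `"rf"` is a
#' Gini/CART random forest with `ntree = 500` and
#' `mtry = floor(sqrt(p))` by default. Both are deterministic under a
#' fixed seed.
#'
#' @param train,test Data.frame slices of a feature table.
#' @param classifier `"ksvm"` or `"rf"`.
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return A list with `labels` (character predictions per test row),
#'   `score` (rows x classes matrix used for vote tie-breaking) and
#'   `levels`.
#' @export
train_predict <- function(train, test, classifier = c("ksvm", "rf"),
                          config = pipeline_config(), seed = 1L) {
  classifier <- match.arg(classifier)
  lev <- sort(unique(train$label))
  if (length(lev) < 2)
    stop("training fold is degenerate: a single class (",
         lev, ") cannot be learned from")
  cols <- feature_columns(train)
  Xtr <- as.matrix(train[, cols])
  Xte <- as.matrix(test[, cols, drop = FALSE])
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  y_idx <- match(train$label, lev)

  score <- with_seed(seed, {
    if (classifier == "ksvm") {
      p <- ncol(Xtr)
      gamma <- if (is.null(config$svm$gamma)) 1 / p else config$svm$gamma
      C <- config$svm$C
      if (isTRUE(config$svm$tune)) {
        hp <- svm_tune(Xtr, y_idx, length(lev), config$svm, gamma)
        C <- hp$C; gamma <- hp$gamma
      }
      svm_ovo(Xtr, y_idx, Xte, length(lev), C, gamma)$score
    } else {
      mtry <- config$rf$mtry
      if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(Xtr))))
      v <- .rf_votes(Xtr, y_idx - 1L, length(lev), Xte,
                     as.integer(config$rf$ntree), as.integer(mtry),
                     as.integer(config$rf$min_node),
                     as.integer(config$rf$max_depth))
      v / config$rf$ntree
    }
  })
  pred <- max.col(score, ties.method = "first")
  list(labels = lev[pred], score = score, levels = lev)
}

# Small inner 3-fold grid search over C and gamma scalings; returns the
# pair with the best segment-level accuracy.
svm_tune <- function(X, y_idx, levels_n, svm_cfg, gamma0) {
  n <- nrow(X)
  fold <- rep_len(1:3, n)
  best <- list(C = svm_cfg$C_grid[1], gamma = gamma0, acc = -1)
  for (C in svm_cfg$C_grid) for (gs in svm_cfg$gamma_scale) {
    gamma <- gamma0 * gs
    acc <- mean(unlist(lapply(1:3, function(f) {
      tr <- fold != f
      if (length(unique(y_idx[tr])) < 2) return(NULL)
      out <- svm_ovo(X[tr, , drop = FALSE], y_idx[tr],
                     X[!tr, , drop = FALSE], levels_n, C, gamma)
      out$pred == y_idx[!tr]
    })))
    if (!is.na(acc) && acc > best$acc)
      best <- list(C = C, gamma = gamma, acc = acc)
  }
  best
}

#' Majority vote over the segment predictions of one recording
#'
#' Returns the modal class. Ties are broken by the larger summed
#' prediction score when scores are supplied, otherwise by the lowest
#' class index -- both deterministic.
#'
#' @param labels Character vector of per-segment predictions (>= 1).
#' @param score Optional rows x classes score matrix with `levels` as
#'   `colnames` order.
#' @param levels Class levels corresponding to `score` columns.
#' @return A single class label.
#' @export
majority_vote <- function(labels, score = NULL, levels = NULL) {
  if (!length(labels)) stop("majority_vote needs at least one label")
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  if (!is.null(score) && !is.null(levels)) {
    conf <- colSums(score[, match(top, levels), drop = FALSE])
    return(top[which.max(conf)])
  }
  sort(top)[1]
}

#' Classification metrics from a confusion matrix
#'
#' Rows are true classes, columns predictions. Accuracy is the diagonal
#' sum over the total. For two classes, sensitivity and specificity are
#' reported with `positive` (default: the first row, conventionally the
#' disease class) as the positive class. Per-class F1 is the harmonic
#' mean of one-vs-rest precision and recall; the average F1 is their
#' arithmetic mean. Metrics whose denominator is zero are reported as
#' `NA` (undefined), not 0.
#'
#' @param confusion Square numeric matrix with identical row/column
#'   names.
#' @param positive Positive class for SE/SP in the two-class case.
#' @return A list with `confusion`, `acc`, `se`, `sp` (two-class only),
#'   `f1` (named per-class) and `f1_avg`.
#' @export
eval_metrics <- function(confusion, positive = rownames(confusion)[1]) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || sum(confusion) == 0)
    stop("confusion matrix must be square and non-empty")
  classes <- rownames(confusion)
  total <- sum(confusion)
  acc <- sum(diag(confusion)) / total
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  f1 <- vapply(classes, function(k) {
    tp <- confusion[k, k]
    prec <- safe_div(tp, sum(confusion[, k]))
    rec <- safe_div(tp, sum(confusion[k, ]))
    if (is.na(prec) || is.na(rec) || prec + rec == 0) return(NA_real_)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  out <- list(confusion = confusion, acc = acc, f1 = f1,
              f1_avg = mean(f1))
  if (length(classes) == 2) {
    pos <- positive
    neg <- setdiff(classes, pos)
    out$se <- safe_div(confusion[pos, pos], sum(confusion[pos, ]))
    out$sp <- safe_div(confusion[neg, neg], sum(confusion[neg, ]))
  }
  out
}

#' Leave-one-subject-out evaluation of the full classifier
#'
#' Runs [train_predict()] across all subject folds and reports
#' confusion matrices and metrics both without majority voting (one
#' count per 10 s segment) and with it (one count per recording, the
#' modal class of its segments).
#'
#' @param table A feature table from [extract_features()] with labels.
#' @param classifier `"ksvm"` or `"rf"`.
#' @param config A [pipeline_config()].
#' @param seed Integer seed (per-fold seeds are derived from it).
#' @return A list of class `mcg_eval` with `segment` and `voted`
#'   metric lists ([eval_metrics()]), the per-segment `predictions`
#'   data.frame, `classifier` and `mode`.
#' @export
run_loocv <- function(table, classifier = c("ksvm", "rf"),
                      config = pipeline_config(), seed = 1L) {
  classifier <- match.arg(classifier)
  if (anyNA(table$label)) stop("evaluation needs labelled recordings")
  folds <- loocv_split(table)
  classes <- sort(unique(table$label))
  preds <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    out <- train_predict(table[f$train, ], table[f$test, ], classifier,
                         config, seed = seed + i)
    sc <- matrix(0, length(f$test), length(classes),
                 dimnames = list(NULL, classes))
    sc[, out$levels] <- out$score
    preds[[i]] <- data.frame(subject_id = table$subject_id[f$test],
                             truth = table$label[f$test],
                             pred = out$labels,
                             stringsAsFactors = FALSE)
    preds[[i]]$score <- sc
  }
  pred_df <- do.call(rbind, preds)

  conf_seg <- table_confusion(pred_df$truth, pred_df$pred, classes)
  by_subj <- split(seq_len(nrow(pred_df)), pred_df$subject_id)
  voted <- t(vapply(by_subj, function(rows) {
    c(truth = pred_df$truth[rows[1]],
      pred = majority_vote(pred_df$pred[rows],
                           pred_df$score[rows, , drop = FALSE], classes))
  }, character(2)))
  conf_vote <- table_confusion(voted[, "truth"], voted[, "pred"], classes)

  structure(list(segment = eval_metrics(conf_seg),
                 voted = eval_metrics(conf_vote),
                 predictions = pred_df[, c("subject_id", "truth", "pred")],
                 classifier = classifier, mode = config$mode),
            class = "mcg_eval")
}

table_confusion <- function(truth, pred, classes) {
  tab <- table(factor(truth, classes), factor(pred, classes))
  m <- matrix(as.numeric(tab), length(classes), length(classes),
              dimnames = list(classes, classes))
  m
}

#' @export
print.mcg_eval <- function(x, ...) {
  cat(sprintf("<mcg_eval> %s, %s\n", toupper(x$classifier), x$mode))
  fmt <- function(m, tag) {
    cat(sprintf("  %s: ACC %.3f", tag, m$acc))
    if (!is.null(m$se)) cat(sprintf(", SE %.3f, SP %.3f", m$se, m$sp))
    cat(sprintf(", avg F1 %.3f\n", m$f1_avg))
  }
  fmt(x$segment, "per-segment   ")
  fmt(x$voted, "majority-voted")
  invisible(x)
}
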