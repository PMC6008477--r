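# A small synthetic feature table is enough to exercise the classifier
# plumbing; the full-pipeline benchmark lives in test-acceptance.R.
make_table <- function(n_subj = 8, seg_per_subj = 3, p = 12, sep = 3,
                       seed = 51) {
  set.seed(seed)
  rows <- n_subj * seg_per_subj
  lab <- rep(rep(c("NORMAL", "AFIB"), length.out = n_subj),
             each = seg_per_subj)
  X <- matrix(rnorm(rows * p), rows, p)
  X[lab == "AFIB", ] <- X[lab == "AFIB", ] + sep
  df <- data.frame(subject_id = rep(sprintf("S%02d", 1:n_subj),
                                    each = seg_per_subj),
                   label = lab, episode = rep(1:seg_per_subj, n_subj),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(X))
}

test_that("LOOCV folds partition segments by subject", {
  tab <- make_table(n_subj = 5)
  folds <- loocv_split(tab)
  expect_length(folds, 5)
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(tests, seq_len(nrow(tab)))
  expect_equal(anyDuplicated(tests), 0L)
  for (f in folds) {
    expect_length(f$test, 3)
    expect_length(intersect(tab$subject_id[f$train],
                            tab$subject_id[f$test]), 0)
  }
  expect_error(loocv_split(tab[tab$subject_id == "S01", ]), "2 subjects")
})

test_that("both classifiers solve a separable problem and are seed-deterministic", {
  tab <- make_table(sep = 3)
  for (cls in c("ksvm", "rf")) {
    ev <- run_loocv(tab, cls, pipeline_config(rf = list(ntree = 100L)),
                    seed = 1)
    expect_equal(ev$segment$acc, 1, label = cls)
    expect_equal(ev$voted$acc, 1, label = cls)
    ev2 <- run_loocv(tab, cls, pipeline_config(rf = list(ntree = 100L)),
                     seed = 1)
    expect_identical(ev$predictions, ev2$predictions, label = cls)
  }
})

test_that("duplicated training rows leave KSVM predictions unchanged", {
  tab <- make_table(sep = 3)
  train <- tab[tab$subject_id != "S01", ]
  test <- tab[tab$subject_id == "S01", ]
  a <- train_predict(train, test, "ksvm", seed = 2)
  b <- train_predict(rbind(train, train), test, "ksvm", seed = 2)
  expect_identical(a$labels, b$labels)
})

test_that("degenerate single-class training folds are refused", {
  tab <- make_table()
  train <- tab[tab$label == "NORMAL", ]
  expect_error(train_predict(train, tab[1:2, ], "ksvm"), "single class")
})

test_that("majority voting is modal with deterministic tie-breaks", {
  expect_equal(majority_vote(c("A", "A", "B")), "A")
  expect_equal(majority_vote("A"), "A")
  expect_equal(majority_vote(c("A", "B")), "A")   # no scores: lowest index
  sc <- rbind(c(0.1, 0.9), c(0.45, 0.55))
  expect_equal(majority_vote(c("A", "B"), sc, c("A", "B")), "B")
  expect_error(majority_vote(character(0)), "at least one")
})

test_that("metrics reproduce hand-computed confusion-matrix values", {
  perfect <- matrix(c(40, 0, 0, 23), 2, byrow = TRUE,
                    dimnames = list(c("AFIB", "NORMAL"),
                                    c("AFIB", "NORMAL")))
  m <- eval_metrics(perfect, positive = "AFIB")
  expect_equal(c(m$se, m$sp, m$acc), c(1, 1, 1))

  near <- matrix(c(39, 1, 0, 23), 2, byrow = TRUE,
                 dimnames = list(c("AFIB", "NORMAL"),
                                 c("AFIB", "NORMAL")))
  m2 <- eval_metrics(near, positive = "AFIB")
  expect_equal(m2$se, 0.975)
  expect_equal(m2$acc, 62 / 63)
  expect_equal(m2$sp, 1)

  three <- diag(c(10, 10, 10))
  dimnames(three) <- list(c("A", "B", "C"), c("A", "B", "C"))
  m3 <- eval_metrics(three)
  expect_equal(m3$acc, 1)
  expect_equal(unname(m3$f1), c(1, 1, 1))
  expect_equal(m3$f1_avg, 1)

  # an unpredicted class has undefined precision -> NA, not 0
  skew <- matrix(c(5, 0, 3, 0), 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_true(is.na(eval_metrics(skew)$f1["B"]))
})

test_that("majority voting never hurts recordings whose segments are mostly right", {
  tab <- make_table(n_subj = 6, seg_per_subj = 5, sep = 2.5, seed = 52)
  ev <- run_loocv(tab, "ksvm", seed = 3)
  per_subj <- split(ev$predictions, ev$predictions$subject_id)
  for (s in names(per_subj)) {
    df <- per_subj[[s]]
    if (mean(df$pred == df$truth) > 0.5) {
      voted <- majority_vote(df$pred)
      expect_equal(voted, df$truth[1])
    }
  }
})
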