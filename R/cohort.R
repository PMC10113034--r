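#' Discard tracks shorter than half of the video
#'
#' Guarantees that no physical animal contributes more than one track to a
#' cohort analysis: two tracks of at least half the video each would have to
#' overlap in time. Exactly half is kept (weakest exclusion preserving the
#' guarantee).
#'
#' @param tracks list of [track_record()]
#' @param video_len_frames total video length in frames
#' @return the kept tracks
#' @export
filter_tracks <- function(tracks, video_len_frames) {
  keep <- vapply(tracks, function(tr)
    tr$duration_frames >= video_len_frames / 2, TRUE)
  tracks[keep]
}

#' Assemble a cohort table of the 30 random-forest attributes
#'
#' @param records list of one-row attribute data frames from
#'   [compute_attributes()]
#' @param labels genotype/condition per row
#' @param na_action `"drop"` rows with missing features or `"impute"` by the
#'   column median
#' @return data.frame with the 30 feature columns plus `label`
#' @export
cohort_table <- function(records, labels, na_action = c("drop", "impute")) {
  na_action <- match.arg(na_action)
  stopifnot(length(records) == length(labels))
  feats <- rf_attribute_names()
  tab <- do.call(rbind, lapply(records, function(r) r[, feats, drop = FALSE]))
  tab$label <- as.character(labels)
  bad <- !stats::complete.cases(tab[, feats])
  if (any(bad)) {
    if (na_action == "drop") tab <- tab[!bad, , drop = FALSE]
    else for (f in feats) {
      miss <- !is.finite(tab[[f]])
      if (any(miss)) tab[[f]][miss] <- median(tab[[f]][!miss])
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Accuracy as the unweighted mean of per-class correct-assignment rates
#'
#' @param confusion square confusion matrix, rows = actual, cols = predicted
#' @return accuracy in `[0, 1]`
#' @export
accuracy_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  rates <- diag(confusion) / rowSums(confusion)
  mean(rates)
}

# deterministic sub-seed stream derived from one integer seed
seed_stream <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Random-forest classification with repeated cross-validation
#'
#' The published protocol: a CART-based random forest (Gini splits,
#' bootstrap bagging, `sqrt(p)` features per split) evaluated by five-fold
#' cross-validation repeated three times with reshuffling. Out-of-fold
#' predictions are pooled into a confusion matrix; the reported accuracy is
#' the unweighted mean of the per-class correct-assignment rates. Fully
#' deterministic for a fixed seed.
#'
#' @param table a [cohort_table()] (or any data.frame of numeric features
#'   plus a label column)
#' @param label_col name of the class column
#' @param seed integer seed
#' @param ntree trees per forest
#' @param folds,reps cross-validation geometry
#' @return an `rf_result`: `accuracy`, `confusion`, `per_class_rates`,
#'   `importance` (mean decrease in impurity, averaged over folds and reps)
#' @export
rf_classify <- function(table, label_col = "label", seed = 1L, ntree = 500,
                        folds = 5, reps = 3) {
  y <- as.factor(table[[label_col]])
  if (nlevels(y) < 2) stop("at least two classes required")
  X <- as.matrix(table[, setdiff(colnames(table), label_col), drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (min(table(y)) < 2) stop("each class needs at least 2 rows")
  mtry <- max(1L, floor(sqrt(p)))
  K <- nlevels(y)
  yi <- as.integer(y) - 1L
  confusion <- matrix(0L, K, K, dimnames = list(actual = levels(y),
                                                predicted = levels(y)))
  importance <- numeric(p)
  seeds <- seed_stream(seed, reps * (folds + 1))
  si <- 0L
  for (rep in seq_len(reps)) {
    si <- si + 1L
    fold_of <- with_seed(seeds[si], sample(rep_len(seq_len(folds), n)))
    for (fd in seq_len(folds)) {
      si <- si + 1L
      test <- fold_of == fd
      fit <- .rf_fit_predict(X[!test, , drop = FALSE], yi[!test],
                             X[test, , drop = FALSE], K, ntree, mtry,
                             seeds[si])
      for (k in seq_len(sum(test)))
        confusion[yi[test][k] + 1L, fit$pred[k] + 1L] <-
          confusion[yi[test][k] + 1L, fit$pred[k] + 1L] + 1L
      importance <- importance + fit$importance
    }
  }
  imp <- importance / (reps * folds)
  names(imp) <- colnames(X)
  structure(list(accuracy = accuracy_from_confusion(confusion),
                 confusion = confusion,
                 per_class_rates = diag(confusion) / rowSums(confusion),
                 importance = imp, seed = seed, ntree = ntree),
            class = "rf_result")
}

#' @export
print.rf_result <- function(x, ...) {
  cat(sprintf("<rf_result> accuracy %.3f (per-class %s)\n", x$accuracy,
              paste(sprintf("%.2f", x$per_class_rates), collapse = ", ")))
  invisible(x)
}

#' Attribute importance ranks over repeated forest runs
#'
#' The complete cross-validated forest is run `n_runs` times; per run the
#' attributes are ranked by impurity importance (rank 1 = most important)
#' and the mean rank across runs orders the output.
#'
#' @inheritParams rf_classify
#' @param n_runs repetitions of the complete model
#' @return data.frame sorted by `mean_rank`: `attribute`, `mean_rank`,
#'   `mean_importance`
#' @export
rf_importance <- function(table, label_col = "label", n_runs = 10,
                          seed = 1L, ntree = 500, folds = 5, reps = 3) {
  seeds <- seed_stream(seed, n_runs)
  ranks <- NULL; imps <- NULL
  for (r in seq_len(n_runs)) {
    fit <- rf_classify(table, label_col, seed = seeds[r], ntree = ntree,
                       folds = folds, reps = reps)
    ranks <- rbind(ranks, rank(-fit$importance, ties.method = "average"))
    imps <- rbind(imps, fit$importance)
  }
  out <- data.frame(attribute = colnames(ranks),
                    mean_rank = colMeans(ranks),
                    mean_importance = colMeans(imps))
  out[order(out$mean_rank), ]
}

#' Nonparametric test battery with Bonferroni-Holm correction
#'
#' Runs a declared family of two-tailed nonparametric tests and adjusts the
#' p-values with the Holm step-down procedure within the family
#' (experiment-wide error rate below 5%). Test kinds: `"KW"`
#' (Kruskal-Wallis over a list of groups), `"MW"` (Mann-Whitney U between
#' two groups), `"WS"` (Wilcoxon signed-rank on paired values), `"SC"`
#' (Spearman rank correlation).
#'
#' @param family list of tests; each element is
#'   `list(kind = , data = , name = )` where `data` is a list of numeric
#'   vectors (groups for KW/MW, the two paired/correlated vectors for WS/SC)
#' @param alpha family-wise significance level
#' @return data.frame: `name`, `kind`, `statistic`, `p_raw`, `p_adjusted`,
#'   `significant`
#' @export
run_tests <- function(family, alpha = 0.05) {
  one <- function(te) {
    kind <- match.arg(te$kind, c("KW", "MW", "WS", "SC"))
    d <- te$data
    res <- switch(kind,
      KW = kruskal.test(d),
      MW = suppressWarnings(wilcox.test(d[[1]], d[[2]], exact = FALSE)),
      WS = suppressWarnings(wilcox.test(d[[1]], d[[2]], paired = TRUE,
                                        exact = FALSE)),
      SC = suppressWarnings(cor.test(d[[1]], d[[2]], method = "spearman",
                                     exact = FALSE)))
    data.frame(name = te$name %||% kind, kind = kind,
               statistic = unname(res$statistic), p_raw = res$p.value)
  }
  out <- do.call(rbind, lapply(family, one))
  out$p_adjusted <- p.adjust(out$p_raw, method = "holm")
  out$significant <- out$p_adjusted < alpha
  out
}

#' Kruskal-Wallis with Holm-corrected pairwise follow-up
#'
#' Pairwise Mann-Whitney comparisons are only run when the omnibus
#' Kruskal-Wallis test is significant.
#'
#' @param groups named list of numeric vectors
#' @param alpha significance level
#' @return list: `kw` (the omnibus row), `pairwise` (data.frame or NULL)
#' @export
kw_with_posthoc <- function(groups, alpha = 0.05) {
  kw <- run_tests(list(list(kind = "KW", data = groups, name = "omnibus")),
                  alpha)
  pw <- NULL
  if (kw$significant[1]) {
    nm <- names(groups) %||% paste0("g", seq_along(groups))
    fam <- list()
    for (i in seq_along(groups)[-length(groups)])
      for (j in (i + 1):length(groups))
        fam[[length(fam) + 1]] <- list(kind = "MW",
                                       data = list(groups[[i]], groups[[j]]),
                                       name = paste(nm[i], "vs", nm[j]))
    pw <- run_tests(fam, alpha)
  }
  list(kw = kw, pairwise = pw)
}

#' Empirical type-I error of a test under a null simulator
#'
#' @param simulator function(i) returning the `data` list for one null
#'   dataset (groups/pairs as in [run_tests()])
#' @param kind test kind (`"KW"`, `"MW"`, `"WS"`, `"SC"`)
#' @param n_reps number of simulated datasets
#' @param alpha nominal level
#' @param seed RNG seed
#' @return rejection rate, with attribute `"se"` (binomial standard error)
#' @export
type_I_error_suite <- function(simulator, kind = "MW", n_reps = 2000,
                               alpha = 0.05, seed = 1L) {
  rej <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      res <- run_tests(list(list(kind = kind, data = simulator(i))), alpha)
      res$p_raw[1] < alpha
    }, TRUE)
  })
  rate <- mean(rej)
  attr(rate, "se") <- sqrt(alpha * (1 - alpha) / n_reps)
  rate
}
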