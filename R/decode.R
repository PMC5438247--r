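# Population decoding: feature encodings, Euclidean leave-one-out nearest-mean
# classification, the three classification tasks, pseudopopulation permutation
# statistics and temporal-window analyses.

#' Panel structure of a trial table
#'
#' Identifies the distinct non-blank stimuli, the concentration-series odorants
#' (those presented at more than one concentration) and the nominal
#' concentration (the one at which every odorant appears).
#'
#' @param trials a trial table.
#' @return list with `stimuli` (data.frame odorant, concentration),
#'   `series_odorants`, `nominal_concentration`, and for each series stimulus
#'   the number of training stimuli and of training stimuli sharing its
#'   identity when it is held out.
#' @export
generalization_panel <- function(trials) {
  st <- unique(trials[!trials$is_blank, c("odorant", "concentration")])
  st <- st[order(st$odorant, st$concentration), ]
  rownames(st) <- NULL
  tab <- table(st$odorant)
  series <- names(tab)[tab > 1]
  conc_counts <- table(st$concentration)
  nominal <- as.numeric(names(conc_counts)[which.max(conc_counts)])
  held <- st[st$odorant %in% series, ]
  held$n_train <- nrow(st) - 1L
  held$n_shared_identity <- as.integer(tab[held$odorant] - 1L)
  list(stimuli = st, series_odorants = series,
       nominal_concentration = nominal, held_out = held,
       chance_generalization = unique(held$n_shared_identity) /
         unique(held$n_train))
}

#' Encode trials as decoder feature vectors
#'
#' Three encodings of the population response in the 480 ms following
#' inhalation: `summed` (per-cell spike counts; a rate code), `binned`
#' (concatenated 30 ms bin counts per cell; a temporal code) and `binary`
#' (per-cell responding-or-not, thresholded at the blank-trial mean plus
#' `binary_threshold_sd` blank-trial standard deviations, strict inequality;
#' a membership code). Blank statistics are pooled over all blank trials.
#'
#' @param binned a [binned_count_array()].
#' @param scheme `"summed"`, `"binned"` or `"binary"`.
#' @param binary_threshold_sd threshold multiplier on the blank-count SD.
#' @return object of class `encoded_features`: list with the feature `matrix`
#'   (all trials, including blanks), `trials`, `scheme`, `cells` and the
#'   column-to-cell map `col_cell`.
#' @export
encode_features <- function(binned, scheme = c("summed", "binned", "binary"),
                            binary_threshold_sd = 1) {
  scheme <- match.arg(scheme)
  trials <- attr(binned, "trials")
  cells <- dimnames(binned)[[2]]
  counts <- rowSums(binned, dims = 2)   # trials x cells
  if (scheme == "summed") {
    x <- counts
    col_cell <- seq_along(cells)
  } else if (scheme == "binned") {
    nb <- dim(binned)[3]
    x <- matrix(aperm(binned, c(1, 3, 2)), nrow = dim(binned)[1])
    col_cell <- rep(seq_along(cells), each = nb)
  } else {
    if (binary_threshold_sd < 0) stopf("threshold multiplier must be >= 0")
    bl <- which(trials$is_blank)
    if (!length(bl)) stopf("binary encoding requires blank trials")
    mu <- colMeans(counts[bl, , drop = FALSE])
    sdv <- apply(counts[bl, , drop = FALSE], 2, stats::sd)
    sdv[is.na(sdv)] <- 0
    thr <- mu + binary_threshold_sd * sdv
    x <- (sweep(counts, 2, thr, ">")) * 1
    col_cell <- seq_along(cells)
  }
  structure(list(matrix = x, trials = trials, scheme = scheme, cells = cells,
                 col_cell = col_cell),
            class = "encoded_features")
}

# column indices of the feature matrix belonging to a cell subset
feature_cols <- function(features, cell_idx) {
  which(features$col_cell %in% cell_idx)
}

#' Euclidean leave-one-out nearest-mean classification accuracy
#'
#' Each trial is held out, class mean vectors are recomputed from the training
#' trials, and the trial is assigned to the class with the nearest mean
#' (Euclidean distance; ties broken deterministically toward the lowest class
#' index). Accuracy is the average of per-class accuracies.
#'
#' With `folds = "balanced"` (the default for balanced designs) each fold holds
#' out one trial per class, so all classes train on equally many trials. This
#' keeps the estimator centered: with single-trial exclusion (`folds = "loo"`),
#' the held-out trial's own class trains on one fewer trial than the others,
#' which biases label-shuffled accuracy measurably below theoretical chance at
#' typical trial counts. `"loo"` is retained for unbalanced designs (and used
#' automatically when classes are unbalanced).
#'
#' @param x trials x features matrix.
#' @param y class labels (one per row); every class needs >= 2 trials.
#' @param folds `"balanced"` or `"loo"`.
#' @return list with `accuracy` (macro-averaged), `per_class` and `predicted`.
#' @export
euclidean_loo <- function(x, y, folds = c("balanced", "loo")) {
  folds <- match.arg(folds)
  y <- factor(y)
  lev <- levels(y)
  x <- as.matrix(x)
  nc <- table(y)
  if (any(nc < 2)) stopf("every class needs >= 2 trials for leave-one-out")
  if (folds == "balanced" && length(unique(nc)) > 1) folds <- "loo"
  s <- rowsum(x, y)                   # class sums, rows ordered by levels
  m <- s / as.vector(nc)
  pred <- character(nrow(x))
  if (folds == "loo") {
    d2 <- outer(rowSums(x^2), rep(1, length(lev))) - 2 * (x %*% t(m)) +
      matrix(rowSums(m^2), nrow(x), length(lev), byrow = TRUE)
    for (ci in seq_along(lev)) {      # replace own-class column by LOO mean
      idx <- which(y == lev[ci])
      mp <- (matrix(s[ci, ], length(idx), ncol(x), byrow = TRUE) -
               x[idx, , drop = FALSE]) / (nc[ci] - 1)
      d2[idx, ci] <- rowSums((x[idx, , drop = FALSE] - mp)^2)
    }
    pred <- lev[max.col(-d2, ties.method = "first")]
  } else {
    n_fold <- nc[1]
    fold_of <- integer(nrow(x))       # j-th trial of each class -> fold j
    for (ci in seq_along(lev)) fold_of[y == lev[ci]] <- seq_len(n_fold)
    for (j in seq_len(n_fold)) {
      te <- which(fold_of == j)
      mtr <- (s - x[te, , drop = FALSE][order(y[te]), , drop = FALSE]) /
        (as.vector(nc) - 1)
      d2 <- outer(rowSums(x[te, , drop = FALSE]^2), rep(1, length(lev))) -
        2 * (x[te, , drop = FALSE] %*% t(mtr)) +
        matrix(rowSums(mtr^2), length(te), length(lev), byrow = TRUE)
      pred[te] <- lev[max.col(-d2, ties.method = "first")]
    }
  }
  per_class <- vapply(lev, function(l) mean(pred[y == l] == l), numeric(1))
  list(accuracy = mean(per_class), per_class = per_class, predicted = pred)
}

# nearest-mean prediction of test rows given training data
nearest_mean_predict <- function(train_x, train_y, test_x) {
  train_y <- factor(train_y)
  lev <- levels(train_y)
  m <- rowsum(as.matrix(train_x), train_y) / as.vector(table(train_y))
  d2 <- outer(rowSums(test_x^2), rep(1, length(lev))) -
    2 * (test_x %*% t(m)) +
    matrix(rowSums(m^2), nrow(test_x), length(lev), byrow = TRUE)
  lev[max.col(-d2, ties.method = "first")]
}

# task accuracy on a feature matrix restricted to a cell subset (columns cols)
task_accuracy <- function(features, task, cols, panel, perm_labels = NULL) {
  x <- features$matrix[, cols, drop = FALSE]
  trials <- features$trials
  if (task == "odorant") {
    rows <- which(!trials$is_blank &
                    abs(trials$concentration - panel$nominal_concentration) < 1e-12)
    y <- trials$odorant[rows]
    if (!is.null(perm_labels)) y <- y[perm_labels$odorant]
    euclidean_loo(x[rows, , drop = FALSE], y)$accuracy
  } else if (task == "concentration") {
    acc <- vapply(panel$series_odorants, function(od) {
      rows <- which(trials$odorant == od)
      y <- factor(trials$concentration[rows])
      if (!is.null(perm_labels)) y <- y[perm_labels[[od]]]
      euclidean_loo(x[rows, , drop = FALSE], y)$accuracy
    }, numeric(1))
    mean(acc)
  } else if (task == "generalization") {
    rows <- which(!trials$is_blank)
    stim <- paste(trials$odorant[rows], signif(trials$concentration[rows], 6))
    if (!is.null(perm_labels)) stim <- stim[perm_labels$panel]
    odor_of <- trials$odorant[rows]
    names(odor_of) <- stim
    held <- panel$held_out
    acc <- numeric(nrow(held))
    for (h in seq_len(nrow(held))) {
      hs <- paste(held$odorant[h], signif(held$concentration[h], 6))
      te <- which(stim == hs)
      tr <- which(stim != hs)
      pred <- nearest_mean_predict(x[rows[tr], , drop = FALSE], stim[tr],
                                   x[rows[te], , drop = FALSE])
      pred_odor <- vapply(strsplit(pred, " "), `[[`, character(1), 1)
      acc[h] <- mean(pred_odor == strsplit(hs, " ")[[1]][1])
    }
    mean(acc)
  } else stopf("unknown task '%s'", task)
}

# label permutations for shuffled-control decoding; returns index permutations
# applied to the task's label vector(s)
draw_perm_labels <- function(features, task, panel) {
  trials <- features$trials
  if (task == "odorant") {
    rows <- which(!trials$is_blank &
                    abs(trials$concentration - panel$nominal_concentration) < 1e-12)
    list(odorant = sample.int(length(rows)))
  } else if (task == "concentration") {
    out <- lapply(panel$series_odorants, function(od)
      sample.int(sum(trials$odorant == od)))
    names(out) <- panel$series_odorants
    out
  } else {
    list(panel = sample.int(sum(!trials$is_blank)))
  }
}

#' Run a decoding task over pseudopopulations
#'
#' Draws `n_permutations` random pseudopopulations of each requested size
#' (cells sampled without replacement within a permutation), classifies
#' single-trial feature vectors with the Euclidean leave-one-out nearest-mean
#' decoder, and averages accuracy per size. Three tasks are supported:
#' `"odorant"` (6-way at the nominal concentration), `"concentration"` (4-way,
#' trained and tested separately for each concentration-series odorant, then
#' averaged) and `"generalization"` (train on 11 stimuli with one
#' concentration of one series odorant held out, score held-out trials as
#' correct when the predicted identity matches regardless of concentration;
#' averaged over all held-out stimuli; chance 3/11). With `shuffle = TRUE`,
#' trial labels are randomly reassigned in every permutation, giving the
#' empirical chance level.
#'
#' Cell draws depend only on `seed`, `sizes` and `n_permutations`, so results
#' for different encodings with the same seed are paired permutation-by-
#' permutation (see [compare_encodings()]).
#'
#' @param features an [encode_features()] result.
#' @param task `"odorant"`, `"concentration"` or `"generalization"`.
#' @param sizes pseudopopulation sizes (default: the full population).
#' @param n_permutations repetitions per size (default 200).
#' @param seed RNG seed for cell draws and shuffles.
#' @param shuffle shuffle trial labels (chance control).
#' @return object of class `decode_result`: list with `accuracy`
#'   (data.frame size, perm, accuracy), `summary` (per-size mean/sd/sem),
#'   `chance`, `task`, `scheme`, `seed`.
#' @export
run_task <- function(features, task = c("odorant", "concentration",
                                        "generalization"),
                     sizes = NULL, n_permutations = 200, seed = 1,
                     shuffle = FALSE) {
  task <- match.arg(task)
  panel <- generalization_panel(features$trials)
  n_cells <- length(features$cells)
  sizes <- sizes %||% n_cells
  if (any(sizes > n_cells)) stopf("population size exceeds available cells")
  draws <- with_seed(seed, {
    d <- lapply(sizes, function(sz)
      lapply(seq_len(n_permutations), function(i) sort(sample.int(n_cells, sz))))
    p <- if (shuffle)
      lapply(seq_len(length(sizes) * n_permutations), function(i)
        draw_perm_labels(features, task, panel))
    list(cells = d, perms = p)
  })
  rows <- vector("list", length(sizes) * n_permutations)
  k <- 0L
  for (si in seq_along(sizes)) {
    for (pi in seq_len(n_permutations)) {
      k <- k + 1L
      cols <- feature_cols(features, draws$cells[[si]][[pi]])
      pl <- if (shuffle) draws$perms[[k]] else NULL
      rows[[k]] <- data.frame(size = sizes[si], perm = pi,
                              accuracy = task_accuracy(features, task, cols,
                                                       panel, pl))
    }
  }
  acc <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(acc, acc$size), function(d)
    data.frame(size = d$size[1], mean_accuracy = mean(d$accuracy),
               sd = stats::sd(d$accuracy),
               sem = stats::sd(d$accuracy) / sqrt(nrow(d)))))
  rownames(summ) <- NULL
  chance <- switch(task,
                   odorant = 1 / length(unique(panel$stimuli$odorant)),
                   concentration = 1 / length(unique(
                     panel$stimuli$concentration[
                       panel$stimuli$odorant %in% panel$series_odorants])),
                   generalization = panel$chance_generalization)
  structure(list(task = task, scheme = features$scheme, accuracy = acc,
                 summary = summ, chance = chance, sizes = sizes,
                 n_permutations = n_permutations, seed = seed,
                 shuffled = shuffle),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> task=%s scheme=%s%s chance=%.3f\n", x$task,
              x$scheme, if (x$shuffled) " (label-shuffled)" else "", x$chance))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Paired comparison of two encodings
#'
#' Computes per-size paired accuracy differences (result_a minus result_b)
#' across permutations that used identical pseudopopulation draws (same seed,
#' sizes and permutation count), with the 2.5th-97.5th percentile band; a
#' difference is flagged significant when the band excludes zero.
#'
#' @param result_a,result_b [run_task()] results on the same dataset and task.
#' @return data.frame size, mean_diff, lo, hi, significant.
#' @export
compare_encodings <- function(result_a, result_b) {
  if (result_a$seed != result_b$seed ||
      !identical(result_a$sizes, result_b$sizes) ||
      result_a$n_permutations != result_b$n_permutations ||
      result_a$task != result_b$task)
    stopf("results are not paired (seed, sizes, permutations and task must match)")
  d <- merge(result_a$accuracy, result_b$accuracy, by = c("size", "perm"))
  d$diff <- d$accuracy.x - d$accuracy.y
  out <- do.call(rbind, lapply(split(d, d$size), function(g)
    data.frame(size = g$size[1], mean_diff = mean(g$diff),
               lo = unname(stats::quantile(g$diff, 0.025)),
               hi = unname(stats::quantile(g$diff, 0.975)))))
  out$significant <- out$lo > 0 | out$hi < 0
  rownames(out) <- NULL
  out
}

#' Linear-SVM cross-validated accuracy (robustness check)
#'
#' Same fold structure as [euclidean_loo()] but with a linear-kernel support
#' vector machine (one-vs-one multiclass) in place of the nearest-mean rule.
#' Requires the `e1071` package.
#'
#' @inheritParams euclidean_loo
#' @param cost SVM cost parameter.
#' @return list with `accuracy` (macro-averaged) and `predicted`.
#' @export
svm_loo <- function(x, y, folds = c("balanced", "loo"), cost = 1) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stopf("svm_loo requires the e1071 package")
  folds <- match.arg(folds)
  y <- factor(y)
  lev <- levels(y)
  x <- as.matrix(x)
  nc <- table(y)
  if (folds == "balanced" && length(unique(nc)) > 1) folds <- "loo"
  fold_of <- if (folds == "loo") seq_len(nrow(x)) else {
    fo <- integer(nrow(x))
    for (ci in seq_along(lev)) fo[y == lev[ci]] <- seq_len(nc[ci])
    fo
  }
  keep <- which(apply(x, 2, stats::var) > 0)   # svm scaling needs variance
  pred <- character(nrow(x))
  for (f in unique(fold_of)) {
    te <- which(fold_of == f)
    tr <- setdiff(seq_len(nrow(x)), te)
    fit <- e1071::svm(x[tr, keep, drop = FALSE], y[tr], kernel = "linear",
                      cost = cost)
    pred[te] <- as.character(stats::predict(fit, x[te, keep, drop = FALSE]))
  }
  per_class <- vapply(lev, function(l) mean(pred[y == l] == l), numeric(1))
  list(accuracy = mean(per_class), per_class = per_class, predicted = pred)
}

#' Temporal evolution of decoding accuracy
#'
#' Decodes from pseudopopulation vectors assembled from all cells using either
#' an expanding window of increasing numbers of 30 ms bins (`"expanding"`) or a
#' single 30 ms window stepped through the response (`"sliding"`).
#'
#' @param binned a [binned_count_array()] over the full response window.
#' @param task decoding task, as in [run_task()].
#' @param mode `"expanding"` or `"sliding"`.
#' @return data.frame with bin index, window start/end (s) and accuracy.
#' @export
temporal_decoding <- function(binned, task = c("odorant", "concentration",
                                               "generalization"),
                              mode = c("expanding", "sliding")) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  features <- encode_features(binned, "binned")
  panel <- generalization_panel(features$trials)
  nb <- dim(binned)[3]
  bw <- attr(binned, "bin_width")
  w0 <- attr(binned, "window")[1]
  ncell <- length(features$cells)
  # feature columns are laid out bin-fastest within cell
  bin_of_col <- rep(seq_len(nb), times = ncell)
  out <- lapply(seq_len(nb), function(k) {
    cols <- if (mode == "expanding") which(bin_of_col <= k)
            else which(bin_of_col == k)
    data.frame(bin = k,
               t_start = w0 + if (mode == "expanding") 0 else (k - 1) * bw,
               t_end = w0 + k * bw,
               accuracy = task_accuracy(features, task, cols, panel))
  })
  do.call(rbind, out)
}

#' Onset time at which decoding accuracy rises above chance
#'
#' Operational onset used for latency comparisons between tasks: the earliest
#' window end time from which accuracy exceeds `chance + margin` and stays
#' above it for all later windows.
#'
#' @param temporal a [temporal_decoding()] result.
#' @param chance task chance level.
#' @param margin required exceedance (accuracy units).
#' @return onset time (s), or NA when never reached.
#' @export
decoding_onset <- function(temporal, chance, margin = 0.05) {
  above <- temporal$accuracy > chance + margin
  sustained <- rev(cumprod(rev(above))) == 1
  if (!any(sustained)) return(NA_real_)
  temporal$t_end[which(sustained)[1]]
}
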