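# Shared fixtures, built once per test run and memoized across test files.
# Problem sizes: the "default" fixture uses the full study conditions
# (459 PCx / 126 OB cells, 12-stimulus panel + blank, 10 trials each); the
# "small" fixture trades population size for speed in unit tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fx_default_config <- function() fixture("default_config", function() {
  synth_config(seed = 1)
})

fx_default_dataset <- function() fixture("default_dataset", function() {
  generate_dataset(fx_default_config())
})

fx_default_stats <- function() fixture("default_stats", function() {
  compute_response_stats(fx_default_dataset())
})

fx_default_binned <- function() fixture("default_binned", function() {
  binned_count_array(fx_default_dataset(), region = "PCx")
})

fx_null_dataset <- function() fixture("null_dataset", function() {
  cfg <- synth_config(frac_activated = 0, frac_suppressed = 0, frac_mixed = 0,
                      n_cells_ob = 0, seed = 2)
  generate_dataset(cfg)
})

fx_null_stats <- function() fixture("null_stats", function() {
  compute_response_stats(fx_null_dataset())
})

fx_small_config <- function() fixture("small_config", function() {
  synth_config(n_cells_pcx = 120, n_cells_ob = 40, n_populations_pcx = 3,
               n_populations_ob = 2, seed = 7)
})

fx_small_dataset <- function() fixture("small_dataset", function() {
  generate_dataset(fx_small_config())
})

# brute-force cross-validated nearest-mean classifier, deliberately naive:
# the independent oracle for euclidean_loo
brute_force_cv <- function(x, y, folds = "balanced") {
  y <- factor(y)
  lev <- levels(y)
  n <- nrow(x)
  fold_of <- integer(n)
  if (folds == "balanced") {
    for (l in lev) fold_of[y == l] <- seq_len(sum(y == l))
  } else {
    fold_of <- seq_len(n)
  }
  pred <- character(n)
  for (f in unique(fold_of)) {
    test_idx <- which(fold_of == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    for (i in test_idx) {
      d <- sapply(lev, function(l) {
        tr <- train_idx[y[train_idx] == l]
        mu <- colMeans(x[tr, , drop = FALSE])
        sqrt(sum((x[i, ] - mu)^2))
      })
      pred[i] <- lev[which.min(d)]
    }
  }
  mean(sapply(lev, function(l) mean(pred[y == l] == l)))
}

# exhaustive pair-counting auROC (ties count 1/2): oracle for response_index
brute_force_auroc <- function(odor, blank) {
  tot <- 0
  for (a in odor) for (b in blank)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(odor) * length(blank))
}
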