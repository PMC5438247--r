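# Population response vectors and trial-by-trial correlation structure.

#' Build population spike-count vectors
#'
#' One vector per trial: per-cell spike counts over the per-trial first full
#' respiration cycle (or a fixed window).
#'
#' @inheritParams spike_count_matrix
#' @return list with `counts` (trials x cells matrix) and `trials`.
#' @export
build_vectors <- function(dataset, window = "sniff", region = NULL,
                          cells = NULL) {
  counts <- spike_count_matrix(dataset, window, region, cells)
  list(counts = counts, trials = attr(counts, "trials"))
}

#' Trial-pair population-vector correlations by stimulus condition
#'
#' Computes the correlation (Spearman rank by default, to accommodate the
#' non-normal spike-count distribution; Pearson optional) between every pair of
#' trial population vectors and averages them by condition: same stimulus
#' (distinct trial pairs only), same odorant at increasing log10-concentration
#' differences, and different odorants. Zero-variance vectors are skipped with
#' a message.
#'
#' @param vectors a [build_vectors()] result.
#' @param method `"spearman"` or `"pearson"`.
#' @param include_blank include blank trials (default FALSE).
#' @return data.frame condition, delta_log10_conc, mean_rho, n_pairs.
#' @export
correlation_by_condition <- function(vectors, method = c("spearman", "pearson"),
                                     include_blank = FALSE) {
  method <- match.arg(method)
  trials <- vectors$trials
  keep <- if (include_blank) rep(TRUE, nrow(trials)) else !trials$is_blank
  m <- vectors$counts[keep, , drop = FALSE]
  trials <- trials[keep, ]
  zv <- apply(m, 1, function(v) stats::var(v) == 0)
  if (any(zv)) {
    message(sum(zv), " zero-variance trial vector(s) skipped")
    m <- m[!zv, , drop = FALSE]
    trials <- trials[!zv, ]
  }
  rho <- stats::cor(t(m), method = method)
  n <- nrow(trials)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  same_od <- trials$odorant[i] == trials$odorant[j]
  dlc <- abs(log10(trials$concentration[i]) - log10(trials$concentration[j]))
  dlc_half <- round(dlc * 2) / 2   # stimulus design uses 0.5 log10 steps
  cond <- ifelse(!same_od, "different_odorant",
          ifelse(dlc_half == 0, "same_stimulus",
                 sprintf("same_odorant_dlog%.1f", dlc_half)))
  r <- rho[ut]
  agg <- aggregate(list(mean_rho = r), list(condition = cond), mean)
  agg$n_pairs <- as.integer(table(cond)[agg$condition])
  agg$delta_log10_conc <- NA_real_
  agg$delta_log10_conc[agg$condition == "same_stimulus"] <- 0
  is_step <- grepl("^same_odorant_dlog", agg$condition)
  agg$delta_log10_conc[is_step] <-
    as.numeric(sub("same_odorant_dlog", "", agg$condition[is_step]))
  o <- order(is.na(agg$delta_log10_conc), agg$delta_log10_conc)
  agg[o, c("condition", "delta_log10_conc", "mean_rho", "n_pairs")]
}
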