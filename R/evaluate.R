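#' Rank-based AUC
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half — the Mann-Whitney form of the
#' area under the ROC curve.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, same length.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Threshold classification metrics
#'
#' Precision, recall, F1 and specificity at a score threshold. A metric
#' with a zero denominator (e.g. precision with no predicted positives) is
#' returned as `NA` with a warning, never as 0, and callers drop such
#' values from run averages.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @param threshold decision threshold (default 0.5; score >= threshold is
#'   a predicted positive).
#' @return named list: `precision`, `recall`, `f1`, `specificity`, plus the
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  pred <- scores >= threshold
  labels <- as.integer(labels)
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  specificity <- safe_div(tn, tn + fp, "specificity")
  list(precision = precision, recall = recall, f1 = f1,
       specificity = specificity, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Build a 2x2 prediction-vs-reference contingency table
#'
#' Counts the scored candidate universe against an external reference
#' association list (e.g. a pharmacovigilance system). The reference is
#' intersected with the universe first: pairs never scored cannot be
#' counted either way. Layout: `x` predicted & in reference, `y` predicted
#' & not, `z` not predicted & in reference, `w` neither.
#'
#' @param predicted an [association_table()] (or data.frame with
#'   drug/side_effect) of predicted-positive pairs.
#' @param reference external reference associations.
#' @param universe all scored pairs (data.frame with drug/side_effect).
#' @return object of class `contingency_table` with integer fields
#'   `x`, `y`, `z`, `w`, `n`.
#' @export
build_contingency <- function(predicted, reference, universe) {
  key <- function(df) paste(df$drug, df$side_effect, sep = "\r")
  uk <- unique(key(universe))
  pk <- intersect(unique(key(predicted)), uk)
  rk <- intersect(unique(key(reference)), uk)
  x <- length(intersect(pk, rk))
  y <- length(setdiff(pk, rk))
  z <- length(setdiff(rk, pk))
  w <- length(uk) - x - y - z
  contingency_table(x, y, z, w)
}

#' Construct a contingency table from counts
#'
#' @param x,y,z,w non-negative integer cell counts: predicted∧reference,
#'   predicted only, reference only, neither.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(x, y, z, w) {
  cells <- c(x = x, y = y, z = z, w = w)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  n <- sum(cells)
  if (n == 0) stop("contingency table is empty")
  structure(list(x = x, y = y, z = z, w = w, n = n),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$x, x$z, x$y, x$w), 2,
              dimnames = list(predicted = c("true", "false"),
                              reference = c("true", "false")))
  print(m)
  invisible(x)
}

# log point probability of each table with the observed margins, indexed by
# the top-left cell k over its support; log-gamma arithmetic so n ~ 1e5 is
# exact to double precision.
hyper_log_support <- function(t) {
  m1 <- t$x + t$y   # predicted-positive row total
  c1 <- t$x + t$z   # reference-positive column total
  n <- t$n
  lo <- max(0L, c1 - (n - m1))
  hi <- min(c1, m1)
  k <- lo:hi
  logp <- lchoose(m1, k) + lchoose(n - m1, c1 - k) - lchoose(n, c1)
  list(k = k, logp = logp)
}

#' Hypergeometric point probabilities over a table's support
#'
#' All tables sharing the observed margins, indexed by the top-left cell;
#' the probabilities sum to 1 by construction (a normalization check used
#' in the test suite).
#'
#' @param t a [contingency_table()].
#' @return data.frame with columns `k` and `prob`.
#' @export
contingency_support_probs <- function(t) {
  s <- hyper_log_support(t)
  data.frame(k = s$k, prob = exp(s$logp))
}

# conditional MLE of the odds ratio: solve E_psi[K] = x for the noncentral
# hypergeometric parameter psi, as stats::fisher.test does.
cmle_odds_ratio <- function(t) {
  s <- hyper_log_support(t)
  if (length(s$k) == 1L) return(NA_real_)
  x <- t$x
  mean_k <- function(log_psi) {
    lw <- s$logp + s$k * log_psi
    lw <- lw - max(lw)
    w <- exp(lw)
    sum(s$k * w) / sum(w)
  }
  if (x <= min(s$k)) return(0)
  if (x >= max(s$k)) return(Inf)
  root <- stats::uniroot(function(lp) mean_k(lp) - x,
                         lower = -50, upper = 50, tol = 1e-12)$root
  exp(root)
}

#' Fisher's exact test on a 2x2 table
#'
#' The point probability of the observed table is the hypergeometric mass
#' given its margins, computed with log-gamma arithmetic; the two-sided p
#' is the sum of the probabilities of all tables with the same margins
#' whose point probability does not exceed the observed one
#' (minimum-likelihood rule, the convention of standard statistical
#' software). The headline odds ratio is the conditional maximum-likelihood
#' estimate; the sample odds ratio xw/yz is reported alongside.
#'
#' @param t a [contingency_table()].
#' @return list: `p_value` (two-sided), `odds_ratio` (conditional MLE),
#'   `sample_odds_ratio`, `point_prob`.
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if ((t$x + t$y) == 0 || (t$z + t$w) == 0 || (t$x + t$z) == 0 || (t$y + t$w) == 0) {
    return(list(p_value = 1, odds_ratio = NA_real_,
                sample_odds_ratio = NA_real_, point_prob = 1))
  }
  s <- hyper_log_support(t)
  obs <- s$logp[match(t$x, s$k)]
  # relative tolerance guards against ties broken by rounding, as in
  # standard implementations
  p <- sum(exp(s$logp[s$logp <= obs + 1e-7]))
  p <- min(1, p)
  sample_or <- (t$x * t$w) / (t$y * t$z)
  list(p_value = p, odds_ratio = cmle_odds_ratio(t),
       sample_odds_ratio = sample_or, point_prob = exp(obs))
}

#' Enrichment report for a prediction-vs-reference comparison
#'
#' Builds the contingency table and runs [fisher_exact()], returning both.
#'
#' @inheritParams build_contingency
#' @return list: `table` (contingency_table), `test` (fisher_exact result).
#' @export
enrichment_test <- function(predicted, reference, universe) {
  t <- build_contingency(predicted, reference, universe)
  list(table = t, test = fisher_exact(t))
}

#' Average per-run metrics into a report
#'
#' Arithmetic mean of each metric over runs; `NA` (undefined) values are
#' dropped with their count reported.
#'
#' @param per_run data.frame with columns `run_id`, `model`, `subset`,
#'   `metric`, `value` (long format).
#' @return data.frame with columns `model`, `subset`, `metric`, `mean`,
#'   `n_runs`, `n_dropped`.
#' @export
average_metrics <- function(per_run) {
  keys <- unique(per_run[, c("model", "subset", "metric")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- per_run$model == keys$model[i] & per_run$subset == keys$subset[i] &
      per_run$metric == keys$metric[i]
    v <- per_run$value[sel]
    data.frame(keys[i, ], mean = mean(v, na.rm = TRUE),
               n_runs = sum(!is.na(v)), n_dropped = sum(is.na(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
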