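#' Rank percentile
#'
#' The percentage of genes ranking worse than the target:
#' `100 * (N - rank) / N`. A rank of 1 out of 6681 gives 99.99; the worst
#' rank N gives 0. This direction makes a strong (low-numbered) rank a high
#' percentile, matching how single-gene results are reported.
#'
#' @param rank gene rank(s), real values in `[1, N]` (averaged replicate
#'   ranks may be non-integer).
#' @param N total number of ranked genes.
#' @return Percentile(s) in `[0, 100)`.
#' @seealso [format_rank_percentile()] for the display convention.
#' @export
#' @examples
#' rank_percentile(2080, 6681)   # 68.87
#' format_rank_percentile(2080, 6681)  # "69"
#' format_rank_percentile(20, 6681)    # "99.7"
rank_percentile <- function(rank, N) {
  check_scalar_number(N, "N")
  if (!is.numeric(rank) || any(!is.finite(rank)))
    stopf("'rank' must be finite numeric")
  if (any(rank < 1 | rank > N))
    stopf("rank(s) outside [1, %d]: %s", N,
          paste(rank[rank < 1 | rank > N], collapse = ", "))
  100 * (N - rank) / N
}

#' Display-rounded rank percentile
#'
#' Rounds the percentile to the nearest integer (half away from zero),
#' except that when integer rounding would print 100 for a rank worse than 1
#' the value is kept at one decimal place (so a rank of 20 out of 6681 prints
#' 99.7, not 100).
#'
#' @inheritParams rank_percentile
#' @return Character vector of display values.
#' @export
format_rank_percentile <- function(rank, N) {
  pct <- rank_percentile(rank, N)
  out <- character(length(pct))
  for (i in seq_along(pct)) {
    r <- round_half_up(pct[i])
    if (r == 100 && rank[i] > 1) {
      out[i] <- sprintf("%.1f", round_half_up(pct[i], 1))
    } else {
      out[i] <- sprintf("%d", as.integer(r))
    }
  }
  out
}

#' Gene-set ROC curve and AUC%
#'
#' Sweeps the rank threshold t from 0 to p; at each threshold the
#' true-positive rate is the fraction of set members with rank <= t and the
#' false-positive rate the fraction of non-members with rank <= t. The area
#' under the (FPR, TPR) curve is computed by the trapezoid rule and reported
#' as a percentage; 50% is the random-guess expectation.
#'
#' @param ranking a `gene_ranking`.
#' @param set a [gene_set()]; must be a proper nonempty subset of the ranked
#'   genes.
#' @return A list of class `roc_curve`: `thresholds` (0..p), `tpr`, `fpr`,
#'   `auc_percent`.
#' @export
gene_set_roc <- function(ranking, set) {
  stopifnot(inherits(ranking, "gene_ranking"), inherits(set, "gene_set"))
  genes <- ranking$genes
  p <- length(genes)
  unknown <- setdiff(set$members, genes)
  if (length(unknown))
    stopf("gene set member(s) not in the ranking: %s",
          paste(unknown, collapse = ", "))
  s <- length(set$members)
  if (s == 0L || s >= p)
    stopf("gene set must be a proper nonempty subset of the %d ranked genes", p)
  member <- genes %in% set$members
  member_by_rank <- member[order(ranking$rank)]
  tpr <- c(0, cumsum(member_by_rank)) / s
  fpr <- c(0, cumsum(!member_by_rank)) / (p - s)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  structure(list(thresholds = 0:p, tpr = tpr, fpr = fpr,
                 auc_percent = 100 * auc, set_name = set$name),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve for gene set '%s': AUC = %.1f%%\n",
              x$set_name, x$auc_percent))
  invisible(x)
}

#' Average AUC% over replicate ROC curves
#'
#' @param curves list of `roc_curve` objects (or bare AUC% numbers).
#' @return The arithmetic mean AUC%.
#' @export
average_auc <- function(curves) {
  if (!length(curves)) stopf("at least one ROC curve is required")
  vals <- vapply(curves, function(cv) {
    if (inherits(cv, "roc_curve")) cv$auc_percent
    else if (is.numeric(cv) && length(cv) == 1L) as.numeric(cv)
    else stopf("elements must be roc_curve objects or AUC%% numbers")
  }, numeric(1L))
  mean(vals)
}

#' Rank change under training-compendium modification
#'
#' `RC = rank_original - rank_modified`: positive when the gene's rank
#' improved (decreased) after the modification, zero for no change, negative
#' when it worsened.
#'
#' @param rank_original,rank_modified ranks from the original and modified
#'   training compendium (vectors allowed, recycled pairwise).
#' @return Numeric RC value(s).
#' @export
rank_change <- function(rank_original, rank_modified) {
  if (any(!is.finite(rank_original)) || any(!is.finite(rank_modified)))
    stopf("ranks must be finite")
  rank_original - rank_modified
}

#' RC percentile
#'
#' Compares a target gene's rank change against the genome-wide RC vector of
#' the same experiment: the percentage of RCs strictly below the target's,
#' reported only when the target RC is positive (an improvement). For
#' RC <= 0 the percentile is undefined and displayed "n/a".
#'
#' @param rc_target the target gene's RC.
#' @param all_rcs numeric vector of RCs for all genes in the experiment.
#' @return Percentile in `[0, 100)`, or `NA` when `rc_target <= 0`.
#' @seealso [format_rc_percentile()]
#' @export
rc_percentile <- function(rc_target, all_rcs) {
  check_scalar_number(rc_target, "rc_target")
  if (!length(all_rcs)) stopf("'all_rcs' must be a nonempty RC vector")
  if (any(!is.finite(all_rcs))) stopf("'all_rcs' must be finite")
  if (rc_target <= 0) return(NA_real_)
  100 * sum(all_rcs < rc_target) / length(all_rcs)
}

#' @rdname rc_percentile
#' @export
format_rc_percentile <- function(rc_target, all_rcs) {
  pct <- rc_percentile(rc_target, all_rcs)
  if (is.na(pct)) "n/a" else sprintf("%d", as.integer(round_half_up(pct)))
}
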