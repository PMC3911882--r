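new_gene_ranking <- function(genes, residual, abs_residual, rank) {
  structure(list(genes = as.character(genes),
                 residual = as.numeric(residual),
                 abs_residual = as.numeric(abs_residual),
                 rank = as.numeric(rank)),
            class = "gene_ranking")
}

#' Compute perturbation residuals for a test experiment
#'
#' The testing phase: the test expression vector is centered with the
#' training means and adjusted for all inferred gene-gene interactions,
#' `r = y_tilde - B_hat %*% y_tilde`. What the trained network cannot explain
#' — the external perturbation plus noise — remains in the residual.
#'
#' @param net an `interaction_network` from [fit_network()].
#' @param y_pert named numeric vector of expression values over the
#'   network's gene universe (a single test experiment), or a one-column
#'   `expr_compendium`.
#' @return A list of class `residual_profile`: `genes`, `y_pert`,
#'   `residuals`.
#' @export
compute_residuals <- function(net, y_pert) {
  stopifnot(inherits(net, "interaction_network"))
  if (inherits(y_pert, "expr_compendium")) {
    if (n_samples(y_pert) != 1L)
      stopf("'y_pert' compendium must contain exactly one sample (got %d)",
            n_samples(y_pert))
    y_pert <- y_pert$values[, 1L]
  }
  if (is.null(names(y_pert)))
    stopf("'y_pert' must be named by gene identifier")
  missing <- setdiff(net$genes, names(y_pert))
  surplus <- setdiff(names(y_pert), net$genes)
  if (length(missing) || length(surplus))
    stopf("gene universe mismatch: %s",
          paste(c(if (length(missing)) sprintf("missing: %s", paste(missing, collapse = ", ")),
                  if (length(surplus)) sprintf("unknown: %s", paste(surplus, collapse = ", "))),
                collapse = "; "))
  y <- y_pert[net$genes]
  if (any(!is.finite(y))) stopf("'y_pert' contains non-finite values")
  ytilde <- y - net$train_means
  r <- as.numeric(ytilde - net$B_hat %*% ytilde)
  structure(list(genes = net$genes, y_pert = as.numeric(y),
                 residuals = setNames(r, net$genes)),
            class = "residual_profile")
}

#' Rank genes by absolute residual
#'
#' Rank 1 is assigned to the largest |residual| — the strongest candidate
#' target. Ties are broken by gene order in the compendium (stable), and
#' ranks are a permutation of 1..p.
#'
#' @param profile a `residual_profile` from [compute_residuals()].
#' @return A `gene_ranking`: `genes`, `residual`, `abs_residual`, `rank`.
#' @export
rank_genes <- function(profile) {
  stopifnot(inherits(profile, "residual_profile"))
  a <- abs(profile$residuals)
  ord <- order(-a)                       # stable for ties: gene order wins
  rnk <- integer(length(a))
  rnk[ord] <- seq_along(a)
  new_gene_ranking(profile$genes, profile$residuals, a, rnk)
}

#' @export
print.gene_ranking <- function(x, n = 6L, ...) {
  p <- length(x$genes)
  cat(sprintf("Gene ranking over %d genes; top %d:\n", p, min(n, p)))
  top <- order(x$rank)[seq_len(min(n, p))]
  print(data.frame(gene = x$genes[top], rank = x$rank[top],
                   abs_residual = signif(x$abs_residual[top], 4)),
        row.names = FALSE)
  invisible(x)
}

#' Average gene ranks across replicate experiments
#'
#' Replicate experiments are combined by averaging each gene's rank (the
#' ranks themselves, not the residuals). The exact mean is returned together
#' with a display value rounded half-up to integer.
#'
#' @param rankings list of `gene_ranking` objects over identical gene
#'   universes.
#' @return A data.frame with columns `gene`, `mean_rank` (exact) and
#'   `display_rank` (rounded half-up).
#' @export
average_rankings <- function(rankings) {
  if (!length(rankings)) stopf("at least one ranking is required")
  lapply(rankings, function(r) stopifnot(inherits(r, "gene_ranking")))
  genes <- rankings[[1L]]$genes
  for (r in rankings[-1L]) {
    if (!identical(r$genes, genes))
      stopf("rankings cover different gene universes")
  }
  ranks <- vapply(rankings, function(r) r$rank, numeric(length(genes)))
  mean_rank <- if (is.matrix(ranks)) rowMeans(ranks) else ranks
  data.frame(gene = genes, mean_rank = mean_rank,
             display_rank = round_half_up(mean_rank),
             stringsAsFactors = FALSE)
}

#' z-score baseline ranking
#'
#' The comparison method: genes are ranked by the absolute z-score of the
#' test value against the training compendium, `|(y - mean) / sd|`, with no
#' network adjustment. Genes with zero training standard deviation get score
#' zero (with a warning).
#'
#' @param train training [expression_compendium()].
#' @param y_pert named numeric vector over the compendium's gene universe, or
#'   a one-column `expr_compendium`.
#' @return A `gene_ranking` whose `residual`/`abs_residual` hold the signed
#'   and absolute z-scores.
#' @export
zscore_ranking <- function(train, y_pert) {
  stopifnot(inherits(train, "expr_compendium"))
  if (inherits(y_pert, "expr_compendium")) {
    if (n_samples(y_pert) != 1L)
      stopf("'y_pert' compendium must contain exactly one sample")
    y_pert <- y_pert$values[, 1L]
  }
  genes <- compendium_genes(train)
  if (is.null(names(y_pert))) stopf("'y_pert' must be named by gene identifier")
  missing <- setdiff(genes, names(y_pert))
  surplus <- setdiff(names(y_pert), genes)
  if (length(missing) || length(surplus))
    stopf("gene universe mismatch: %s",
          paste(c(if (length(missing)) sprintf("missing: %s", paste(missing, collapse = ", ")),
                  if (length(surplus)) sprintf("unknown: %s", paste(surplus, collapse = ", "))),
                collapse = "; "))
  y <- y_pert[genes]
  mu <- rowMeans(train$values)
  s <- apply(train$values, 1L, sd)
  z <- numeric(length(genes))
  ok <- s > 0
  if (any(!ok))
    warning(sprintf("%d gene(s) with zero training SD scored 0", sum(!ok)),
            call. = FALSE)
  z[ok] <- (y[ok] - mu[ok]) / s[ok]
  a <- abs(z)
  ord <- order(-a)
  rnk <- integer(length(a))
  rnk[ord] <- seq_along(a)
  new_gene_ranking(genes, z, a, rnk)
}
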