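#' Lasso configuration for network training
#'
#' Each row of the interaction matrix is estimated by an L1-penalized
#' regression of one gene on all others, minimizing
#' `(1/2n) ||y_k - sum_{j != k} B_kj y_j||^2 + lambda * sum |B_kj|`
#' with no intercept (genes are centered first). The `1/2n` objective scaling
#' makes `lambda` comparable across training-set sizes.
#'
#' @param penalty_mode `"cv"` chooses `lambda` per row by K-fold
#'   cross-validation; `"fixed"` uses `fixed_lambda` for every row.
#' @param cv_folds number of CV folds (>= 2).
#' @param cv_rule `"1se"` (default) picks the largest `lambda` whose mean
#'   validation MSE is within one standard error of the minimum — the sparser,
#'   noise-robust choice; `"min"` picks the MSE-minimizing `lambda`.
#' @param fixed_lambda penalty value when `penalty_mode = "fixed"` (> 0).
#' @param standardize standardize predictors internally during fitting;
#'   coefficients are always reported on the centered, unstandardized scale.
#' @param max_iter,tol solver iteration cap and convergence threshold.
#' @param seed integer seed controlling CV fold assignment.
#' @return A list of class `lasso_config`.
#' @export
lasso_config <- function(penalty_mode = c("cv", "fixed"), cv_folds = 5,
                         cv_rule = c("1se", "min"), fixed_lambda = NULL,
                         standardize = TRUE, max_iter = 1e5, tol = 1e-9,
                         seed = 1) {
  penalty_mode <- match.arg(penalty_mode)
  cv_rule <- match.arg(cv_rule)
  if (penalty_mode == "fixed") {
    if (is.null(fixed_lambda) || !is.numeric(fixed_lambda) ||
        length(fixed_lambda) != 1L || !is.finite(fixed_lambda) ||
        fixed_lambda <= 0)
      stopf("'fixed_lambda' must be a single positive number when penalty_mode = \"fixed\"")
  } else {
    if (!is.null(fixed_lambda))
      stopf("'fixed_lambda' is only used when penalty_mode = \"fixed\"")
    check_scalar_number(cv_folds, "cv_folds")
    if (cv_folds < 2) stopf("'cv_folds' must be at least 2")
  }
  structure(list(penalty_mode = penalty_mode,
                 cv_folds = as.integer(cv_folds),
                 cv_rule = cv_rule,
                 fixed_lambda = fixed_lambda,
                 standardize = isTRUE(standardize),
                 max_iter = max_iter, tol = tol,
                 seed = check_seed(seed)),
            class = "lasso_config")
}

#' Fit one row of the interaction matrix
#'
#' Regresses the (centered) expression of gene `k` on all other genes by
#' Lasso. The returned coefficient vector has length p with the k-th entry
#' forced to exactly zero — a gene never explains itself.
#'
#' @param k 1-based gene index of the response.
#' @param Y_centered p x n matrix of expression values with per-gene mean
#'   zero across samples.
#' @param config a [lasso_config()].
#' @return Numeric length-p coefficient vector, names taken from the rows of
#'   `Y_centered`; attribute `lambda` carries the penalty used.
#' @export
fit_row <- function(k, Y_centered, config = lasso_config()) {
  stopifnot(inherits(config, "lasso_config"))
  p <- nrow(Y_centered); n <- ncol(Y_centered)
  if (k < 1 || k > p) stopf("row index %d outside 1..%d", k, p)
  beta <- setNames(numeric(p), rownames(Y_centered))
  y <- Y_centered[k, ]
  if (sd(y) == 0) {
    warning(sprintf("response gene %d has zero variance; returning an all-zero row", k),
            call. = FALSE)
    attr(beta, "lambda") <- NA_real_
    return(beta)
  }
  X <- t(Y_centered[-k, , drop = FALSE])
  if (config$penalty_mode == "cv") {
    if (n < config$cv_folds)
      stopf("n = %d samples is fewer than cv_folds = %d", n, config$cv_folds)
    foldid <- withr::with_seed(config$seed + k,
                               sample(rep_len(seq_len(config$cv_folds), n)))
    fit <- glmnet::cv.glmnet(X, y, foldid = foldid, intercept = FALSE,
                             standardize = config$standardize,
                             maxit = config$max_iter, thresh = config$tol)
    s_rule <- if (config$cv_rule == "min") "lambda.min" else "lambda.1se"
    lam <- if (config$cv_rule == "min") fit$lambda.min else fit$lambda.1se
    co <- as.numeric(coef(fit, s = s_rule))[-1L]
  } else {
    lam <- config$fixed_lambda
    fit <- glmnet::glmnet(X, y, intercept = FALSE,
                          standardize = config$standardize,
                          maxit = config$max_iter, thresh = config$tol)
    co <- as.numeric(coef(fit, s = lam, exact = TRUE, x = X, y = y,
                          intercept = FALSE,
                          standardize = config$standardize,
                          maxit = config$max_iter,
                          thresh = config$tol))[-1L]
  }
  beta[-k] <- co
  attr(beta, "lambda") <- lam
  beta
}

#' Train the gene-gene interaction network
#'
#' The training phase: with the perturbation term set to zero, every gene is
#' modelled as a sparse linear combination of all other genes and the
#' resulting coefficient rows are assembled into the estimated interaction
#' matrix. Per-gene training means are stored for test-time centering.
#'
#' @param train an [expression_compendium()] of unperturbed training samples.
#' @param config a [lasso_config()].
#' @param verbose log per-row progress to stderr.
#' @return A list of class `interaction_network`: `genes`, `B_hat`
#'   (p x p matrix, zero diagonal), `train_means` (named vector),
#'   `lasso_report` (data.frame of per-row lambda and nonzero count).
#' @export
fit_network <- function(train, config = lasso_config(), verbose = FALSE) {
  stopifnot(inherits(train, "expr_compendium"), inherits(config, "lasso_config"))
  p <- n_genes(train); n <- n_samples(train)
  min_n <- max(if (config$penalty_mode == "cv") config$cv_folds else 0L, 3L)
  if (n < min_n) stopf("training requires at least %d samples, got %d", min_n, n)
  genes <- compendium_genes(train)
  train_means <- rowMeans(train$values)
  Yc <- train$values - train_means
  B_hat <- matrix(0, p, p, dimnames = list(genes, genes))
  lambdas <- numeric(p); nnz <- integer(p)
  for (k in seq_len(p)) {
    row_k <- tryCatch(
      withCallingHandlers(
        fit_row(k, Yc, config),
        warning = function(w) {
          warning(sprintf("gene '%s': %s", genes[k], conditionMessage(w)),
                  call. = FALSE)
          invokeRestart("muffleWarning")
        }),
      error = function(e) stopf("fitting row for gene '%s' failed: %s",
                                genes[k], conditionMessage(e)))
    B_hat[k, ] <- row_k
    lambdas[k] <- attr(row_k, "lambda")
    nnz[k] <- sum(row_k != 0)
    if (verbose) message(sprintf("fit gene %d/%d (%s): lambda=%.4g, %d nonzero",
                                 k, p, genes[k], lambdas[k], nnz[k]))
  }
  structure(list(genes = genes, B_hat = B_hat, train_means = train_means,
                 lasso_report = data.frame(gene = genes, lambda = lambdas,
                                           nonzero = nnz,
                                           stringsAsFactors = FALSE)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  p <- length(x$genes)
  nz <- sum(x$B_hat != 0)
  cat(sprintf("Interaction network: %d genes, %d nonzero coefficients (%.2f%% of off-diagonal)\n",
              p, nz, 100 * nz / (p * (p - 1))))
  invisible(x)
}

#' Serialize / load a trained network
#'
#' The network is written as a sparse edge-list TSV
#' (`target_gene`, `source_gene`, `coefficient`) plus a per-gene means TSV,
#' both plain text.
#'
#' @param net an `interaction_network`.
#' @param dir directory to write into (created if needed).
#' @return `dir` (write) or an `interaction_network` (read), invisibly.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "interaction_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- which(net$B_hat != 0, arr.ind = TRUE)
  edges <- data.frame(target_gene = net$genes[nz[, "row"]],
                      source_gene = net$genes[nz[, "col"]],
                      coefficient = net$B_hat[nz], stringsAsFactors = FALSE)
  edges <- edges[order(edges$target_gene, edges$source_gene), ]
  write.table(format(edges, digits = 17, trim = TRUE, scientific = FALSE),
              file.path(dir, "network_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  means <- data.frame(gene = net$genes, mean = net$train_means,
                      stringsAsFactors = FALSE)
  write.table(format(means, digits = 17, trim = TRUE, scientific = FALSE),
              file.path(dir, "train_means.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_network
#' @param dir directory previously written by `write_network`.
#' @export
read_network <- function(dir) {
  means <- read.delim(file.path(dir, "train_means.tsv"),
                      stringsAsFactors = FALSE)
  edges <- read.delim(file.path(dir, "network_edges.tsv"),
                      stringsAsFactors = FALSE)
  genes <- as.character(means$gene)
  p <- length(genes)
  B <- matrix(0, p, p, dimnames = list(genes, genes))
  if (nrow(edges))
    B[cbind(match(edges$target_gene, genes),
            match(edges$source_gene, genes))] <- edges$coefficient
  structure(list(genes = genes, B_hat = B,
                 train_means = setNames(as.numeric(means$mean), genes),
                 lasso_report = NULL),
            class = "interaction_network")
}
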