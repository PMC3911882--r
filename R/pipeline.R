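#' Run configuration for the two-stage pipeline
#'
#' Bundles everything a full run needs: the training compendium, test
#' experiments with replicate groupings and free-text condition labels,
#' gene sets, target and orthogonal gene lists, the Lasso configuration, and
#' (for the training phase) a list of experiment tables to append to the
#' compendium, one modified compendium per entry.
#'
#' Compendium and gene-set entries may be in-memory objects or file paths;
#' paths are loaded through [read_expression_table()] / [read_gene_set()].
#'
#' @param train training compendium (`expr_compendium` or path).
#' @param tests list of test experiments; each element is a list with
#'   `label` (condition label, free text) and `compendium` (an
#'   `expr_compendium` or path whose columns are the replicates).
#' @param gene_sets list of [gene_set()] objects or paths (may be empty).
#' @param target_genes,orthogonal_genes character vectors of gene
#'   identifiers to report individually.
#' @param lasso a [lasso_config()].
#' @param modifications named list of experiments (`expr_compendium` or
#'   path) to append to the training compendium, one modified compendium
#'   each.
#' @param out_dir output directory; `NULL` disables file output.
#' @param seed integer seed recorded in the manifest and used to derive the
#'   Lasso seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(train, tests, gene_sets = list(),
                       target_genes = character(),
                       orthogonal_genes = character(),
                       lasso = NULL, modifications = list(),
                       out_dir = NULL, seed = 1) {
  seed <- check_seed(seed)
  if (is.null(lasso)) lasso <- lasso_config(seed = seed)
  train <- as_compendium(train)
  if (!length(tests)) stopf("at least one test experiment is required")
  tests <- lapply(seq_along(tests), function(i) {
    tt <- tests[[i]]
    if (inherits(tt, "expr_compendium") || is.character(tt))
      tt <- list(label = sprintf("experiment_%d", i), compendium = tt)
    tt$compendium <- as_compendium(tt$compendium)
    if (is.null(tt$label)) tt$label <- sprintf("experiment_%d", i)
    if (n_samples(tt$compendium) < 1L)
      stopf("test experiment '%s' has no replicate columns", tt$label)
    tt
  })
  gene_sets <- lapply(gene_sets, function(g)
    if (is.character(g)) read_gene_set(g) else g)
  lapply(gene_sets, function(g) stopifnot(inherits(g, "gene_set")))
  if (!length(gene_sets) && !length(target_genes))
    stopf("provide at least one gene set or one target gene to evaluate")
  if (length(modifications)) {
    if (is.null(names(modifications)) || any(!nzchar(names(modifications))))
      names(modifications) <- sprintf("modification_%d", seq_along(modifications))
    modifications <- lapply(modifications, as_compendium)
  }
  structure(list(train = train, tests = tests, gene_sets = gene_sets,
                 target_genes = as.character(target_genes),
                 orthogonal_genes = as.character(orthogonal_genes),
                 lasso = lasso, modifications = modifications,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

as_compendium <- function(x) {
  if (inherits(x, "expr_compendium")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_expression_table(x))
  stopf("expected an expression compendium or a file path")
}

# Tiny stable polynomial hash so manifests can identify a configuration
# without external digest dependencies.
config_hash <- function(config) {
  bytes <- serialize(list(lasso = config$lasso, seed = config$seed,
                          genes = compendium_genes(config$train),
                          n_train = n_samples(config$train)),
                     connection = NULL, version = 2)
  h <- 0
  for (b in as.integer(bytes)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

rank_all_columns <- function(net, comp) {
  lapply(compendium_samples(comp), function(s)
    rank_genes(compute_residuals(net, setNames(comp$values[, s],
                                               compendium_genes(comp)))))
}

#' Testing-phase experiment series
#'
#' Trains the interaction network once (or reuses a supplied one), then for
#' every test condition: ranks each replicate, averages ranks across
#' replicates, reports ranks/percentiles for the listed target and
#' orthogonal genes, and computes gene-set AUC% per replicate and averaged.
#'
#' @param config a [run_config()].
#' @param network optional pre-trained `interaction_network`; when `NULL`
#'   the network is fitted from `config$train`.
#' @return A list of class `testing_phase_result`: `network`, `gene_table`
#'   (condition x gene rank/percentile rows), `auc_table` (condition x
#'   gene-set AUC% rows), `rankings` (per-condition list of per-replicate
#'   `gene_ranking`s plus the averaged table), and `manifest`. Tables are
#'   also written under `config$out_dir` when set.
#' @export
run_testing_phase <- function(config, network = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(network)) network <- fit_network(config$train, config$lasso)
  stopifnot(inherits(network, "interaction_network"))
  p <- length(network$genes)
  genes_of_interest <- unique(c(config$target_genes, config$orthogonal_genes))
  missing <- setdiff(genes_of_interest, network$genes)
  if (length(missing))
    stopf("target/orthogonal gene(s) not in the compendium: %s",
          paste(missing, collapse = ", "))
  gene_rows <- list(); auc_rows <- list(); rankings <- list()
  for (tt in config$tests) {
    reps <- rank_all_columns(network, tt$compendium)
    avg <- average_rankings(reps)
    rankings[[tt$label]] <- list(replicates = reps, averaged = avg)
    if (length(genes_of_interest)) {
      idx <- match(genes_of_interest, avg$gene)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        condition = tt$label, gene = genes_of_interest,
        role = ifelse(genes_of_interest %in% config$target_genes,
                      "target", "orthogonal"),
        mean_rank = avg$mean_rank[idx],
        display_rank = avg$display_rank[idx],
        percentile = rank_percentile(avg$mean_rank[idx], p),
        display_percentile = format_rank_percentile(avg$mean_rank[idx], p),
        stringsAsFactors = FALSE)
    }
    for (gs in config$gene_sets) {
      aucs <- vapply(reps, function(r) gene_set_roc(r, gs)$auc_percent,
                     numeric(1L))
      auc_rows[[length(auc_rows) + 1L]] <- data.frame(
        condition = tt$label, gene_set = gs$name,
        replicate = c(compendium_samples(tt$compendium), "mean"),
        auc_percent = c(aucs, mean(aucs)), stringsAsFactors = FALSE)
    }
  }
  gene_table <- if (length(gene_rows)) do.call(rbind, gene_rows) else NULL
  auc_table <- if (length(auc_rows)) do.call(rbind, auc_rows) else NULL
  manifest <- list(phase = "testing", seed = config$seed,
                   config_hash = config_hash(config),
                   n_genes = p, n_train = n_samples(config$train),
                   conditions = vapply(config$tests, `[[`, "", "label"),
                   gene_sets = vapply(config$gene_sets, `[[`, "", "name"),
                   package_version = as.character(utils::packageVersion("ssemtarget")))
  res <- structure(list(network = network, gene_table = gene_table,
                        auc_table = auc_table, rankings = rankings,
                        manifest = manifest),
                   class = "testing_phase_result")
  if (!is.null(config$out_dir)) write_testing_outputs(res, config)
  res
}

write_testing_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(res$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(res$gene_table))
    write.table(res$gene_table, file.path(config$out_dir, "gene_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$auc_table))
    write.table(res$auc_table, file.path(config$out_dir, "auc_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (label in names(res$rankings)) {
    reps <- res$rankings[[label]]$replicates
    for (i in seq_along(reps))
      write_ranking_table(reps[[i]],
                          file.path(config$out_dir,
                                    sprintf("ranks_%s_rep%d.tsv", label, i)))
  }
  invisible(config$out_dir)
}

#' Training-phase experiment series
#'
#' For every modification in the configuration: appends the experiment to the
#' training compendium, retrains the network, re-ranks every test experiment
#' and reports the genome-wide rank-change vector together with RC and RC
#' percentile for the listed target genes. A failure in one modification is
#' reported without aborting the others.
#'
#' @param config a [run_config()] with a nonempty `modifications` list.
#' @param original optional `testing_phase_result` for the unmodified
#'   compendium (recomputed when `NULL`); its rankings are the RC baseline.
#' @return A list of class `training_phase_result`: `original` (the baseline
#'   testing-phase result), `reports` (one data.frame per modification with
#'   per-condition, per-target RC and RC percentile), `rc_vectors` (nested
#'   list: modification -> condition -> named genome-wide RC vector),
#'   `errors` (named list of failed modifications), `manifest`.
#' @export
run_training_phase <- function(config, original = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!length(config$modifications))
    stopf("training phase requires a nonempty modification list")
  if (!length(config$target_genes))
    stopf("training phase requires target genes to report RC for")
  if (is.null(original)) original <- run_testing_phase(config)
  p <- length(original$network$genes)
  reports <- list(); rc_vectors <- list(); errors <- list()
  for (mod_name in names(config$modifications)) {
    res <- tryCatch({
      modified <- append_experiments(config$train,
                                     config$modifications[[mod_name]])
      net_mod <- fit_network(modified, config$lasso)
      rows <- list(); rcs_by_cond <- list()
      for (tt in config$tests) {
        avg_orig <- original$rankings[[tt$label]]$averaged
        avg_mod <- average_rankings(rank_all_columns(net_mod, tt$compendium))
        rc_vec <- setNames(rank_change(avg_orig$mean_rank, avg_mod$mean_rank),
                           avg_orig$gene)
        rcs_by_cond[[tt$label]] <- rc_vec
        idx <- match(config$target_genes, avg_orig$gene)
        rc_t <- rc_vec[idx]
        rows[[length(rows) + 1L]] <- data.frame(
          modification = mod_name, condition = tt$label,
          gene = config$target_genes,
          rank_original = avg_orig$mean_rank[idx],
          rank_modified = avg_mod$mean_rank[idx],
          rc = as.numeric(rc_t),
          rc_percentile = vapply(rc_t, rc_percentile, numeric(1L),
                                 all_rcs = rc_vec),
          rc_percentile_display = vapply(rc_t, format_rc_percentile,
                                         character(1L), all_rcs = rc_vec),
          stringsAsFactors = FALSE)
      }
      list(report = do.call(rbind, rows), rcs = rcs_by_cond)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("modification '%s' failed: %s", mod_name,
                      conditionMessage(res)), call. = FALSE)
      errors[[mod_name]] <- conditionMessage(res)
    } else {
      reports[[mod_name]] <- res$report
      rc_vectors[[mod_name]] <- res$rcs
    }
  }
  manifest <- list(phase = "training", seed = config$seed,
                   config_hash = config_hash(config), n_genes = p,
                   modifications = names(config$modifications),
                   failed = names(errors),
                   package_version = as.character(utils::packageVersion("ssemtarget")))
  out <- structure(list(original = original, reports = reports,
                        rc_vectors = rc_vectors, errors = errors,
                        manifest = manifest),
                   class = "training_phase_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest_training.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    for (mod_name in names(reports))
      write.table(reports[[mod_name]],
                  file.path(config$out_dir,
                            sprintf("rc_report_%s.tsv", mod_name)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Load a run configuration from a YAML file
#'
#' The YAML mirrors the arguments of [run_config()]; compendium and gene-set
#' entries are file paths resolved relative to the YAML file's directory.
#'
#' @param path path to a YAML configuration.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(f) if (is.character(f) && !startsWith(f, "/"))
    file.path(base, f) else f
  tests <- lapply(y$tests, function(tt)
    list(label = tt$label, compendium = resolve(tt$compendium)))
  lasso <- if (is.null(y$lasso)) NULL else
    do.call(lasso_config, y$lasso)
  run_config(train = resolve(y$train), tests = tests,
             gene_sets = lapply(y$gene_sets, resolve),
             target_genes = y$target_genes %||% character(),
             orthogonal_genes = y$orthogonal_genes %||% character(),
             lasso = lasso,
             modifications = lapply(y$modifications, resolve),
             out_dir = y$out_dir, seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
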