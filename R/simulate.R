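#' Simulation configuration
#'
#' Collects the parameters of the synthetic-compendium generator. Samples are
#' drawn from the structural model Y = BY + Phi + E: a sparse gene-gene
#' interaction matrix B (zero diagonal), additive external perturbations Phi
#' on target genes, and i.i.d. Gaussian noise E. Gene-specific baselines are
#' added on top so the simulated tables resemble normalized log2 chip
#' intensities; training later centers them out.
#'
#' @param p number of genes (>= 3).
#' @param n_train number of unperturbed training samples (>= 2).
#' @param density target fraction of nonzero off-diagonal entries of B,
#'   in `[0, 1]`.
#' @param strength_range length-2 interval of absolute interaction
#'   coefficients before rescaling.
#' @param spectral_target desired spectral radius of B, in (0, 1); keeping it
#'   below one guarantees `I - B` is invertible so the structural system has a
#'   unique solution.
#' @param noise_sd standard deviation of the Gaussian noise E (log-expression
#'   units, >= 0).
#' @param replicates number of replicate columns per test experiment.
#' @param baseline_range interval the per-gene baseline expression levels are
#'   drawn from (log2-like units).
#' @param seed mandatory integer seed; every stochastic operation in the
#'   generator is reproducible from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(p = 20, n_train = 50, seed = 1)
simulation_config <- function(p, n_train, density = 0.1,
                              strength_range = c(0.3, 0.8),
                              spectral_target = 0.5, noise_sd = 0.25,
                              replicates = 2, baseline_range = c(6, 10),
                              seed) {
  check_scalar_number(p, "p"); check_scalar_number(n_train, "n_train")
  check_scalar_number(density, "density")
  check_scalar_number(spectral_target, "spectral_target")
  check_scalar_number(noise_sd, "noise_sd")
  check_scalar_number(replicates, "replicates")
  if (length(strength_range) != 2L || any(!is.finite(strength_range)) ||
      any(strength_range < 0) || strength_range[1L] > strength_range[2L])
    stopf("'strength_range' must be a nonnegative (low, high) interval")
  if (length(baseline_range) != 2L || any(!is.finite(baseline_range)) ||
      baseline_range[1L] > baseline_range[2L])
    stopf("'baseline_range' must be a (low, high) interval")
  if (p < 3) stopf("'p' must be at least 3")
  if (n_train < 2) stopf("'n_train' must be at least 2")
  if (density < 0 || density > 1) stopf("'density' must lie in [0, 1]")
  if (spectral_target <= 0 || spectral_target >= 1)
    stopf("'spectral_target' must lie strictly in (0, 1)")
  if (noise_sd < 0) stopf("'noise_sd' must be nonnegative")
  if (replicates < 1) stopf("'replicates' must be at least 1")
  structure(list(p = as.integer(p), n_train = as.integer(n_train),
                 density = density, strength_range = strength_range,
                 spectral_target = spectral_target, noise_sd = noise_sd,
                 replicates = as.integer(replicates),
                 baseline_range = baseline_range,
                 seed = check_seed(seed)),
            class = "sim_config")
}

#' Perturbation specification
#'
#' Describes the ground-truth external perturbation Phi of a simulated test
#' experiment: which genes are shifted and by how much (additive shifts on
#' the log-expression scale).
#'
#' @param targets character vector of distinct target gene identifiers.
#' @param shifts numeric vector of per-target additive shifts (recycled if
#'   length 1).
#' @param label free-text label for the experiment.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(targets, shifts, label = "") {
  targets <- as.character(targets)
  if (anyDuplicated(targets)) stopf("perturbation targets must be distinct")
  if (length(shifts) == 1L) shifts <- rep(shifts, length(targets))
  if (length(shifts) != length(targets))
    stopf("'shifts' must match 'targets' in length")
  if (any(!is.finite(shifts))) stopf("perturbation shifts must be finite")
  structure(list(targets = targets, shifts = as.numeric(shifts),
                 label = as.character(label)),
            class = "perturbation_spec")
}

#' Generate a sparse, stable gene-gene interaction matrix
#'
#' Off-diagonal support is drawn uniformly at random at the configured
#' density, signs are random, magnitudes uniform in `strength_range`, and the
#' whole matrix is rescaled so its spectral radius equals `spectral_target`
#' (relative tolerance 1e-6). The diagonal is exactly zero. Per-gene baseline
#' expression levels are drawn uniformly from `baseline_range`.
#'
#' @param config a [simulation_config()].
#' @return A list of class `true_network` with elements `genes`, `B`
#'   (p x p matrix) and `baseline` (length-p named vector).
#' @export
generate_interaction_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$p
  genes <- sprintf("g%0*d", nchar(p), seq_len(p))
  withr::with_seed(config$seed, {
    B <- matrix(0, p, p, dimnames = list(genes, genes))
    off <- which(row(B) != col(B))
    n_edges <- as.integer(round(config$density * length(off)))
    if (n_edges > 0L) {
      support <- sample(off, n_edges)
      mag <- runif(n_edges, config$strength_range[1L], config$strength_range[2L])
      B[support] <- mag * sample(c(-1, 1), n_edges, replace = TRUE)
      rho <- max(Mod(eigen(B, only.values = TRUE)$values))
      if (rho > .Machine$double.eps^0.5)
        B <- B * (config$spectral_target / rho)
    }
    baseline <- setNames(
      runif(p, config$baseline_range[1L], config$baseline_range[2L]), genes)
    structure(list(genes = genes, B = B, baseline = baseline),
              class = "true_network")
  })
}

#' Simulate expression samples from the structural model
#'
#' Each sample column is `baseline + solve(I - B, phi + e)` with
#' `e ~ N(0, noise_sd^2)` i.i.d. per gene and sample, and `phi` holding the
#' perturbation shifts on target genes (zero elsewhere, the zero vector for
#' an unperturbed sample).
#'
#' @param net a `true_network` from [generate_interaction_matrix()].
#' @param n number of samples to draw (>= 1).
#' @param noise_sd Gaussian noise standard deviation.
#' @param pert a [perturbation_spec()] or `NULL` for unperturbed samples.
#' @param seed integer seed.
#' @param sample_prefix prefix for generated sample identifiers.
#' @return An [expression_compendium()] with `n` columns.
#' @export
simulate_samples <- function(net, n, noise_sd, pert = NULL, seed,
                             sample_prefix = "s") {
  stopifnot(inherits(net, "true_network"))
  check_scalar_number(n, "n"); check_scalar_number(noise_sd, "noise_sd")
  if (n < 1) stopf("'n' must be at least 1")
  if (noise_sd < 0) stopf("'noise_sd' must be nonnegative")
  seed <- check_seed(seed)
  p <- length(net$genes)
  phi <- rep(0, p)
  label <- ""
  if (!is.null(pert)) {
    stopifnot(inherits(pert, "perturbation_spec"))
    idx <- match(pert$targets, net$genes)
    if (anyNA(idx))
      stopf("perturbation target(s) not in the network: %s",
            paste(pert$targets[is.na(idx)], collapse = ", "))
    phi[idx] <- pert$shifts
    label <- pert$label
  }
  rho <- max(Mod(eigen(net$B, only.values = TRUE)$values))
  if (rho >= 1)
    stopf("I - B is singular or near-singular (spectral radius %.3f >= 1); the interaction matrix must have spectral radius < 1", rho)
  withr::with_seed(seed, {
    E <- matrix(rnorm(p * n, sd = noise_sd), p, n)
    X <- solve(diag(p) - net$B, E + phi)
    values <- net$baseline + X
    samples <- sprintf("%s%d", sample_prefix, seq_len(n))
    md <- data.frame(condition = rep(if (nzchar(label)) label else "unperturbed", n),
                     stringsAsFactors = FALSE)
    expression_compendium(values, genes = net$genes, samples = samples,
                          metadata = md)
  })
}

#' Generate a full synthetic study scenario
#'
#' Produces a ground-truth network, an unperturbed training compendium
#' (Phi = 0 throughout) and a list of replicate test experiments with known
#' perturbation targets — everything needed to exercise training, scoring and
#' evaluation end-to-end.
#'
#' @param config a [simulation_config()].
#' @param perturbations list of [perturbation_spec()] objects, one per test
#'   experiment. By default a single experiment shifting the first gene by
#'   `5 * noise_sd`.
#' @return A list of class `sim_scenario` with elements `network`
#'   (`true_network`), `train` (`expr_compendium`), and `tests` (list of
#'   `list(compendium, pert)` entries, each compendium holding
#'   `config$replicates` columns).
#' @export
generate_scenario <- function(config, perturbations = NULL) {
  stopifnot(inherits(config, "sim_config"))
  net <- generate_interaction_matrix(config)
  if (is.null(perturbations)) {
    perturbations <- list(perturbation_spec(net$genes[1L],
                                            5 * config$noise_sd,
                                            label = "pert1"))
  }
  train <- simulate_samples(net, config$n_train, config$noise_sd,
                            pert = NULL, seed = config$seed + 1L,
                            sample_prefix = "train_s")
  tests <- vector("list", length(perturbations))
  for (i in seq_along(perturbations)) {
    pert <- perturbations[[i]]
    stopifnot(inherits(pert, "perturbation_spec"))
    comp <- simulate_samples(net, config$replicates, config$noise_sd,
                             pert = pert, seed = config$seed + 1L + i,
                             sample_prefix = sprintf("test%d_r", i))
    tests[[i]] <- list(compendium = comp, pert = pert)
  }
  structure(list(network = net, train = train, tests = tests,
                 config = config),
            class = "sim_scenario")
}

#' Write simulation ground truth as plain-text tables
#'
#' The true network is written as a 3-column sparse edge list
#' (`source`, `target`, `coefficient`) and the perturbation ground truth as a
#' per-gene table (`gene`, `true_target`, `shift`).
#'
#' @param scenario a `sim_scenario`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_ground_truth <- function(scenario, dir) {
  stopifnot(inherits(scenario, "sim_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  B <- scenario$network$B
  nz <- which(B != 0, arr.ind = TRUE)
  edges <- data.frame(source = scenario$network$genes[nz[, "col"]],
                      target = scenario$network$genes[nz[, "row"]],
                      coefficient = B[nz], stringsAsFactors = FALSE)
  write.table(edges, file.path(dir, "true_network_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (i in seq_along(scenario$tests)) {
    pert <- scenario$tests[[i]]$pert
    genes <- scenario$network$genes
    shift <- setNames(rep(0, length(genes)), genes)
    shift[pert$targets] <- pert$shifts
    df <- data.frame(gene = genes,
                     true_target = as.integer(genes %in% pert$targets),
                     shift = as.numeric(shift), stringsAsFactors = FALSE)
    write.table(df, file.path(dir, sprintf("truth_test%d.tsv", i)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
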