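#' Simulate a cell-type-structured expression matrix with planted
#' gene-dependence modules
#'
#' Every gene is zero-inflated: a cell detects it with probability
#' `1 - dropout_rate`, and a detected value is log-normal,
#' `X = mu_g + 2 * sqrt(ds) * G + sqrt(1 - ds) * eps`
#' on the log scale, with gene baseline `mu_g`, level driver `G` and noise
#' `eps` both standard normal, and `ds = dependence_strength`. Outside a
#' module both the detection indicator and `G` are independent across
#' genes, so the expression is pure noise.
#'
#' Genes belonging to one of a type's modules are co-regulated in that
#' type's cells only: there the module's members share a single per-cell
#' detection indicator (they burst on and off together) and a single
#' per-cell level driver `G` (their on-levels rise and fall together,
#' near-comonotone as `ds` approaches 1). This emulates the joint
#' transcriptional bursting that single-cell correlation networks are
#' built to detect, and at `ds = 0` the level coupling vanishes. Because
#' indicator rate, baseline and level distribution are identical in every
#' cell, module genes keep exactly the same marginal distribution in all
#' types when `mean_shift = 0`: the types then differ in gene-gene wiring
#' but not in expression level (the "network-only" contrast). A positive
#' `mean_shift` is added to module genes in their own type's cells,
#' turning them into conventional expression markers as well.
#'
#' The first gene of every module is its hub: its baseline `mu_g` is
#' raised by one log unit above its siblings, making it the member the
#' expression-weighted random walk visits most when the module is on (a
#' property of the gene itself, so its expression distribution is still
#' identical in every type). The test-bench probes the hubs when checking
#' hub/dark-gene recovery.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param n_types Number of cell types.
#' @param modules_per_type Dependence modules planted per type (0 for none).
#' @param module_size Genes per module (>= 2); module gene blocks are
#'   disjoint and must fit into `n_genes`.
#' @param dependence_strength Tightness of the shared module level, in
#'   \[0, 1\]: 0 plants no level coupling, values near 1 make member genes
#'   near-comonotone within their type's cells.
#' @param mean_shift Log-scale mean offset of module genes in their own
#'   type (0 for matched-mean scenarios).
#' @param dropout_rate Zero-inflation rate in \[0, 1): probability a gene
#'   goes undetected in a cell. Zeros are independent everywhere except
#'   within a planted module in its own type's cells, where the members
#'   drop out jointly (the coordinated off-state is part of the wiring).
#' @param seed Integer seed; output is bit-identical for equal seeds.
#' @return List with `gem` (a raw [expression_matrix()]) and `truth`
#'   (class `SimTruth`: `labels`, `modules`, `hubs`, `params`).
#' @export
simulate_gem <- function(n_cells = 500, n_genes = 60, n_types = 3,
                         modules_per_type = 1, module_size = 8,
                         dependence_strength = 0.9, mean_shift = 0,
                         dropout_rate = 0.4, seed = 0) {
  stopifnot(n_cells >= n_types, n_types >= 1,
            dependence_strength >= 0, dependence_strength <= 1,
            dropout_rate >= 0, dropout_rate < 1)
  n_module_genes <- n_types * modules_per_type * module_size
  if (modules_per_type > 0 && module_size < 2)
    stop("module_size must be >= 2")
  if (n_module_genes > n_genes)
    stop(sprintf("module layout needs %d genes but only %d available",
                 n_module_genes, n_genes))
  set.seed(seed)

  type_of <- sort(rep_len(seq_len(n_types), n_cells))
  labels <- paste0("type", type_of)

  mu <- stats::rnorm(n_genes, mean = 1, sd = 0.5)
  eps <- matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells)
  G <- matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells)
  detected <- matrix(stats::runif(n_genes * n_cells) >= dropout_rate,
                     n_genes, n_cells)
  shift <- matrix(0, n_genes, n_cells)
  modules <- vector("list", n_types)
  hubs <- integer(0)
  g_next <- 1L
  for (t in seq_len(n_types)) {
    modules[[t]] <- list()
    for (m in seq_len(modules_per_type)) {
      genes <- seq.int(g_next, length.out = module_size)
      g_next <- g_next + module_size
      modules[[t]][[m]] <- genes
      hubs <- c(hubs, genes[1L])
      mu[genes[1L]] <- mu[genes[1L]] + 1   # hub: highest-expressed member
      cells_t <- which(type_of == t)
      # members share one level driver and one detection state per cell
      g_shared <- stats::rnorm(length(cells_t))
      on_shared <- stats::runif(length(cells_t)) >= dropout_rate
      G[genes, cells_t] <- matrix(g_shared, module_size, length(cells_t),
                                  byrow = TRUE)
      detected[genes, cells_t] <- matrix(on_shared, module_size,
                                         length(cells_t), byrow = TRUE)
      shift[genes, cells_t] <- mean_shift
    }
  }
  X <- mu + 2 * sqrt(dependence_strength) * G +
    sqrt(1 - dependence_strength) * eps + shift
  E <- exp(X) * detected
  gem <- expression_matrix(
    E,
    gene_ids = sprintf("g%03d", seq_len(n_genes)),
    cell_ids = sprintf("c%04d", seq_len(n_cells)),
    stage = "raw"
  )
  truth <- structure(
    list(labels = labels,
         modules = stats::setNames(modules, paste0("type", seq_len(n_types))),
         hubs = hubs,
         params = list(seed = seed, n_cells = n_cells, n_genes = n_genes,
                       n_types = n_types, modules_per_type = modules_per_type,
                       module_size = module_size,
                       dependence_strength = dependence_strength,
                       mean_shift = mean_shift, dropout_rate = dropout_rate)),
    class = "SimTruth"
  )
  list(gem = gem, truth = truth)
}

#' Named simulation presets used throughout the test-bench
#'
#' * `tiny`: 6 genes x 20 cells, 2 types — a fast smoke-test fixture.
#' * `null`: 60 genes x 500 cells, 3 types, no modules, no shifts — pure noise.
#' * `network_only`: 60 genes x 500 cells, 3 types, one 8-gene module per type,
#'   `mean_shift = 0` — types differ only in gene-gene wiring.
#' * `expression_only`: as `network_only` but with independent genes and a
#'   log-scale mean shift of 1.5 — classic expression markers.
#' * `mixed`: both wiring and mean shift.
#'
#' @param name Preset name.
#' @param seed Integer seed forwarded to [simulate_gem()].
#' @return As [simulate_gem()].
#' @export
make_fixture <- function(name = c("tiny", "null", "network_only",
                                  "expression_only", "mixed"),
                         seed = 0) {
  name <- match.arg(name)
  switch(
    name,
    tiny = simulate_gem(n_cells = 20, n_genes = 6, n_types = 2,
                        modules_per_type = 1, module_size = 3,
                        dependence_strength = 0.9, mean_shift = 1,
                        dropout_rate = 0.1, seed = seed),
    null = simulate_gem(n_cells = 500, n_genes = 60, n_types = 3,
                        modules_per_type = 0, module_size = 2,
                        dependence_strength = 0, mean_shift = 0,
                        dropout_rate = 0.3, seed = seed),
    network_only = simulate_gem(n_cells = 500, n_genes = 60, n_types = 3,
                                modules_per_type = 1, module_size = 8,
                                dependence_strength = 0.95, mean_shift = 0,
                                dropout_rate = 0.3, seed = seed),
    expression_only = simulate_gem(n_cells = 500, n_genes = 60, n_types = 3,
                                   modules_per_type = 1, module_size = 8,
                                   dependence_strength = 0, mean_shift = 1.5,
                                   dropout_rate = 0.3, seed = seed),
    mixed = simulate_gem(n_cells = 500, n_genes = 60, n_types = 3,
                         modules_per_type = 1, module_size = 8,
                         dependence_strength = 0.95, mean_shift = 1.5,
                         dropout_rate = 0.3, seed = seed)
  )
}
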