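#' Simulate a paralog tree with known evolutionary fates
#'
#' Builds a caterpillar tree (3 leaves for 2 layers, 4 for 3 layers) with
#' unit branch lengths, assigns each internal node a fate uniformly at
#' random (or as given), and generates expression top-down from the root
#' value: SF halves the parent value into each child, CF copies it to both,
#' NF keeps it in one (uniformly chosen) child and doubles it in the other.
#' Optional multiplicative log-normal noise on the leaves (off by default,
#' so leaf values are exactly consistent with the recorded fates).
#'
#' @param layers 2 or 3 (internal-node depth levels).
#' @param root_value Expression level of the oldest ancestor (> 0).
#' @param fates Optional character vector of fates (`"SF"`, `"CF"`, `"NF"`)
#'   per internal node in depth-index order; default random.
#' @param nf_child Optional integer vector (1 or 2) per internal node saying
#'   which child gains (doubles) at NF nodes; default random. Child 1 is the
#'   internal (spine) child where there is one.
#' @param noise_sd Standard deviation (log scale) of multiplicative
#'   log-normal noise applied to leaf values; 0 disables noise.
#' @param seed Optional integer seed.
#' @return An object of class `simulated_tree`: list with `tree` (a
#'   `paralog_tree` with leaf values attached) and `truth` (tibble
#'   `node_index`, `fate`, `value` of the true ancestral expression).
#' @export
#' @examples
#' # the 3-leaf example: NF at the root (leaf gains), SF below it
#' sim <- simulate_tree(2, 100, fates = c("NF", "SF"), nf_child = c(2, 1))
#' sim$tree$leaf_values # 50 50 200
simulate_tree <- function(layers = 2, root_value = 100, fates = NULL,
                          nf_child = NULL, noise_sd = 0, seed = NULL) {
  stopifnot(layers %in% c(2L, 3L), root_value > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_int <- as.integer(layers)
  if (is.null(fates)) {
    fates <- sample(c("SF", "CF", "NF"), n_int, replace = TRUE)
  }
  stopifnot(length(fates) == n_int, all(fates %in% c("SF", "CF", "NF")))
  if (is.null(nf_child)) {
    nf_child <- sample(1:2, n_int, replace = TRUE)
  }
  stopifnot(length(nf_child) == n_int, all(nf_child %in% 1:2))

  # caterpillar: node k has children (node k+1 or leaf, leaf); the spine
  # child is child 1, matching the Newick below
  nwk <- if (layers == 2) "((g1:1,g2:1):1,g3:1);"
         else "(((g1:1,g2:1):1,g3:1):1,g4:1);"
  tree <- read_paralog_trees(text = nwk)[[1]]

  value <- numeric(n_int)
  value[1] <- root_value
  # child values per internal node: (child1, child2)
  child_vals <- matrix(NA_real_, n_int, 2)
  for (k in seq_len(n_int)) {
    v <- value[k]
    child_vals[k, ] <- switch(fates[k],
      SF = c(v / 2, v / 2),
      CF = c(v, v),
      NF = if (nf_child[k] == 1L) c(2 * v, v) else c(v, 2 * v)
    )
    if (k < n_int) value[k + 1] <- child_vals[k, 1] # spine child is child 1
  }
  # leaves in tip order g1..gN: the youngest node (index n_int) has leaves
  # (g1, g2); node k < n_int has leaf child g_{nleaf - k + 1} as child 2
  nleaf <- n_int + 1L
  leaf_vals <- numeric(nleaf)
  leaf_vals[1:2] <- child_vals[n_int, ]
  if (n_int > 1) {
    for (k in seq_len(n_int - 1L)) {
      leaf_vals[nleaf - k + 1L] <- child_vals[k, 2]
    }
  }
  if (noise_sd > 0) {
    leaf_vals <- leaf_vals * exp(stats::rnorm(nleaf, 0, noise_sd))
  }
  names(leaf_vals) <- tree$phy$tip.label
  tree <- set_leaf_values(tree, leaf_vals)
  structure(
    list(tree = tree,
         truth = tibble::tibble(node_index = seq_len(n_int), fate = fates,
                                value = value),
         layers = as.integer(layers), noise_sd = noise_sd),
    class = "simulated_tree"
  )
}

#' @export
print.simulated_tree <- function(x, ...) {
  cat("<simulated_tree> ", x$layers, " layers; true fates: ",
      paste(x$truth$fate, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate a dataset of paralog trees with known fates
#'
#' Root values are drawn uniformly from `root_range` (default 50 to 500,
#' typical microarray intensities well above the noise floor); fates are
#' uniform over SF/CF/NF at every internal node.
#'
#' @param n_trees Number of trees (>= 1).
#' @param layers 2 or 3.
#' @param seed Optional integer seed for the whole dataset.
#' @param root_range Length-2 numeric range for root expression values.
#' @param noise_sd Leaf noise, as in [simulate_tree()].
#' @return A list of `simulated_tree` objects.
#' @export
simulate_dataset <- function(n_trees, layers = 2, seed = NULL,
                             root_range = c(50, 500), noise_sd = 0) {
  if (n_trees < 1) stop("n_trees must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  roots <- stats::runif(n_trees, root_range[1], root_range[2])
  lapply(seq_len(n_trees), function(i) {
    simulate_tree(layers = layers, root_value = roots[i], noise_sd = noise_sd)
  })
}

#' Fate-classification accuracy
#'
#' Percentage of nodes whose predicted fate label equals the true fate:
#' `100 * mean(predicted == truth)`.
#'
#' @param predicted,truth Aligned character vectors of fate labels.
#' @return Accuracy in percent.
#' @export
#' @examples
#' classification_accuracy(c("SF", "SF", "CF"), c("SF", "NF", "CF")) # 66.7
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have the same length", call. = FALSE)
  }
  if (length(predicted) == 0) stop("no predictions to score", call. = FALSE)
  100 * mean(predicted == truth)
}

# deterministic per-(dataset, tree) seed derived from a master seed
.derive_seed <- function(seed, dataset, tree) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 7919 * dataset + 104729 * tree) %%
               2147483647)
}

#' Benchmark fate classification on replicate synthetic datasets
#'
#' For each replicate dataset: simulate trees with known fates
#' ([simulate_dataset()]), reconstruct ancestral expression by belief
#' propagation ([run_nbp()]), classify every duplication event
#' ([infer_fates()]) and score per-node-index accuracy
#' ([classification_accuracy()]). Reports mean and standard deviation of
#' accuracy across replicates.
#'
#' @param n_datasets Number of replicate datasets (default 5).
#' @param n_trees Trees per dataset (default 250, comparable to genome-scale
#'   paralog family counts for small trees).
#' @param layers 2 or 3.
#' @param config An [nbp_config()]; per-tree seeds are derived
#'   deterministically from `seed`.
#' @param seed Master integer seed.
#' @param noise_sd Leaf noise passed to the generator (default 0).
#' @return A tibble of class `fate_accuracy`: `node_index`, `mean_accuracy`,
#'   `sd_accuracy` (percent, across datasets), `n_datasets`, `n_trees`,
#'   `layers`, plus a list-column `accuracies` of per-dataset values.
#' @export
run_table1_experiment <- function(n_datasets = 5, n_trees = 250, layers = 2,
                                  config = nbp_config(T = 200),
                                  seed = NULL, noise_sd = 0) {
  per_dataset <- lapply(seq_len(n_datasets), function(d) {
    sims <- simulate_dataset(n_trees, layers = layers,
                             seed = .derive_seed(seed, d, 0L),
                             noise_sd = noise_sd)
    calls <- purrr::map_dfr(seq_along(sims), function(i) {
      cfg <- config
      cfg$seed <- .derive_seed(seed, d, i)
      fit <- run_nbp(sims[[i]]$tree, cfg)
      dplyr::inner_join(
        infer_fates(fit)[, c("node_index", "label")],
        sims[[i]]$truth[, c("node_index", "fate")],
        by = "node_index"
      )
    })
    calls |>
      dplyr::group_by(.data$node_index) |>
      dplyr::summarise(
        accuracy = classification_accuracy(.data$label, .data$fate),
        .groups = "drop"
      ) |>
      dplyr::mutate(dataset = d)
  })
  out <- dplyr::bind_rows(per_dataset) |>
    dplyr::group_by(.data$node_index) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = if (dplyr::n() > 1) stats::sd(.data$accuracy) else 0,
      accuracies = list(.data$accuracy),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_datasets = n_datasets, n_trees = n_trees,
                  layers = as.integer(layers))
  class(out) <- c("fate_accuracy", class(out))
  out
}
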