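#' Remove trees whose leaves are all below the expression noise floor
#'
#' Microarray intensities below about 200 are indistinguishable from noise;
#' a tree is removed iff every leaf value is strictly below `floor` (a
#' single leaf at or above the floor retains the tree).
#'
#' @param trees A list of `paralog_tree` objects with leaf values attached.
#' @param floor Noise floor (default 200, intensity units).
#' @return The retained subset of `trees`.
#' @export
filter_low_expression_trees <- function(trees, floor = 200) {
  keep <- vapply(trees, function(tr) {
    stopifnot(inherits(tr, "paralog_tree"))
    if (is.null(tr$leaf_values)) stop("attach expression before filtering",
                                      call. = FALSE)
    any(tr$leaf_values >= floor)
  }, logical(1))
  trees[keep]
}

#' High-confidence fate calls
#'
#' Retains calls whose maximum fate probability strictly exceeds `cutoff`.
#'
#' @param calls A tibble of fate calls with a `confidence` column
#'   (e.g. from [infer_fates()]).
#' @param cutoff Probability cutoff (default 0.75, strict `>`).
#' @return The retained subset of `calls`.
#' @export
high_confidence <- function(calls, cutoff = 0.75) {
  stopifnot(is.data.frame(calls), "confidence" %in% names(calls))
  dplyr::filter(calls, !is.na(.data$confidence), .data$confidence > cutoff)
}

#' Permutation negative control for an expression table
#'
#' Independently permutes each gene's row of values across tissue labels,
#' preserving the multiset of values per gene while destroying the
#' gene-tissue mapping.
#'
#' @param expr Expression tibble (`gene_id` plus >= 2 tissue columns).
#' @param seed Optional integer seed.
#' @return A tibble of the same shape with permuted rows.
#' @export
permute_control <- function(expr, seed = NULL) {
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr))
  tissues <- setdiff(names(expr), "gene_id")
  if (length(tissues) < 2) {
    stop("permutation control needs at least 2 tissues", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mat <- as.matrix(expr[tissues])
  perm <- t(apply(mat, 1, sample))
  out <- tibble::as_tibble(as.data.frame(perm))
  names(out) <- tissues
  dplyr::bind_cols(expr["gene_id"], out)
}

#' Proportions of SF/CF/NF calls per node index and stratum
#'
#' @param calls Tibble of fate calls with columns `node_index`, `label` and
#'   optionally `stratum`. Calls flagged `unclassifiable` (NA label) are
#'   excluded from denominators.
#' @return A tibble with one row per (stratum, node index): call count `n`
#'   and percentages `SF`, `CF`, `NF` summing to 100 (NA when `n` is 0).
#' @export
#' @examples
#' tibble::tibble(node_index = 1, label = c("SF", "SF", "CF")) |>
#'   summarize_proportions()
summarize_proportions <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("node_index", "label") %in% names(calls)))
  if (!"stratum" %in% names(calls)) calls$stratum <- "overall"
  grid <- tidyr::expand_grid(
    stratum = unique(calls$stratum),
    node_index = sort(unique(calls$node_index))
  )
  counted <- calls |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::count(.data$stratum, .data$node_index, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  for (f in c("SF", "CF", "NF")) {
    if (!f %in% names(counted)) counted[[f]] <- 0L
  }
  grid |>
    dplyr::left_join(counted, by = c("stratum", "node_index")) |>
    dplyr::mutate(dplyr::across(c("SF", "CF", "NF"),
                                ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::mutate(n = .data$SF + .data$CF + .data$NF) |>
    dplyr::mutate(dplyr::across(c("SF", "CF", "NF"),
                                ~ ifelse(n > 0, 100 * .x / n, NA_real_))) |>
    dplyr::select("stratum", "node_index", "n", "SF", "CF", "NF")
}

#' Per-tissue fate inference across a set of paralog trees
#'
#' For each tissue: attaches expression to every tree, removes trees whose
#' leaves all sit below the noise floor, reconstructs ancestral expression
#' by belief propagation, classifies every duplication event, and
#' summarizes fate proportions for three strata: all calls (`overall`),
#' calls with confidence above the cutoff (`high_confidence`), and calls on
#' a per-gene tissue-permuted control matrix (`permuted`, optional). A tree
#' that fails (e.g. genes missing from the table) is logged and skipped.
#' Per-(tissue, tree) RNG seeds are derived deterministically from `seed`,
#' so results do not depend on execution order.
#'
#' @param trees List of `paralog_tree` objects (leaf labels = gene IDs).
#' @param expr Expression tibble from [read_expression_table()].
#' @param tissues Character vector of tissue columns to analyze (default:
#'   all).
#' @param config An [nbp_config()].
#' @param floor Expression noise floor (see
#'   [filter_low_expression_trees()]).
#' @param confidence High-confidence cutoff (strict `>`).
#' @param permute Run the permutation negative control (default `TRUE`).
#' @param seed Master integer seed.
#' @return An object of class `fate_run`: list with `calls` (tibble: tissue,
#'   tree, stratum `real`/`permuted`, node index, triple, probabilities,
#'   label, confidence, flags), `summary` (the [summarize_proportions()]
#'   table over strata `overall`, `high_confidence`, `permuted`), and `log`
#'   (tibble of per-tissue tree counts: analyzed, filtered, failed).
#' @export
run_all <- function(trees, expr, tissues = NULL, config = nbp_config(),
                    floor = 200, confidence = 0.75, permute = TRUE,
                    seed = NULL) {
  stopifnot(is.list(trees), is.data.frame(expr))
  if (is.null(tissues)) tissues <- setdiff(names(expr), "gene_id")
  stopifnot(all(tissues %in% names(expr)))

  matrices <- list(real = expr)
  if (permute) {
    matrices$permuted <- permute_control(expr, seed = .derive_seed(seed, 0L,
                                                                   0L))
  }

  calls <- list()
  log_rows <- list()
  for (stratum in names(matrices)) {
    m <- matrices[[stratum]]
    for (ti in seq_along(tissues)) {
      tissue <- tissues[ti]
      attached <- list()
      failed <- 0L
      for (tr in trees) {
        at <- tryCatch(attach_expression(tr, m, tissue),
                       error = function(e) {
                         message("skipping tree in ", tissue, ": ",
                                 conditionMessage(e))
                         NULL
                       })
        if (!is.null(at)) attached <- c(attached, list(at))
        else failed <- failed + 1L
      }
      kept <- filter_low_expression_trees(attached, floor = floor)
      rows <- purrr::map_dfr(seq_along(kept), function(i) {
        cfg <- config
        cfg$seed <- .derive_seed(seed, ti + 1000L * (stratum == "permuted"),
                                 i)
        fit <- run_nbp(kept[[i]], cfg)
        dplyr::bind_cols(
          tibble::tibble(tissue = tissue, stratum = stratum, tree = i),
          infer_fates(fit)
        )
      })
      calls <- c(calls, list(rows))
      log_rows <- c(log_rows, list(tibble::tibble(
        tissue = tissue, stratum = stratum, n_trees = length(trees),
        n_failed = failed, n_filtered = length(attached) - length(kept),
        n_analyzed = length(kept)
      )))
    }
  }
  calls <- dplyr::bind_rows(calls)

  strata <- list()
  if (nrow(calls) > 0) {
    real <- dplyr::filter(calls, .data$stratum == "real")
    strata$overall <- dplyr::mutate(real, stratum = "overall")
    strata$high_confidence <- dplyr::mutate(
      high_confidence(real, cutoff = confidence), stratum = "high_confidence")
    if (permute) {
      strata$permuted <- dplyr::filter(calls, .data$stratum == "permuted")
    }
  }
  summary <- if (length(strata) > 0) {
    summarize_proportions(dplyr::bind_rows(strata))
  } else {
    summarize_proportions(tibble::tibble(node_index = integer(),
                                         label = character()))
  }
  structure(list(calls = calls, summary = summary,
                 log = dplyr::bind_rows(log_rows)),
            class = "fate_run")
}

#' @export
print.fate_run <- function(x, ...) {
  cat("<fate_run> ", nrow(x$calls), " fate calls over ",
      length(unique(x$calls$tissue)), " tissue(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @describeIn run_all Fate calls as a tibble.
#' @param x A `fate_run`.
#' @param ... Unused.
#' @export
tidy.fate_run <- function(x, ...) x$calls

#' @describeIn run_all Per-(stratum, node index) proportion summary.
#' @export
glance.fate_run <- function(x, ...) x$summary
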