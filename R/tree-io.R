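#' Construct a paralog tree from an `ape::phylo` object
#'
#' Validates that the tree is rooted and strictly binary, assigns depth
#' indices to internal nodes (1 = root, increasing from older to younger
#' ancestors; ties at equal depth broken by left-to-right traversal order),
#' and precomputes the node relations used by belief propagation.
#'
#' Branch lengths are interpreted as dS (synonymous substitutions per
#' synonymous site). Trees are treated as pre-rooted; no re-rooting is
#' performed. Missing branch lengths are replaced by `default_branch_length`
#' with a warning. Zero-length branches are kept as stored and floored at
#' `1e-6` only where a length enters a denominator (CF weighting).
#'
#' @param phy An `ape::phylo` tree, rooted and binary.
#' @param default_branch_length Length substituted (with a warning) when the
#'   tree carries no branch lengths.
#' @return An object of class `paralog_tree`: a list with elements `phy`,
#'   `nodes` (a tibble of internal-node relations: `index`, `node_id`,
#'   `depth`, children ids/types/lengths, parent index, sibling id/type and
#'   branch lengths), and `leaf_values` (`NULL` until
#'   [attach_expression()]).
#' @seealso [read_paralog_trees()], [attach_expression()]
#' @export
as_paralog_tree <- function(phy, default_branch_length = 1.0) {
  if (!inherits(phy, "phylo")) stop("`phy` must be an ape phylo object",
                                    call. = FALSE)
  if (!ape::is.rooted(phy)) {
    stop("tree must be rooted: input is unrooted (basal polytomy)",
         call. = FALSE)
  }
  if (!ape::is.binary(phy)) {
    stop("tree must be strictly binary (no polytomies)", call. = FALSE)
  }
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; using default length ",
            default_branch_length, call. = FALSE)
    phy$edge.length <- rep(default_branch_length, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length) || any(phy$edge.length < 0)) {
    stop("branch lengths must be nonnegative and non-missing", call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  phy <- stats::reorder(phy, "cladewise")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  nnode <- phy$Nnode
  # topological depth via the preorder edge list
  depth <- integer(ntip + nnode)
  for (e in seq_len(nrow(phy$edge))) {
    depth[phy$edge[e, 2]] <- depth[phy$edge[e, 1]] + 1L
  }
  internal <- root:(ntip + nnode)
  pre_pos <- match(internal, c(root, phy$edge[, 2]))
  ord <- internal[order(depth[internal], pre_pos)]
  index_of <- integer(ntip + nnode) # 0 for leaves
  index_of[ord] <- seq_len(nnode)

  rows <- lapply(seq_len(nnode), function(i) {
    nid <- ord[i]
    er <- which(phy$edge[, 1] == nid)
    ch <- phy$edge[er, 2]
    # parent / sibling
    pe <- which(phy$edge[, 2] == nid)
    if (length(pe) == 0L) {
      parent_index <- NA_integer_; sib_id <- NA_integer_
      l_self <- NA_real_; l_sib <- NA_real_
    } else {
      pid <- phy$edge[pe, 1]
      parent_index <- index_of[pid]
      se <- setdiff(which(phy$edge[, 1] == pid), pe)
      sib_id <- phy$edge[se, 2]
      l_self <- phy$edge.length[pe]
      l_sib <- phy$edge.length[se]
    }
    tibble::tibble(
      index = i, node_id = nid, depth = depth[nid],
      child1 = ch[1], child2 = ch[2],
      child1_leaf = ch[1] <= ntip, child2_leaf = ch[2] <= ntip,
      l1 = phy$edge.length[er[1]], l2 = phy$edge.length[er[2]],
      parent_index = parent_index,
      sib_id = sib_id, sib_leaf = !is.na(sib_id) && sib_id <= ntip,
      l_self = l_self, l_sib = l_sib
    )
  })
  structure(
    list(phy = phy, nodes = dplyr::bind_rows(rows), leaf_values = NULL,
         tissue = NULL),
    class = "paralog_tree"
  )
}

#' @export
print.paralog_tree <- function(x, ...) {
  cat("<paralog_tree> ", length(x$phy$tip.label), " leaves, ",
      nrow(x$nodes), " internal nodes (indices 1..", nrow(x$nodes),
      ", 1 = root)\n", sep = "")
  if (!is.null(x$leaf_values)) {
    cat("  expression attached",
        if (!is.null(x$tissue)) paste0(" (tissue: ", x$tissue, ")"), "\n",
        sep = "")
  }
  invisible(x)
}

#' Number of tree layers (internal-node depth levels)
#' @param tree A `paralog_tree`.
#' @return Integer: 2 for a 3-leaf tree, 3 for a 4-leaf caterpillar, etc.
#' @export
n_layers <- function(tree) {
  stopifnot(inherits(tree, "paralog_tree"))
  max(tree$nodes$depth) + 1L
}

#' Read rooted binary paralog trees from Newick
#'
#' Parses one or more Newick trees (via \pkg{ape}) and converts each with
#' [as_paralog_tree()]. Polytomies and unrooted trees are errors; trees
#' without branch lengths get `default_branch_length` with a warning.
#'
#' @param file Path to a Newick file (one or more trees), or `NULL` when
#'   `text` is given.
#' @param text A Newick string, as an alternative to `file`.
#' @param default_branch_length Substitute for missing branch lengths.
#' @return A list of `paralog_tree` objects.
#' @export
#' @examples
#' read_paralog_trees(text = "((A:0.1,B:0.2):0.3,C:0.4);")
read_paralog_trees <- function(file = NULL, text = NULL,
                               default_branch_length = 1.0) {
  if (is.null(file) == is.null(text)) {
    stop("supply exactly one of `file` or `text`", call. = FALSE)
  }
  phy <- if (is.null(file)) ape::read.tree(text = text)
         else ape::read.tree(file = file)
  if (is.null(phy)) stop("malformed Newick input", call. = FALSE)
  if (inherits(phy, "phylo")) phy <- list(phy)
  lapply(phy, as_paralog_tree, default_branch_length = default_branch_length)
}

#' Serialize a paralog tree to Newick
#'
#' @param tree A `paralog_tree`.
#' @return A Newick string with branch lengths.
#' @export
write_paralog_tree <- function(tree) {
  stopifnot(inherits(tree, "paralog_tree"))
  ape::write.tree(tree$phy)
}

#' Read a gene-by-tissue expression table
#'
#' Expects tab-separated text with a header row of tissue names and gene IDs
#' in the first column. Values must be numeric and nonnegative; offending
#' cells are named in the error.
#'
#' @param file Path to the TSV file.
#' @return A tibble with character column `gene_id` followed by one numeric
#'   column per tissue.
#' @export
read_expression_table <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  if (file.size(file) == 0) stop("empty expression file: ", file,
                                 call. = FALSE)
  raw <- utils::read.delim(file, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop("expression table needs a gene column and at least one tissue",
         call. = FALSE)
  }
  genes <- raw[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene IDs: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    num <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(num) & !is.na(vals[[j]]) & nzchar(vals[[j]]))
    if (length(bad) > 0) {
      stop("non-numeric expression for gene '", genes[bad[1]],
           "' in tissue '", names(vals)[j], "'", call. = FALSE)
    }
    neg <- which(num < 0)
    if (length(neg) > 0) {
      stop("negative expression for gene '", genes[neg[1]],
           "' in tissue '", names(vals)[j], "'", call. = FALSE)
    }
    vals[[j]] <- num
  }
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(vals))
}

#' Attach per-tissue expression values to tree leaves
#'
#' @param tree A `paralog_tree` whose leaf labels are gene IDs.
#' @param expr An expression tibble from [read_expression_table()] (column
#'   `gene_id` plus tissue columns).
#' @param tissue Name of the tissue column to use.
#' @return The tree with `leaf_values` set (named numeric vector in
#'   `tip.label` order) and `tissue` recorded.
#' @export
attach_expression <- function(tree, expr, tissue) {
  stopifnot(inherits(tree, "paralog_tree"), is.data.frame(expr))
  if (!tissue %in% names(expr)) {
    stop("tissue '", tissue, "' not found in expression table", call. = FALSE)
  }
  tips <- tree$phy$tip.label
  miss <- setdiff(tips, expr$gene_id)
  if (length(miss) > 0) {
    stop("genes missing from expression table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  vals <- expr[[tissue]][match(tips, expr$gene_id)]
  if (any(is.na(vals))) {
    stop("missing expression values for: ",
         paste(tips[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  set_leaf_values(tree, stats::setNames(as.numeric(vals), tips), tissue)
}

#' Set leaf expression values directly
#'
#' Lower-level companion to [attach_expression()] for programmatic use
#' (e.g. the synthetic generator).
#'
#' @param tree A `paralog_tree`.
#' @param values Named nonnegative numeric vector covering every leaf label,
#'   or unnamed in `tip.label` order.
#' @param tissue Optional tissue name to record.
#' @return The tree with `leaf_values` set.
#' @export
set_leaf_values <- function(tree, values, tissue = NULL) {
  stopifnot(inherits(tree, "paralog_tree"))
  tips <- tree$phy$tip.label
  if (is.null(names(values))) {
    if (length(values) != length(tips)) {
      stop("need one value per leaf", call. = FALSE)
    }
    names(values) <- tips
  }
  miss <- setdiff(tips, names(values))
  if (length(miss) > 0) {
    stop("missing values for leaves: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(values < 0) || anyNA(values)) {
    stop("leaf expression values must be nonnegative", call. = FALSE)
  }
  tree$leaf_values <- as.numeric(values[tips])
  names(tree$leaf_values) <- tips
  tree$tissue <- tissue
  tree
}
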