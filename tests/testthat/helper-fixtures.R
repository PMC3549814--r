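# Shared fixture builders (everything is generated in code; no data files).

# 3-leaf caterpillar with unit branch lengths and given leaf values
make_two_layer <- function(v = c(g1 = 50, g2 = 50, g3 = 200)) {
  tr <- read_paralog_trees(text = "((g1:1,g2:1):1,g3:1);")[[1]]
  set_leaf_values(tr, v)
}

# random valid expression triples (never all-zero)
random_triples <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      x = stats::runif(n, 0, 500),
      a = stats::runif(n, 0, 500),
      b = stats::runif(n, 0, 500)
    )
  })
}

# write a small expression TSV and return its path
write_expr_tsv <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                            .local_envir =
                                                              parent.frame())) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
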