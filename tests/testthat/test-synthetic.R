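test_that("forced fates reproduce the canonical 3-leaf example", {
  sim <- simulate_tree(2, 100, fates = c("NF", "SF"), nf_child = c(2, 1))
  expect_equal(unname(sim$tree$leaf_values), c(50, 50, 200))
  expect_equal(sim$truth$fate, c("NF", "SF"))
  expect_equal(sim$truth$value, c(100, 100))

  cf <- simulate_tree(2, 100, fates = c("CF", "CF"))
  expect_equal(unname(cf$tree$leaf_values), c(100, 100, 100))

  expect_error(simulate_tree(2, 0), "root_value")
  expect_error(simulate_tree(4, 100), "layers")
})

test_that("generation is deterministic under a seed", {
  s1 <- simulate_tree(3, 200, seed = 99)
  s2 <- simulate_tree(3, 200, seed = 99)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$tree$leaf_values, s2$tree$leaf_values)
  d1 <- simulate_dataset(5, layers = 2, seed = 7)
  d2 <- simulate_dataset(5, layers = 2, seed = 7)
  expect_length(d1, 5)
  expect_identical(lapply(d1, `[[`, "truth"), lapply(d2, `[[`, "truth"))
  expect_error(simulate_dataset(0), "n_trees")
})

test_that("noise-free trees are exactly consistent with their fates", {
  sims <- simulate_dataset(40, layers = 3, seed = 21)
  for (sim in sims) {
    nodes <- sim$tree$nodes
    vals <- sim$truth$value
    for (k in seq_len(nrow(nodes))) {
      ch <- c(nodes$child1[k], nodes$child2[k])
      leaf <- c(nodes$child1_leaf[k], nodes$child2_leaf[k])
      cv <- ifelse(leaf, sim$tree$leaf_values[ch],
                   vals[match(ch, nodes$node_id)])
      x <- vals[k]
      switch(sim$truth$fate[k],
        SF = expect_equal(sum(cv), x),
        CF = expect_equal(cv, c(x, x), ignore_attr = TRUE),
        NF = {
          expect_equal(min(cv), x)
          expect_equal(max(cv), 2 * x)
        }
      )
    }
  }
})

test_that("true triples classify back to the generating fate", {
  sims <- simulate_dataset(30, layers = 2, seed = 33)
  for (sim in sims) {
    nodes <- sim$tree$nodes
    vals <- sim$truth$value
    for (k in seq_len(nrow(nodes))) {
      ch <- c(nodes$child1[k], nodes$child2[k])
      leaf <- c(nodes$child1_leaf[k], nodes$child2_leaf[k])
      cv <- ifelse(leaf, sim$tree$leaf_values[ch],
                   vals[match(ch, nodes$node_id)])
      call <- classify_fate(vals[k], cv[1], cv[2])
      expect_identical(call$label, sim$truth$fate[k])
      expect_gt(call[[paste0("p_", tolower(sim$truth$fate[k]))]], 1 - 1e-9)
    }
  }
})

test_that("fates are drawn uniformly across many nodes", {
  sims <- simulate_dataset(500, layers = 2, seed = 4)
  fates <- unlist(lapply(sims, function(s) s$truth$fate))
  tab <- table(fates) / length(fates)
  expect_true(all(abs(tab - 1 / 3) < 0.05)) # 1000 nodes, ~3 sigma
})

test_that("log-normal leaf noise perturbs leaves but not the truth", {
  s <- simulate_tree(2, 100, fates = c("CF", "CF"), noise_sd = 0.2, seed = 8)
  expect_false(any(s$tree$leaf_values == 100))
  expect_true(all(s$tree$leaf_values > 0))
  expect_equal(s$truth$value, c(100, 100))
})

test_that("accuracy is a simple percentage with strict alignment", {
  expect_equal(classification_accuracy(c("SF", "SF", "CF"),
                                       c("SF", "NF", "CF")), 200 / 3)
  expect_equal(classification_accuracy(rep("NF", 4), rep("NF", 4)), 100)
  expect_equal(classification_accuracy(rep("SF", 4), rep("NF", 4)), 0)
  expect_error(classification_accuracy(c("SF"), c("SF", "CF")), "length")
  expect_error(classification_accuracy(character(0), character(0)), "no pred")
})

test_that("the benchmark report aggregates per node index", {
  acc <- run_table1_experiment(n_datasets = 2, n_trees = 4, layers = 2,
                               config = nbp_config(M = 20, T = 10),
                               seed = 60)
  expect_s3_class(acc, "fate_accuracy")
  expect_equal(acc$node_index, 1:2)
  expect_true(all(acc$mean_accuracy >= 0 & acc$mean_accuracy <= 100))
  expect_equal(acc$n_datasets, c(2, 2))
  expect_length(acc$accuracies[[1]], 2)
  # a single dataset reports zero spread by convention
  one <- run_table1_experiment(n_datasets = 1, n_trees = 3, layers = 2,
                               config = nbp_config(M = 15, T = 5), seed = 3)
  expect_equal(one$sd_accuracy, c(0, 0))
})
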