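weights_fixture <- function() {
  expr <- rbind(A = c(1, 1, 10, 10), B = c(2, 2, 8, 8),
                C = c(3, 3, 6, 6), D = c(4, 4, 4, 4))
  colnames(expr) <- sprintf("S%d", 1:4)
  md <- suppressMessages(deggs:::build_sample_metadata(
    colnames(expr), rep(c("g1", "g2"), each = 2), "group"))
  list(expr = expr, md = md)
}

test_that("node weights are per-group means with the stated missing policy", {
  f <- weights_fixture()
  w <- compute_node_weights(f$expr, f$md, "g1")
  expect_equal(unname(w), c(1, 2, 3, 4))
  f$expr["A", "S2"] <- NA
  w2 <- compute_node_weights(f$expr, f$md, "g1")
  expect_equal(unname(w2["A"]), 1)  # [2, missing] -> mean 2 analogue
  f$expr["A", "S1"] <- NA
  expect_equal(unname(compute_node_weights(f$expr, f$md, "g1")["A"]), -Inf)
  expect_error(compute_node_weights(f$expr, f$md, "nope"), "not present")
})

test_that("nearest-rank cut-off reproduces the worked example", {
  net <- as_meta_network(data.frame(source = c("A", "B", "C"),
                                    target = c("B", "C", "D")))
  w <- c(A = 1, B = 2, C = 3, D = 4)
  out <- apply_percolation_filter(net, w, 50)
  expect_equal(out$cutoff, 2)
  expect_setequal(out$nodes, c("B", "C", "D"))
  expect_equal(nrow(out$edges), 2L)  # A-B dropped with A
  # percentile 0 retains everything
  out0 <- apply_percolation_filter(net, w, 0)
  expect_setequal(out0$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(out0$edges), 3L)
})

test_that("retention is monotone non-increasing in the percentile", {
  set.seed(12)
  genes <- sprintf("G%02d", 1:30)
  net <- as_meta_network(data.frame(source = genes[1:29], target = genes[2:30]))
  w <- stats::setNames(rnorm(30, 5), genes)
  kept <- vapply(seq(0, 90, 10), function(p)
    length(apply_percolation_filter(net, w, p)$nodes), integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("common-interaction removal enforces strict specificity", {
  mk <- function(s, t) as_meta_network(data.frame(source = s, target = t))
  e1 <- c("A", "B"); e2 <- c("B", "C"); e3 <- c("C", "D")
  two <- remove_common_interactions(list(
    g1 = mk(c(e1[1], e2[1]), c(e1[2], e2[2])),
    g2 = mk(c(e2[1], e3[1]), c(e2[2], e3[2]))))
  expect_identical(deggs:::edge_key(two$g1), "A|B")
  expect_identical(deggs:::edge_key(two$g2), "C|D")
  # identical sets -> both empty
  same <- remove_common_interactions(list(g1 = mk("A", "B"), g2 = mk("A", "B")))
  expect_equal(vapply(same, nrow, integer(1)), c(g1 = 0L, g2 = 0L))
  # 3 groups, strict: an edge in two of three groups vanishes everywhere
  three <- remove_common_interactions(list(
    g1 = mk(c("A", "B"), c("B", "C")),
    g2 = mk("B", "C"),
    g3 = mk(c("B", "C"), c("C", "D"))))
  expect_identical(deggs:::edge_key(three$g1), "A|B")
  expect_equal(nrow(three$g2), 0L)
  expect_identical(deggs:::edge_key(three$g3), "C|D")
})

test_that("significant links are counted on non-missing p below alpha, with caching", {
  sim <- simulate_dataset(simulation_spec(
    n_genes = 20L, n_samples_per_group = c(A = 15L, B = 15L),
    network_edges = 12L, n_differential_edges = 3L, seed = 5))
  groups <- levels(sim$metadata$group)
  w <- lapply(setNames(groups, groups), function(g)
    compute_node_weights(sim$expr, sim$metadata, g))
  filt <- function(p) lapply(setNames(groups, groups), function(g)
    apply_percolation_filter(sim$network, w[[g]], p)$edges)
  cache <- new.env(parent = emptyenv())
  s30 <- remove_common_interactions(filt(30))
  r1 <- count_significant_links(s30, sim$expr, sim$metadata, cache = cache)
  calls_after_first <- cache$fit_calls
  expect_equal(calls_after_first, sum(vapply(s30, nrow, integer(1))))
  # overlapping edge set at another threshold re-fits only new pairs
  s50 <- remove_common_interactions(filt(50))
  r2 <- count_significant_links(s50, sim$expr, sim$metadata, cache = cache)
  keys <- function(sets) unlist(lapply(sets, deggs:::edge_key))
  new_pairs <- length(setdiff(keys(s50), keys(s30)))
  expect_equal(cache$fit_calls - calls_after_first, new_pairs)
  # counting rule on injected p-values
  expect_equal(sum(!is.na(c(0.01, 0.2, NA)) & c(0.01, 0.2, NA) < 0.05), 1L)
  empty <- count_significant_links(
    list(A = sim$network[0, ], B = sim$network[0, ]), sim$expr, sim$metadata)
  expect_equal(empty$count, 0L)
  expect_equal(nrow(empty$results), 0L)
})

test_that("the optimizer matches a cache-free brute-force grid search exactly", {
  sim <- simulate_dataset(simulation_spec(
    n_genes = 20L, n_samples_per_group = c(A = 20L, B = 20L),
    network_edges = 30L, n_differential_edges = 4L, seed = 42))
  grid <- seq(0, 90, 10)
  prof <- optimize_percolation_threshold(sim$network, sim$expr, sim$metadata,
                                         grid = grid, robust = FALSE)
  brute <- oracle_grid_search(sim$network, sim$expr, sim$metadata, grid,
                              robust = FALSE)
  expect_identical(prof$sig_count, brute$counts)
  expect_identical(prof$chosen, brute$chosen)
  expect_equal(max(prof$sig_count), prof$sig_count[match(prof$chosen, grid)])
  # removed-node counts are non-decreasing in the percentile per group
  expect_true(all(apply(prof$nodes_removed, 2, function(v) all(diff(v) >= 0))))
})

test_that("threshold ties break to the smallest percentile", {
  # constructed so the significant count is exactly 1 at percentiles 20, 30
  # and 40: one strongly differential pair whose regulator drops out of
  # group B at every one of them, plus constant-valued filler genes whose
  # edges are either removed as common or degenerate (zero variance)
  set.seed(99)
  n <- 30
  grp <- rep(c("A", "B"), each = n)
  dsrc <- ifelse(grp == "B", 0.5, 5) + rnorm(2 * n, sd = 0.3)
  dtgt <- 1 + ifelse(grp == "B", 3, 1) * dsrc + rnorm(2 * n, sd = 0.2)
  expr <- rbind(DS = dsrc, DT = dtgt,
                F1 = ifelse(grp == "B", 5, 1), F2 = ifelse(grp == "B", 5, 1),
                F3 = ifelse(grp == "B", 5, 1), F4 = ifelse(grp == "B", 5, 1),
                F5 = ifelse(grp == "B", 5, 1), F6 = ifelse(grp == "B", 5, 1))
  colnames(expr) <- sprintf("S%02d", 1:(2 * n))
  md <- suppressMessages(deggs:::build_sample_metadata(
    colnames(expr), grp, "group"))
  net <- as_meta_network(data.frame(source = c("DS", "F1", "F3", "F5"),
                                    target = c("DT", "F2", "F4", "F6"),
                                    directed = TRUE))
  prof <- optimize_percolation_threshold(net, expr, md,
                                         grid = c(20, 30, 40),
                                         robust = FALSE)
  expect_true(all(prof$sig_count == 1L))
  expect_equal(prof$chosen, 20)
  # degenerate all-zero case: smallest grid value wins
  null_sim <- simulate_dataset(simulation_spec(
    n_genes = 12L, n_samples_per_group = c(A = 8L, B = 8L),
    network_edges = 6L, n_differential_edges = 0L,
    low_expression_fraction = 0, seed = 2))
  prof0 <- optimize_percolation_threshold(
    null_sim$network, null_sim$expr, null_sim$metadata,
    grid = seq(0, 90, 10), alpha = 1e-12, robust = FALSE)
  expect_equal(prof0$chosen, 0)
})
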