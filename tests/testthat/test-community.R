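test_that("tabu search respects optima and climbs from singletons", {
  tri2 <- two_triangles()
  opt <- c(1, 1, 1, 2, 2, 2)
  out <- tabu_local_search(tri2, opt)
  expect_equal(unname(out), opt)
  expect_equal(modularity_q(tri2, out), 0.5)

  up <- tabu_local_search(tri2, 1:6)
  expect_equal(unname(up), opt)

  # feasible start: returned Q never lower
  withr::with_seed(21, {
    for (rep in 1:10) {
      net <- random_connected_graph(7)
      start <- rep(1, 7)  # single community is always connected
      ref <- tabu_local_search(net, start)
      expect_gte(modularity_q(net, ref), modularity_q(net, start) - 1e-12)
    }
  })
})

test_that("the disconnectivity penalty counts violating communities", {
  tri2 <- two_triangles()
  # {1,4} spans the two components: one disconnected community
  lab <- c(1L, 2L, 2L, 1L, 3L, 3L)
  expect_equal(mfmicd:::count_disconnected_communities(lab, tri2$adj), 1L)
  expect_equal(mfmicd:::count_disconnected_communities(
    c(1L, 1L, 1L, 2L, 2L, 2L), tri2$adj), 0L)
  # lambda = 0 removes the penalty from the objective entirely: a
  # disconnected optimum-Q labelling scores plain Q under lambda 0
  bridged <- two_triangles_bridged()
  s <- tabu_local_search(bridged, c(1, 1, 1, 2, 2, 2), max_gen = 0,
                         lambda = 0)
  expect_equal(unname(s), c(1, 1, 1, 2, 2, 2))
})

test_that("mfmicd solves the two-triangle graph and traces its search", {
  tri2 <- two_triangles()
  fit <- mfmicd(tri2, pop_size = 30, max_gen_global = 15, seed = 1)
  expect_s3_class(fit, "mfmicd")
  expect_equal(fit$q, 0.5)
  expect_equal(unname(fit$membership), c(1, 1, 1, 2, 2, 2))
  expect_equal(fit$n_communities, 2)
  # reported Q equals an independent recomputation
  expect_equal(fit$q, modularity_q(tri2, fit$membership))
  # elitism: best Q non-decreasing over generations
  expect_true(all(diff(fit$trace$best_q) >= -1e-12))
  expect_equal(nrow(fit$trace), 15)
  expect_true(all(fit$trace$pc >= 0.5 & fit$trace$pc <= 0.99))
  expect_true(all(fit$trace$pm >= 0.01 & fit$trace$pm <= 0.5))
})

test_that("every fitted membership is a valid partition", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      net <- random_connected_graph(sample(5:8, 1))
      fit <- mfmicd(net, pop_size = 20, max_gen_global = 10, seed = rep)
      m <- fit$membership
      expect_length(m, net$n_nodes)
      expect_equal(names(m), net$node_names)
      expect_setequal(unique(unname(m)), seq_len(max(m)))
    }
  })
})

test_that("fits are bit-identical under the same seed", {
  net <- withr::with_seed(41, random_connected_graph(8))
  f1 <- mfmicd(net, pop_size = 30, max_gen_global = 10, seed = 123)
  f2 <- mfmicd(net, pop_size = 30, max_gen_global = 10, seed = 123)
  expect_identical(f1$membership, f2$membership)
  expect_identical(f1$q, f2$q)
  expect_identical(f1$trace, f2$trace)
})

test_that("multi-run fits report cross-run stability", {
  tri2 <- two_triangles()
  fit <- mfmicd(tri2, pop_size = 20, max_gen_global = 10, runs = 3, seed = 2)
  expect_equal(fit$stability_nmi, 1)  # trivial graph: every run agrees
  expect_equal(fit$q, 0.5)
  one <- mfmicd(tri2, pop_size = 20, max_gen_global = 5, seed = 2)
  expect_true(is.na(one$stability_nmi))
})

test_that("S3 methods print, summarise, tabulate and plot", {
  fit <- mfmicd(two_triangles(), pop_size = 20, max_gen_global = 5, seed = 3)
  expect_output(print(fit), "modularity Q = 0.5000")
  expect_output(print(summary(fit)), "community sizes: 3, 3")
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 6)
  expect_equal(df$community, c(1, 1, 1, 2, 2, 2))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
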