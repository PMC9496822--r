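test_that("identifier-passing initialisation copies neighbour ids only", {
  edgeless <- binary_network(matrix(integer(0), ncol = 2), n_nodes = 4)
  pop <- withr::with_seed(1, initialize_population(edgeless, 5))
  expect_true(all(pop == matrix(1:4, 5, 4, byrow = TRUE)))

  k3 <- binary_network(rbind(c(1, 2), c(1, 3), c(2, 3)))
  popk <- withr::with_seed(2, initialize_population(k3, 50))
  expect_true(all(popk %in% 1:3))

  # labels never cross connected components
  tri2 <- two_triangles()
  withr::with_seed(3, {
    for (rep in 1:20) {
      p <- initialize_population(tri2, 50)
      expect_true(all(p[, 1:3] %in% 1:3))
      expect_true(all(p[, 4:6] %in% 4:6))
    }
  })
  expect_error(initialize_population(tri2, 1), "at least 2")
})

test_that("fitness calibration shifts to a zero minimum", {
  expect_equal(calibrated_fitness(c(-0.1, 0.2, 0.5)), c(0, 0.3, 0.6))
  expect_equal(calibrated_fitness(c(0.4, 0.4)), c(0, 0))
  withr::with_seed(4, {
    for (rep in 1:10) {
      f <- calibrated_fitness(stats::rnorm(20))
      expect_equal(min(f), 0)
      expect_true(all(f >= 0))
    }
  })
  expect_error(calibrated_fitness(numeric(0)), "empty")
})

test_that("convergence rate and dynamic rates follow the inverse schedule", {
  expect_equal(convergence_rate(c(1, 2, 3)), 1)
  expect_equal(convergence_rate(c(0, 1)), 0.5)
  expect_identical(convergence_rate(c(2, 2, 2)), Inf)

  wide <- list(pm = c(0.001, 0.999), pc = c(0.001, 0.999))
  r1 <- dynamic_rates(1, wide$pm, wide$pc)
  expect_equal(r1$pm, 0.5)
  expect_equal(r1$pc, 0.5)
  # phi = 0 -> pm = 1 before clamping -> upper pm bound
  r0 <- dynamic_rates(0)
  expect_equal(r0$pm, 0.5)
  expect_equal(r0$pc, 0.5)
  # converged sentinel -> lower pm bound
  rinf <- dynamic_rates(Inf)
  expect_equal(rinf$pm, 0.01)
  expect_equal(rinf$pc, 0.99)
  # complementarity when no clamp binds
  for (phi in c(0.5, 1, 2, 5)) {
    r <- dynamic_rates(phi, wide$pm, wide$pc)
    expect_equal(r$pm + r$pc, 1, tolerance = 1e-12)
  }
})

test_that("roulette selection is fitness-proportional", {
  expect_error(roulette_select(c(1, -1), 2), "non-negative")
  withr::with_seed(11, {
    draws <- roulette_select(c(1, 3), 1e5)
    freq <- tabulate(draws, 2) / 1e5
    expect_equal(freq, c(0.25, 0.75), tolerance = 0.01)
    # degenerate all-zero fitness falls back to uniform
    u <- tabulate(roulette_select(c(0, 0, 0, 0), 4e4), 4) / 4e4
    expect_equal(u, rep(0.25, 4), tolerance = 0.02)
  })
})

test_that("circular crossover swaps the [cut1, cut2) wrapping segment", {
  # hand-traced wrap: length 6, cuts (4, 1) -> 0-based positions {4, 5, 0}
  expect_equal(mfmicd:::circular_segment(4, 1, 6), c(5L, 6L, 1L))
  expect_equal(mfmicd:::circular_segment(1, 4, 6), c(2L, 3L, 4L))
  expect_equal(mfmicd:::circular_segment(3, 3, 6), integer(0))
  expect_equal(mfmicd:::circular_segment(4, 0, 6), c(5L, 6L))

  pop <- rbind(rep(1L, 6), rep(2L, 6), rep(3L, 6), rep(4L, 6))
  fit <- c(4, 3, 2, 1)
  # pc = 0: offspring are the parents (in fitness order)
  off0 <- withr::with_seed(5, strongest_first_crossover(pop, fit, 0))
  expect_equal(off0, pop)
  # identical parents: crossover is invisible
  same <- rbind(c(1L, 2L, 1L), c(1L, 2L, 1L))
  offs <- withr::with_seed(6, strongest_first_crossover(same, c(1, 1), 1))
  expect_equal(offs, same)
  # crossing pairs exchange whole-segment content: the multiset of labels
  # at each locus across a pair is conserved
  off1 <- withr::with_seed(7, strongest_first_crossover(pop, fit, 1))
  for (p in 1:2) {
    a <- off1[2 * p - 1, ]; b <- off1[2 * p, ]
    expect_true(all(sort(c(a[1], b[1])) == sort(c(2 * p - 1, 2 * p))))
    expect_equal(a + b, rep((2 * p - 1) + 2 * p, 6))
  }
  # odd population: last member passes through unchanged
  off_odd <- withr::with_seed(8, strongest_first_crossover(
    pop[1:3, ], fit[1:3], 1))
  expect_equal(off_odd[3, ], pop[3, ])
})

test_that("mutation is neighbour-constrained", {
  tri2 <- two_triangles()
  chrom <- c(1L, 1L, 1L, 4L, 4L, 4L)
  expect_equal(withr::with_seed(1, mutate_chromosome(chrom, 0, tri2)), chrom)
  edgeless <- binary_network(matrix(integer(0), ncol = 2), n_nodes = 6)
  expect_equal(withr::with_seed(1, mutate_chromosome(chrom, 1, edgeless)),
               chrom)
  # mutated labels always come from the closed neighbourhood's labels
  withr::with_seed(12, {
    for (rep in 1:50) {
      net <- random_connected_graph(6)
      src <- sample.int(6, 6, replace = TRUE)
      out <- mutate_chromosome(src, 0.8, net)
      for (v in 1:6) {
        expect_true(out[v] %in% src[c(v, net$adj[[v]])])
      }
    }
  })
})

test_that("the immune operator never degrades and tends to help", {
  tri2 <- two_triangles()
  q_of <- function(pop) apply(pop, 1, function(l) modularity_q(tri2, l))
  # identical members: vaccination is a no-op
  pop_same <- matrix(rep(c(1L, 1L, 1L, 2L, 2L, 2L), 5), 5, byrow = TRUE)
  out_same <- withr::with_seed(1, immune_operator(pop_same, q_of(pop_same),
                                                  tri2))
  expect_equal(out_same$pop, pop_same)

  withr::with_seed(13, {
    gains <- replicate(100, {
      pop <- rbind(c(1L, 1L, 1L, 2L, 2L, 2L),
                   matrix(sample.int(6, 4 * 6, replace = TRUE), 4))
      q <- q_of(pop)
      out <- immune_operator(pop, q, tri2)
      # per-member Q never decreases, best member untouched
      expect_true(all(out$raw_q >= q - 1e-12))
      expect_equal(out$pop[which.max(q), ], pop[which.max(q), ])
      mean(out$raw_q) - mean(q)
    })
    expect_gte(mean(gains), 0)
  })
})
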