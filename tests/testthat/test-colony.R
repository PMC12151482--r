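test_that("deterministic timer colonies form full binary trees", {
  p <- pt_params()
  for (gens in c(4, 6)) {
    snap <- simulate_colony(p, partition_model(1),
                            cycle_model("timer", cv2_tau = 0),
                            stop = list(generations = gens), seed = gens,
                            synthesis = "deterministic")
    expect_identical(snap$n_cells, as.integer(2^gens))
    expect_false(snap$truncated)
    cells <- snap$cells
    # every divided cell has exactly two daughters
    divided <- cells$cell[!is.na(cells$division_time)]
    kids <- table(cells$parent[!is.na(cells$parent)])
    expect_true(all(kids == 2))
    expect_setequal(as.integer(names(kids)), divided)
  }
})

test_that("all live cells are advanced to the exact snapshot time", {
  # with no synthesis and perfect splitting, every cell holds x0*exp(-g*T)
  p <- burst_params(0, 10, log(2), k = 0)
  snap <- simulate_colony(p, partition_model(0),
                          cycle_model("timer", cv2_tau = 1),
                          stop = list(time = 3), x0 = 64, seed = 1,
                          synthesis = "bursty")
  live <- snap$cells[snap$cells$alive, ]
  expect_equal(live$x, rep(64 * exp(-log(2) * 3), nrow(live)),
               tolerance = 1e-10)
  expect_true(all(live$birth_time <= 3))
})

test_that("population growth rate matches gamma in the unregulated model", {
  p <- burst_params(10, 10, 1, k = 0)
  snaps <- simulate_colonies(150, p, stop = list(time = 4.5), seed = 2)
  fit <- estimate_growth_rate(snaps)
  expect_lt(abs(fit$mu - 1), 0.05)
})

test_that("pooled feedback colonies match the stationary population law", {
  p <- fb_params()
  plaw <- stationary_law(p, "population")
  snaps <- simulate_colonies(120, p, stop = list(time = 6),
                             x0 = function(n) rstationary(n, plaw),
                             seed = 3)
  pool <- pool_cells(snaps)
  expect_gt(nrow(pool), 3000)
  expect_lt(ks_distance(pool$x, plaw), 0.05)
  ps <- population_stats(snaps, n_boot = 100)
  expect_lt(abs(ps$mean - 84.0), 3 * ps$se_mean)
})

test_that("deterministic cell cycles equalize noise across perspectives", {
  p <- pt_params()
  pm <- partition_model(1)
  cyc <- cycle_model("timer", cv2_tau = 0)
  sc <- summary_stats(
    simulate_partition_ensemble(p, pm, cyc, n = 4000, n_generations = 6,
                                seed = 4)$x,
    n_boot = 100
  )
  snaps <- simulate_colonies(250, p, pm, cyc, stop = list(generations = 6),
                             synthesis = "deterministic", seed = 5)
  pop <- population_stats(snaps, n_boot = 100)
  expect_lt(abs(pop$cv2 - sc$cv2), 3 * se_diff(pop$se_cv2, sc$se_cv2))
})

test_that("population noise rises with cell-cycle noise while lineage noise is flat", {
  p <- pt_params()
  pm <- partition_model(1)
  grid <- c(0, 0.25, 0.5, 1)
  sc_cv2 <- pop_cv2 <- pop_se <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cyc <- cycle_model("timer", cv2_tau = grid[i])
    sc_cv2[i] <- summary_stats(
      simulate_partition_ensemble(p, pm, cyc, n = 3000, n_generations = 6,
                                  seed = 20 + i)$x,
      n_boot = 0
    )$cv2
    ps <- population_stats(
      simulate_colonies(150, p, pm, cyc, stop = list(generations = 6),
                        synthesis = "deterministic", seed = 30 + i),
      n_boot = 50
    )
    pop_cv2[i] <- ps$cv2
    pop_se[i] <- ps$se_cv2
  }
  expect_true(all(diff(pop_cv2) > 0))
  # lineage noise flat at the predicted level
  pred <- predicted_partition_cv2(20, 1, 0)
  expect_true(all(abs(sc_cv2 - pred) < 0.15 * pred))
  # population noise roughly twice the lineage noise at exponential cycles
  expect_gt(pop_cv2[4] / sc_cv2[4], 1.6)
  expect_lt(pop_cv2[4] / sc_cv2[4], 2.4)
})

test_that("constant dilution with coupled bursts equalizes the perspectives", {
  p <- burst_params(8, 10, log(2), k = 0.02, burst_mode = "growth_coupled",
                    dilution_mode = "constant")
  sc <- simulate_feedback_ensemble(p, 3000, t_end = 40, x0 = 0, seed = 6)
  snaps <- simulate_colonies(150, p, stop = list(generations = 6), x0 = 0,
                             seed = 7)
  pool <- pool_cells(snaps)
  ecdf_pool <- stats::ecdf(pool$x)
  expect_lt(ks_distance(sc$x, function(q) ecdf_pool(q)), 0.05)
  cmp <- compare_perspectives(summary_stats(sc$x, n_boot = 100),
                              population_stats(snaps, n_boot = 100))
  expect_lt(abs(cmp$ratio[cmp$metric == "mean"] - 1),
            3 * cmp$se_ratio[cmp$metric == "mean"])
})

test_that("population mean plateaus where the lineage mean diverges", {
  p <- burst_params(1.2, 10, 1, k = 0.2)
  expect_identical(existence_status(p), "population_only")
  pop_means <- vapply(c(8, 16), function(tt) {
    population_stats(simulate_colonies(80, p, stop = list(time = tt),
                                       x0 = 0, seed = 8),
                     n_boot = 0)$mean
  }, numeric(1))
  sc_means <- vapply(c(8, 16), function(tt) {
    mean(simulate_feedback_ensemble(p, 600, t_end = tt, x0 = 0, seed = 9,
                                    cap = 1e12)$x)
  }, numeric(1))
  analytic <- stationary_moments(p, "population")$mean
  # population stays near its stationary mean; lineage keeps growing
  expect_lt(pop_means[2], 1.3 * analytic)
  expect_lt(pop_means[2] / pop_means[1], sc_means[2] / sc_means[1])
  expect_gt(sc_means[2] / sc_means[1], 1.5)
})

test_that("adder size control amplifies population noise with added-size noise", {
  p <- pt_params()
  pm <- partition_model(1)
  res <- lapply(c(0.25, 1), function(cv2a) {
    cyc <- cycle_model("adder", cv2_added = cv2a)
    list(
      sc = summary_stats(
        simulate_partition_ensemble(p, pm, cyc, n = 2500,
                                    n_generations = 6, seed = 40)$x,
        n_boot = 50
      ),
      pop = population_stats(
        simulate_colonies(150, p, pm, cyc, stop = list(generations = 6),
                          synthesis = "deterministic", seed = 41),
        n_boot = 50
      )
    )
  })
  expect_gt(res[[2]]$pop$cv2, res[[1]]$pop$cv2)
  expect_gt(res[[2]]$pop$cv2,
            res[[2]]$sc$cv2 +
              2 * se_diff(res[[2]]$pop$se_cv2, res[[2]]$sc$se_cv2))
})

test_that("newick export round-trips through ape", {
  p <- pt_params()
  # progenitor only
  snap0 <- simulate_colony(p, partition_model(0),
                           cycle_model("timer", cv2_tau = 0),
                           stop = list(time = 0.5), seed = 1,
                           synthesis = "deterministic")
  expect_identical(snap0$n_cells, 1L)
  tr0 <- ape::read.tree(text = export_lineage_newick(snap0))
  expect_identical(length(tr0$tip.label), 1L)
  # one division: a two-leaf cherry whose branch lengths are daughter ages
  snap1 <- simulate_colony(p, partition_model(0),
                           cycle_model("timer", cv2_tau = 0),
                           stop = list(time = 1.5), seed = 2,
                           synthesis = "deterministic")
  tree1 <- ape::read.tree(text = export_lineage_newick(snap1))
  expect_identical(length(tree1$tip.label), 2L)
  live1 <- snap1$cells[snap1$cells$alive, ]
  expect_equal(sort(tree1$edge.length),
               sort(snap1$time - live1$birth_time))
  # leaf count equals live-cell count in a branching colony
  snap <- simulate_colony(p, partition_model(1),
                          cycle_model("timer", cv2_tau = 1),
                          stop = list(generations = 4), seed = 3,
                          synthesis = "deterministic")
  tree <- ape::read.tree(text = export_lineage_newick(snap))
  expect_identical(length(tree$tip.label), as.integer(snap$n_cells))
})

test_that("cell caps truncate loudly and max_cells stops at the target size", {
  p <- pt_params()
  snap <- simulate_colony(p, partition_model(0),
                          cycle_model("timer", cv2_tau = 0),
                          stop = list(generations = 6), seed = 4,
                          synthesis = "deterministic", max_cells = 8)
  expect_true(snap$truncated)
  snap2 <- simulate_colony(p, partition_model(0),
                           cycle_model("timer", cv2_tau = 0.5),
                           stop = list(max_cells = 16), seed = 5,
                           synthesis = "deterministic")
  expect_gte(snap2$n_cells, 16L)
  expect_error(
    simulate_colony(p, stop = list(bogus = 1)),
    "stop"
  )
})

test_that("population statistics pool cells with equal weight", {
  cells <- tibble::tibble(colony = c(1, 1, 2), x = c(5, 5, 5))
  ps <- population_stats(cells, n_boot = 0)
  expect_equal(ps$mean, 5)
  expect_equal(ps$cv2, 0)
  expect_error(population_stats(tibble::tibble(colony = integer(),
                                               x = numeric())),
               "no live cells")
})
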