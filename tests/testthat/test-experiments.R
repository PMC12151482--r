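test_that("experiment configs validate their inputs", {
  expect_error(experiment_config("not_an_experiment"), "unknown experiment")
  expect_error(experiment_config("adder", 1, 1, NULL, 5), "named")
  cfg <- experiment_config("cycle_noise_sweep", seed = 3, scale = 0.5)
  expect_s3_class(cfg, "experiment_config")
  expect_identical(cfg$seed, 3L)
})

test_that("experiments reproduce bit-identically under a fixed seed", {
  cfg <- experiment_config("cycle_noise_sweep", seed = 7, scale = 0.03,
                           cv2_tau_grid = c(0, 1), generations = 4)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$tables, r2$tables)
})

test_that("feedback sweep reduces to the unregulated law at k = 0", {
  res <- run_experiment("feedback_sweep", seed = 1, scale = 0.1,
                        k_grid = c(0, 0.01), t_colony = 6)
  tab <- res$tables$stats
  k0 <- tab[tab$k == 0, ]
  expect_equal(k0$cv2[k0$source == "analytic"], rep(0.1, 2),
               tolerance = 1e-10)
  expect_true(all(abs(k0$cv2[k0$source == "simulation"] - 0.1) < 0.03))
  # under feedback the simulated population mean drops below the lineage mean
  kf <- tab[tab$k == 0.01 & tab$source == "simulation", ]
  expect_lt(kf$mean[kf$perspective == "population"],
            kf$mean[kf$perspective == "single_cell"])
})

test_that("cycle-noise sweep shows a flat lineage curve and rising population curve", {
  res <- run_experiment("cycle_noise_sweep", seed = 2, scale = 0.1,
                        cv2_tau_grid = c(0, 1))
  tab <- res$tables$stats
  sc <- tab[tab$perspective == "single_cell", ]
  pop <- tab[tab$perspective == "population", ]
  pred <- predicted_partition_cv2(20, 1, 0)
  expect_true(all(abs(sc$cv2 - pred) < 0.2 * pred))
  expect_gt(pop$cv2[pop$cv2_tau == 1], pop$cv2[pop$cv2_tau == 0])
  expect_gt(pop$cv2[pop$cv2_tau == 1] / sc$cv2[sc$cv2_tau == 1], 1.5)
})

test_that("noise scales inversely with the mean in both perspectives", {
  res <- run_experiment("mean_scaling", seed = 3, scale = 0.06,
                        mean_grid = c(5, 50))
  tab <- res$tables$stats
  for (persp in c("single_cell", "population")) {
    sub <- tab[tab$perspective == persp, ]
    ratio <- sub$cv2[sub$target_mean == 5] / sub$cv2[sub$target_mean == 50]
    expect_gt(ratio, 5) # exact inverse scaling gives 10
    expect_lt(ratio, 20)
  }
})

test_that("degradation drives both perspectives to the unregulated gamma law", {
  res <- run_experiment("degradation_sweep", seed = 4, scale = 0.3,
                        d_grid = c(0, 20))
  tab <- res$tables$stats
  expect_lt(tab$ks_to_gamma[tab$d == 20], tab$ks_to_gamma[tab$d == 0])
  expect_lt(tab$ks_to_gamma[tab$d == 20], 0.08)
})

test_that("growth-coupled burst frequency keeps the perspectives close", {
  res <- run_experiment("growth_coupled", seed = 5, scale = 0.15)
  cmp <- res$tables$comparison
  mean_ratio <- cmp$ratio[cmp$metric == "mean"]
  expect_gt(mean_ratio, 0.7)
  expect_lt(mean_ratio, 1.05)
})

test_that("experiment tables and config are written to the output directory", {
  out <- withr::local_tempdir()
  run_experiment(experiment_config("cycle_noise_sweep", seed = 6,
                                   scale = 0.03, cv2_tau_grid = c(0, 1),
                                   generations = 4, out_dir = out))
  files <- list.files(out)
  expect_true("cycle_noise_sweep_stats.tsv" %in% files)
  expect_true("cycle_noise_sweep_config.txt" %in% files)
  tab <- utils::read.delim(file.path(out, "cycle_noise_sweep_stats.tsv"))
  expect_true(all(c("cv2_tau", "perspective", "cv2") %in% names(tab)))
})

test_that("writers emit parseable TSV for trajectories and snapshots", {
  p <- pt_params()
  tr <- simulate_lineage_partitioning(p, partition_model(1),
                                      cycle_model("timer", cv2_tau = 1),
                                      n_generations = 4, seed = 1)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, f1)
  back <- utils::read.delim(f1)
  expect_named(back, c("time", "concentration", "event_flag"))
  expect_identical(nrow(back), nrow(tr))

  snap <- simulate_colony(p, partition_model(1),
                          cycle_model("timer", cv2_tau = 0),
                          stop = list(generations = 3), seed = 2,
                          synthesis = "deterministic")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_snapshot_tsv(snap, f2)
  back2 <- utils::read.delim(f2)
  expect_true(all(c("colony_id", "cell_id", "parent_id", "birth_time",
                    "concentration") %in% names(back2)))
  expect_identical(nrow(back2), nrow(snap$cells))
})

test_that("plot helpers return ggplot objects", {
  p <- fb_params()
  gg1 <- autoplot(stationary_law(p, "single_cell"),
                  other = stationary_law(p, "population"))
  expect_s3_class(gg1, "ggplot")
  stats <- tibble::tibble(
    cv2_tau = rep(c(0, 1), 3),
    perspective = rep(c("single_cell", "population", "analytic_sc"),
                      each = 2),
    cv2 = c(0.036, 0.036, 0.036, 0.072, 0.036, 0.036)
  )
  expect_s3_class(plot_cycle_noise(stats), "ggplot")
  ms <- tibble::tibble(target_mean = c(5, 50, 5, 50),
                       perspective = rep(c("single_cell", "population"),
                                         each = 2),
                       cv2 = c(0.14, 0.014, 0.28, 0.028))
  expect_s3_class(plot_noise_vs_mean(ms), "ggplot")
  tr <- simulate_lineage_feedback(p, t_end = 5, x0 = 100, seed = 1)
  expect_s3_class(plot_trajectory(tr), "ggplot")
})
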