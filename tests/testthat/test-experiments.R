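test_that("Pielou evenness matches direct evaluation and its conventions", {
  expect_equal(shannon_evenness(c(5, 5, 5, 5)), 1)
  # direct evaluation of H / ln S for [10, 1]
  p <- c(10, 1) / 11
  expect_equal(shannon_evenness(c(10, 1)), -sum(p * log(p)) / log(2))
  expect_equal(round(shannon_evenness(c(10, 1)), 4), 0.4395)
  expect_equal(shannon_evenness(7), 1)  # single-species convention
  expect_error(shannon_evenness(numeric(0)), "empty")
  expect_error(shannon_evenness(c(3, 0)), "positive")
  set.seed(1)
  for (i in 1:20) {
    ab <- sample(1:50, sample(1:12, 1), replace = TRUE)
    j <- shannon_evenness(ab)
    expect_gte(j, 0); expect_lte(j, 1)
  }
})

test_that("experiment configurations encode the full-scale designs", {
  c1 <- experiment_config(1, scale = 1)
  expect_identical(c1$grid, 100L)
  expect_identical(c1$slots, 100L)
  expect_length(c1$energy_levels, 29)
  expect_identical(c1$replicates_per_level, 4L)
  expect_identical(length(c1$energy_levels) * c1$replicates_per_level, 116L)
  expect_identical(c1$duration, 45000L)
  c3 <- experiment_config(3, scale = 1, long_duration = TRUE)
  expect_identical(c3$duration, 450000L)
  c4 <- experiment_config(4, scale = 1)
  expect_length(c4$refresh_treatments, 2)
  expect_true(is.infinite(c4$refresh_treatments[1]))
  expect_identical(c4$refresh_treatments[2], 200)
  expect_length(c4$energy_levels, 52)
  c5 <- experiment_config(5, scale = 1)
  expect_length(c5$energy_levels, 5)
  expect_identical(c5$extinction_horizon, 500L)
  expect_identical(c5$size_class_width_extinction, 20L)
  expect_identical(c5$sample_window, c(60000L, 90000L))
  c6 <- experiment_config(6, scale = 1)
  expect_identical(c6$size_class_width_speciation, 500L)
  c7 <- experiment_config(7, scale = 1)
  expect_length(c7$energy_levels, 97)
  expect_identical(length(c7$energy_levels) * c7$replicates_per_level, 1552L)
  c8 <- experiment_config(8, scale = 1)
  expect_identical(c8$evenness_energy_cutoff, 2000)
  expect_error(experiment_config(9), "unknown")
  expect_error(experiment_config(1, duration = 100,
                                 sample_window = c(50, 200)), "window")
})

test_that("scaling shrinks grid, energies, durations and class widths together", {
  c5 <- experiment_config(5, scale = 0.2)
  expect_identical(c5$grid, 20L)
  expect_identical(c5$slots, 20L)
  expect_identical(c5$extinction_horizon, 100L)
  expect_identical(c5$size_class_width_extinction, 4L)
  expect_identical(c5$size_class_width_speciation, 100L)
  expect_equal(c5$energy_levels, c(800, 1200, 1600, 2000, 2400) * 0.2)
  st <- mihsim:::.config_settings(c5, 100, 1)
  expect_equal(st$breed_threshold, 100)
  expect_equal(st$breed_cost, 100)
})

test_that("snapshot metrics are internally consistent and match the logs", {
  s <- sim_settings(grid_width = 10, grid_height = 10, slots_per_cell = 8,
                    energy_per_cell = 80, breed_threshold = 40,
                    breed_cost = 40, rng_seed = 31)
  w <- create_world(s, masks = generate_masks(3),
                    environment = generate_ps(3, 10, 10))
  seed_world(w)
  run_simulation(w, 200)
  m <- metrics_snapshot(w)
  expect_equal(m$mean_species_size * m$species_richness, m$total_abundance)
  o <- organisms(w)
  expect_identical(m$total_abundance, as.numeric(nrow(o)))
  expect_identical(m$species_richness, length(unique(o$species_id)))
  expect_equal(m$mean_individual_fitness, mean(o$fitness))
  # snapshot right after a logging pass agrees with the last log row
  wl <- simulation_log(w)
  expect_identical(tail(wl$total_abundance, 1), m$total_abundance)
  expect_identical(tail(wl$species_richness, 1), m$species_richness)
})

# hand-built survey fixture: two runs at different energies with known
# species trajectories
fixture_result <- function() {
  cfg <- experiment_config(5, scale = 0.2, energy_levels = c(100, 200),
                           duration = 1000, sample_window = c(100, 200),
                           extinction_horizon = 100,
                           size_class_width_extinction = 20,
                           size_class_width_speciation = 20)
  mk_log <- function(rows) do.call(rbind, lapply(rows, function(r)
    data.frame(iteration = r[[1]], species_id = r[[2]],
               parent_species_id = NA_integer_, abundance = r[[3]],
               mean_energy = 0)))
  # run 1 (energy 100): species 0 persists; species 1 dies at iteration 250;
  # species 2 appears at 150 as a daughter of 0 and dies at 300
  log1 <- mk_log(list(list(100, 0, 15), list(100, 1, 30),
                      list(150, 0, 25), list(150, 1, 10), list(150, 2, 3),
                      list(200, 0, 45), list(200, 2, 2)))
  reg1 <- data.frame(species_id = c(0L, 1L, 2L),
                     parent_species_id = c(NA, 0L, 0L),
                     origin_iteration = c(0, 50, 150),
                     extinction_iteration = c(NA, 250, 300),
                     last_seen_iteration = c(1000, 200, 250))
  # run 2 (energy 200): one species, never extinct
  log2 <- mk_log(list(list(100, 0, 50), list(150, 0, 55), list(200, 0, 60)))
  reg2 <- data.frame(species_id = 0L, parent_species_id = NA_integer_,
                     origin_iteration = 0,
                     extinction_iteration = NA_real_,
                     last_seen_iteration = 1000)
  structure(list(config = cfg,
                 runs = data.frame(run = 1:2, energy = c(100, 200),
                                   replicate = 1L, treatment = "default",
                                   seed = 1:2, richness = c(2L, 1L),
                                   abundance = c(47, 60),
                                   mean_fitness = 7, mean_species_size = 20,
                                   mean_evenness = 0.9),
                 world_logs = list(NULL, NULL),
                 species_logs = list(log1, log2),
                 registries = list(reg1, reg2),
                 niche_count = NA_integer_),
            class = "experiment_result")
}

test_that("the extinction survey bins observations and averages outcomes correctly", {
  res <- fixture_result()
  sv <- extinction_survey(res)
  # run 1 observations (horizon 100):
  #   t=100: sp0 size 15 (ext? 0), sp1 size 30 (ext at 250 > 200: 0)
  #   t=150: sp0 25 (0), sp1 10 (ext at 250 <= 250: 1), sp2 3 (ext 300 > 250: 0)
  #   t=200: sp0 45 (0), sp2 2 (ext at 300 <= 300: 1)
  # run 2: three observations of sizes 50, 55, 60, none extinct
  bc <- sv$by_class
  expect_identical(bc$size_class, c(1L, 2L, 3L))
  # class 1 (sizes 1..20): 15(0), 10(1), 3(0), 2(1) -> mean 0.5, n 4
  expect_equal(bc$mean_extinction[bc$size_class == 1], 0.5)
  expect_identical(bc$n[bc$size_class == 1], 4)
  # class 2 (21..40): 30(0), 25(0) -> 0
  expect_equal(bc$mean_extinction[bc$size_class == 2], 0)
  # class 3 (41..60): 45(0), 50(0), 55(0), 60(0)
  expect_identical(bc$n[bc$size_class == 3], 4)
  ce <- sv$by_class_energy
  expect_equal(ce$rel_mid, ce$class_mid / ce$energy)
  # class midpoints follow the (p-1)w+1 .. pw convention
  expect_equal(unique(ce$class_mid[ce$size_class == 1]), 10.5)
  # truncation drops high classes
  sv2 <- extinction_survey(res, max_size_class = 1)
  expect_identical(sv2$by_class$size_class, 1L)
  # a window that cannot resolve the horizon is an error
  bad <- res
  bad$config$sample_window <- c(100, 1000)
  expect_error(extinction_survey(bad), "horizon")
})

test_that("the speciation survey counts daughters at the next logging step", {
  res <- fixture_result()
  sp <- speciation_survey(res)
  # daughters: species 2 originates at t=150 with parent 0, so the t=100
  # observation of species 0 (size 15, class 1) contributes 1 daughter;
  # every other observation contributes 0. (t=200 has no next step.)
  bc <- sp$by_class
  # class 1 at t=100: sp0 (1 daughter), plus t=150 sp1 size 10 (0), sp2 3 (0)
  expect_equal(bc$mean_daughters[bc$size_class == 1], 1 / 3)
  expect_identical(bc$n[bc$size_class == 1], 3)
  expect_equal(bc$mean_daughters[bc$size_class == 2], 0)
  # registry-diff oracle: total daughters equal new registry entries whose
  # origin lies at a sampled next step
  tot <- sum(bc$mean_daughters * bc$n)
  expect_equal(tot, 1)
})

test_that("a miniature richness experiment produces coherent tables", {
  cfg <- experiment_config(1, scale = 0.12, energy_levels = c(40, 80),
                           replicates_per_level = 1, duration = 400,
                           base_seed = 5)
  res <- run_experiment(cfg)
  expect_s3_class(res, "experiment_result")
  expect_identical(nrow(res$runs), 2L)
  expect_identical(res$runs$energy, c(40, 80))
  expect_false(is.na(res$niche_count))
  expect_length(res$species_logs, 2)
  expect_length(res$registries, 2)
  # richness column equals distinct species in the final logging row
  sl <- res$species_logs[[2]]
  last <- max(sl$iteration)
  expect_identical(res$runs$richness[2],
                   length(unique(sl$species_id[sl$iteration == last &
                                                 sl$abundance > 0])))
})

test_that("a miniature disturbance experiment runs both refresh treatments", {
  cfg <- experiment_config(4, scale = 0.12, energy_levels = 60,
                           replicates_per_level = 1, duration = 300,
                           sample_window = c(200, 300), base_seed = 2)
  res <- run_experiment(cfg)
  expect_identical(nrow(res$runs), 2L)
  expect_setequal(res$runs$treatment, c("static", "200"))
})
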