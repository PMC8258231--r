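test_that("seeding fills the central cell with viable clones", {
  s <- sim_settings(grid_width = 9, grid_height = 9, slots_per_cell = 7,
                    energy_per_cell = 100, rng_seed = 3)
  w <- create_world(s)
  seed_world(w)
  o <- organisms(w)
  expect_identical(nrow(o), 7L)
  expect_identical(unique(o$x), 4L)  # 0-based centre of a 9-cell axis
  expect_identical(unique(o$y), 4L)
  expect_identical(length(unique(o$genome)), 1L)
  expect_true(all(o$fitness >= 1))
  expect_true(all(o$energy == 0) && all(o$age == 0) && all(o$species_id == 0))
  expect_error(seed_world(w), "already seeded")
})

test_that("energy is apportioned proportionally to fitness within each cell", {
  # blue4 masks + black frame: coding popcount p gives bitcount 3p + 4,
  # so p = 19 -> 61 -> fitness 10 and p = 24 -> 76 -> fitness 5
  w <- bench_world(masks = blue4_masks(), energy = 300)
  insert_organism(w, 1, 1, genome_with_popcount(19), energy = 0)
  insert_organism(w, 1, 1, genome_with_popcount(24), energy = 0)
  o <- organisms(w)
  expect_identical(sort(o$fitness), c(5L, 10L))
  run_phase(w, "provision")
  o <- organisms(w)
  expect_equal(o$energy[o$fitness == 10], 200)
  expect_equal(o$energy[o$fitness == 5], 100)
  # a sole occupant with positive fitness receives the full provision
  insert_organism(w, 2, 2, genome_with_popcount(19), energy = 0)
  run_phase(w, "provision")
  o <- organisms(w)
  expect_equal(o$energy[o$x == 2], 300)
  # a cell whose occupants all have fitness zero distributes nothing
  w0 <- bench_world(masks = zero_masks(), energy = 300)
  insert_organism(w0, 0, 0, genome_with_popcount(0), energy = 5)  # bitcount 0
  expect_identical(organisms(w0)$fitness, 0L)
  run_phase(w0, "provision")
  expect_equal(organisms(w0)$energy, 5)
})

test_that("the breed list admits only organisms strictly above the threshold", {
  w <- bench_world(breed_threshold = 100, breed_cost = 50)
  g <- genome_with_popcount(22)  # fitness 15 under zero masks
  insert_organism(w, 1, 1, g, energy = 100)   # exactly at threshold: excluded
  insert_organism(w, 1, 1, g, energy = 100)
  run_phase(w, "breed")
  expect_identical(mihsim:::world_pending_count(w$ptr), 0L)
  expect_equal(organisms(w)$energy, c(100, 100))
  # above the threshold both breed
  w2 <- bench_world(breed_threshold = 100, breed_cost = 50)
  insert_organism(w2, 1, 1, g, energy = 101)
  insert_organism(w2, 1, 1, g, energy = 101)
  run_phase(w2, "breed")
  expect_identical(mihsim:::world_pending_count(w2$ptr), 2L)
  expect_equal(organisms(w2)$energy, c(51, 51))
})

test_that("failed breeding attempts cost nothing", {
  g <- genome_with_popcount(22)
  # singleton breed list
  w <- bench_world()
  insert_organism(w, 1, 1, g, energy = 500)
  run_phase(w, "breed")
  expect_identical(mihsim:::world_pending_count(w$ptr), 0L)
  expect_equal(organisms(w)$energy, 500)
  # genetically incompatible pair (distance 5 > max_breed_difference 2)
  far <- paste0(strrep("1", 22), strrep("0", 10), "11111", strrep("0", 27))
  expect_identical(genome_hamming(g, far), 5L)
  w2 <- bench_world()
  insert_organism(w2, 1, 1, g, energy = 500)
  insert_organism(w2, 1, 1, far, energy = 500)
  run_phase(w2, "breed")
  expect_identical(mihsim:::world_pending_count(w2$ptr), 0L)
  expect_equal(organisms(w2)$energy, c(500, 500))
  # hybridization prohibited: same genome, different species IDs
  w3 <- bench_world(allow_hybridization = FALSE)
  insert_organism(w3, 1, 1, g, energy = 500, species_id = 0)
  insert_organism(w3, 1, 1, g, energy = 500, species_id = 1)
  run_phase(w3, "breed")
  expect_identical(mihsim:::world_pending_count(w3$ptr), 0L)
  expect_equal(organisms(w3)$energy, c(500, 500))
  # with hybridization allowed the same pair breeds
  w4 <- bench_world(allow_hybridization = TRUE)
  insert_organism(w4, 1, 1, g, energy = 500, species_id = 0)
  insert_organism(w4, 1, 1, g, energy = 500, species_id = 1)
  run_phase(w4, "breed")
  expect_identical(mihsim:::world_pending_count(w4$ptr), 2L)
})

test_that("offspring genomes recombine fairly and mutate at most one bit", {
  p1 <- random_genome(1, seed = 55)
  p2 <- random_genome(1, seed = 56)
  d12 <- genome_hamming(p1, p2)
  kids <- make_offspring(p1, p2, mutation_chance = 0, n = 200, seed = 57)
  # exhaustive bit accounting: child bits come from one parent or the other
  expect_true(all(genome_hamming(kids, p1) + genome_hamming(kids, p2) == d12))
  # both parents actually contribute (fair per-bit choice)
  expect_gt(length(unique(genome_hamming(kids, p1))), 5)
  # identical parents, no mutation: clones
  expect_identical(unique(make_offspring(p1, p1, 0, n = 50, seed = 58)), p1)
  # forced mutation: exactly one bit differs from the recombinant
  mut <- make_offspring(p1, p1, mutation_chance = 1, n = 100, seed = 59)
  expect_true(all(genome_hamming(mut, p1) == 1L))
})

test_that("dispersal follows the truncated inverse-distance kernel", {
  # scale 0: offspring always stay in the parent cell
  d0 <- dispersal_draws(10, 10, 4, 7, scale = 0, n = 200, seed = 1)
  expect_true(all(d0$x == 4 & d0$y == 7))
  # chi-square goodness of fit against the analytic kernel, interior parent
  W <- 21; H <- 21; px <- 10; py <- 10; scale <- 3
  draws <- dispersal_draws(W, H, px, py, scale, n = 1e5, seed = 42)
  offs <- expand.grid(dx = -scale:scale, dy = -scale:scale)
  offs$d <- sqrt(offs$dx^2 + offs$dy^2)
  offs <- offs[offs$d <= scale, ]
  offs$w <- 1 / (1 + offs$d)
  key <- paste(px + offs$dx, py + offs$dy)
  counts <- table(factor(paste(draws$x, draws$y), levels = key))
  expect_identical(sum(counts), 100000L)  # nothing outside the kernel
  gof <- suppressWarnings(chisq.test(as.vector(counts), p = offs$w / sum(offs$w)))
  expect_gt(gof$p.value, 0.01)
  # corner parent: all targets in-grid, kernel renormalized over in-grid cells
  cd <- dispersal_draws(10, 10, 0, 0, scale = 3, n = 2e4, seed = 7)
  expect_true(all(cd$x >= 0 & cd$y >= 0 & cd$x < 10 & cd$y < 10))
  ok <- offs$dx >= 0 & offs$dy >= 0
  key2 <- paste(offs$dx[ok], offs$dy[ok])
  counts2 <- table(factor(paste(cd$x, cd$y), levels = key2))
  expect_identical(sum(counts2), 20000L)
  gof2 <- suppressWarnings(chisq.test(as.vector(counts2),
                                      p = offs$w[ok] / sum(offs$w[ok])))
  expect_gt(gof2$p.value, 0.01)
})

test_that("organisms die when their age exceeds the maximum lifespan", {
  w <- bench_world()
  g <- genome_with_popcount(22)
  insert_organism(w, 1, 1, g, age = 15)  # at the lifespan limit
  insert_organism(w, 2, 2, g, age = 0)
  run_phase(w, "age")
  o <- organisms(w)
  expect_identical(nrow(o), 1L)
  expect_identical(o$age, 1L)
})

test_that("slots freed by death are settleable within the same iteration", {
  # a full 2-slot cell of breeders at the lifespan limit: their offspring
  # (dispersal scale 0) settle into the slots the parents vacate
  w <- bench_world(slots = 2, breed_threshold = 100, breed_cost = 50,
                   mutation_chance = 0, dispersal_scale = 0)
  g <- genome_with_popcount(22)
  insert_organism(w, 1, 1, g, energy = 200, age = 15)
  insert_organism(w, 1, 1, g, energy = 200, age = 15)
  step_world(w)
  o <- organisms(w)
  expect_identical(nrow(o), 2L)
  expect_true(all(o$age == 0))
  expect_true(all(o$energy == 0))
  expect_identical(unique(o$genome), g)
})

test_that("settlement fails at capacity or zero fitness", {
  # target cell full: offspring die, occupancy unchanged
  w <- bench_world(slots = 2, breed_threshold = 100, breed_cost = 50,
                   mutation_chance = 0, dispersal_scale = 0)
  g <- genome_with_popcount(22)
  insert_organism(w, 1, 1, g, energy = 200, age = 1)
  insert_organism(w, 1, 1, g, energy = 200, age = 1)
  step_world(w)
  o <- organisms(w)
  expect_identical(nrow(o), 2L)
  expect_true(all(o$age == 2))  # the original pair, one iteration older
  # unfit offspring die: parents fit only in their own cell colour
  s <- sim_settings(grid_width = 3, grid_height = 1, slots_per_cell = 4,
                    energy_per_cell = 300, breed_threshold = 100,
                    breed_cost = 50, mutation_chance = 0,
                    dispersal_scale = 1, rng_seed = 2)
  # masks: all-zero below brightness 100, 16 leading ones above, so the
  # centre (black) suits the test genome and the bright flanks do not
  hi <- paste0(strrep("1", 16), strrep("0", 16))
  bright_masks <- mask_set(rep(c(rep(strrep("0", 32), 100), rep(hi, 156)), 3))
  fr <- array(200L, c(1, 3, 3)); fr[1, 2, ] <- 0L
  w2 <- create_world(s, masks = bright_masks,
                     environment = mihsim:::new_env_frame(fr))
  insert_organism(w2, 1, 0, g, energy = 200)
  insert_organism(w2, 1, 0, g, energy = 200)
  step_world(w2)
  o2 <- organisms(w2)
  expect_true(all(o2$x == 1))  # nothing settles on the unfit flanks
})

test_that("an empty world stays empty and a zero-income population dies out", {
  w <- bench_world()
  step_world(w, 50)
  expect_identical(nrow(organisms(w)), 0L)
  s <- sim_settings(grid_width = 8, grid_height = 8, slots_per_cell = 5,
                    energy_per_cell = 1e-6, rng_seed = 4)
  w2 <- create_world(s)
  seed_world(w2)
  step_world(w2, s$max_lifespan + 1)
  expect_identical(nrow(organisms(w2)), 0L)
})

test_that("occupancy, ages and energies respect their invariants over a long run", {
  s <- sim_settings(grid_width = 10, grid_height = 10, slots_per_cell = 6,
                    energy_per_cell = 60, breed_threshold = 30,
                    breed_cost = 30, rng_seed = 12)
  w <- create_world(s, masks = generate_masks(12),
                    environment = generate_ps(12, 10, 10))
  seed_world(w)
  for (k in 1:10) {
    run_simulation(w, 100, record = FALSE)
    o <- organisms(w)
    if (nrow(o) == 0) break
    expect_lte(nrow(o), 10 * 10 * 6)
    expect_lte(max(table(paste(o$x, o$y))), 6)
    expect_true(all(o$energy >= 0))
    expect_true(all(o$age <= s$max_lifespan))
  }
})

test_that("without mutation a clonal population stays genetically identical", {
  s <- sim_settings(grid_width = 8, grid_height = 8, slots_per_cell = 6,
                    energy_per_cell = 240, breed_threshold = 40,
                    breed_cost = 40, mutation_chance = 0, rng_seed = 21)
  env <- generate_ps(21, 8, 8)
  masks <- generate_masks(21)
  founder <- find_fittest_genome(masks, unclass(env)[5, 5, ], s, seed = 21)
  w <- create_world(s, masks = masks, environment = env)
  seed_world(w, founder = founder)
  run_simulation(w, 300, record = FALSE)
  o <- organisms(w)
  expect_gt(nrow(o), 0)
  expect_identical(unique(o$genome), founder)
  info <- metrics_snapshot(w)
  expect_identical(info$species_richness, 1L)
})

test_that("runs are deterministic and logging does not perturb the trajectory", {
  mk <- function(record) {
    s <- sim_settings(grid_width = 10, grid_height = 10, slots_per_cell = 8,
                      energy_per_cell = 80, breed_threshold = 40,
                      breed_cost = 40, rng_seed = 77)
    w <- create_world(s, masks = generate_masks(7),
                      environment = generate_ps(7, 10, 10))
    seed_world(w)
    run_simulation(w, 400, record = record)
    w
  }
  a <- mk(TRUE); b <- mk(TRUE); c <- mk(FALSE)
  expect_identical(simulation_log(a), simulation_log(b))
  expect_identical(species_abundance_log(a), species_abundance_log(b))
  expect_identical(organisms(a), organisms(b))
  # observer non-interference: recording off leaves the state unchanged
  expect_identical(organisms(a), organisms(c))
  expect_identical(nrow(simulation_log(c)), 0L)
  # logging happens at multiples of the logging interval
  expect_identical(simulation_log(a)$iteration, seq(50, 400, by = 50))
})
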