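#' Create a simulation world
#'
#' Binds settings, masks and an environment into a runnable world. The world
#' starts empty; call [seed_world()] to place the founding clones and
#' [run_simulation()] to iterate. All randomness is drawn from a single
#' stream seeded by `seed`, so `(seed, settings, environment)` fully
#' determine the trajectory.
#'
#' @param settings A [sim_settings()] object.
#' @param masks A `mask_set` (defaults to masks generated from the world
#'   seed).
#' @param environment An `env_frame` (static) or [env_sequence()]. Defaults
#'   to a PS frame matching the grid, generated from the world seed.
#' @param seed Integer seed for the run (defaults to `settings$rng_seed`).
#' @return A `sim_world` handle.
#' @export
#' @examples
#' s <- sim_settings(grid_width = 10, grid_height = 10, slots_per_cell = 10,
#'                   energy_per_cell = 100)
#' w <- create_world(s)
#' seed_world(w)
#' run_simulation(w, 100)
#' metrics_snapshot(w)
create_world <- function(settings, masks = NULL, environment = NULL,
                         seed = settings$rng_seed) {
  stopifnot(inherits(settings, "sim_settings"))
  if (is.null(masks)) masks <- generate_masks(seed)
  stopifnot(inherits(masks, "mask_set"))
  if (is.null(environment))
    environment <- generate_ps(seed, settings$grid_width,
                               settings$grid_height)
  if (inherits(environment, "env_frame"))
    environment <- env_sequence(environment,
                                refresh_interval = settings$env_refresh_interval,
                                interpolate = settings$interpolate_environment)
  stopifnot(inherits(environment, "env_sequence"))
  d <- dim(environment$frames[[1]])
  if (d[1] != settings$grid_height || d[2] != settings$grid_width)
    stop("environment dimensions must match the simulation grid",
         call. = FALSE)
  ptr <- world_create(unclass(settings), unclass(masks),
                      lapply(environment$frames, unclass),
                      environment$refresh_interval,
                      environment$interpolate, environment$cyclic,
                      as.numeric(seed))
  structure(list(ptr = ptr, settings = settings, masks = masks,
                 environment = environment, seed = seed),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  s <- x$settings
  info <- world_info(x$ptr)
  cat(sprintf("Simulation world: %d x %d cells, %d slots, energy %g\n",
              s$grid_width, s$grid_height, s$slots_per_cell,
              s$energy_per_cell))
  cat(sprintf("  iteration %d: %d organisms, %d species\n",
              as.integer(info$iteration), as.integer(info$total_abundance),
              info$species_richness))
  invisible(x)
}

#' Seed a world with founding clones
#'
#' Fills every slot of the central cell with clones of one uniformly drawn
#' genome that qualifies there (genomes are redrawn until one qualifies, up
#' to `max_tries`). By default a genome qualifies when its fitness in the
#' seed cell is positive; `min_fitness` can raise the bar, which gives the
#' founding population a viability margin in environments whose colours
#' drift during the establishment phase. Founders have energy 0, age 0 and
#' species ID 0.
#'
#' @param world A `sim_world`.
#' @param max_tries Cap on founder genome draws before failing.
#' @param min_fitness Minimum founder fitness in the seed cell (default 1).
#' @param founder Optional explicit founder genome (64-bit string with
#'   positive fitness in the seed cell), e.g. from
#'   [find_fittest_genome()]; overrides the random search.
#' @return The world, invisibly.
#' @export
seed_world <- function(world, max_tries = 100000L, min_fitness = 1L,
                       founder = NULL) {
  stopifnot(inherits(world, "sim_world"))
  if (is.null(founder))
    world_seed(world$ptr, as.integer(max_tries), as.integer(min_fitness))
  else
    world_seed_genome(world$ptr, founder)
  invisible(world)
}

#' Advance a world
#'
#' `step_world()` runs bare iterations (energy provisioning, breeding,
#' ageing/death, settlement) without any logging or species detection;
#' `run_simulation()` runs `n_iterations` iterations and applies the species
#' delimitation pass at every logging iteration, accumulating the world and
#' species logs.
#'
#' @param world A seeded `sim_world`.
#' @param n,n_iterations Number of iterations to run.
#' @param record Keep log rows? Species delimitation runs at logging
#'   iterations regardless, so recording never alters the trajectory.
#' @return The world, invisibly.
#' @export
step_world <- function(world, n = 1) {
  stopifnot(inherits(world, "sim_world"))
  world_step(world$ptr, as.integer(n))
  invisible(world)
}

#' @rdname step_world
#' @export
run_simulation <- function(world, n_iterations, record = TRUE) {
  stopifnot(inherits(world, "sim_world"))
  world_run(world$ptr, as.integer(n_iterations), isTRUE(record))
  invisible(world)
}

#' Inspect the living organisms of a world
#'
#' @param world A `sim_world`.
#' @return A data frame with one row per living organism: grid position
#'   (0-based `x`, `y`), `slot`, `genome` (64-bit string), `energy`, `age`,
#'   `species_id` and cached `fitness`.
#' @export
organisms <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  world_state(world$ptr)
}

#' Species registry of a run
#'
#' @param world A `sim_world`.
#' @return A data frame of species records: `species_id`,
#'   `parent_species_id` (NA for the founder), `origin_iteration`,
#'   `extinction_iteration` (NA while extant) and `last_seen_iteration`.
#' @export
species_registry <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  world_registry(world$ptr)
}

#' Accumulated logs of a run
#'
#' `simulation_log()` returns the world-level log (one row per logging
#' iteration: total abundance, species richness, mean fitness, Pielou
#' evenness); `species_abundance_log()` the per-species log (abundance and
#' mean energy per species per logging iteration).
#'
#' @param world A `sim_world`.
#' @return A data frame.
#' @export
simulation_log <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  world_log(world$ptr)
}

#' @rdname simulation_log
#' @export
species_abundance_log <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  world_species_log(world$ptr)
}

#' Snapshot metrics of a world
#'
#' @param world A `sim_world`.
#' @return A list with `species_richness`, `total_abundance`,
#'   `mean_individual_fitness` and `mean_species_size`
#'   (abundance/richness); the means are `NA` for an empty world.
#' @export
metrics_snapshot <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  info <- world_info(world$ptr)
  list(species_richness = info$species_richness,
       total_abundance = info$total_abundance,
       mean_individual_fitness = info$mean_fitness,
       mean_species_size = if (info$species_richness > 0)
         info$total_abundance / info$species_richness else NA_real_)
}

#' Sample offspring dispersal targets
#'
#' Draws settlement targets for offspring of a parent at `(x, y)` from the
#' discrete dispersal kernel: weight proportional to `1 / (1 + d)` for
#' centre-to-centre Euclidean distance `d <= scale`, renormalized over
#' in-grid cells (so the parent cell itself, at `d = 0`, is always a
#' possible target).
#'
#' @param width,height Grid dimensions.
#' @param x,y Parent position (0-based).
#' @param scale Kernel truncation radius in cells.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A data frame with columns `x` and `y` (0-based targets).
#' @export
dispersal_draws <- function(width, height, x, y, scale, n, seed = 1) {
  m <- cpp_dispersal_draws(as.integer(width), as.integer(height),
                           as.integer(x), as.integer(y), as.integer(scale),
                           as.integer(n), as.numeric(seed))
  data.frame(x = m[, 1], y = m[, 2])
}

#' Simulate offspring genome construction
#'
#' Each offspring bit is drawn fairly from the corresponding parental bits;
#' then, with probability `mutation_chance`, exactly one uniformly chosen
#' bit is flipped.
#'
#' @param p1,p2 Parent genomes (64-bit strings).
#' @param mutation_chance Per-offspring single-bit mutation probability.
#' @param n Number of offspring to draw.
#' @param seed Integer seed.
#' @return Character vector of offspring genomes.
#' @export
make_offspring <- function(p1, p2, mutation_chance = 0, n = 1, seed = 1) {
  cpp_make_offspring(p1, p2, as.numeric(mutation_chance),
                     as.numeric(seed), as.integer(n))
}
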