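#' Simulation settings
#'
#' Collects the parameters of the individual-based model into a validated
#' settings object. The fitness function is tent-shaped: an organism whose
#' coding bitcount (see [coding_bitcount()]) equals `fitness_target` has
#' fitness `settle_tolerance`; fitness falls by one per bit of mismatch and is
#' clamped at zero.
#'
#' Defaults follow the standard configuration of the model: a 100 x 100 grid
#' of cells with 100 organism slots each, tent parameters 15/66, a maximum
#' lifespan of 15 iterations, logging every 50 iterations, and environment
#' refresh every 100 iterations with linear colour interpolation. The
#' breeding economy (`breed_threshold`, `breed_cost`), `mutation_chance`,
#' `max_breed_difference` and `dispersal_scale` have no single canonical
#' values; the defaults here are the package's documented calibration, chosen
#' so that mid-range energy levels sustain persistent, speciating populations
#' (see the package vignette).
#'
#' @param grid_width,grid_height Grid dimensions in cells.
#' @param slots_per_cell Organism capacity of each cell.
#' @param energy_per_cell Energy provisioned to every cell each iteration
#'   (the productivity / energy-level parameter).
#' @param settle_tolerance Peak fitness value (default 15).
#' @param fitness_target Coding bitcount at which fitness peaks (default 66).
#' @param breed_threshold Energy an organism must exceed to enter its cell's
#'   breed list.
#' @param breed_cost Energy the initiating organism pays for a successful
#'   breeding attempt. Must not exceed `breed_threshold` so energy can never
#'   go negative.
#' @param mutation_chance Probability that an offspring genome has exactly
#'   one uniformly chosen bit flipped.
#' @param max_breed_difference Maximum full-genome Hamming distance (bits)
#'   at which two organisms can interbreed.
#' @param max_lifespan Maximum organism age in iterations (default 15).
#' @param logging_interval Iterations between logging/speciation passes.
#' @param env_refresh_interval Iterations between environment key frames.
#' @param interpolate_environment Linearly interpolate colours between
#'   temporally adjacent key frames?
#' @param allow_hybridization May organisms carrying different species IDs
#'   interbreed (when genetically compatible)?
#' @param dispersal_scale Truncation radius (cells) of the dispersal kernel.
#' @param rng_seed Integer seed for the run's random stream.
#'
#' @return A list of class `sim_settings`.
#' @seealso [create_world()], [fitness()]
#' @export
#' @examples
#' s <- sim_settings(grid_width = 10, grid_height = 10, slots_per_cell = 5,
#'                   energy_per_cell = 100)
#' s$fitness_target
sim_settings <- function(grid_width = 100,
                         grid_height = 100,
                         slots_per_cell = 100,
                         energy_per_cell = 1000,
                         settle_tolerance = 15,
                         fitness_target = 66,
                         breed_threshold = 500,
                         breed_cost = 500,
                         mutation_chance = 0.68,
                         max_breed_difference = 2,
                         max_lifespan = 15,
                         logging_interval = 50,
                         env_refresh_interval = 100,
                         interpolate_environment = TRUE,
                         allow_hybridization = TRUE,
                         dispersal_scale = 1,
                         rng_seed = 1L) {
  s <- list(
    grid_width = as.integer(grid_width),
    grid_height = as.integer(grid_height),
    slots_per_cell = as.integer(slots_per_cell),
    energy_per_cell = as.numeric(energy_per_cell),
    settle_tolerance = as.integer(settle_tolerance),
    fitness_target = as.integer(fitness_target),
    breed_threshold = as.numeric(breed_threshold),
    breed_cost = as.numeric(breed_cost),
    mutation_chance = as.numeric(mutation_chance),
    max_breed_difference = as.integer(max_breed_difference),
    max_lifespan = as.integer(max_lifespan),
    logging_interval = as.integer(logging_interval),
    env_refresh_interval = as.integer(env_refresh_interval),
    interpolate_environment = isTRUE(interpolate_environment),
    allow_hybridization = isTRUE(allow_hybridization),
    dispersal_scale = as.integer(dispersal_scale),
    rng_seed = as.integer(rng_seed)
  )
  pos <- c("grid_width", "grid_height", "slots_per_cell", "energy_per_cell",
           "settle_tolerance", "fitness_target", "breed_threshold",
           "breed_cost", "max_lifespan", "logging_interval",
           "env_refresh_interval")
  for (nm in pos)
    if (!is.finite(s[[nm]]) || s[[nm]] <= 0)
      stop("'", nm, "' must be strictly positive", call. = FALSE)
  if (s$mutation_chance < 0 || s$mutation_chance > 1)
    stop("'mutation_chance' must lie in [0, 1]", call. = FALSE)
  if (s$settle_tolerance > s$fitness_target)
    stop("'settle_tolerance' must not exceed 'fitness_target'", call. = FALSE)
  if (s$max_breed_difference < 0 || s$max_breed_difference > 64)
    stop("'max_breed_difference' must lie in 0..64", call. = FALSE)
  if (s$dispersal_scale < 0)
    stop("'dispersal_scale' must be non-negative", call. = FALSE)
  if (s$breed_cost > s$breed_threshold)
    stop("'breed_cost' must not exceed 'breed_threshold'", call. = FALSE)
  class(s) <- "sim_settings"
  s
}

#' @export
print.sim_settings <- function(x, ...) {
  cat("Simulation settings\n")
  cat(sprintf("  grid: %d x %d cells, %d slots each\n",
              x$grid_width, x$grid_height, x$slots_per_cell))
  cat(sprintf("  energy per cell: %g; breed threshold/cost: %g/%g\n",
              x$energy_per_cell, x$breed_threshold, x$breed_cost))
  cat(sprintf("  fitness: tolerance %d, target %d; lifespan %d\n",
              x$settle_tolerance, x$fitness_target, x$max_lifespan))
  cat(sprintf("  mutation %g, max breed difference %d bits, dispersal scale %d\n",
              x$mutation_chance, x$max_breed_difference, x$dispersal_scale))
  invisible(x)
}

#' Random genomes
#'
#' Draws uniformly random 64-bit genomes, returned as 64-character binary
#' strings. The first 32 characters form the coding half used by the fitness
#' function; the full string counts toward breeding compatibility.
#'
#' @param n Number of genomes.
#' @param seed Integer seed (independent of R's RNG state).
#' @return Character vector of 64-character `"0"`/`"1"` strings.
#' @export
#' @examples
#' random_genome(2, seed = 1)
random_genome <- function(n = 1, seed = 1) {
  cpp_random_genomes(as.integer(n), as.numeric(seed))
}

#' Hamming distance between bit strings
#'
#' @param a,b Character vectors of equal-length binary strings (recycled if
#'   one has length 1).
#' @return Integer vector of pairwise Hamming distances.
#' @export
#' @examples
#' genome_hamming("0011", "0101")
genome_hamming <- function(a, b) {
  cpp_bit_hamming(as.character(a), as.character(b))
}

#' Coding bitcount of a genome in a given environment colour
#'
#' XORs the 32-bit coding half of each genome with the three channel masks
#' selected by the cell colour and sums the set bits, giving a value between
#' 0 and 96. The tent-shaped fitness function is evaluated on this count.
#'
#' @param genome Character vector of 64-bit genome strings.
#' @param colour Integer vector `c(r, g, b)`, each channel 0..255.
#' @param masks A [mask_set] (see [generate_masks()]).
#' @return Integer vector of bitcounts in 0..96.
#' @export
#' @examples
#' m <- generate_masks(seed = 1)
#' coding_bitcount(random_genome(3, seed = 2), c(10, 200, 30), m)
coding_bitcount <- function(genome, colour, masks) {
  stopifnot(inherits(masks, "mask_set"))
  cpp_coding_bitcount(as.character(genome), as.integer(colour),
                      unclass(masks))
}

#' Organism fitness
#'
#' Fitness is `settle_tolerance - |fitness_target - coding_bitcount|`,
#' clamped below at zero. With the default tolerance 15 and target 66 this
#' gives integral values in 0..15; most random genomes score zero in a given
#' colour, so there are far more ways to be unfit than optimally fit.
#'
#' @inheritParams coding_bitcount
#' @param settings A [sim_settings] object (supplies the tent parameters).
#' @return Integer vector of fitness values in `0..settle_tolerance`.
#' @export
#' @examples
#' m <- generate_masks(seed = 1)
#' s <- sim_settings()
#' fitness(random_genome(5, seed = 3), c(0, 0, 0), m, s)
fitness <- function(genome, colour, masks, settings = sim_settings()) {
  bc <- coding_bitcount(genome, colour, masks)
  pmax(0L, settings$settle_tolerance - abs(settings$fitness_target - bc))
}

#' Search for a genome near the fitness optimum of a colour
#'
#' Deterministic greedy hill climb on the coding half: starting from a
#' seeded random genome, single-bit flips that move the coding bitcount
#' toward `fitness_target` are applied until the tent peak (or a plateau)
#' is reached, with seeded restarts. Useful for constructing founder
#' genomes whose establishment does not depend on the luck of the random
#' search, and for building worked examples.
#'
#' @param masks A `mask_set`.
#' @param colour Integer `c(r, g, b)` cell colour.
#' @param settings A [sim_settings()] (tent parameters).
#' @param seed Integer seed for the start points.
#' @param restarts Number of restarts before accepting the best genome seen.
#' @return A 64-character genome string.
#' @export
find_fittest_genome <- function(masks, colour, settings = sim_settings(),
                                seed = 1, restarts = 20) {
  stopifnot(inherits(masks, "mask_set"))
  target <- settings$fitness_target
  best_g <- NULL
  best_d <- Inf
  for (r in seq_len(restarts)) {
    g <- random_genome(1, seed + r - 1)
    bits <- strsplit(g, "")[[1]]
    bc <- coding_bitcount(g, colour, masks)
    repeat {
      if (bc == target) break
      improved <- FALSE
      for (i in 1:32) {
        cand <- bits
        cand[i] <- if (bits[i] == "1") "0" else "1"
        cg <- paste(cand, collapse = "")
        cbc <- coding_bitcount(cg, colour, masks)
        if (abs(cbc - target) < abs(bc - target)) {
          bits <- cand; g <- cg; bc <- cbc; improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    if (abs(bc - target) < best_d) {
      best_d <- abs(bc - target)
      best_g <- g
    }
    if (best_d == 0) break
  }
  best_g
}
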