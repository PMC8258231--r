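# Shared fixtures: engineered mask sets and genomes with known bitcounts,
# plus small world builders. With an all-zero mask set and a black cell the
# coding bitcount is 3 * popcount(coding half), so fitness can be pinned to
# chosen values exactly.

zero_masks <- function() {
  mask_set(rep(strrep("0", 32), 768))
}

# masks whose blue channel has popcount 4 at every brightness: bitcount of a
# left-packed coding half with p ones (p <= 28) is 3p + 4 under black
blue4_masks <- function() {
  blue <- paste0(strrep("0", 28), "1111")
  mask_set(c(rep(strrep("0", 32), 512), rep(blue, 256)))
}

# genome whose coding half is p ones then zeros; neutral half all zeros
genome_with_popcount <- function(p, neutral = strrep("0", 32)) {
  paste0(strrep("1", p), strrep("0", 32 - p), neutral)
}

black_frame <- function(w, h) {
  mihsim:::new_env_frame(array(0L, dim = c(h, w, 3L)))
}

# a tiny world over a black frame with all-zero (or given) masks, empty
# until organisms are inserted through the test hook
bench_world <- function(width = 4, height = 4, slots = 4, energy = 300,
                        breed_threshold = 100, breed_cost = 50,
                        mutation_chance = 0, max_breed_difference = 2,
                        dispersal_scale = 0, masks = zero_masks(),
                        allow_hybridization = TRUE, seed = 1) {
  s <- sim_settings(grid_width = width, grid_height = height,
                    slots_per_cell = slots, energy_per_cell = energy,
                    breed_threshold = breed_threshold, breed_cost = breed_cost,
                    mutation_chance = mutation_chance,
                    max_breed_difference = max_breed_difference,
                    dispersal_scale = dispersal_scale,
                    allow_hybridization = allow_hybridization,
                    rng_seed = seed)
  create_world(s, masks = masks, environment = black_frame(width, height))
}

insert_organism <- function(world, x, y, genome, energy = 0, age = 0,
                            species_id = 0) {
  mihsim:::world_insert(world$ptr, x, y, genome, energy, age, species_id)
  invisible(world)
}

run_phase <- function(world, phase) {
  mihsim:::world_phase(world$ptr, phase)
  invisible(world)
}

# independent per-character oracle for Hamming distance
naive_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# independent per-bit oracle for the coding bitcount
naive_bitcount <- function(genome, colour, masks) {
  coding <- strsplit(substr(genome, 1, 32), "")[[1]]
  total <- 0L
  for (ch in 1:3) {
    mask <- strsplit(unclass(masks)[colour[ch] + 1, ch], "")[[1]]
    total <- total + sum(coding != mask)
  }
  total
}

# Independent oracle: transitive closure of the pairwise compatibility
# relation (matrix reachability), versus the union-find / graph-component
# implementation.
closure_partition <- function(genomes, maxdiff) {
  n <- length(genomes)
  adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    naive_hamming(genomes[i], genomes[j]) <= maxdiff))
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # label by first reachable member
  apply(reach, 1, function(r) which(r)[1])
}

same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

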