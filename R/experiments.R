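# Experiment orchestration: configurable-scale versions of the eight study
# designs, plus the extinction and speciation surveys computed from run logs.

#' Pielou's evenness of a community
#'
#' Shannon entropy of the relative abundances divided by `log(S)`. A
#' single-species community is defined to have evenness 1 (documented
#' convention; the ratio is 0/0 there).
#'
#' @param abundances Positive integer vector of per-species abundances.
#' @return Evenness in `[0, 1]`.
#' @export
#' @examples
#' shannon_evenness(c(5, 5, 5, 5))  # 1
#' shannon_evenness(c(10, 1))
shannon_evenness <- function(abundances) {
  if (length(abundances) == 0) stop("empty abundance vector", call. = FALSE)
  if (any(abundances <= 0)) stop("abundances must be positive", call. = FALSE)
  s <- length(abundances)
  if (s == 1) return(1)
  p <- abundances / sum(abundances)
  H <- -sum(p * log(p))
  H / log(s)
}

#' Configure one of the eight study experiments
#'
#' Builds a validated configuration for a (possibly scaled-down) version of
#' one of the experiment designs: species richness versus energy in
#' environments of known niche availability (1 = PS, 2 = 2x2-expanded PS,
#' 3 = 4x4-expanded PS, with `long_duration` giving the 10x-duration rerun
#' of 3), total abundance under disturbance (4, dynamic lights with a static
#' and a 200-iteration refresh treatment), extinction risk by size class
#' (5, hybridization prohibited), daughter-species production by size class
#' (6), mean species size versus total abundance (7), and community evenness
#' versus energy (8).
#'
#' Scaling shrinks the grid and slot count together (`scale = 0.25` gives a
#' 25 x 25 grid with 25 slots) and scales energy levels and durations in
#' proportion to per-cell capacity; size-class widths scale the same way so
#' classes stay populated. Full scale (`scale = 1`) reproduces the designs
#' as configured for cluster runs: 29 energy levels x 4 replicates for
#' experiments 1-3, 52 levels x 2 treatments x 2 replicates for 4, five
#' single runs for 5-6, and 97 levels x 16 replicates for 7-8.
#'
#' @param experiment Integer 1..8.
#' @param scale Linear scaling fraction (1 = full size).
#' @param energy_levels Energy levels to sweep (defaults per experiment,
#'   pre-scaled).
#' @param replicates_per_level Simulations per energy level (and per
#'   treatment for experiment 4).
#' @param duration Final iteration sampled.
#' @param sample_window `(start, end)` iterations of the survey window
#'   (experiments 5, 6, 8).
#' @param extinction_horizon Iterations ahead used to score a species
#'   extinct (full-scale default 500, scaled with per-cell capacity like
#'   every other duration).
#' @param size_class_width_extinction,size_class_width_speciation Size-class
#'   widths for the surveys (full-scale defaults 20 and 500, scaled with
#'   per-cell capacity).
#' @param refresh_treatments Environment refresh treatments for experiment 4
#'   (`Inf` = static first frame).
#' @param long_duration For experiment 3: sample after 10x the default
#'   duration.
#' @param base_seed Integer; run seeds are derived as `base_seed + run
#'   index`.
#' @param settings Named list of [sim_settings()] overrides.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(experiment,
                              scale = 0.25,
                              energy_levels = NULL,
                              replicates_per_level = NULL,
                              duration = NULL,
                              sample_window = NULL,
                              extinction_horizon = NULL,
                              size_class_width_extinction = NULL,
                              size_class_width_speciation = NULL,
                              refresh_treatments = c(Inf, 200),
                              long_duration = FALSE,
                              base_seed = 1,
                              settings = list()) {
  experiment <- as.integer(experiment)
  if (!experiment %in% 1:8) stop("unknown experiment id", call. = FALSE)
  if (scale <= 0 || scale > 1) stop("'scale' must lie in (0, 1]",
                                    call. = FALSE)
  grid <- max(4L, as.integer(round(100 * scale)))
  slots <- max(4L, as.integer(round(100 * scale)))
  cap <- slots / 100  # per-cell capacity fraction of full scale

  if (is.null(energy_levels)) {
    full <- switch(as.character(experiment),
                   "1" = , "2" = , "3" = seq(100, 2900, by = 100),
                   "4" = seq(50, 2600, by = 50),
                   "5" = , "6" = c(800, 1200, 1600, 2000, 2400),
                   "7" = , "8" = seq(30, 2910, by = 30))
    energy_levels <- full * cap
  }
  if (is.null(replicates_per_level))
    replicates_per_level <- switch(as.character(experiment),
                                   "1" = , "2" = , "3" = 4L,
                                   "4" = 2L,
                                   "5" = , "6" = 1L,
                                   "7" = , "8" = 16L)
  base_duration <- switch(as.character(experiment),
                          "1" = , "2" = , "3" = , "4" = 45000,
                          "5" = , "6" = , "7" = , "8" = 90000)
  if (experiment == 3 && long_duration) base_duration <- 450000
  if (is.null(duration)) duration <- round(base_duration * cap)
  if (is.null(sample_window)) {
    w <- round(c(60000, 90000) * cap)
    sample_window <- c(min(w[1], duration), min(w[2], duration))
  }
  if (is.null(extinction_horizon))
    extinction_horizon <- max(50L, round(500 * cap))
  if (is.null(size_class_width_extinction))
    size_class_width_extinction <- max(2L, round(20 * cap))
  if (is.null(size_class_width_speciation))
    size_class_width_speciation <- max(10L, round(500 * cap))
  evenness_energy_cutoff <- 2000 * cap
  if (sample_window[1] > sample_window[2] || sample_window[2] > duration)
    stop("sample window must lie within the run duration", call. = FALSE)
  if (size_class_width_extinction <= 0 || size_class_width_speciation <= 0)
    stop("size-class widths must be positive", call. = FALSE)

  structure(list(experiment = experiment,
                 scale = scale,
                 grid = grid,
                 slots = slots,
                 energy_levels = as.numeric(energy_levels),
                 replicates_per_level = as.integer(replicates_per_level),
                 duration = as.integer(duration),
                 sample_window = as.integer(sample_window),
                 extinction_horizon = as.integer(extinction_horizon),
                 size_class_width_extinction =
                   as.integer(size_class_width_extinction),
                 size_class_width_speciation =
                   as.integer(size_class_width_speciation),
                 refresh_treatments = refresh_treatments,
                 evenness_energy_cutoff = evenness_energy_cutoff,
                 long_duration = isTRUE(long_duration),
                 base_seed = as.integer(base_seed),
                 settings = settings),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment %d config: scale %.2f (%d x %d grid, %d slots)\n",
              x$experiment, x$scale, x$grid, x$grid, x$slots))
  cat(sprintf("  %d energy level(s) x %d replicate(s), duration %d\n",
              length(x$energy_levels), x$replicates_per_level, x$duration))
  invisible(x)
}

# settings for one run of a config; the breeding economy scales with
# per-cell capacity exactly as the energy levels do, so the per-organism
# iterations-to-breed is invariant under scaling
.config_settings <- function(config, energy, seed, allow_hybridization = TRUE) {
  cap <- config$slots / 100
  args <- list(grid_width = config$grid, grid_height = config$grid,
               slots_per_cell = config$slots, energy_per_cell = energy,
               breed_threshold = 500 * cap, breed_cost = 500 * cap,
               rng_seed = as.integer(seed),
               allow_hybridization = allow_hybridization)
  args[names(config$settings)] <- config$settings
  do.call(sim_settings, args)
}

# run one simulation and harvest its logs; experiments seed with a
# peak-fitness founder so that desk-scale establishment is governed by the
# energy budget rather than founder-neighbourhood luck
.run_single <- function(settings, masks, environment, duration) {
  w <- create_world(settings, masks = masks, environment = environment)
  f0 <- frame_at(environment, 0)
  colour <- unclass(f0)[settings$grid_height %/% 2 + 1,
                        settings$grid_width %/% 2 + 1, ]
  founder <- find_fittest_genome(masks, colour, settings,
                                 seed = settings$rng_seed)
  seed_world(w, founder = founder)
  run_simulation(w, duration)
  list(world_log = simulation_log(w),
       species_log = species_abundance_log(w),
       registry = species_registry(w),
       final = metrics_snapshot(w))
}

#' Run a configured experiment
#'
#' Generates the environment(s) the design calls for, runs every simulation
#' with seeds derived from `base_seed`, and returns per-run summaries plus
#' the raw logs needed by the surveys. Experiments 1-3 use a static PS (or
#' block-expanded PS) frame shared across runs; experiment 4 runs each
#' energy level under each refresh treatment of a lights environment;
#' experiments 5-8 use dynamic lights environments (hybridization is
#' prohibited in experiment 5).
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress progress output?
#' @return A list of class `experiment_result` with elements `config`,
#'   `runs` (one row per simulation: energy, replicate, treatment, seed,
#'   final-state summaries, and sample-window means of abundance and
#'   evenness), `world_logs`, `species_logs`, `registries` (parallel
#'   lists), and `niche_count` for the static environments.
#' @export
run_experiment <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  ex <- config$experiment
  masks <- generate_masks(config$base_seed)

  envs <- list()
  niche_count <- NA_integer_
  if (ex %in% 1:3) {
    k <- c(1L, 2L, 4L)[ex]
    ps <- generate_ps(config$base_seed, config$grid, config$grid)
    frame <- expand_blocks(ps, k)
    envs[["static"]] <- env_sequence(frame)
    niche_count <- count_niches(frame)
  } else if (ex == 4) {
    lights <- generate_lights(config$base_seed, config$grid, config$grid,
                              n_frames = 10, centre_light = TRUE,
                              refresh_interval = 200)
    for (tr in config$refresh_treatments) {
      key <- if (is.infinite(tr)) "static" else as.character(tr)
      envs[[key]] <- if (is.infinite(tr))
        env_sequence(lights$frames[[1]])
      else env_sequence(lights$frames, refresh_interval = tr)
    }
  }

  rows <- list()
  world_logs <- list()
  species_logs <- list()
  registries <- list()
  run_idx <- 0L

  treatments <- if (ex == 4) names(envs) else "default"
  for (tr in treatments) {
    for (energy in config$energy_levels) {
      for (rep_i in seq_len(config$replicates_per_level)) {
        run_idx <- run_idx + 1L
        seed <- config$base_seed + run_idx
        hyb <- !(ex == 5)
        st <- .config_settings(config, energy, seed,
                               allow_hybridization = hyb)
        env <- if (ex %in% 1:3) {
          envs[["static"]]
        } else if (ex == 4) {
          envs[[tr]]
        } else {
          # per-run dynamic lights environment; patches persist for many
          # logging intervals so species dynamics, not habitat turnover,
          # dominate the surveys
          generate_lights(seed, config$grid, config$grid, n_frames = 20,
                          speed = 0.03 * config$grid,
                          lifetime_range = c(10, 20), centre_light = TRUE,
                          refresh_interval = st$env_refresh_interval)
        }
        if (!quiet)
          message(sprintf("run %d: energy %g, treatment %s", run_idx,
                          energy, tr))
        res <- .run_single(st, masks, env, config$duration)
        wl <- res$world_log
        in_window <- wl$iteration >= config$sample_window[1] &
          wl$iteration <= config$sample_window[2]
        rows[[run_idx]] <- data.frame(
          run = run_idx, energy = energy, replicate = rep_i,
          treatment = tr, seed = seed,
          richness = res$final$species_richness,
          abundance = res$final$total_abundance,
          mean_fitness = res$final$mean_individual_fitness,
          mean_species_size = res$final$mean_species_size,
          mean_abundance = if (any(in_window))
            mean(wl$total_abundance[in_window]) else NA_real_,
          mean_evenness = if (any(in_window))
            mean(wl$evenness[in_window], na.rm = TRUE) else NA_real_,
          stringsAsFactors = FALSE)
        world_logs[[run_idx]] <- wl
        species_logs[[run_idx]] <- res$species_log
        registries[[run_idx]] <- res$registry
      }
    }
  }

  structure(list(config = config,
                 runs = do.call(rbind, rows),
                 world_logs = world_logs,
                 species_logs = species_logs,
                 registries = registries,
                 niche_count = niche_count),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment %d result: %d run(s)\n", x$config$experiment,
              nrow(x$runs)))
  if (!is.na(x$niche_count))
    cat("  environment niches:", x$niche_count, "\n")
  print(utils::head(x$runs))
  invisible(x)
}

.class_mid <- function(class_index, width) {
  ((class_index - 1) * width + 1 + class_index * width) / 2
}

#' Extinction survey by species size class
#'
#' For every logging iteration in the sample window, every extant species
#' contributes one observation: its population size and whether it was
#' extinct `extinction_horizon` iterations later (from the run's species
#' registry). Sizes are binned into classes of width
#' `size_class_width_extinction` (class p covers sizes (p-1)w+1 .. pw);
#' binary outcomes are averaged per class, both pooled over runs and per
#' (class, energy level), the latter supporting the relative-size models.
#' Empty classes do not appear.
#'
#' @param result An `experiment_result` (typically experiment 5).
#' @param config Optional config override (defaults to `result$config`).
#' @param max_size_class Drop size classes above this index before
#'   aggregating (large classes carry few observations and substantial
#'   sampling noise; the survey axis is truncated accordingly).
#' @return A list of class `extinction_survey` with data frames
#'   `by_class_energy` (`size_class`, `class_mid`, `energy`, `rel_mid`,
#'   `n`, `mean_extinction`) and `by_class` (pooled over energy levels).
#' @export
extinction_survey <- function(result, config = result$config,
                              max_size_class = Inf) {
  stopifnot(inherits(result, "experiment_result"))
  width <- config$size_class_width_extinction
  horizon <- config$extinction_horizon
  win <- config$sample_window
  if (win[2] + horizon > config$duration)
    stop("sample window plus horizon exceeds the run duration",
         call. = FALSE)
  obs <- list()
  for (i in seq_len(nrow(result$runs))) {
    sl <- result$species_logs[[i]]
    reg <- result$registries[[i]]
    energy <- result$runs$energy[i]
    sel <- sl$iteration >= win[1] & sl$iteration <= win[2] & sl$abundance > 0
    if (!any(sel)) next
    s <- sl[sel, , drop = FALSE]
    ext_iter <- reg$extinction_iteration[match(s$species_id, reg$species_id)]
    extinct <- !is.na(ext_iter) & ext_iter <= s$iteration + horizon &
      ext_iter > s$iteration
    obs[[length(obs) + 1]] <- data.frame(
      energy = energy,
      size = s$abundance,
      size_class = as.integer(ceiling(s$abundance / width)),
      extinct = as.numeric(extinct))
  }
  if (length(obs) == 0) stop("no observations in the sample window",
                             call. = FALSE)
  d <- do.call(rbind, obs)
  d <- d[d$size_class <= max_size_class, , drop = FALSE]
  by_ce <- stats::aggregate(extinct ~ size_class + energy, data = d,
                            FUN = function(v) c(mean(v), length(v)))
  by_ce <- data.frame(size_class = by_ce$size_class,
                      energy = by_ce$energy,
                      mean_extinction = by_ce$extinct[, 1],
                      n = by_ce$extinct[, 2])
  by_ce$class_mid <- .class_mid(by_ce$size_class, width)
  by_ce$rel_mid <- by_ce$class_mid / by_ce$energy
  by_c <- stats::aggregate(extinct ~ size_class, data = d,
                           FUN = function(v) c(mean(v), length(v)))
  by_c <- data.frame(size_class = by_c$size_class,
                     mean_extinction = by_c$extinct[, 1],
                     n = by_c$extinct[, 2])
  by_c$class_mid <- .class_mid(by_c$size_class, width)
  structure(list(by_class_energy =
                   by_ce[order(by_ce$energy, by_ce$size_class), ],
                 by_class = by_c[order(by_c$size_class), ],
                 width = width, horizon = horizon),
            class = "extinction_survey")
}

#' Speciation survey by parent species size class
#'
#' For every logging iteration in the sample window, every extant species
#' contributes its population size and the number of daughter species that
#' first appear (in the registry) at the next logging step with the focal
#' species as parent. Sizes are binned into classes of width
#' `size_class_width_speciation`.
#'
#' @inheritParams extinction_survey
#' @return A list of class `speciation_survey` with data frames
#'   `by_class_energy` and `by_class` (`mean_daughters` per size class).
#' @export
speciation_survey <- function(result, config = result$config) {
  stopifnot(inherits(result, "experiment_result"))
  width <- config$size_class_width_speciation
  win <- config$sample_window
  obs <- list()
  for (i in seq_len(nrow(result$runs))) {
    sl <- result$species_logs[[i]]
    reg <- result$registries[[i]]
    energy <- result$runs$energy[i]
    log_iters <- sort(unique(sl$iteration))
    for (t in log_iters) {
      if (t < win[1] || t > win[2]) next
      nxt <- log_iters[log_iters > t]
      if (length(nxt) == 0) next
      t2 <- nxt[1]
      s <- sl[sl$iteration == t & sl$abundance > 0, , drop = FALSE]
      if (nrow(s) == 0) next
      new_sp <- reg[reg$origin_iteration == t2, , drop = FALSE]
      daughters <- vapply(s$species_id, function(id)
        sum(new_sp$parent_species_id == id, na.rm = TRUE), integer(1))
      obs[[length(obs) + 1]] <- data.frame(
        energy = energy,
        size = s$abundance,
        size_class = as.integer(ceiling(s$abundance / width)),
        daughters = daughters)
    }
  }
  if (length(obs) == 0) stop("no observations in the sample window",
                             call. = FALSE)
  d <- do.call(rbind, obs)
  by_ce <- stats::aggregate(daughters ~ size_class + energy, data = d,
                            FUN = function(v) c(mean(v), length(v)))
  by_ce <- data.frame(size_class = by_ce$size_class,
                      energy = by_ce$energy,
                      mean_daughters = by_ce$daughters[, 1],
                      n = by_ce$daughters[, 2])
  by_ce$class_mid <- .class_mid(by_ce$size_class, width)
  by_ce$rel_mid <- by_ce$class_mid / by_ce$energy
  by_c <- stats::aggregate(daughters ~ size_class, data = d,
                           FUN = function(v) c(mean(v), length(v)))
  by_c <- data.frame(size_class = by_c$size_class,
                     mean_daughters = by_c$daughters[, 1],
                     n = by_c$daughters[, 2])
  by_c$class_mid <- .class_mid(by_c$size_class, width)
  structure(list(by_class_energy =
                   by_ce[order(by_ce$energy, by_ce$size_class), ],
                 by_class = by_c[order(by_c$size_class), ],
                 width = width),
            class = "speciation_survey")
}
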