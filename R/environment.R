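# Environment generators and containers. A frame is an integer array
# [height, width, 3] of 8-bit channel values; a sequence is an ordered list
# of frames plus a refresh interval and interpolation/cycling rules.

# run code under a local, restored R RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

new_env_frame <- function(arr) {
  if (length(dim(arr)) != 3 || dim(arr)[3] != 3)
    stop("a frame must be a [height, width, 3] array", call. = FALSE)
  if (any(arr < 0) || any(arr > 255))
    stop("channel values must lie in 0..255", call. = FALSE)
  storage.mode(arr) <- "integer"
  class(arr) <- "env_frame"
  arr
}

#' @export
print.env_frame <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Environment frame: %d x %d cells, 3 channels (0..%d)\n",
              d[2], d[1], max(x)))
  invisible(x)
}

#' Generate a pure-spatial-heterogeneity (PS) environment frame
#'
#' Every channel of every cell is drawn independently and uniformly from
#' 0..255, then the frame is combined 50/50 with an all-black image (integer
#' floor), so final channel values lie in 0..127. Neighbouring cells are
#' uncorrelated: on a 100 x 100 grid nearly every cell is its own niche
#' (a unique colour region).
#'
#' @param seed Integer seed; reproducible for a given seed.
#' @param width,height Frame dimensions in cells.
#' @return An `env_frame`.
#' @seealso [expand_blocks()], [count_niches()]
#' @export
#' @examples
#' f <- generate_ps(seed = 1, width = 20, height = 20)
#' range(f)  # 0..127
generate_ps <- function(seed = 1, width = 100, height = 100) {
  if (width < 1 || height < 1)
    stop("frame dimensions must be positive", call. = FALSE)
  raw <- with_local_seed(seed, {
    array(sample.int(256L, height * width * 3L, replace = TRUE) - 1L,
          dim = c(height, width, 3L))
  })
  black <- array(0L, dim = c(height, width, 3L))
  combine_frames(new_env_frame(raw), new_env_frame(black), 0.5, 0.5)
}

#' Combine two frames by a per-channel weighted mean
#'
#' Channel values are floored to integers after weighting, matching 8-bit
#' image arithmetic.
#'
#' @param a,b Frames of identical dimensions.
#' @param wa,wb Weights summing to 1.
#' @return An `env_frame`.
#' @export
combine_frames <- function(a, b, wa = 0.5, wb = 0.5) {
  if (!identical(dim(a), dim(b)))
    stop("frames must have identical dimensions", call. = FALSE)
  if (abs(wa + wb - 1) > 1e-9)
    stop("weights must sum to 1", call. = FALSE)
  out <- floor(wa * unclass(a) + wb * unclass(b) + 1e-9)
  new_env_frame(array(as.integer(out), dim = dim(a)))
}

#' Expand single cells into k x k monochromatic blocks
#'
#' Magnifies the top-left (height/k) x (width/k) portion of the frame so
#' that each of its cells becomes a k x k monochromatic tile (tile (i, j)
#' takes the colour of input cell (i, j)). Dimensions are unchanged while
#' the number of distinct niches drops by a factor of ~k^2, and expanding
#' by 2 twice is the same as expanding by 4 once.
#'
#' @param frame An `env_frame`.
#' @param k Block edge length; must divide both dimensions.
#' @return An `env_frame` of the same dimensions.
#' @export
#' @examples
#' f <- generate_ps(1, 8, 8)
#' g <- expand_blocks(f, 2)
expand_blocks <- function(frame, k) {
  d <- dim(frame)
  k <- as.integer(k)
  if (k < 1) stop("'k' must be a positive integer", call. = FALSE)
  if (d[1] %% k != 0 || d[2] %% k != 0)
    stop("'k' must divide both frame dimensions", call. = FALSE)
  if (k == 1) return(frame)
  rows <- ceiling(seq_len(d[1]) / k)
  cols <- ceiling(seq_len(d[2]) / k)
  new_env_frame(unclass(frame)[rows, cols, , drop = FALSE])
}

#' Assemble an environment sequence
#'
#' @param frames A single `env_frame` (static environment) or a list of
#'   frames of identical dimensions (key frames of a dynamic environment).
#' @param refresh_interval Iterations between key frames (default 100).
#' @param interpolate Linearly interpolate colours between adjacent key
#'   frames?
#' @param cyclic Wrap from the last key frame back to the first?
#' @return An `env_sequence`.
#' @seealso [frame_at()], [generate_lights()]
#' @export
env_sequence <- function(frames, refresh_interval = 100, interpolate = TRUE,
                         cyclic = TRUE) {
  if (inherits(frames, "env_frame")) frames <- list(frames)
  if (length(frames) < 1) stop("need at least one frame", call. = FALSE)
  frames <- lapply(frames, function(f) {
    if (!inherits(f, "env_frame")) f <- new_env_frame(f)
    f
  })
  d <- dim(frames[[1]])
  for (f in frames)
    if (!identical(dim(f), d))
      stop("all frames must share dimensions", call. = FALSE)
  structure(list(frames = frames,
                 refresh_interval = as.integer(refresh_interval),
                 interpolate = isTRUE(interpolate),
                 cyclic = isTRUE(cyclic)),
            class = "env_sequence")
}

#' @export
print.env_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "Environment sequence: %d frame(s) of %d x %d, refresh %d, %s, %s\n",
    length(x$frames), d[2], d[1], x$refresh_interval,
    if (x$interpolate) "interpolated" else "stepped",
    if (x$cyclic) "cyclic" else "clamped"))
  invisible(x)
}

#' Environment frame at a given iteration
#'
#' With interpolation enabled, channel values are the floored weighted mean
#' of the two bracketing key frames (fraction `(iteration mod refresh) /
#' refresh`); at exact multiples of the refresh interval the key frame itself
#' is returned. Single-frame sequences are constant; cyclic sequences wrap
#' from the last key frame to the first.
#'
#' @param seq An [env_sequence()].
#' @param iteration Iteration number (>= 0).
#' @return An `env_frame`.
#' @export
frame_at <- function(seq, iteration) {
  stopifnot(inherits(seq, "env_sequence"), iteration >= 0)
  n <- length(seq$frames)
  if (n == 1) return(seq$frames[[1]])
  r <- seq$refresh_interval
  idx <- iteration %/% r
  frac <- iteration %% r
  if (seq$cyclic) {
    ia <- idx %% n + 1
    ib <- (idx + 1) %% n + 1
  } else {
    ia <- min(idx, n - 1) + 1
    ib <- min(idx + 1, n - 1) + 1
  }
  a <- unclass(seq$frames[[ia]])
  if (!seq$interpolate || frac == 0) return(seq$frames[[ia]])
  b <- unclass(seq$frames[[ib]])
  v <- (a * (r - frac) + b * frac) %/% r
  new_env_frame(array(as.integer(v), dim = dim(a)))
}

#' Count niches in a frame
#'
#' A niche is a maximal 4-connected region of cells sharing one exact colour
#' (one unique combination of the three environmental variables).
#'
#' @param frame An `env_frame`.
#' @return Integer region count.
#' @export
#' @examples
#' count_niches(new_env_frame(array(0L, c(4, 4, 3))))  # 1
count_niches <- function(frame) {
  a <- unclass(frame)
  h <- dim(a)[1]; w <- dim(a)[2]
  id <- a[, , 1] * 65536L + a[, , 2] * 256L + a[, , 3]
  cell <- matrix(seq_len(h * w), nrow = h)
  edges <- NULL
  if (w > 1) {
    same <- id[, -w, drop = FALSE] == id[, -1, drop = FALSE]
    edges <- rbind(edges, cbind(cell[, -w][same], cell[, -1][same]))
  }
  if (h > 1) {
    same <- id[-h, , drop = FALSE] == id[-1, , drop = FALSE]
    edges <- rbind(edges, cbind(cell[-h, ][same], cell[-1, ][same]))
  }
  g <- igraph::make_empty_graph(n = h * w, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  as.integer(igraph::components(g)$no)
}

#' Generate a dynamic "lights" environment sequence
#'
#' Emulates a dynamic habitat-patch environment: coloured circles on a black
#' background that drift through space as random walks, brighten and fade
#' along a triangular envelope over their lifetime, respawn elsewhere when
#' they expire, and combine by per-channel maximum where they intersect. The
#' result is an environment with gradients (via interpolation between key
#' frames), temporal structure and habitat patches of variable size.
#'
#' Defaults scale with the grid so that several patches of varying size
#' coexist at any time; they are the package's documented emulation of a
#' dynamic patchy environment, not a replica of any particular image set.
#'
#' @param seed Integer seed.
#' @param width,height Frame dimensions in cells.
#' @param n_frames Number of key frames to render.
#' @param n_lights Number of concurrent lights (default scales with area).
#' @param radius_range Range of circle radii in cells.
#' @param speed Standard deviation of the per-frame centre displacement.
#' @param lifetime_range Range of light lifetimes in key frames.
#' @param centre_light Open the sequence with a maximal-radius light at
#'   peak brightness over the grid centre, so that simulations seeded there
#'   begin inside a habitat patch rather than at the mercy of the random
#'   layout.
#' @param refresh_interval,interpolate,cyclic Passed to [env_sequence()].
#' @return An `env_sequence` with `n_frames` key frames.
#' @export
generate_lights <- function(seed = 1, width = 100, height = 100,
                            n_frames = 10,
                            n_lights = 8,
                            radius_range = NULL,
                            speed = NULL,
                            lifetime_range = c(4, 7),
                            centre_light = FALSE,
                            refresh_interval = 100,
                            interpolate = TRUE,
                            cyclic = TRUE) {
  stopifnot(n_frames >= 1)
  if (is.null(radius_range)) radius_range <- c(0.20, 0.50) * min(width, height)
  if (is.null(speed)) speed <- 0.08 * min(width, height)
  frames <- with_local_seed(seed, {
    spawn <- function() {
      list(x = runif(1, 1, width), y = runif(1, 1, height),
           r = runif(1, radius_range[1], radius_range[2]),
           col = sample.int(256L, 3L, replace = TRUE) - 1L,
           life = round(runif(1, lifetime_range[1], lifetime_range[2])),
           age = 0)
    }
    lights <- if (n_lights > 0)
      lapply(seq_len(n_lights), function(i) {
        l <- spawn()
        l$age <- sample.int(max(1, l$life), 1) - 1
        l
      }) else list()
    if (centre_light && n_lights > 0) {
      lights[[1]]$x <- width / 2 + 1
      lights[[1]]$y <- height / 2 + 1
      lights[[1]]$r <- radius_range[2]
      lights[[1]]$life <- max(lifetime_range)
      lights[[1]]$age <- floor(lights[[1]]$life / 2)  # at peak brightness
    }
    xs <- matrix(rep(seq_len(width), each = height), nrow = height)
    ys <- matrix(rep(seq_len(height), width), nrow = height)
    out <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      arr <- array(0L, dim = c(height, width, 3L))
      for (li in seq_along(lights)) {
        l <- lights[[li]]
        bright <- 1 - abs(2 * l$age / l$life - 1)
        if (bright > 0) {
          inside <- (xs - l$x)^2 + (ys - l$y)^2 <= l$r^2
          for (ch in 1:3) {
            plane <- arr[, , ch]
            val <- as.integer(round(l$col[ch] * bright))
            plane[inside] <- pmax(plane[inside], val)
            arr[, , ch] <- plane
          }
        }
        # advance: reflected random walk, ageing, respawn on expiry
        l$x <- min(max(l$x + rnorm(1, 0, speed), 1), width)
        l$y <- min(max(l$y + rnorm(1, 0, speed), 1), height)
        l$age <- l$age + 1
        if (l$age >= l$life) l <- spawn()
        lights[[li]] <- l
      }
      out[[f]] <- new_env_frame(arr)
    }
    out
  })
  env_sequence(frames, refresh_interval = refresh_interval,
               interpolate = interpolate, cyclic = cyclic)
}

#' Read and write frames as 8-bit RGB PNG
#'
#' @param frame An `env_frame`.
#' @param path PNG file path.
#' @return `write_frame()` returns `path` invisibly; `read_frame()` returns
#'   an `env_frame`.
#' @export
write_frame <- function(frame, path) {
  png::writePNG(unclass(frame) / 255, target = path)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  new_env_frame(array(as.integer(round(img * 255)), dim = dim(img)))
}

#' Read and write environment sequences as numbered PNGs plus a manifest
#'
#' Frames are written as `frame_0000.png`, `frame_0001.png`, ... together
#' with a `manifest.txt` recording the refresh interval, interpolation and
#' cycling flags.
#'
#' @param seq An `env_sequence`.
#' @param dir Directory (created if missing).
#' @return `write_env_sequence()` returns `dir` invisibly;
#'   `read_env_sequence()` returns an `env_sequence`.
#' @export
write_env_sequence <- function(seq, dir) {
  stopifnot(inherits(seq, "env_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(seq$frames))
    write_frame(seq$frames[[i]],
                file.path(dir, sprintf("frame_%04d.png", i - 1)))
  writeLines(c(paste("refresh_interval", seq$refresh_interval),
               paste("interpolate", seq$interpolate),
               paste("cyclic", seq$cyclic)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname write_env_sequence
#' @export
read_env_sequence <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frame PNGs found in '", dir, "'",
                               call. = FALSE)
  man <- readLines(file.path(dir, "manifest.txt"))
  kv <- strsplit(man, " ")
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  env_sequence(lapply(files, read_frame),
               refresh_interval = as.integer(vals[["refresh_interval"]]),
               interpolate = as.logical(vals[["interpolate"]]),
               cyclic = as.logical(vals[["cyclic"]]))
}
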