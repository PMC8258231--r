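#' Generate the per-channel brightness masks
#'
#' Builds the three sets of 256 masks (one set per colour channel, one mask
#' per brightness level) that translate environment colours into fitness.
#' Each mask is a 32-bit binary string; masks for adjacent brightness levels
#' within one channel differ by exactly one bit, so similar colours select
#' similar fitness optima. The first mask of each channel is uniform random
#' and each successive mask flips one uniformly chosen bit of its
#' predecessor, the simplest construction satisfying the one-bit adjacency.
#' Mask generation uses its own seeded stream and is fixed for the lifetime
#' of a run.
#'
#' @param seed Integer seed; identical seeds give identical mask sets.
#' @return A `mask_set`: a 256 x 3 character matrix (brightness x channel,
#'   channels ordered red, green, blue) of 32-character binary strings, with
#'   the seed stored as an attribute.
#' @seealso [coding_bitcount()], [write_masks()]
#' @export
#' @examples
#' m <- generate_masks(seed = 7)
#' genome_hamming(m[1, "red"], m[2, "red"])  # always 1
generate_masks <- function(seed = 1) {
  m <- cpp_generate_masks(as.numeric(seed))
  colnames(m) <- c("red", "green", "blue")
  rownames(m) <- as.character(0:255)
  attr(m, "seed") <- seed
  class(m) <- "mask_set"
  m
}

#' Build a mask set from explicit bit strings
#'
#' Mainly useful for replaying exported masks or constructing degenerate
#' fixtures. The one-bit adjacency between neighbouring brightness levels is
#' not enforced here, so engineered mask sets (e.g. all-zero masks) can be
#' used to pin organism fitness to known values.
#'
#' @param strings A 256 x 3 matrix (or 768-vector, channel-major
#'   red/green/blue) of 32-character binary strings.
#' @return A `mask_set`.
#' @export
mask_set <- function(strings) {
  if (is.matrix(strings)) {
    if (nrow(strings) != 256 || ncol(strings) != 3)
      stop("mask matrix must be 256 x 3", call. = FALSE)
    m <- strings
  } else {
    if (length(strings) != 768)
      stop("expected 768 mask strings (channel-major)", call. = FALSE)
    m <- matrix(strings, nrow = 256, ncol = 3)
  }
  if (!all(nchar(m) == 32) || !all(grepl("^[01]+$", m)))
    stop("masks must be 32-character binary strings", call. = FALSE)
  colnames(m) <- c("red", "green", "blue")
  rownames(m) <- as.character(0:255)
  class(m) <- "mask_set"
  m
}

#' @export
print.mask_set <- function(x, ...) {
  cat("Mask set: 3 channels x 256 brightness levels x 32 bits\n")
  if (!is.null(attr(x, "seed"))) cat("  seed:", attr(x, "seed"), "\n")
  cat("  red[0]:  ", unclass(x)[1, 1], "\n")
  cat("  red[255]:", unclass(x)[256, 1], "\n")
  invisible(x)
}

#' Export and import mask sets
#'
#' Masks are written as plain text, one 32-bit binary string per line, 768
#' lines in channel-major order (red 0..255, then green, then blue), so a
#' mask set can be replayed across runs and inspected by eye.
#'
#' @param masks A `mask_set`.
#' @param path File path.
#' @return `write_masks()` returns `path` invisibly; `read_masks()` returns
#'   a `mask_set`.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "mask_set"))
  writeLines(as.vector(unclass(masks)), path)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  lines <- readLines(path)
  if (length(lines) != 768)
    stop("mask file must contain exactly 768 lines", call. = FALSE)
  mask_set(lines)
}
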