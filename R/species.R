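# Species delimitation under the biological species concept: a species
# splits when its members partition into clusters such that no member of one
# cluster can interbreed with any member of another. Chains of compatibility
# keep a cluster together; all-pairs compatibility is not required.

#' Genetic compatibility of two genomes
#'
#' Two organisms can interbreed when their full 64-bit genomes differ by at
#' most `max_breed_difference` bits.
#'
#' @param g1,g2 Genome strings (vectorized).
#' @param max_breed_difference Threshold in bits.
#' @return Logical vector.
#' @export
#' @examples
#' g <- random_genome(2, seed = 1)
#' compatible(g[1], g[1], 3)
compatible <- function(g1, g2, max_breed_difference) {
  genome_hamming(g1, g2) <= max_breed_difference
}

#' Partition a species into reproductively isolated clusters
#'
#' Computes the connected components of the compatibility graph over the
#' given genomes: nodes are unique genotypes, edges join genotypes within
#' `max_breed_difference` bits. Within-component connectivity via chains is
#' sufficient; members of different components are pairwise incompatible.
#'
#' @param genomes Character vector of genome strings (one per organism;
#'   duplicated genotypes allowed).
#' @param max_breed_difference Threshold in bits.
#' @return Integer vector of cluster labels (1-based), one per organism.
#'   Labels are ordered by decreasing cluster abundance, ties broken by the
#'   lexicographically smallest genome, so label 1 is the cluster that
#'   retains the ancestral species ID under [assign_species_ids()].
#' @export
#' @examples
#' g <- c("a" = strrep("0", 64), "b" = paste0(strrep("0", 60), "1111"))
#' split_species(unname(g), max_breed_difference = 3)  # two clusters
split_species <- function(genomes, max_breed_difference) {
  stopifnot(length(genomes) > 0)
  ug <- sort(unique(genomes))
  u <- length(ug)
  memb_u <- if (u == 1) {
    1L
  } else {
    d <- cpp_hamming_matrix(ug)
    adj <- d <= max_breed_difference
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::components(g)$membership
  }
  memb <- memb_u[match(genomes, ug)]
  # relabel: decreasing abundance, ties by smallest genome in the cluster
  ab <- tabulate(memb)
  ming <- vapply(seq_along(ab), function(k) min(genomes[memb == k]), "")
  ord <- order(-ab, ming)
  relabel <- integer(length(ab))
  relabel[ord] <- seq_along(ab)
  relabel[memb]
}

#' Assign species IDs after a split
#'
#' The most abundant cluster retains the ancestral species ID; every other
#' cluster receives a fresh ID (issued in decreasing cluster-abundance
#' order) with the ancestral species as parent and the current logging
#' iteration as origin. Ties in abundance are broken in favour of the
#' cluster containing the lexicographically smallest genome.
#'
#' @param clusters Integer cluster labels from [split_species()].
#' @param ancestral_id Species ID the population carried before the split.
#' @param next_id First unused species ID.
#' @param iteration Current logging iteration (recorded as the origin of new
#'   species).
#' @return A list with `ids` (per-organism species IDs), `records` (a data
#'   frame of newly created species: `species_id`, `parent_species_id`,
#'   `origin_iteration`) and `next_id`.
#' @export
assign_species_ids <- function(clusters, ancestral_id, next_id, iteration) {
  k <- max(clusters)
  ancestral_id <- as.integer(ancestral_id)
  next_id <- as.integer(next_id)
  # cluster 1 (most abundant under split_species labelling) keeps the ID
  new_ids <- if (k > 1) next_id + seq_len(k - 1) - 1L else integer(0)
  map <- c(ancestral_id, new_ids)
  ids <- map[clusters]
  records <- data.frame(species_id = new_ids,
                        parent_species_id = rep(ancestral_id, k - 1),
                        origin_iteration = rep(iteration, k - 1))
  list(ids = ids, records = records, next_id = next_id + max(0L, k - 1L))
}
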