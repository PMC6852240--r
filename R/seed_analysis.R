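# Seed-level analysis: spatial clustering of predicted patches' seeds,
# partner counting by sequence homology, and the multi-strategy
# partner-multiplicity indicator.

#' Cluster seeds in 3D by average-linkage on their atom sets
#'
#' Seeds from the `SC_notLig`, `SC_geom` and `SC_dock` strategies are
#' clustered by agglomerative average linkage on the Euclidean distances
#' between their atoms (all seed atoms, not centroids); `SC_cons` seeds
#' are discarded.  The dendrogram is cut at `cut` Angstrom (default 23).
#'
#' @param seeds Tibble from [patch_seeds()] (columns `strategy`,
#'   `patch_id`, `residues`).
#' @param s The query [read_structure()] tibble.
#' @param cut Dendrogram cut height in Angstrom (default 23).
#' @return Tibble of class `surf_seed_clusters`: `cluster_id`, `seeds`
#'   (list of member seed labels), `strategies` (list), `n_strategies`,
#'   `residues` (union, list-column).
#' @export
cluster_seeds <- function(seeds, s, cut = 23) {
  if (any(seeds$strategy == "SC_cons")) {
    inform("SC_cons seeds discarded before clustering")
    seeds <- filter(seeds, .data$strategy != "SC_cons")
  }
  if (nrow(seeds) == 0) abort("no seeds to cluster")
  lab <- sprintf("%s.%d", seeds$strategy, seeds$patch_id)
  coords <- lapply(seeds$residues, function(r) atom_coords(s, r)$xyz)
  n <- length(coords)
  if (n == 1) {
    strat1 <- unique(seeds$strategy)
    resid1 <- sort(unlist(seeds$residues))
    out <- tibble(cluster_id = 1L, seeds = list(lab),
                  strategies = list(strat1),
                  n_strategies = 1L,
                  residues = list(resid1))
    return(structure(out, class = c("surf_seed_clusters", class(tibble()))))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- mean(cross_dist(coords[[i]], coords[[j]]))
  }
  hc <- hclust(as.dist(D), method = "average",
               members = vapply(coords, nrow, integer(1)))
  grp <- cutree(hc, h = cut)
  out <- purrr::imap(split(seq_len(n), grp), function(idx, gi) {
    strat <- sort(unique(seeds$strategy[idx]))
    resid <- sort(unique(unlist(seeds$residues[idx])))
    member <- lab[idx]
    tibble(cluster_id = as.integer(gi),
           seeds = list(member),
           strategies = list(strat),
           n_strategies = length(strat),
           residues = list(resid))
  }) |> bind_rows()
  structure(out, class = c("surf_seed_clusters", class(tibble())))
}

#' Count distinct partners by sequence-identity clustering
#'
#' Partners are single-linkage clustered on global-alignment percent
#' identity: two partners join one cluster when they share at least 90\%
#' identity; the returned cluster count estimates the number of distinct
#' partners.
#'
#' @param partner_seqs Character vector of partner sequences (ungapped).
#' @param identity_threshold Linking threshold (default 90, inclusive).
#' @return Integer cluster count (0 for an empty input).
#' @export
count_partners <- function(partner_seqs, identity_threshold = 90) {
  n <- length(partner_seqs)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(partner_seqs[i]),
      Biostrings::AAString(partner_seqs[j]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    if (Biostrings::pid(aln) >= identity_threshold) {
      a <- find(i); b <- find(j)
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Multi-strategy partner-multiplicity indicator of an interacting region
#'
#' Counts the distinct scoring strategies contributing at least one seed
#' lying (almost) completely within the region: a seed counts when its
#' precision `|seed n IR| / |seed|` reaches `ppv_min` (default 0.8).  The
#' count (0-3 over `SC_notLig`/`SC_geom`/`SC_dock`) increases with the
#' number of partners using the region.
#'
#' @param ir_residues Residue-id vector of the interacting region.
#' @param seeds Tibble from [patch_seeds()] (strategy-tagged residue sets).
#' @param ppv_min Minimum seed-in-region precision (default 0.8).
#' @return Integer count of strategies.
#' @export
sc_multiplicity <- function(ir_residues, seeds, ppv_min = 0.8) {
  seeds <- filter(seeds, .data$strategy != "SC_cons")
  if (nrow(seeds) == 0) return(0L)
  ppv <- map_dbl(seeds$residues, function(r)
    length(intersect(r, ir_residues)) / length(r))
  length(unique(seeds$strategy[ppv >= ppv_min]))
}
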