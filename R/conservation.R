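# Evolutionary conservation by tree-trace levels averaged over sampled
# distance trees.  Homolog search and alignment are inputs: the pool holds
# sequences already aligned to the query (same length, '-' for gaps).

#' Construct a homolog pool
#'
#' @param query Query sequence (single string, aligned coordinate system).
#' @param homologs Tibble with columns `name`, `seq` and optionally
#'   `identity` (percent identity to the query; computed over non-gap
#'   columns when absent).
#' @param query_name Name for the query sequence.
#' @return Object of class `homolog_pool`.
#' @export
homolog_pool <- function(query, homologs, query_name = "query") {
  homologs <- as_tibble(homologs)
  stopifnot(all(c("name", "seq") %in% names(homologs)))
  bad <- nchar(homologs$seq) != nchar(query)
  if (any(bad)) abort("homolog sequences must be aligned to the query (equal length)")
  if (!"identity" %in% names(homologs)) {
    homologs$identity <- map_dbl(homologs$seq, seq_identity, b = query)
  }
  if (any(homologs$identity <= 0 | homologs$identity > 100)) {
    abort("identities must lie in (0, 100]")
  }
  structure(list(query = query, query_name = query_name,
                 homologs = homologs), class = "homolog_pool")
}

# percent identity over columns where neither sequence is gapped
seq_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- ca != "-" & cb != "-"
  if (!any(ok)) return(0)
  100 * mean(ca[ok] == cb[ok])
}

identity_bin <- function(id) {
  cut(id, breaks = c(20, 40, 60, 80, 98), right = FALSE,
      labels = c("20-39", "40-59", "60-79", "80-98"),
      include.lowest = FALSE) |>
    as.character() |>
    (\(x) ifelse(id == 98, "80-98", x))()
}

#' Sample representative homolog subsets stratified by identity
#'
#' Homologs outside (20, 98] percent identity to the query are excluded;
#' the rest fall into four identity bins (20-39, 40-59, 60-79, 80-98).
#' Each subset is drawn without replacement aiming at equal quarters per
#' bin; a bin's deficit is redistributed proportionally to the remaining
#' bins' availability.
#'
#' @param pool A [homolog_pool()].
#' @param n_subsets,subset_size Number of subsets and sequences per subset;
#'   both default to `min(50, ceiling(sqrt(n_eligible)))`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return List of character vectors of homolog names (the query is added
#'   later when trees are built).
#' @export
sample_subsets <- function(pool, n_subsets = NULL, subset_size = NULL,
                           seed = 1) {
  stopifnot(inherits(pool, "homolog_pool"))
  elig <- filter(pool$homologs, .data$identity > 20, .data$identity <= 98)
  if (nrow(elig) == 0) abort("no homologs in the (20, 98] identity range")
  n_default <- min(50L, ceiling(sqrt(nrow(elig))))
  n_subsets <- n_subsets %||% n_default
  subset_size <- subset_size %||% n_default
  if (nrow(elig) <= subset_size) {
    warn("pool smaller than subset size; using the whole pool once")
    return(list(elig$name))
  }
  bins <- split(elig$name, identity_bin(elig$identity))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(seq_len(n_subsets), function(i) {
    avail <- vapply(bins, length, integer(1))
    base <- subset_size %/% length(bins)
    want <- rep(base, length(bins))
    extra <- subset_size - sum(want)
    if (extra > 0) want[order(-avail)[seq_len(extra)]] <- want[order(-avail)[seq_len(extra)]] + 1
    # redistribute deficits proportionally to remaining availability
    repeat {
      take <- pmin(want, avail)
      deficit <- sum(want - take)
      if (deficit == 0) break
      room <- avail - take
      if (sum(room) == 0) break
      add <- floor(deficit * room / sum(room))
      while (sum(add) < deficit && any(room - add > 0)) {
        j <- which.max(room - add); add[j] <- add[j] + 1
      }
      want <- take + add
    }
    unlist(lapply(names(bins), function(b) {
      k <- min(want[match(b, names(bins))], length(bins[[b]]))
      if (k <= 0) character(0) else sample(bins[[b]], k)
    }), use.names = FALSE) |> sort()
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Pairwise distance matrix from an alignment
#'
#' Distance between two aligned sequences is the fraction of mismatched
#' columns over the columns where neither carries a gap.
#'
#' @param seqs Named character vector of aligned sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1) abort("aligned lengths differ")
  M <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- M[i, ] != "-" & M[j, ] != "-"
    if (!any(ok)) abort(sprintf("no comparable columns between %s and %s",
                                names(seqs)[i], names(seqs)[j]))
    d[i, j] <- d[j, i] <- mean(M[i, ok] != M[j, ok])
  }
  d
}

#' Neighbor-joining tree with deterministic handling of small cases
#'
#' Standard NJ (via \pkg{ape}) for four or more taxa; two- and three-taxon
#' cases use the closed-form branch lengths.  Negative branch lengths are
#' clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix with at least two taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-9))) {
    abort("distance matrix is not symmetric")
  }
  n <- nrow(d)
  lab <- rownames(d) %||% paste0("t", seq_len(n))
  tr <- if (n == 2) {
    structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                   edge.length = rep(d[1, 2] / 2, 2), tip.label = lab,
                   Nnode = 1L), class = "phylo")
  } else if (n == 3) {
    v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    structure(list(edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), 3, 2, byrow = TRUE),
                   edge.length = c(v1, v2, v3), tip.label = lab,
                   Nnode = 1L), class = "phylo")
  } else {
    ape::nj(as.dist(d))
  }
  if (any(tr$edge.length < 0)) {
    warn("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# rooted tree (midpoint) + integer node levels: root = 0, leaves deepest
root_and_levels <- function(tr) {
  rt <- if (ape::Ntip(tr) <= 2) {
    if (!ape::is.rooted(tr)) ape::root(tr, 1, resolve.root = TRUE) else tr
  } else {
    phangorn::midpoint(tr)
  }
  ntip <- ape::Ntip(rt)
  root <- ntip + 1L
  depth <- rep(NA_integer_, ntip + rt$Nnode)
  depth[root] <- 0L
  # edges in preorder: parent depth known before child
  ord <- ape::reorder.phylo(rt, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    depth[ord$edge[k, 2]] <- depth[ord$edge[k, 1]] + 1L
  }
  list(tree = rt, depth = depth, L = max(depth[seq_len(ntip)]))
}

#' Tree trace levels for each query position
#'
#' For every alignment column, the trace level is the depth of the
#' shallowest internal ancestor of the query leaf whose whole leaf set
#' carries the query's amino acid at that column (root depth 0).  Columns
#' conserved in no internal ancestor get level `L` and are flagged as
#' having no trace.
#'
#' @param tr An unrooted `phylo` from [nj_tree()] (midpoint-rooted here).
#' @param aln Named character vector of aligned sequences (leaves of `tr`
#'   plus the query).
#' @param query_name Name of the query sequence in `aln`.
#' @return Tibble `position`, `level`, `L`, `traced` (logical).
#' @export
trace_levels <- function(tr, aln, query_name = "query") {
  if (!query_name %in% tr$tip.label) {
    abort("query leaf missing from the tree; append the query to its subsets")
  }
  rl <- root_and_levels(tr)
  rt <- rl$tree
  ntip <- ape::Ntip(rt)
  M <- do.call(rbind, strsplit(aln[rt$tip.label], ""))
  qrow <- match(query_name, rt$tip.label)
  qleaf <- qrow
  anc <- ape::nodepath(rt, from = ntip + 1L, to = qleaf)
  anc <- anc[anc > ntip]  # internal ancestors, shallow to deep
  tips_below <- phangorn::Descendants(rt, anc, type = "tips")
  L <- rl$L
  npos <- ncol(M)
  level <- integer(npos); traced <- logical(npos)
  for (j in seq_len(npos)) {
    a <- M[qrow, j]
    if (a == "-") { level[j] <- L; traced[j] <- FALSE; next }
    hit <- NA_integer_
    for (k in seq_along(anc)) {
      if (all(M[tips_below[[k]], j] == a)) { hit <- k; break }
    }
    if (is.na(hit)) { level[j] <- L; traced[j] <- FALSE }
    else { level[j] <- rl$depth[anc[hit]]; traced[j] <- TRUE }
  }
  tibble(position = seq_len(npos), level = level, L = L, traced = traced)
}

#' Relative trace significance (T_JET) from per-tree trace levels
#'
#' `T_JET(j) = (1/M_j) * sum_t (L_t - l_jt) / L_t` over the trees where a
#' trace was computed for position `j`; positions traced in no tree score 0.
#'
#' @param traces Tibble binding [trace_levels()] outputs over trees (a
#'   `tree` column distinguishes them).
#' @return Tibble `position`, `tjet`, `m` (number of contributing trees).
#' @export
compute_tjet <- function(traces) {
  traces |>
    group_by(.data$position) |>
    summarise(
      m = sum(.data$traced),
      tjet = if (sum(.data$traced) == 0) 0 else
        mean(((.data$L - .data$level) / .data$L)[.data$traced]),
      .groups = "drop"
    ) |>
    select("position", "tjet", "m")
}

#' Full conservation pipeline for a homolog pool
#'
#' Samples identity-stratified subsets, builds an NJ distance tree per
#' subset (query appended), computes trace levels and averages them into
#' T_JET scores.
#'
#' @inheritParams sample_subsets
#' @return Tibble `position`, `query_aa`, `tjet`, `m`.
#' @examples
#' pool <- make_homolog_pool(strrep("ACDEFGHIKL", 4),
#'                           n_per_bin = c(4, 4, 4, 4),
#'                           conserved_cols = 1:8, seed = 1)
#' compute_conservation(pool, seed = 1)
#' @export
compute_conservation <- function(pool, n_subsets = NULL, subset_size = NULL,
                                 seed = 1) {
  subs <- sample_subsets(pool, n_subsets, subset_size, seed = seed)
  seqs_all <- setNames(pool$homologs$seq, pool$homologs$name)
  traces <- purrr::imap(subs, function(nms, t_idx) {
    aln <- c(seqs_all[nms], setNames(pool$query, pool$query_name))
    d <- distance_matrix(aln)
    tr <- suppressWarnings(nj_tree(d))
    trace_levels(tr, aln, query_name = pool$query_name) |>
      mutate(tree = t_idx)
  }) |> bind_rows()
  qaa <- strsplit(pool$query, "")[[1]]
  compute_tjet(traces) |>
    mutate(query_aa = qaa[.data$position]) |>
    select("position", "query_aa", "tjet", "m")
}
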