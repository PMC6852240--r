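# Seed -> extension -> outer-layer patch growing under four scoring
# strategies, with an iterative consensus.  This is the package's core
# algorithm: seeds are small clusters of top-scoring surface residues,
# extensions admit progressively weaker signal among residues in contact
# with the growing patch, and a final outer layer is added once.

strategy_names <- c("SC_cons", "SC_notLig", "SC_geom", "SC_dock")

#' Layer scoring specification for a strategy
#'
#' Maps each strategy to the scores driving its seed, extension and outer
#' layers:
#' * `SC_cons`: seed T_JET; extension T_JET+PC; outer PC+CV.
#' * `SC_notLig`: seed and extension T_JET+CV; outer PC+CV.
#' * `SC_geom`: PC+CV for all three layers.
#' * `SC_dock`: NIP for all three layers.
#' Where a layer names two scores they are combined by their arithmetic
#' mean on the [0, 1] scale (configurable to `min` or `prod`).
#'
#' @param strategy One of `"SC_cons"`, `"SC_notLig"`, `"SC_geom"`,
#'   `"SC_dock"`.
#' @param combine Combination rule for two-score layers.
#' @return List with fields `strategy`, `seed_cols`, `ext_cols`,
#'   `outer_cols`, `combine`.
#' @export
strategy_spec <- function(strategy = strategy_names,
                          combine = c("mean", "min", "prod")) {
  strategy <- match.arg(strategy)
  combine <- match.arg(combine)
  cols <- switch(strategy,
    SC_cons   = list(seed = "tjet", ext = c("tjet", "pc"), outer = c("pc", "cv")),
    SC_notLig = list(seed = c("tjet", "cv"), ext = c("tjet", "cv"),
                     outer = c("pc", "cv")),
    SC_geom   = list(seed = c("pc", "cv"), ext = c("pc", "cv"),
                     outer = c("pc", "cv")),
    SC_dock   = list(seed = "nip01", ext = "nip01", outer = "nip01")
  )
  list(strategy = strategy, seed_cols = cols$seed, ext_cols = cols$ext,
       outer_cols = cols$outer, combine = combine)
}

combine_cols <- function(table, cols, combine) {
  need <- cols[!cols %in% names(table) |
                 vapply(cols, function(c) all(is.na(table[[c]])), logical(1))]
  if (length(need) > 0) {
    abort(sprintf("strategy requires score(s) not available: %s",
                  paste(need, collapse = ", ")))
  }
  M <- as.matrix(table[, cols, drop = FALSE])
  switch(combine,
         mean = rowMeans(M),
         min = apply(M, 1, min),
         prod = apply(M, 1, prod))
}

layer_scores <- function(table, spec) {
  tibble(
    res_uid = table$res_uid,
    seed_score = combine_cols(table, spec$seed_cols, spec$combine),
    ext_score = combine_cols(table, spec$ext_cols, spec$combine),
    outer_score = combine_cols(table, spec$outer_cols, spec$combine)
  )
}

# canonical residue ordering used for every tie-break
canonical_order <- function(uids, score) {
  f <- uid_fields(uids)
  order(-score, f$chain, f$resno, f$icode)
}

#' Detect seeds of highly scored surface residues
#'
#' Surface residues at or above the seed quantile of the strategy's seed
#' score are clustered by 5 A atomic connectivity; clusters of fewer than
#' three residues are discarded and clusters closer than 5 A are merged.
#' A flat score profile yields no seed.
#'
#' @param table A [assemble_score_table()] tibble.
#' @param strategy Strategy name or a [strategy_spec()].
#' @param s The query [read_structure()] tibble.
#' @param config A [surf_config()]; supplies the seed quantile (0.9), the
#'   contact cutoff (5 A) and the minimum seed size (3).
#' @return Tibble `seed_id`, `strategy`, `residues` (list-column); zero
#'   rows when nothing passes.
#' @export
detect_seeds <- function(table, strategy, s, config = surf_config()) {
  spec <- if (is.list(strategy)) strategy else
    strategy_spec(strategy, combine = config$combine)
  sc <- layer_scores(table, spec)
  empty <- tibble(seed_id = integer(), strategy = character(),
                  residues = list())
  if (length(unique(sc$seed_score)) < 2) return(empty)
  # order-statistic quantile: the threshold is an attained score, so ties
  # at the cut survive the >= admission
  thr <- quantile(sc$seed_score, config$seed_quantile, names = FALSE,
                  type = 1)
  cand <- sc$res_uid[sc$seed_score >= thr]
  if (length(cand) == 0) return(empty)
  pairs <- residue_adjacency(s, cand, cutoff = config$contact_cutoff)
  comps <- contact_components(cand, pairs)
  comps <- comps[vapply(comps, length, integer(1)) >= config$min_seed_size]
  comps <- merge_close_sets(comps, s, config$contact_cutoff)
  if (length(comps) == 0) return(empty)
  tibble(seed_id = seq_along(comps), strategy = spec$strategy,
         residues = unname(comps))
}

# merge residue sets whose closest atoms are < cutoff apart (transitively)
merge_close_sets <- function(sets, s, cutoff) {
  if (length(sets) <= 1) return(sets)
  repeat {
    merged <- FALSE
    for (i in seq_len(length(sets) - 1)) {
      for (j in (i + 1):length(sets)) {
        if (length(intersect(sets[[i]], sets[[j]])) > 0 ||
            min(residue_min_dists(s, sets[[i]], sets[[j]])$dist, Inf) < cutoff) {
          sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
          sets <- sets[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  sets
}

#' Grow patches from detected seeds
#'
#' Each seed is extended by repeatedly admitting the best-scoring surface
#' residue in contact (< 5 A) with the current patch whose extension score
#' reaches the extension quantile, until the target patch size is reached
#' or no candidate remains.  Grown patches closer than 5 A are merged.
#' Finally an outer layer -- contact residues at or above the outer
#' quantile -- is added once.  The quantile ordering seed > extension >
#' outer realises the strong-seed / fading-signal design and is enforced
#' at configuration load.
#'
#' @inheritParams detect_seeds
#' @param seeds Output of [detect_seeds()].
#' @return Tibble of class `surf_patches`: `strategy`, `patch_id`,
#'   `res_uid`, `layer`.
#' @export
grow_patches <- function(seeds, table, strategy, s, config = surf_config()) {
  spec <- if (is.list(strategy)) strategy else
    strategy_spec(strategy, combine = config$combine)
  empty <- tibble(strategy = character(), patch_id = integer(),
                  res_uid = character(), layer = character())
  if (nrow(seeds) == 0) return(structure(empty, class = c("surf_patches", class(tibble()))))
  sc <- layer_scores(table, spec)
  surf_ids <- table$res_uid
  pairs <- residue_adjacency(s, surf_ids, cutoff = config$contact_cutoff)
  nbr <- build_neighbour_list(surf_ids, pairs)
  ext_thr <- quantile(sc$ext_score, config$ext_quantile, names = FALSE,
                      type = 1)
  outer_thr <- quantile(sc$outer_score, config$outer_quantile,
                        names = FALSE, type = 1)
  frac <- config$target_fraction[[spec$strategy]] %||% 0.25
  raw_target <- ceiling(frac * length(surf_ids))
  max_seed <- max(vapply(seeds$residues, length, integer(1)))
  if (raw_target < max_seed) {
    warn("target patch size below seed size; patch kept at seed + outer layer")
  }
  target <- max(raw_target, max_seed)
  ext_of <- setNames(sc$ext_score, sc$res_uid)
  outer_of <- setNames(sc$outer_score, sc$res_uid)
  grown <- lapply(seeds$residues, function(seed) {
    members <- seed
    while (length(members) < target) {
      frontier <- setdiff(unique(unlist(nbr[members], use.names = FALSE)),
                          members)
      frontier <- frontier[ext_of[frontier] >= ext_thr]
      if (length(frontier) == 0) break
      pick <- frontier[canonical_order(frontier, ext_of[frontier])[1]]
      members <- c(members, pick)
    }
    list(seed = seed, members = sort(members))
  })
  # merge grown patches that overlap or are in contact
  sets <- lapply(grown, `[[`, "members")
  groups <- merge_set_groups(sets, s, config$contact_cutoff)
  out <- purrr::imap(groups, function(idx, gi) {
    seed_res <- sort(unique(unlist(lapply(grown[idx], `[[`, "seed"))))
    members <- sort(unique(unlist(lapply(grown[idx], `[[`, "members"))))
    ring <- setdiff(unique(unlist(nbr[members], use.names = FALSE)), members)
    ring <- sort(ring[outer_of[ring] >= outer_thr])
    tibble(
      strategy = spec$strategy, patch_id = as.integer(gi),
      res_uid = c(members, ring),
      layer = c(ifelse(members %in% seed_res, "seed", "extension"),
                rep("outer", length(ring)))
    )
  }) |> bind_rows()
  structure(out, class = c("surf_patches", class(tibble())))
}

build_neighbour_list <- function(uids, pairs) {
  nbr <- setNames(vector("list", length(uids)), uids)
  if (nrow(pairs) > 0) {
    fw <- split(pairs$uid_b, pairs$uid_a)
    bw <- split(pairs$uid_a, pairs$uid_b)
    for (u in names(fw)) nbr[[u]] <- c(nbr[[u]], fw[[u]])
    for (u in names(bw)) nbr[[u]] <- c(nbr[[u]], bw[[u]])
  }
  nbr
}

# group indices of residue sets that overlap or sit < cutoff apart
merge_set_groups <- function(sets, s, cutoff) {
  n <- length(sets)
  if (n == 1) return(list(1L))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0 ||
      min(residue_min_dists(s, sets[[i]], sets[[j]])$dist, Inf) < cutoff
  }
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (adj[i, j]) comp[comp == comp[j]] <- comp[i]
  }
  unname(split(seq_len(n), match(comp, unique(comp))))
}

#' Predict consensus patches over iterations
#'
#' Runs seed detection and patch growth `n_iter` times and keeps the
#' residues detected in at least `min_hits` iterations (the iterative
#' consensus).  For the conservation-driven strategies (`SC_cons`,
#' `SC_notLig`) each iteration recomputes T_JET from freshly re-sampled
#' homolog subsets, which is the source of iteration diversity; for
#' `SC_geom`/`SC_dock` the scores are deterministic, iterations coincide
#' and the consensus reduces to a single run.  Consensus residues are
#' re-clustered at 5 A into the final patches.
#'
#' @inheritParams detect_seeds
#' @param pool Optional [homolog_pool()]; required to re-sample T_JET for
#'   the conservation-driven strategies.
#' @param chain Query chain id (used to key re-sampled conservation scores
#'   to residues).
#' @param n_iter Number of iterations (default 10).
#' @param min_hits Minimum number of iterations a residue must be detected
#'   in (default 2).
#' @param seed Integer RNG seed; output is deterministic given the seed.
#' @return Tibble of class `surf_patches` with columns `strategy`,
#'   `patch_id`, `res_uid`, `chain`, `resno`, `icode`, `layer`, `hits`.
#' @examples
#' # see vignette("surface-decryption") for an end-to-end run
#' @export
predict_patches <- function(table, strategy, s, config = surf_config(),
                            pool = NULL, chain = NULL,
                            n_iter = config$n_iter,
                            min_hits = config$min_hits, seed = 1) {
  spec <- strategy_spec(strategy, combine = config$combine)
  uses_tjet <- "tjet" %in% c(spec$seed_cols, spec$ext_cols)
  resample <- uses_tjet && !is.null(pool)
  hit_env <- new.env(parent = emptyenv())
  tally <- function(uids, layer) {
    for (u in uids) {
      cur <- hit_env[[u]] %||% c(hits = 0, seed = 0, extension = 0, outer = 0)
      cur["hits"] <- cur["hits"] + 1
      cur[layer] <- cur[layer] + 1
      hit_env[[u]] <- cur
    }
  }
  iters <- if (resample) n_iter else 1L
  for (it in seq_len(iters)) {
    tab_it <- table
    if (resample) {
      it_seed <- (as.integer(seed) * 97L + it * 131L) %% 2147483647L
      tj <- compute_conservation(pool, seed = it_seed)
      tj_res <- conservation_to_residues(tj, s, chain %||% table$chain[1])
      tab_it$tjet <- tj_res$tjet[match(tab_it$res_uid, tj_res$res_uid)]
    }
    sds <- detect_seeds(tab_it, spec, s, config)
    p <- grow_patches(sds, tab_it, spec, s, config)
    if (nrow(p) > 0) {
      # one tally per residue per iteration; layer precedence seed > ext > outer
      best <- p |>
        mutate(rank = match(.data$layer, c("seed", "extension", "outer"))) |>
        group_by(.data$res_uid) |>
        summarise(layer = c("seed", "extension", "outer")[min(.data$rank)],
                  .groups = "drop")
      for (ly in c("seed", "extension", "outer")) {
        tally(best$res_uid[best$layer == ly], ly)
      }
    }
  }
  eff_min <- if (resample) min_hits else 1L
  uids <- ls(hit_env)
  hits <- vapply(uids, function(u) hit_env[[u]][["hits"]], numeric(1))
  keep <- uids[hits >= eff_min]
  empty <- tibble(strategy = character(), patch_id = integer(),
                  res_uid = character(), chain = character(),
                  resno = integer(), icode = character(),
                  layer = character(), hits = integer())
  if (length(keep) == 0) {
    return(structure(empty, class = c("surf_patches", class(tibble()))))
  }
  pairs <- residue_adjacency(s, keep, cutoff = config$contact_cutoff)
  comps <- contact_components(sort(keep), pairs)
  out <- purrr::imap(comps, function(uids_i, ci) {
    ly <- vapply(uids_i, function(u) {
      cnt <- hit_env[[u]][c("seed", "extension", "outer")]
      c("seed", "extension", "outer")[which.max(cnt)]
    }, character(1))
    tibble(strategy = spec$strategy, patch_id = as.integer(ci),
           res_uid = uids_i, layer = unname(ly),
           hits = as.integer(vapply(uids_i, function(u)
             hit_env[[u]][["hits"]], numeric(1))))
  }) |> bind_rows()
  out <- out |>
    left_join(uid_fields(unique(out$res_uid)), by = "res_uid") |>
    select("strategy", "patch_id", "res_uid", "chain", "resno", "icode",
           "layer", "hits") |>
    arrange(.data$patch_id, .data$chain, .data$resno, .data$icode)
  structure(out, class = c("surf_patches", class(tibble())))
}

#' Residue sets of the seeds of predicted patches
#'
#' @param patches A `surf_patches` tibble (possibly several strategies
#'   bound together).
#' @return Tibble `strategy`, `patch_id`, `residues` (list of seed-layer
#'   residue ids), one row per patch with a non-empty seed.
#' @export
patch_seeds <- function(patches) {
  patches |>
    filter(.data$layer == "seed") |>
    group_by(.data$strategy, .data$patch_id) |>
    summarise(residues = list(sort(.data$res_uid)), .groups = "drop")
}
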