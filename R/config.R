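#' Pipeline configuration: every tunable threshold in one place
#'
#' All thresholds used across the package are carried by this object so a
#' run is fully described by its configuration: the 5 A contact cutoff,
#' the 5\% surface and 25\% burial accessibility thresholds, the 60\%
#' region-merge overlap, the 23 A seed-cluster cut, the 2.7 kcal/mol pose
#' energy window, the 10-iteration / 2-hit consensus, the seed/extension/
#' outer admission quantiles and the circular-variance radius.  The
#' quantile ordering seed > extension > outer (strong seed, fading
#' extension) is enforced here.
#'
#' @param contact_cutoff Contact distance, Angstrom (default 5).
#' @param surface_threshold rasa surface threshold (default 0.05).
#' @param burial_threshold rasa burial threshold for layers (default 0.25).
#' @param overlap_threshold IS/IR merge overlap (default 0.60).
#' @param seed_cluster_cut Seed dendrogram cut, Angstrom (default 23).
#' @param energy_window Pose energy window, kcal/mol (default 2.7).
#' @param n_iter,min_hits Iterative consensus parameters (defaults 10, 2).
#' @param seed_quantile,ext_quantile,outer_quantile Admission quantiles
#'   (defaults 0.9, 0.6, 0.5; must be strictly decreasing).
#' @param r_c Circular-variance radius, Angstrom (default 100).
#' @param combine Two-score layer combination rule (default "mean").
#' @param min_seed_size Minimum residues per seed cluster (default 3).
#' @param target_fraction Named list of target patch sizes as fractions of
#'   the surface residue count per strategy.
#' @param ppv_min Seed-in-region precision threshold (default 0.8).
#' @return A list of class `surf_config`.
#' @export
surf_config <- function(contact_cutoff = 5, surface_threshold = 0.05,
                        burial_threshold = 0.25, overlap_threshold = 0.60,
                        seed_cluster_cut = 23, energy_window = 2.7,
                        n_iter = 10, min_hits = 2,
                        seed_quantile = 0.9, ext_quantile = 0.6,
                        outer_quantile = 0.5, r_c = 100,
                        combine = c("mean", "min", "prod"),
                        min_seed_size = 3,
                        target_fraction = list(SC_cons = 0.33,
                                               SC_notLig = 0.33,
                                               SC_geom = 0.25,
                                               SC_dock = 0.25),
                        ppv_min = 0.8) {
  combine <- match.arg(combine)
  cfg <- list(contact_cutoff = contact_cutoff,
              surface_threshold = surface_threshold,
              burial_threshold = burial_threshold,
              overlap_threshold = overlap_threshold,
              seed_cluster_cut = seed_cluster_cut,
              energy_window = energy_window,
              n_iter = n_iter, min_hits = min_hits,
              seed_quantile = seed_quantile, ext_quantile = ext_quantile,
              outer_quantile = outer_quantile, r_c = r_c,
              combine = combine, min_seed_size = min_seed_size,
              target_fraction = target_fraction, ppv_min = ppv_min)
  if (!(seed_quantile > ext_quantile && ext_quantile > outer_quantile)) {
    abort("admission quantiles must satisfy seed > extension > outer")
  }
  if (any(vapply(cfg[c("contact_cutoff", "seed_cluster_cut", "energy_window",
                       "r_c")], function(x) x <= 0, logical(1)))) {
    abort("distance/energy thresholds must be positive")
  }
  if (n_iter < 1 || min_hits < 1 || min_hits > n_iter) {
    abort("need 1 <= min_hits <= n_iter")
  }
  structure(cfg, class = "surf_config")
}

#' Run the full prediction pipeline on one query chain
#'
#' Orders the stages scores -> patches -> regions -> seed clustering ->
#' evaluation.  Strategies whose inputs are missing are skipped with a
#' message (no homolog pool disables `SC_cons`/`SC_notLig`; no poses
#' disables `SC_dock`).
#'
#' @param s Query [read_structure()] tibble.
#' @param chain Query chain id.
#' @param config A [surf_config()].
#' @param pool Optional [homolog_pool()] for conservation.
#' @param poses Optional pose tibble for docking propensities.
#' @param complexes Optional list of complex `surf_structure`s (each
#'   containing `chain`) from which interacting sites are extracted and
#'   merged into regions for evaluation.
#' @param seed Integer RNG seed for the whole run.
#' @param out_dir Optional directory: writes score/patch/region TSVs and a
#'   provenance manifest (all thresholds, input checksums, versions).
#' @return List of class `surf_run` with elements `config`, `surface`,
#'   `scores`, `patches`, `seeds`, `seed_clusters`, `sites`, `regions`,
#'   `evaluation`, `coverage`, `manifest`.
#' @export
run_pipeline <- function(s, chain, config = surf_config(), pool = NULL,
                         poses = NULL, complexes = NULL, seed = 1,
                         out_dir = NULL) {
  surface <- compute_rasa(s, chains = chain,
                          surface_threshold = config$surface_threshold)
  cv <- compute_cv(s, r_c = config$r_c, chains = chain)
  tjet_res <- NULL
  if (!is.null(pool)) {
    tj <- compute_conservation(pool, seed = seed)
    tjet_res <- conservation_to_residues(tj, s, chain)
  } else inform("no homolog pool: SC_cons/SC_notLig disabled")
  nip <- NULL
  if (!is.null(poses)) {
    kept <- filter_poses(poses, window = config$energy_window)
    surf_ids <- surface$res_uid[surface$surface]
    nip <- compute_nip(compute_ip(kept, residues = surf_ids))
  } else inform("no docking poses: SC_dock disabled")
  tab <- assemble_score_table(surface, cv = cv, tjet = tjet_res, nip = nip)
  strategies <- c(if (!is.null(tjet_res)) c("SC_cons", "SC_notLig"),
                  "SC_geom", if (!is.null(nip)) "SC_dock")
  patches <- lapply(strategies, function(st)
    predict_patches(tab, st, s, config, pool = pool, chain = chain,
                    seed = seed)) |> bind_rows()
  class(patches) <- c("surf_patches", class(tibble()))
  seeds <- patch_seeds(patches)
  seed_clusters <- if (nrow(filter(seeds, .data$strategy != "SC_cons")) > 0) {
    suppressMessages(cluster_seeds(seeds, s, cut = config$seed_cluster_cut))
  } else NULL
  sites <- NULL; regions <- NULL; evaluation <- NULL
  if (!is.null(complexes)) {
    sites <- lapply(complexes, partner_grouping, chain = chain,
                    cutoff = config$contact_cutoff) |> bind_rows()
    class(sites) <- c("surf_sites", class(tibble()))
    regions <- merge_regions(sites,
                             overlap_threshold = config$overlap_threshold)
    if (nrow(regions) > 0 && nrow(patches) > 0) {
      evaluation <- best_match(patches, regions)
    }
  }
  surf_ids <- surface$res_uid[surface$surface]
  cov <- list(
    predicted = coverage(split(patches$res_uid, patches$patch_id), surf_ids),
    experimental = if (!is.null(regions) && nrow(regions) > 0)
      coverage(regions$residues, surf_ids) else NA_real_
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("surfpatch")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = unclass(config),
    inputs = list(
      structure = digest::digest(as.data.frame(s)),
      pool = if (!is.null(pool)) digest::digest(pool) else NULL,
      poses = if (!is.null(poses)) digest::digest(as.data.frame(
        mutate(poses, residues = map_chr(.data$residues, paste,
                                         collapse = ";")))) else NULL
    ),
    strategies = strategies
  )
  manifest$hash <- digest::digest(manifest)
  out <- list(config = config, surface = surface, scores = tab,
              patches = patches, seeds = seeds,
              seed_clusters = seed_clusters, sites = sites,
              regions = regions, evaluation = evaluation, coverage = cov,
              manifest = manifest)
  class(out) <- "surf_run"
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  w(run$surface, "surface.tsv")
  w(run$scores, "scores.tsv")
  if (nrow(run$patches) > 0) w(run$patches, "patches.tsv")
  if (!is.null(run$regions) && nrow(run$regions) > 0) {
    w(tidy(run$regions), "regions.tsv")
  }
  if (!is.null(run$evaluation)) {
    w(select(run$evaluation, -"members"), "evaluation.tsv")
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.surf_run <- function(x, ...) {
  cat("surfpatch run\n")
  cat(sprintf("  surface residues: %d\n", sum(x$surface$surface)))
  cat(sprintf("  strategies: %s\n",
              paste(x$manifest$strategies, collapse = ", ")))
  cat(sprintf("  predicted patches: %d (%d residues)\n",
              length(unique(paste(x$patches$strategy, x$patches$patch_id))),
              length(unique(x$patches$res_uid))))
  if (!is.null(x$regions)) {
    cat(sprintf("  interacting regions: %d\n", nrow(x$regions)))
  }
  if (!is.null(x$evaluation)) {
    cat(sprintf("  mean best-match F1: %.3f\n", mean(x$evaluation$f1)))
  }
  invisible(x)
}
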