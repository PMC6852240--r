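# Residue-level scoring of predictions against experimental interfaces,
# surface coverage, and conformational variability of interacting regions.

#' Precision, recall and F1 between residue sets
#'
#' `P = |pred n truth| / |pred|`, `R = |pred n truth| / |truth|`, F1 their
#' harmonic mean (0 when `P + R = 0`); an empty prediction scores `P = 0`.
#'
#' @param predicted,truth Residue-id vectors on the same chain numbering.
#' @return One-row tibble `precision`, `recall`, `f1`, `tp`, `fp`, `fn`
#'   (counts) plus list-columns with the residue sets.
#' @export
prf <- function(predicted, truth) {
  predicted <- unique(predicted); truth <- unique(truth)
  tp_set <- intersect(predicted, truth)
  fp_set <- setdiff(predicted, truth)
  fn_set <- setdiff(truth, predicted)
  p <- if (length(predicted) == 0) 0 else length(tp_set) / length(predicted)
  r <- if (length(truth) == 0) 0 else length(tp_set) / length(truth)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble(precision = p, recall = r, f1 = f1,
         tp = length(tp_set), fp = length(fp_set), fn = length(fn_set),
         tp_set = list(sort(tp_set)), fp_set = list(sort(fp_set)),
         fn_set = list(sort(fn_set)))
}

#' Best-matching patch (or combination of patches) per interacting region
#'
#' For each region, searches the patch subsets whose union maximises the
#' F1-score against the region (ties broken by the smaller union).  The
#' search is exhaustive up to `max_exhaustive` patches; beyond that a
#' greedy forward search is used with a warning.
#'
#' @param patches Named list of residue-id vectors (one per patch), or a
#'   `surf_patches` tibble (split by strategy and patch id).
#' @param regions Named list of residue-id vectors, or a `surf_regions`
#'   tibble.
#' @param max_exhaustive Exhaustive-search cap (default 12 patches).
#' @return Tibble of class `surf_eval`: one row per region with
#'   `region`, `members` (patch labels in the best subset), `precision`,
#'   `recall`, `f1`, `missed` (no overlapping patch at all).
#' @export
best_match <- function(patches, regions, max_exhaustive = 12) {
  pl <- as_named_sets(patches, prefix = "patch")
  rl <- as_named_sets(regions, prefix = "IR")
  if (length(pl) == 0) abort("no patches to match")
  search_one <- function(truth) {
    k <- length(pl)
    if (k <= max_exhaustive) {
      best <- list(f1 = -1, size = Inf, members = character(0),
                   p = 0, r = 0)
      for (mask in seq_len(2^k - 1)) {
        idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
        u <- unique(unlist(pl[idx], use.names = FALSE))
        m <- prf(u, truth)
        if (m$f1 > best$f1 + 1e-12 ||
            (abs(m$f1 - best$f1) <= 1e-12 && length(u) < best$size)) {
          best <- list(f1 = m$f1, size = length(u), members = names(pl)[idx],
                       p = m$precision, r = m$recall)
        }
      }
      best
    } else {
      warn("more patches than the exhaustive cap; using greedy search")
      chosen <- integer(0); cur <- list(f1 = 0, p = 0, r = 0)
      repeat {
        cand <- setdiff(seq_len(k), chosen)
        gains <- map_dbl(cand, function(i) {
          prf(unique(unlist(pl[c(chosen, i)], use.names = FALSE)), truth)$f1
        })
        if (length(cand) == 0 || max(gains) <= cur$f1) break
        chosen <- c(chosen, cand[which.max(gains)])
        u <- unique(unlist(pl[chosen], use.names = FALSE))
        m <- prf(u, truth)
        cur <- list(f1 = m$f1, p = m$precision, r = m$recall)
      }
      u <- unique(unlist(pl[chosen], use.names = FALSE))
      list(f1 = cur$f1, size = length(u), members = names(pl)[chosen],
           p = cur$p, r = cur$r)
    }
  }
  out <- purrr::imap(rl, function(truth, nm) {
    b <- search_one(truth)
    missed <- b$f1 <= 0
    tibble(region = nm,
           members = list(if (missed) character(0) else b$members),
           precision = if (missed) 0 else b$p,
           recall = if (missed) 0 else b$r,
           f1 = max(b$f1, 0), missed = missed)
  }) |> bind_rows()
  structure(out, class = c("surf_eval", class(tibble())))
}

as_named_sets <- function(x, prefix = "set") {
  if (inherits(x, "surf_patches")) {
    sp <- split(x$res_uid, sprintf("%s.%d", x$strategy, x$patch_id))
    lapply(sp, unique)
  } else if (inherits(x, "surf_regions") ||
             (is.data.frame(x) && "residues" %in% names(x))) {
    setNames(x$residues, paste0(prefix, x$region_id %||% seq_len(nrow(x))))
  } else {
    if (is.null(names(x))) names(x) <- paste0(prefix, seq_along(x))
    x
  }
}

#' Fraction of the surface covered by a union of residue sets
#'
#' @param sets List of residue-id vectors (subsets of the surface).
#' @param surface_ids Character vector of surface residue ids.
#' @return `|union| / |surface|`.
#' @export
coverage <- function(sets, surface_ids) {
  if (length(surface_ids) == 0) abort("empty surface")
  u <- unique(unlist(sets, use.names = FALSE))
  length(intersect(u, surface_ids)) / length(surface_ids)
}

#' Least-squares superposition (Kabsch) RMSD
#'
#' Optimally superposes two paired coordinate sets by the Kabsch SVD
#' rotation (reflections excluded) and returns the residual RMSD.
#'
#' @param X,Y n x 3 coordinate matrices with paired rows.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3, ncol(Y) == 3)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  sv <- svd(crossprod(Yc, Xc))
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  Yr <- Yc %*% R
  sqrt(mean(rowSums((Xc - Yr)^2)))
}

#' Conformational variability of an interacting region
#'
#' For each homolog structure on which the region was detected, the
#' region's backbone atoms (N, CA, C, O; CA-only fallback when the full
#' backbone is not shared) are least-squares superposed onto the query and
#' the RMSD recorded; the mean over homologs is returned.
#'
#' @param ir_residues Residue ids of the region on the query chain.
#' @param query Query [read_structure()] tibble.
#' @param homologs List of entries, each a list with fields `structure`
#'   (a `surf_structure`), `map` (named character vector: query residue id
#'   -> homolog residue id) and optionally `detected` (region residues
#'   detected on this homolog; defaults to all mappable ones).
#' @return List with `mean_rmsd` (Angstrom) and `per_homolog` tibble
#'   (`homolog`, `rmsd`, `n_residues`, `atoms`).
#' @export
ir_rmsd <- function(ir_residues, query, homologs) {
  per <- purrr::imap(homologs, function(h, nm) {
    res_q <- intersect(ir_residues, h$detected %||% names(h$map))
    res_q <- res_q[res_q %in% names(h$map)]
    if (length(res_q) < 3) {
      warn(sprintf("homolog %s: fewer than 3 mappable region residues; skipped", nm))
      return(NULL)
    }
    bb <- c("N", "CA", "C", "O")
    pair_coords <- function(atoms) {
      qa <- filter(query, .data$res_uid %in% res_q, .data$atom %in% atoms)
      ha <- filter(h$structure, .data$res_uid %in% unname(h$map[res_q]),
                   .data$atom %in% atoms)
      qa <- mutate(qa, key = paste(.data$res_uid, .data$atom))
      ha <- mutate(ha, key = paste(names(h$map)[match(.data$res_uid, h$map)],
                                   .data$atom))
      common <- intersect(qa$key, ha$key)
      list(X = as.matrix(qa[match(common, qa$key), c("x", "y", "z")]),
           Y = as.matrix(ha[match(common, ha$key), c("x", "y", "z")]),
           n = length(common))
    }
    pc <- pair_coords(bb)
    atoms_used <- "backbone"
    if (pc$n < 3) {  # backbone not shared -> CA-only fallback
      pc <- pair_coords("CA")
      atoms_used <- "CA"
      if (pc$n < 3) {
        warn(sprintf("homolog %s: too few paired atoms; skipped", nm))
        return(NULL)
      }
    }
    tibble(homolog = as.character(nm), rmsd = kabsch_rmsd(pc$X, pc$Y),
           n_residues = length(res_q), atoms = atoms_used)
  }) |> bind_rows()
  if (nrow(per) == 0) abort("no homolog could be superposed")
  list(mean_rmsd = mean(per$rmsd), per_homolog = per)
}
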