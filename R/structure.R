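#' Read a protein structure from PDB-format text
#'
#' Parses a PDB file (or in-memory PDB text) into an atom-level tibble with
#' one row per atom.  Heteroatoms are excluded by default and water is always
#' excluded; alternate locations are resolved to the highest-occupancy
#' conformer.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB-format lines.
#' @param model Which MODEL to read when the file holds several:
#'   `"first"` (default) or an integer index via `model_index`.
#' @param model_index Integer model index used when `model = "index"`.
#' @param keep_hetero Keep non-water HETATM records? Default `FALSE`.
#' @param id Structure identifier stored in the `"id"` attribute; defaults to
#'   the file name (or `"structure"` for in-memory text).
#'
#' @return A tibble of class `surf_structure` with columns `chain`, `resno`,
#'   `icode`, `restype`, `res_uid`, `atom`, `element`, `x`, `y`, `z`.
#'   Residues appear in author order.
#' @examples
#' pdb <- fixture_pdb_lines()
#' s <- read_structure(pdb)
#' dplyr::count(s, chain)
#' @export
read_structure <- function(pdb, model = c("first", "index"), model_index = 1L,
                           keep_hetero = FALSE, id = NULL) {
  model <- match.arg(model)
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    id <- id %||% sub("\\.(pdb|ent)$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n"))
    id <- id %||% "structure"
  }
  if (length(lines) == 0 || all(!nzchar(lines))) {
    abort("empty PDB input: no records found")
  }
  atom_idx <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(atom_idx)) {
    bad <- which(nzchar(lines))[1]
    abort(sprintf("no ATOM/HETATM records; first non-blank line %d: '%s'",
                  bad, substr(lines[bad], 1, 30)))
  }
  # model selection on raw lines so bio3d sees a single model
  if (any(grepl("^MODEL", lines))) {
    starts <- grep("^MODEL", lines)
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts)) ends <- c(ends, length(lines))
    k <- if (model == "first") 1L else as.integer(model_index)
    if (k < 1L || k > length(starts)) {
      abort(sprintf("model index %d out of range (%d models)", k, length(starts)))
    }
    keep <- seq(starts[k] + 1L, ends[k] - 1L)
    lines <- lines[keep]
  }
  recs <- lines[grepl("^(ATOM  |HETATM)", lines)]
  coords <- suppressWarnings(cbind(
    as.numeric(substr(recs, 31, 38)),
    as.numeric(substr(recs, 39, 46)),
    as.numeric(substr(recs, 47, 54))
  ))
  if (anyNA(coords)) {
    bad <- which(apply(coords, 1, anyNA))[1]
    abort(sprintf("unparsable coordinates in record: '%s'", recs[bad]))
  }
  occ <- suppressWarnings(as.numeric(substr(recs, 55, 60)))
  occ[is.na(occ)] <- 1
  at <- tibble(
    type = trimws(substr(recs, 1, 6)),
    atom = trimws(substr(recs, 13, 16)),
    alt = trimws(substr(recs, 17, 17)),
    restype = trimws(substr(recs, 18, 20)),
    chain = trimws(substr(recs, 22, 22)),
    resno = as.integer(substr(recs, 23, 26)),
    icode = trimws(substr(recs, 27, 27)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occ = occ,
    element = trimws(substr(recs, 77, 78))
  )
  at$element <- ifelse(nzchar(at$element), at$element,
                       substr(gsub("^[0-9]", "", at$atom), 1, 1))
  at <- filter(at, .data$restype != "HOH")
  if (!keep_hetero) at <- filter(at, .data$type == "ATOM")
  if (nrow(at) == 0) abort("no atoms left after heteroatom/water filtering")
  # altloc: keep highest-occupancy conformer per (residue, atom name)
  at <- at |>
    mutate(.ord = row_number()) |>
    group_by(.data$chain, .data$resno, .data$icode, .data$atom) |>
    arrange(dplyr::desc(.data$occ), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$.ord)
  out <- at |>
    mutate(res_uid = res_uid(.data$chain, .data$resno, .data$icode)) |>
    select("chain", "resno", "icode", "restype", "res_uid",
           "atom", "element", "x", "y", "z")
  new_structure(out, id)
}

new_structure <- function(tbl, id = "structure") {
  out <- as_tibble(tbl)
  stopifnot(all(c("chain", "resno", "icode", "restype", "res_uid",
                  "atom", "element", "x", "y", "z") %in% names(out)))
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    abort("non-finite atom coordinates")
  }
  attr(out, "id") <- id
  class(out) <- c("surf_structure", class(tibble()))
  out
}

#' Write a structure to a PDB file
#'
#' @param s A `surf_structure` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  xyz <- as.vector(t(as.matrix(s[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(s)),
    resno = s$resno, resid = s$restype, chain = s$chain,
    insert = ifelse(nzchar(s$icode), s$icode, ""),
    elety = s$atom, elesy = s$element,
    o = rep(1, nrow(s)), b = rep(0, nrow(s))
  )
  invisible(path)
}

#' List residues of a structure
#'
#' One row per residue in author order, with the atom count.
#' @param s A `surf_structure`.
#' @param chains Optional chain subset.
#' @return Tibble with `chain`, `resno`, `icode`, `restype`, `res_uid`,
#'   `n_atoms`.
#' @export
structure_residues <- function(s, chains = NULL) {
  if (!is.null(chains)) s <- filter(s, .data$chain %in% chains)
  s |>
    group_by(.data$chain, .data$resno, .data$icode, .data$restype,
             .data$res_uid) |>
    summarise(n_atoms = n(), .groups = "drop") |>
    arrange(match(.data$res_uid, unique(s$res_uid)))
}

# coordinate matrix + residue index for a residue-id subset
atom_coords <- function(s, uids = NULL) {
  if (!is.null(uids)) s <- filter(s, .data$res_uid %in% uids)
  list(xyz = as.matrix(s[, c("x", "y", "z")]), uid = s$res_uid,
       atom = s$atom)
}

cross_dist <- function(A, B) {
  # Euclidean distances between rows of A and rows of B
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# minimum inter-atom distance for candidate residue pairs between two sets;
# centroid prefilter keeps this near-linear for compact structures
residue_min_dists <- function(s, uids_a, uids_b, max_dist = 5) {
  ca <- atom_coords(s, uids_a); cb <- atom_coords(s, uids_b)
  cen_a <- rowsum(ca$xyz, ca$uid); cnt_a <- as.vector(rowsum(rep(1, length(ca$uid)), ca$uid))
  cen_a <- cen_a / cnt_a
  cen_b <- rowsum(cb$xyz, cb$uid); cnt_b <- as.vector(rowsum(rep(1, length(cb$uid)), cb$uid))
  cen_b <- cen_b / cnt_b
  # generous prefilter radius: residues span at most ~12 A from centroid here
  pre <- cross_dist(cen_a, cen_b) < (max_dist + 16)
  ia <- rownames(cen_a); ib <- rownames(cen_b)
  idx <- which(pre, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(uid_a = character(), uid_b = character(), dist = numeric()))
  }
  split_a <- split(seq_along(ca$uid), ca$uid)
  split_b <- split(seq_along(cb$uid), cb$uid)
  d <- vapply(seq_len(nrow(idx)), function(k) {
    A <- ca$xyz[split_a[[ia[idx[k, 1]]]], , drop = FALSE]
    B <- cb$xyz[split_b[[ib[idx[k, 2]]]], , drop = FALSE]
    min(cross_dist(A, B))
  }, numeric(1))
  tibble(uid_a = ia[idx[, 1]], uid_b = ib[idx[, 2]], dist = d)
}

# undirected residue contact pairs (< cutoff between any atoms) within a set
residue_adjacency <- function(s, uids, cutoff = 5) {
  dd <- residue_min_dists(s, uids, uids, max_dist = cutoff)
  dd |>
    filter(.data$uid_a < .data$uid_b, .data$dist < cutoff) |>
    select(uid_a = "uid_a", uid_b = "uid_b", dist = "dist")
}

# connected components over residue ids given contact pairs
contact_components <- function(uids, pairs) {
  comp <- stats::setNames(seq_along(uids), uids)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(match(pairs$uid_a[k], uids))
      b <- find(match(pairs$uid_b[k], uids))
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_along(uids), find, integer(1))
  split(uids, match(roots, unique(roots)))
}
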