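# Synthetic fixtures: idealised helical complexes with planted contact
# regions, homolog pools with planted conserved columns, and docking pose
# sets with a planted hot region.  These emulate the inputs the analysis
# consumes (structures, aligned homolog pools, pose records) without
# claiming physically realistic folds or energetics.

aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

# idealised alpha-helix: CA trace of radius 2.3 A, 1.5 A rise, 100 deg/res,
# with N/C/O/CB placed at plausible offsets
helix_atoms <- function(n_res, seq1) {
  th <- (seq_len(n_res) - 1) * 100 * pi / 180
  r <- 2.3
  ca <- cbind(r * cos(th), r * sin(th), (seq_len(n_res) - 1) * 1.5)
  prev <- rbind(ca[1, ] - c(0, 0, 1.5), ca[-n_res, , drop = FALSE])
  nxt <- rbind(ca[-1, , drop = FALSE], ca[n_res, ] + c(0, 0, 1.5))
  nn <- 0.65 * ca + 0.35 * prev
  cc <- 0.65 * ca + 0.35 * nxt
  rad <- cbind(cos(th), sin(th), 0)
  oo <- cc + 1.23 * rad
  cb <- ca + 1.53 * rad
  out <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    xyz <- rbind(nn[i, ], ca[i, ], cc[i, ], oo[i, ], cb[i, ])
    out[[i]] <- tibble(resno = i, restype = unname(aa3[seq1[i]]),
                       atom = c("N", "CA", "C", "O", "CB"),
                       element = c("N", "C", "C", "O", "C"),
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  bind_rows(out)
}

rot_y180 <- function(xyz) cbind(-xyz[, 1], xyz[, 2], -xyz[, 3])
rot_z <- function(xyz, phi) cbind(cos(phi) * xyz[, 1] - sin(phi) * xyz[, 2],
                                  sin(phi) * xyz[, 1] + cos(phi) * xyz[, 2],
                                  xyz[, 3])

# one shell "residue" per grid point of a cylindrical sector around the
# query helix axis; single carbon atom, poly-GLY chain
shell_atoms <- function(radius, theta_range, z_range, d_theta = 20,
                        d_z = 2.5) {
  th <- seq(theta_range[1], theta_range[2], by = d_theta) * pi / 180
  zz <- seq(z_range[1], z_range[2], by = d_z)
  g <- expand.grid(th = th, z = zz)
  tibble(resno = seq_len(nrow(g)), restype = "GLY", atom = "CA",
         element = "C", x = radius * cos(g$th), y = radius * sin(g$th),
         z = g$z)
}

#' Generate a synthetic helical complex with a planted contact region
#'
#' Builds one query helix (chain A) surrounded by one or more partner
#' chains shaped as cylindrical shell sectors at a `gap` Angstrom gap from
#' the helix side chains.  A partner covering a window of the helix makes
#' every residue of that window interfacial by construction, so the
#' planted interface is a contiguous, 5 A-connected stretch of
#' controllable size.  The ground truth is recorded at zero noise by a
#' brute-force all-atom contact scan restricted to surface residues (the
#' package's interface definition); coordinate noise is added afterwards.
#'
#' @param n_res Residues of the query helix (default 30).
#' @param contact_window Integer range `c(first, last)` of query residues
#'   the first partner faces (default the middle third).
#' @param partners List of partner specs, each
#'   `list(theta = c(min, max))` in degrees (default full wrap) and
#'   optionally `window = c(first, last)`; defaults to a single
#'   full-wrap partner over `contact_window`.  Partners whose sectors
#'   come closer than 5 A touch each other.
#' @param gap Closest approach between query side-chain atoms and the
#'   partner shell (default 4.5 A, inside the 5 A contact cutoff).
#' @param noise_sd Coordinate noise s.d. in Angstrom, added after the
#'   truth is recorded (default 0).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param seq Optional one-letter query sequence.
#' @return List with `structure` (a `surf_structure`), `truth` (named list
#'   of interface residue ids per chain from the zero-noise brute-force
#'   scan), `sequences` (one-letter, per chain) and `pdb_lines`.
#' @examples
#' cx <- make_complex(n_res = 14, seed = 1)
#' length(cx$truth$A)
#' @export
make_complex <- function(n_res = 30, contact_window = NULL, partners = NULL,
                         gap = 4.5, noise_sd = 0, seed = 1, seq = NULL) {
  stopifnot(noise_sd >= 0, n_res >= 6)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  contact_window <- contact_window %||%
    c(floor(n_res / 3) + 1, floor(2 * n_res / 3))
  partners <- partners %||% list(list(theta = c(0, 340)))
  if (length(partners) > length(LETTERS) - 1) abort("too many partners")
  chains <- LETTERS[seq_len(length(partners) + 1)]
  seq <- seq %||% paste(sample(names(aa3), n_res, replace = TRUE),
                        collapse = "")
  seqs <- c(seq, rep(NA_character_, length(partners)))
  atoms <- list(mutate(helix_atoms(n_res, strsplit(seq, "")[[1]]),
                       chain = chains[1]))
  radius <- 2.3 + 1.53 + gap
  for (k in seq_along(partners)) {
    p <- partners[[k]]
    win <- p$window %||% contact_window
    zr <- c((win[1] - 1) * 1.5 - 0.75, (win[2] - 1) * 1.5 + 0.75)
    sh <- shell_atoms(radius, p$theta %||% c(0, 340), zr)
    sh$chain <- chains[k + 1]
    seqs[k + 1] <- strrep("G", nrow(sh))
    atoms[[k + 1]] <- sh
  }
  at <- bind_rows(atoms) |>
    mutate(icode = "", res_uid = res_uid(.data$chain, .data$resno, "")) |>
    select("chain", "resno", "icode", "restype", "res_uid", "atom",
           "element", "x", "y", "z")
  s0 <- new_structure(at, id = sprintf("synthetic_%d", seed))
  # clash gate on the noiseless geometry
  n_chains <- length(chains)
  for (i in seq_len(n_chains - 1)) for (j in (i + 1):n_chains) {
    dd <- residue_min_dists(s0, unique(at$res_uid[at$chain == chains[i]]),
                            unique(at$res_uid[at$chain == chains[j]]))
    if (nrow(dd) > 0 && min(dd$dist) < 2.0) {
      abort("infeasible geometry: chains clash beyond tolerance")
    }
  }
  truth <- lapply(chains, function(ch) {
    others <- setdiff(chains, ch)
    brute_force_interface(s0, ch, others, cutoff = 5)
  })
  names(truth) <- chains
  s <- s0
  if (noise_sd > 0) {
    s$x <- s$x + rnorm(nrow(s), 0, noise_sd)
    s$y <- s$y + rnorm(nrow(s), 0, noise_sd)
    s$z <- s$z + rnorm(nrow(s), 0, noise_sd)
  }
  tf <- tempfile(fileext = ".pdb")
  write_structure(s, tf)
  lines <- readLines(tf); unlink(tf)
  list(structure = s, truth = truth, sequences = setNames(seqs, chains),
       pdb_lines = lines)
}

# O(n^2) all-atom-pair oracle for the interface of `chain` vs `others`,
# restricted to monomer-surface residues; independent of detect_interface's
# prefiltered path
brute_force_interface <- function(s, chain, others, cutoff = 5) {
  A <- filter(s, .data$chain == !!chain)
  B <- filter(s, .data$chain %in% others)
  D <- cross_dist(as.matrix(A[, c("x", "y", "z")]),
                  as.matrix(B[, c("x", "y", "z")]))
  hit <- unique(A$res_uid[apply(D < cutoff, 1, any)])
  surf <- compute_rasa(s, chains = chain)
  sort(intersect(hit, surf$res_uid[surf$surface]))
}

#' Generate an aligned homolog pool with planted conserved columns
#'
#' Homologs are derived from the query by random substitutions targeting a
#' per-bin identity (drawn uniformly within each requested bin), leaving a
#' designated set of conserved columns untouched -- the planted
#' conservation signal.
#'
#' @param query One-letter query sequence.
#' @param n_per_bin Integer vector of homolog counts for the four identity
#'   bins 20-39, 40-59, 60-79 and 80-98 percent.
#' @param conserved_cols Integer positions never mutated.
#' @param seed Integer seed.
#' @return A [homolog_pool()] with realized identities recorded.
#' @export
make_homolog_pool <- function(query, n_per_bin = c(5, 5, 5, 5),
                              conserved_cols = integer(0), seed = 1) {
  stopifnot(length(n_per_bin) == 4, all(n_per_bin >= 0))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  L <- nchar(query)
  q <- strsplit(query, "")[[1]]
  free <- setdiff(seq_len(L), conserved_cols)
  lo <- c(21, 40, 60, 80); hi <- c(39, 59, 79, 98)
  rows <- list()
  idx <- 0
  for (b in 1:4) {
    for (k in seq_len(n_per_bin[b])) {
      idx <- idx + 1
      target <- runif(1, lo[b], hi[b])
      n_mut <- round(L * (1 - target / 100))
      if (n_mut > length(free)) {
        warn("not enough mutable columns to reach the target identity")
        n_mut <- length(free)
      }
      h <- q
      pos <- sample(free, n_mut)
      for (p in pos) h[p] <- sample(setdiff(names(aa3), q[p]), 1)
      rows[[idx]] <- tibble(name = sprintf("h%03d", idx),
                            seq = paste(h, collapse = ""),
                            identity = 100 * (1 - n_mut / L))
    }
  }
  if (length(rows) == 0) {
    return(homolog_pool(query, tibble(name = character(), seq = character(),
                                      identity = numeric())))
  }
  homolog_pool(query, bind_rows(rows))
}

#' Generate a docking pose set with a planted hot region
#'
#' Each pose's interface residues are drawn from the surface with sampling
#' weight `bias` inside the hot region and 1 outside; pose energies are
#' drawn lower (more favourable) the more a pose overlaps the hot region.
#'
#' @param surface_ids Character vector of surface residue ids.
#' @param hot_region Subset of `surface_ids` forming the planted signal.
#' @param bias Sampling weight ratio inside vs outside (>= 1; default 10).
#' @param n_poses Number of poses (default 500).
#' @param n_partners Number of synthetic partners the poses are spread
#'   over (default 5).
#' @param seed Integer seed.
#' @return Pose tibble (`pose_id`, `partner_id`, `energy`, `residues`)
#'   suitable for [filter_poses()].
#' @export
make_poses <- function(surface_ids, hot_region, bias = 10, n_poses = 500,
                       n_partners = 5, seed = 1) {
  stopifnot(bias >= 1, all(hot_region %in% surface_ids))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  w <- ifelse(surface_ids %in% hot_region, bias, 1)
  m_target <- max(3, length(hot_region))
  rows <- lapply(seq_len(n_poses), function(i) {
    m <- min(max(3, rpois(1, m_target)), length(surface_ids))
    res <- sample(surface_ids, m, prob = w)
    overlap <- length(intersect(res, hot_region)) / max(length(hot_region), 1)
    tibble(pose_id = sprintf("p%05d", i),
           partner_id = sprintf("partner%02d", 1 + (i %% n_partners)),
           energy = rnorm(1, -8, 1.5) - 4 * overlap,
           residues = list(sort(res)))
  })
  bind_rows(rows)
}

#' Minimal hand-written PDB text for parser examples and tests
#'
#' Three residues on one chain, the first with A/B alternate locations
#' (occupancies 0.6/0.4).
#' @return Character vector of PDB lines.
#' @export
fixture_pdb_lines <- function() {
  c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.60 10.00           N",
    "ATOM      2  N  BALA A   1       0.500   0.000   0.000  0.40 10.00           N",
    "ATOM      3  CA AALA A   1       1.458   0.000   0.000  0.60 10.00           C",
    "ATOM      4  CA BALA A   1       1.958   0.000   0.000  0.40 10.00           C",
    "ATOM      5  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      6  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    "ATOM      7  N   GLY A   2       3.332   1.536   0.000  1.00 10.00           N",
    "ATOM      8  CA  GLY A   2       3.988   2.839   0.000  1.00 10.00           C",
    "ATOM      9  C   GLY A   2       5.504   2.693   0.000  1.00 10.00           C",
    "ATOM     10  O   GLY A   2       6.030   1.581   0.000  1.00 10.00           O",
    "ATOM     11  N   SER A   3       6.235   3.801   0.000  1.00 10.00           N",
    "ATOM     12  CA  SER A   3       7.689   3.790   0.000  1.00 10.00           C",
    "ATOM     13  C   SER A   3       8.250   5.202   0.000  1.00 10.00           C",
    "ATOM     14  O   SER A   3       7.507   6.184   0.000  1.00 10.00           O",
    "HETATM   15  O   HOH A 101       9.000   9.000   9.000  1.00 10.00           O",
    "END"
  )
}
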