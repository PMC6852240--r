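# Solvent accessibility by Shrake-Rupley sphere sampling.
#
# A deterministic golden-spiral point set replaces random sampling so that
# results are bit-reproducible at fixed resolution.  The probe radius is
# 1.4 A (water) and per-element van der Waals radii follow Bondi.

vdw_radius <- function(element) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
           SE = 1.90)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Reference maximal per-residue ASA (A^2), theoretical values of
# Tien et al. (2013) PLoS ONE 8:e80635; used to normalise ASA into rasa.
#' Reference maximal accessible surface areas
#'
#' Theoretical maximum accessible surface area per residue type
#' (Tien et al. 2013), used to normalise absolute ASA into relative
#' accessibility (rasa).
#' @return Named numeric vector (A^2) over the 20 standard residues.
#' @export
max_asa_reference <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

# deterministic unit sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# absolute ASA per atom for the atoms of `s` (all used as occluders)
shrake_rupley <- function(s, n_points = 960, probe = 1.4) {
  xyz <- as.matrix(s[, c("x", "y", "z")])
  r <- vdw_radius(s$element) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  D <- cross_dist(xyz, xyz)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < r[i] + r & seq_len(n) != i)
    if (length(nb) == 0) { asa[i] <- 4 * pi * r[i]^2; next }
    P <- sweep(pts * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    # nearest occluders first: most points die early
    nb <- nb[order(D[i, nb])]
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (P[free, 1] - xyz[j, 1])^2 + (P[free, 2] - xyz[j, 2])^2 +
        (P[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 >= r[j]^2
    }
    asa[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  asa
}

#' Relative accessible surface area and surface definition
#'
#' Computes per-residue absolute ASA (Shrake-Rupley sphere sampling, probe
#' 1.4 A, deterministic spiral point set) within a chain context, normalises
#' it by the per-residue-type reference maximum, and flags surface residues
#' (rasa >= 5\% by default).
#'
#' @param s A [read_structure()] tibble.
#' @param chains Chains forming the occlusion context; accessibility is
#'   reported for the residues of these chains.  Default: all chains.
#' @param n_points Sphere sample points per atom (default 960).
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param surface_threshold rasa threshold for the surface flag
#'   (default 0.05; "at least" semantics, i.e. `>=`).
#' @param reference Named vector of reference maximal ASA values; defaults
#'   to [max_asa_reference()].  Residue types absent from the table are
#'   dropped with a warning.
#'
#' @return Tibble of class `surf_surface`: `chain`, `resno`, `icode`,
#'   `restype`, `res_uid`, `asa`, `rasa`, `surface`.
#' @examples
#' s <- make_complex(n_res = 12, seed = 1)$structure
#' compute_rasa(s, chains = "A")
#' @export
compute_rasa <- function(s, chains = NULL, n_points = 960, probe = 1.4,
                         surface_threshold = 0.05,
                         reference = max_asa_reference()) {
  if (is.null(chains)) chains <- unique(s$chain)
  ctx <- filter(s, .data$chain %in% chains)
  if (nrow(ctx) == 0) abort("no atoms in the requested chain context")
  asa_atom <- shrake_rupley(ctx, n_points = n_points, probe = probe)
  res <- ctx |>
    mutate(.asa = asa_atom) |>
    group_by(.data$chain, .data$resno, .data$icode, .data$restype,
             .data$res_uid) |>
    summarise(asa = sum(.data$.asa), .groups = "drop") |>
    arrange(match(.data$res_uid, unique(ctx$res_uid)))
  unknown <- setdiff(unique(res$restype), names(reference))
  if (length(unknown) > 0) {
    warn(sprintf("residue types without reference ASA dropped from surface: %s",
                 paste(unknown, collapse = ", ")))
    res <- filter(res, .data$restype %in% names(reference))
  }
  res |>
    mutate(rasa = .data$asa / unname(reference[.data$restype]),
           surface = .data$rasa >= surface_threshold) |>
    structure(class = c("surf_surface", class(tibble())))
}
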