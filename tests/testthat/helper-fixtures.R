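# Shared synthetic fixtures, built once per test run.

CX <- make_complex(n_res = 40, seed = 1)
TRUTH_A <- CX$truth$A
WIN_A <- as.integer(sub("A\\|(\\d+)\\|", "\\1", TRUTH_A))
SURF_A <- compute_rasa(CX$structure, chains = "A")
SURF_IDS_A <- SURF_A$res_uid[SURF_A$surface]
POOL_A <- suppressWarnings(
  make_homolog_pool(CX$sequences[["A"]], n_per_bin = c(8, 8, 8, 8),
                    conserved_cols = WIN_A, seed = 3)
)
POSES_A <- make_poses(SURF_IDS_A, TRUTH_A, bias = 10, n_poses = 300,
                      seed = 2)

# structure from bare atom records (one row per atom) for geometric cases
toy_structure <- function(df, id = "toy") {
  df <- tibble::as_tibble(df)
  if (!"icode" %in% names(df)) df$icode <- ""
  if (!"restype" %in% names(df)) df$restype <- "ALA"
  if (!"atom" %in% names(df)) df$atom <- "CA"
  if (!"element" %in% names(df)) df$element <- "C"
  df$res_uid <- surfpatch:::res_uid(df$chain, df$resno, df$icode)
  surfpatch:::new_structure(
    df[, c("chain", "resno", "icode", "restype", "res_uid", "atom",
           "element", "x", "y", "z")], id = id)
}

# independent O(n^2) all-atom interface scan (surface-restricted)
oracle_interface <- function(s, chain, others, cutoff = 5) {
  A <- s[s$chain == chain, ]
  B <- s[s$chain %in% others, ]
  hits <- character(0)
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B$x - A$x[i])^2 + (B$y - A$y[i])^2 + (B$z - A$z[i])^2)
    if (any(d < cutoff)) hits <- c(hits, A$res_uid[i])
  }
  surf <- compute_rasa(s, chains = chain)
  sort(intersect(unique(hits), surf$res_uid[surf$surface]))
}

# naive average-linkage (UPGMA over atom sets) oracle: repeatedly merge the
# pair of clusters with minimal mean inter-atom distance until it exceeds
# the cut; returns seed-index sets
oracle_upgma <- function(atom_sets, cut) {
  cl <- lapply(seq_along(atom_sets),
               function(i) list(idx = i, xyz = atom_sets[[i]]))
  repeat {
    n <- length(cl)
    if (n == 1) break
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- mean(surfpatch:::cross_dist(cl[[i]]$xyz, cl[[j]]$xyz))
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    if (bd > cut) break
    cl[[best[1]]] <- list(idx = c(cl[[best[1]]]$idx, cl[[best[2]]]$idx),
                          xyz = rbind(cl[[best[1]]]$xyz, cl[[best[2]]]$xyz))
    cl <- cl[-best[2]]
  }
  lapply(cl, function(x) sort(x$idx))
}

# naive re-derivation of the IS -> IR closure: scan canonically ordered
# pairs, merge the first eligible one, restart; drop small regions last
oracle_region_closure <- function(sites, thr = 0.60, small = 5, min_sz = 5) {
  regs <- unname(lapply(sites, function(r) sort(unique(r))))
  elig <- function(a, b) {
    ov <- length(intersect(a, b))
    if (ov == 0) return(FALSE)
    if (min(length(a), length(b)) <= small) return(TRUE)
    max(ov / length(a), ov / length(b)) > thr
  }
  repeat {
    ord <- order(-vapply(regs, length, integer(1)),
                 vapply(regs, function(r) r[1], character(1)))
    regs <- regs[ord]
    n <- length(regs)
    hit <- FALSE
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (elig(regs[[i]], regs[[j]])) {
            regs[[i]] <- sort(union(regs[[i]], regs[[j]]))
            regs <- regs[-j]; hit <- TRUE; break
          }
        }
        if (hit) break
      }
    }
    if (!hit) break
  }
  regs <- regs[vapply(regs, length, integer(1)) > min_sz]
  regs[order(-vapply(regs, length, integer(1)),
             vapply(regs, function(r) r[1], character(1)))]
}

# independent Monte-Carlo sphere-occlusion ASA oracle
oracle_asa <- function(s, n_points = 20000, probe = 1.4, seed = 99) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  r <- unname(radii[toupper(s$element)]); r[is.na(r)] <- 1.70
  r <- r + probe
  xyz <- as.matrix(s[, c("x", "y", "z")])
  set.seed(seed)
  g <- matrix(stats::rnorm(3 * n_points), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  asa <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    P <- sweep(g * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      d2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      free <- free & d2 >= r[j]^2
    }
    asa[i] <- 4 * pi * r[i]^2 * mean(free)
  }
  tapply(asa, s$res_uid, sum)
}
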