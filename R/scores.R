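# Per-residue surface descriptors and the assembled score table feeding the
# patch-growing strategies.

#' Circular variance of each residue
#'
#' Atomic circular variance `CV_i = 1 - ||sum_j r_ij/||r_ij|| || / n_i`
#' over the `n_i` atoms within `r_c` of atom `i`; a residue's CV is the
#' mean over its (heavy, by default) atoms.  Low values mark protruding
#' residues, high values buried ones.  The raw values lie in [0, 1]; the
#' min-max rescaling over surface residues mandated for score combination
#' happens in [assemble_score_table()].
#'
#' @param s A [read_structure()] tibble.
#' @param r_c Neighbourhood radius in Angstrom (default 100, effectively
#'   global density).
#' @param chains Chains whose atoms act as the density context (default all).
#' @param heavy_only Drop hydrogens before averaging (default `TRUE`).
#' @return Tibble `res_uid`, `cv` (raw, unscaled).
#' @export
compute_cv <- function(s, r_c = 100, chains = NULL, heavy_only = TRUE) {
  if (r_c <= 0) abort("r_c must be positive")
  ctx <- if (is.null(chains)) s else filter(s, .data$chain %in% chains)
  if (heavy_only) ctx <- filter(ctx, toupper(ctx$element) != "H")
  xyz <- as.matrix(ctx[, c("x", "y", "z")])
  n <- nrow(xyz)
  cv <- numeric(n)
  zero_nb <- FALSE
  for (i in seq_len(n)) {
    v <- sweep(xyz, 2, xyz[i, ])
    d <- sqrt(rowSums(v^2))
    nb <- which(d > 0 & d < r_c)
    if (length(nb) == 0) { cv[i] <- 0; zero_nb <- TRUE; next }
    u <- v[nb, , drop = FALSE] / d[nb]
    cv[i] <- 1 - sqrt(sum(colSums(u)^2)) / length(nb)
  }
  if (zero_nb) warn("atom(s) with no neighbour within r_c: CV set to 0")
  ctx |>
    mutate(.cv = cv) |>
    group_by(.data$res_uid) |>
    summarise(cv = mean(.data$.cv), .groups = "drop")
}

#' Physicochemical interface propensity per residue type
#'
#' Looks up the per-amino-acid interface propensity and scales it globally
#' by the table's documented maximum (2.21), mapping scores into [0, 1].
#' Nonstandard residue types score 0 with a warning.
#'
#' @param restypes Character vector of 3-letter residue types.
#' @param table Named numeric propensity vector on the raw 0-2.21 scale;
#'   defaults to the packaged asset (see [pc_propensity_table()]).
#' @return Numeric vector of PC scores in [0, 1].
#' @export
pc_scores <- function(restypes, table = pc_propensity_table()) {
  if (is.null(table) || length(table) == 0) {
    abort("propensity table asset missing")
  }
  raw <- table[restypes]
  if (anyNA(raw)) {
    warn(sprintf("nonstandard residue types scored 0: %s",
                 paste(unique(restypes[is.na(raw)]), collapse = ", ")))
    raw[is.na(raw)] <- 0
  }
  unname(raw) / 2.21
}

#' Amino-acid interface propensity asset
#'
#' Loads the packaged propensity table (raw scale 0-2.21).  The shipped
#' asset is a synthetic stand-in (see its provenance header): it reproduces
#' the documented range and the qualitative ordering of interface
#' propensity scales (aromatic/hydrophobic high, charged low) but not any
#' specific published values; supply `path` to use a real table.
#'
#' @param path Optional TSV override with columns `restype`, `propensity`.
#' @return Named numeric vector over residue types.
#' @export
pc_propensity_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pc_propensity_synthetic.tsv",
                                package = "surfpatch")
  if (!nzchar(path) || !file.exists(path)) abort("propensity table asset missing")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  setNames(tab$propensity, tab$restype)
}

#' Assemble the per-surface-residue score table
#'
#' Joins the available descriptors on residue identity, restricted to
#' surface residues.  CV is min-max rescaled over the surface residues so
#' 0 marks the most protruding and 1 the least protruding residue; NIP is
#' kept on its native scale with a [0, 1] min-max copy (`nip01`) used
#' wherever strategies combine scores.
#'
#' @param surface A [compute_rasa()] table for the query chain.
#' @param tjet Optional tibble `res_uid`, `tjet` (see
#'   [conservation_to_residues()] to key sequence positions to residues).
#' @param cv Tibble `res_uid`, `cv` from [compute_cv()].
#' @param nip Optional tibble `res_uid`, `nip` from [compute_nip()].
#' @param pc_table Propensity table override passed to [pc_scores()].
#' @return Tibble of class `score_table` with columns `chain`, `resno`,
#'   `icode`, `restype`, `res_uid`, `rasa`, `tjet`, `pc`, `cv`, `nip`,
#'   `nip01` (absent inputs give `NA` columns).
#' @export
assemble_score_table <- function(surface, cv, tjet = NULL, nip = NULL,
                                 pc_table = pc_propensity_table()) {
  surf <- filter(surface, .data$surface)
  if (nrow(surf) == 0) abort("no surface residues")
  join_check <- function(tbl, col, what) {
    if (is.null(tbl)) return(rep(NA_real_, nrow(surf)))
    hit <- match(surf$res_uid, tbl$res_uid)
    frac <- mean(!is.na(hit))
    if (frac < 0.5) {
      abort(sprintf("only %.0f%% of surface residues found in the %s input; likely a numbering mismatch",
                    100 * frac, what))
    }
    if (frac < 1) {
      warn(sprintf("%d surface residues missing from the %s input",
                   sum(is.na(hit)), what))
    }
    tbl[[col]][hit]
  }
  out <- surf |>
    mutate(
      tjet = join_check(tjet, "tjet", "conservation"),
      pc = pc_scores(.data$restype, table = pc_table),
      cv = rescale01(join_check(cv, "cv", "circular variance")),
      nip = join_check(nip, "nip", "docking")
    ) |>
    mutate(nip01 = if (all(is.na(.data$nip))) NA_real_ else
      rescale01(.data$nip)) |>
    select("chain", "resno", "icode", "restype", "res_uid", "rasa",
           "tjet", "pc", "cv", "nip", "nip01")
  class(out) <- c("score_table", class(tibble()))
  out
}

#' Key sequence-position conservation scores to structure residues
#'
#' Maps the i-th position of the query sequence to the i-th residue of the
#' query chain (author order).
#'
#' @param tjet Tibble from [compute_conservation()].
#' @param s A [read_structure()] tibble.
#' @param chain Query chain id.
#' @return Tibble `res_uid`, `tjet`, `m`.
#' @export
conservation_to_residues <- function(tjet, s, chain) {
  cons <- tjet
  res <- structure_residues(s, chains = chain)
  if (nrow(res) < max(cons$position)) {
    abort("query sequence longer than the chain; cannot key positions to residues")
  }
  tibble(res_uid = res$res_uid[cons$position], tjet = cons$tjet,
         m = cons$m)
}
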