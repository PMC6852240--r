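# Experimentally-derived interacting sites (IS) and interacting regions
# (IR).  ISs come from single complex structures; partners in mutual
# contact define one multi-partner IS.  ISs mapped onto a common query
# numbering are merged into IRs by a maximum-overlap closure.

#' Extract interacting sites from a complex, grouping partners in contact
#'
#' Partner chains of the query are grouped by transitive 5 A contact among
#' themselves; each group yields one interacting site (the query surface
#' residues within 5 A of any chain of the group).  Groups not touching
#' each other give separate single-partner sites.
#'
#' @param s Complex [read_structure()] tibble (query + partner chains).
#' @param chain Query chain id.
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @param source Provenance label (default the structure id).
#' @return Tibble of class `surf_sites`: `site_id`, `source`,
#'   `partner_chains`, `multi_partner`, `residues` (list-column of query
#'   residue ids).
#' @export
partner_grouping <- function(s, chain, cutoff = 5,
                             source = attr(s, "id") %||% "complex") {
  partners <- setdiff(unique(s$chain), chain)
  if (length(partners) == 0) abort("complex needs at least two chains")
  # chain-chain contact graph among the partners
  ch_pairs <- tibble(uid_a = character(), uid_b = character())
  if (length(partners) > 1) {
    combs <- utils::combn(sort(partners), 2)
    touch <- vapply(seq_len(ncol(combs)), function(k) {
      a <- unique(filter(s, .data$chain == combs[1, k])$res_uid)
      b <- unique(filter(s, .data$chain == combs[2, k])$res_uid)
      dd <- residue_min_dists(s, a, b, max_dist = cutoff)
      nrow(dd) > 0 && min(dd$dist) < cutoff
    }, logical(1))
    ch_pairs <- tibble(uid_a = combs[1, touch], uid_b = combs[2, touch])
  }
  groups <- contact_components(sort(partners), ch_pairs)
  qsurf <- compute_rasa(s, chains = chain)
  sites <- purrr::imap(groups, function(grp, gi) {
    iface <- detect_interface(s, chain, grp, cutoff = cutoff,
                              surface = qsurf)$query
    tibble(site_id = as.integer(gi), source = source,
           partner_chains = paste(sort(grp), collapse = "+"),
           multi_partner = length(grp) > 1,
           residues = list(sort(iface$res_uid)))
  }) |> bind_rows()
  sites <- filter(sites, map_int(.data$residues, length) > 0) |>
    mutate(site_id = row_number())
  structure(sites, class = c("surf_sites", class(tibble())))
}

#' Map a site from a homolog sequence onto the query numbering
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 (gap open 10, gap
#' extend 0.5) aligns the homolog to the query; site positions aligned to
#' gaps are dropped.  A warning is raised when the aligned identity falls
#' below 90\% (outside the close-homolog criterion), but the site is still
#' mapped.
#'
#' @param site Integer positions of the site on the homolog sequence
#'   (1-based, ungapped coordinates).
#' @param homolog_seq,query_seq Plain (ungapped) sequences.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return Integer positions on the query sequence.
#' @export
map_site <- function(site, homolog_seq, query_seq,
                     gap_open = 10, gap_extend = 0.5) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(homolog_seq), Biostrings::AAString(query_seq),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"
  )
  if (Biostrings::pid(aln) < 90) {
    warn(sprintf("aligned identity %.1f%% is below the 90%% homolog criterion",
                 Biostrings::pid(aln)))
  }
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  hpos <- cumsum(pa != "-")
  qpos <- cumsum(sa != "-")
  ok <- pa != "-" & sa != "-"
  m <- setNames(qpos[ok], hpos[ok])
  out <- m[as.character(site)]
  sort(unname(out[!is.na(out)]))
}

#' Maximum overlap between two interacting sites
#'
#' `max(|a n b| / |a|, |a n b| / |b|)`.
#'
#' @param a,b Non-empty residue-id vectors.
#' @return Fraction in [0, 1].
#' @export
overlap_fraction <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("sites must be non-empty")
  ov <- length(intersect(a, b))
  max(ov / length(a), ov / length(b))
}

sites_as_list <- function(sites) {
  if (inherits(sites, "surf_sites") || (is.data.frame(sites) &&
                                        "residues" %in% names(sites))) {
    res <- sites$residues
    names(res) <- sites$source %||% paste0("IS", seq_along(res))
    names(res) <- paste0(names(res), "#", sites$site_id %||% seq_along(res))
    res
  } else {
    res <- sites
    if (is.null(names(res))) names(res) <- paste0("IS", seq_along(res))
    res
  }
}

#' Merge interacting sites into interacting regions
#'
#' Agglomerative closure: two sites/regions merge when their maximum
#' overlap exceeds 60\% (strict), or when one of them has at most five
#' residues and they share at least one residue.  After merging a pair,
#' subsequent overlap tests use the accumulated union.  The procedure is
#' iterated to a fixpoint under a canonical processing order (size
#' descending, then lexicographically smallest residue id), which makes
#' the result invariant to the input permutation.  Regions of five or
#' fewer residues are dropped at the end.
#'
#' @param sites A `surf_sites` tibble (or a list of residue-id vectors).
#' @param overlap_threshold Merge threshold (default 0.60, strict `>`).
#' @param small_site_max Size at or below which the shared-residue
#'   relaxation applies (default 5).
#' @param min_region_size Regions with at most this many residues are
#'   discarded after the fixpoint (default 5).
#' @return Tibble of class `surf_regions`: `region_id`, `residues`
#'   (list-column, the exact union of the members), `members` (list of
#'   member site labels), `n_members`, `n_residues`.
#' @examples
#' merge_regions(list(a = paste0("A|", 1:10, "|"),
#'                    b = paste0("A|", 4:13, "|")))
#' @export
merge_regions <- function(sites, overlap_threshold = 0.60,
                          small_site_max = 5, min_region_size = 5) {
  res <- sites_as_list(sites)
  regions <- lapply(seq_along(res), function(i) {
    list(residues = sort(unique(res[[i]])), members = names(res)[i])
  })
  eligible <- function(a, b) {
    ov <- length(intersect(a, b))
    if (ov == 0) return(FALSE)
    if (min(length(a), length(b)) <= small_site_max) return(TRUE)
    overlap_fraction(a, b) > overlap_threshold
  }
  repeat {
    ord <- region_canonical_order(regions)
    regions <- regions[ord]
    merged <- FALSE
    n <- length(regions)
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (eligible(regions[[i]]$residues, regions[[j]]$residues)) {
            regions[[i]] <- list(
              residues = sort(union(regions[[i]]$residues,
                                    regions[[j]]$residues)),
              members = c(regions[[i]]$members, regions[[j]]$members)
            )
            regions <- regions[-j]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  regions <- regions[vapply(regions, function(r)
    length(r$residues), integer(1)) > min_region_size]
  regions <- regions[region_canonical_order(regions)]
  out <- tibble(
    region_id = seq_along(regions),
    residues = lapply(regions, function(r) r$residues),
    members = lapply(regions, function(r) sort(r$members)),
    n_members = map_int(regions, function(r) length(r$members)),
    n_residues = map_int(regions, function(r) length(r$residues))
  )
  structure(out, class = c("surf_regions", class(tibble())))
}

region_canonical_order <- function(regions) {
  if (length(regions) == 0) return(integer(0))
  sz <- vapply(regions, function(r) length(r$residues), integer(1))
  first <- vapply(regions, function(r) r$residues[1], character(1))
  order(-sz, first)
}
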