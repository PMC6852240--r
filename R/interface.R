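#' Detect the interface between a query chain and partner chains
#'
#' A residue of the query chain is interfacial when any of its atoms lies
#' strictly closer than `cutoff` (default 5 A) to any atom of any partner
#' chain; the partner side is detected symmetrically.  Interfaces contain
#' surface residues only (rasa >= 5\% in the full-complex context).
#'
#' @param s A [read_structure()] tibble holding all chains.
#' @param chain Query chain id.
#' @param partners Character vector of partner chain ids.
#' @param cutoff Contact distance in Angstrom, strict `<` (default 5).
#' @param surface Optional precomputed surface table covering both sides.
#'   When `NULL` (default) the surface is computed per side in its own
#'   monomeric context (query chain alone, partner chains alone), so that
#'   residues buried upon binding still count as surface.
#' @return List with tibbles `query` and `partner` (columns `res_uid`,
#'   `chain`, `resno`, `icode`, `restype`, `min_dist`).
#' @examples
#' cx <- make_complex(n_res = 14, seed = 1)
#' detect_interface(cx$structure, "A", "B")$query
#' @export
detect_interface <- function(s, chain, partners, cutoff = 5, surface = NULL) {
  if (cutoff <= 0) abort("cutoff must be positive")
  if (chain %in% partners) abort("query chain cannot be one of the partners")
  missing_ch <- setdiff(c(chain, partners), unique(s$chain))
  if (length(missing_ch) > 0) {
    abort(sprintf("chains not in structure: %s", paste(missing_ch, collapse = ", ")))
  }
  if (is.null(surface)) {
    surface <- bind_rows(compute_rasa(s, chains = chain),
                         compute_rasa(s, chains = partners))
  }
  surf_ids <- surface$res_uid[surface$surface]
  qa <- unique(filter(s, .data$chain == !!chain)$res_uid)
  pa <- unique(filter(s, .data$chain %in% partners)$res_uid)
  dd <- residue_min_dists(s, qa, pa, max_dist = cutoff)
  dd <- filter(dd, .data$dist < cutoff)
  side <- function(uids, dmin) {
    uid_fields(uids) |>
      mutate(min_dist = dmin) |>
      inner_join(select(structure_residues(s), "res_uid", "restype"),
                 by = "res_uid") |>
      filter(.data$res_uid %in% surf_ids) |>
      arrange(.data$chain, .data$resno, .data$icode)
  }
  if (nrow(dd) == 0) {
    empty <- side(character(0), numeric(0))
    return(list(query = empty, partner = empty))
  }
  q <- dd |> group_by(uid = .data$uid_a) |>
    summarise(dmin = min(.data$dist), .groups = "drop")
  p <- dd |> group_by(uid = .data$uid_b) |>
    summarise(dmin = min(.data$dist), .groups = "drop")
  list(query = side(q$uid, q$dmin), partner = side(p$uid, p$dmin))
}

#' Split an interface into support, core and rim layers
#'
#' Layers follow the buried/exposed status at a 25\% relative accessibility
#' threshold, with and without the partner: support residues are buried in
#' both contexts, core residues become buried upon binding, rim residues
#' stay exposed.
#'
#' @inheritParams detect_interface
#' @param burial_threshold rasa below which a residue counts as buried
#'   (default 0.25).
#' @return Tibble with `res_uid` and `layer` in
#'   `c("support", "core", "rim")`; the three layers partition the
#'   interface.
#' @export
interface_layers <- function(s, chain, partners, cutoff = 5,
                             burial_threshold = 0.25) {
  surface_complex <- compute_rasa(s, chains = c(chain, partners))
  alone <- compute_rasa(s, chains = chain)
  iface <- detect_interface(s, chain, partners, cutoff = cutoff,
                            surface = alone)$query
  if (nrow(iface) == 0) abort("interface is empty; no layers to assign")
  tib <- iface |>
    left_join(select(surface_complex, "res_uid", rasa_complex = "rasa"),
              by = "res_uid") |>
    left_join(select(alone, "res_uid", rasa_alone = "rasa"), by = "res_uid")
  tib |>
    mutate(layer = dplyr::case_when(
      .data$rasa_alone < burial_threshold &
        .data$rasa_complex < burial_threshold ~ "support",
      .data$rasa_alone >= burial_threshold &
        .data$rasa_complex < burial_threshold ~ "core",
      TRUE ~ "rim"
    )) |>
    select("res_uid", "chain", "resno", "icode", "restype",
           "rasa_alone", "rasa_complex", "layer")
}
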