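# Cross-docking pose statistics: interface propensity (IP) and its
# per-protein normalisation (NIP).  Docking itself is out of scope; poses
# enter as tabular records (one row per pose, with the query residues found
# at the docked interface).

#' Read / write docking pose records
#'
#' The pose table is a TSV with columns `pose_id`, `partner_id`, `energy`
#' (kcal/mol) and `residues` (semicolon-joined residue ids of the query at
#' the docked interface).
#'
#' @param path File path.
#' @return Tibble with a list-column `residues`.
#' @export
read_poses <- function(path) {
  raw <- as_tibble(read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character"))
  tibble(
    pose_id = raw$pose_id,
    partner_id = raw$partner_id,
    energy = as.numeric(raw$energy),
    residues = strsplit(raw$residues, ";", fixed = TRUE)
  )
}

#' @rdname read_poses
#' @param poses Pose tibble as returned by [read_poses()] / [make_poses()].
#' @export
write_poses <- function(poses, path) {
  out <- poses |>
    mutate(residues = map_chr(.data$residues, paste, collapse = ";"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep the lowest-energy poses within an energy window
#'
#' Per partner, poses with `energy - min(energy) < window` (strict) are
#' retained; the best-scored pose is always kept.
#'
#' @param poses Pose tibble (`pose_id`, `partner_id`, `energy`, `residues`).
#' @param window Energy window in kcal/mol (default 2.7).
#' @return Filtered pose tibble.
#' @examples
#' p <- tibble::tibble(pose_id = as.character(1:4), partner_id = "X",
#'                     energy = c(-10, -8, -7.4, -6),
#'                     residues = list("A|1|", "A|2|", "A|3|", "A|4|"))
#' filter_poses(p)$energy
#' @export
filter_poses <- function(poses, window = 2.7) {
  if (nrow(poses) == 0) abort("empty pose set")
  poses |>
    group_by(.data$partner_id) |>
    filter(.data$energy - min(.data$energy) < window) |>
    ungroup()
}

#' Interface propensity of each residue over a pose ensemble
#'
#' `IP(i) = N_int(i) / N_pos`: the fraction of retained poses (pooled over
#' all partners) whose docked interface contains residue `i`.
#'
#' @param poses Filtered pose tibble.
#' @param residues Optional character vector of residue ids defining the
#'   score universe (e.g. the surface residues); residues never docked get
#'   IP 0.  Defaults to the residues seen in the poses.
#' @return Tibble `res_uid`, `ip`.
#' @export
compute_ip <- function(poses, residues = NULL) {
  if (nrow(poses) == 0) abort("empty pose set")
  n_pos <- nrow(poses)
  counts <- table(unlist(poses$residues))
  residues <- residues %||% sort(names(counts))
  ip <- as.numeric(counts[residues])
  ip[is.na(ip)] <- 0
  tibble(res_uid = residues, ip = ip / n_pos)
}

#' Normalised interface propensity (NIP)
#'
#' `NIP(i) = (IP(i) - mean(IP)) / (max(IP) - mean(IP))`, computed over the
#' residues of the table (by convention the surface residues).  Positive
#' values mark residues favoured at docked interfaces; the maximum is 1 and
#' the mean maps to 0.  A constant IP profile yields all-zero NIP with a
#' warning.
#'
#' @param ip Tibble from [compute_ip()].
#' @return Tibble `res_uid`, `ip`, `nip`.
#' @export
compute_nip <- function(ip) {
  if (nrow(ip) == 0) abort("empty IP table")
  if (nrow(ip) < 2) abort("NIP needs at least two residues")
  m <- mean(ip$ip); mx <- max(ip$ip)
  if (mx == m) {
    warn("constant IP profile; NIP set to 0 for all residues")
    return(mutate(ip, nip = 0))
  }
  mutate(ip, nip = (.data$ip - m) / (mx - m))
}
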