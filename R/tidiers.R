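#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a set of interacting regions into one row per residue
#'
#' @param x A `surf_regions` tibble.
#' @param ... Unused.
#' @return Tibble `region_id`, `res_uid`, `chain`, `resno`, `icode`,
#'   `n_members`.
#' @export
tidy.surf_regions <- function(x, ...) {
  out <- x |>
    select("region_id", "residues", "n_members") |>
    tidyr::unnest_longer("residues", values_to = "res_uid")
  out |>
    left_join(uid_fields(unique(out$res_uid)), by = "res_uid") |>
    select("region_id", "res_uid", "chain", "resno", "icode", "n_members")
}

#' @rdname tidy.surf_regions
#' @export
glance.surf_regions <- function(x, ...) {
  tibble(n_regions = nrow(x),
         n_sites = sum(x$n_members),
         mean_size = mean(x$n_residues),
         max_size = if (nrow(x)) max(x$n_residues) else NA_integer_)
}

#' Tidy predicted patches (drops the class, keeps the long table)
#'
#' @param x A `surf_patches` tibble.
#' @param ... Unused.
#' @export
tidy.surf_patches <- function(x, ...) as_tibble(x)

#' @rdname tidy.surf_patches
#' @export
glance.surf_patches <- function(x, ...) {
  x |>
    group_by(.data$strategy) |>
    summarise(n_patches = dplyr::n_distinct(.data$patch_id),
              n_residues = dplyr::n_distinct(.data$res_uid),
              n_seed_residues = dplyr::n_distinct(
                .data$res_uid[.data$layer == "seed"]),
              .groups = "drop")
}

#' Tidy an evaluation report
#'
#' @param x A `surf_eval` tibble from [best_match()].
#' @param ... Unused.
#' @export
tidy.surf_eval <- function(x, ...) {
  x |> mutate(members = map_chr(.data$members, paste, collapse = "+")) |>
    as_tibble()
}

#' @rdname tidy.surf_eval
#' @export
glance.surf_eval <- function(x, ...) {
  tibble(n_regions = nrow(x), mean_f1 = mean(x$f1),
         mean_precision = mean(x$precision), mean_recall = mean(x$recall),
         n_missed = sum(x$missed))
}
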