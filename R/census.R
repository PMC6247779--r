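#' Census of gap-junction coupling motifs
#'
#' Categorises every gap junction by the relationship of its endpoints:
#' `heterocellular` when the two cells belong to different superclasses
#' (e.g. a ganglion cell coupled to an amacrine cell),
#' `homocellular_in_class` when both endpoints share one class, and
#' `homocellular_cross_class` for two different classes of the same
#' superclass (e.g. coupling between two ON cone bipolar classes). The
#' three categories partition the gap-junction set.
#'
#' @param graph A [connectome()].
#' @return An object of class `coupling_census`: a list with
#'   * `junctions` — one row per gap junction with endpoint classes,
#'     superclasses and category;
#'   * `class_pairs` — counts per unordered class pair and category;
#'   * `superclass_pairs` — counts per unordered superclass pair.
#' @export
#' @examples
#' census <- coupling_census(rc1_summary_fixture())
#' census$superclass_pairs
coupling_census <- function(graph) {
  stopifnot(inherits(graph, "connectome"))
  nn <- graph$neurons
  cls <- setNames(nn$class_label, nn$id)
  sup <- setNames(nn$superclass, nn$id)
  cc <- graph$contacts
  gj <- cc[cc$kind == "gap_junction", , drop = FALSE]

  if (nrow(gj) == 0) {
    junctions <- tibble::tibble(
      contact_id = character(), a_id = character(), b_id = character(),
      class_a = character(), class_b = character(),
      superclass_a = character(), superclass_b = character(),
      area_um2 = numeric(), category = character()
    )
  } else {
    class_a <- unname(cls[gj$pre_id])
    class_b <- unname(cls[gj$post_id])
    sup_a <- unname(sup[gj$pre_id])
    sup_b <- unname(sup[gj$post_id])
    category <- dplyr::case_when(
      sup_a != sup_b ~ "heterocellular",
      class_a == class_b ~ "homocellular_in_class",
      TRUE ~ "homocellular_cross_class"
    )
    # order the pair labels so tallies are orientation-free
    lo <- pmin(class_a, class_b)
    hi <- pmax(class_a, class_b)
    junctions <- tibble::tibble(
      contact_id = gj$id, a_id = gj$pre_id, b_id = gj$post_id,
      class_a = lo, class_b = hi,
      superclass_a = pmin(sup_a, sup_b), superclass_b = pmax(sup_a, sup_b),
      area_um2 = gj$area_um2, category = category
    )
  }

  class_pairs <- junctions |>
    dplyr::count(.data$class_a, .data$class_b, .data$category, name = "n") |>
    dplyr::arrange(.data$class_a, .data$class_b)
  superclass_pairs <- junctions |>
    dplyr::count(.data$superclass_a, .data$superclass_b, .data$category,
                 name = "n") |>
    dplyr::arrange(.data$superclass_a, .data$superclass_b)

  structure(list(junctions = junctions, class_pairs = class_pairs,
                 superclass_pairs = superclass_pairs),
            class = "coupling_census")
}

#' @export
print.coupling_census <- function(x, ...) {
  cat("<coupling_census> ", nrow(x$junctions), " gap junctions\n", sep = "")
  print(dplyr::count(x$junctions, .data$category, name = "n"))
  invisible(x)
}

#' Coupled partners of a cell, with transmitter signatures
#'
#' Lists every cell sharing at least one gap junction with `cell_id`,
#' with the partner's class, transmitter, junction count and summed
#' junction area. GABAergic partners are what gives a coupled ganglion
#' cell its intermediate GABA signature.
#'
#' @param graph A [connectome()].
#' @param cell_id Neuron id.
#' @return A tibble with columns `partner_id`, `class_label`,
#'   `transmitter`, `n_junctions`, `total_area_um2`, sorted by decreasing
#'   junction count.
#' @export
coupled_partners <- function(graph, cell_id) {
  stopifnot(inherits(graph, "connectome"))
  if (!cell_id %in% graph$neurons$id) {
    abort(paste0("unknown cell: ", cell_id),
          class = "retcouple_referential_error")
  }
  cc <- graph$contacts
  gj <- cc[cc$kind == "gap_junction" &
             (cc$pre_id == cell_id | cc$post_id == cell_id), , drop = FALSE]
  partner <- ifelse(gj$pre_id == cell_id, gj$post_id, gj$pre_id)
  nn <- graph$neurons
  tibble::tibble(partner_id = partner, area_um2 = gj$area_um2) |>
    dplyr::group_by(.data$partner_id) |>
    dplyr::summarise(n_junctions = dplyr::n(),
                     total_area_um2 = sum(.data$area_um2),
                     .groups = "drop") |>
    dplyr::left_join(
      dplyr::select(nn, partner_id = "id", "class_label", "transmitter"),
      by = "partner_id") |>
    dplyr::select("partner_id", "class_label", "transmitter",
                  "n_junctions", "total_area_um2") |>
    dplyr::arrange(dplyr::desc(.data$n_junctions), .data$partner_id)
}
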