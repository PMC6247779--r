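#' Tabulate the synaptic and coupling drive of one cell
#'
#' Summarises every contact incident to a cell by kind: incoming ribbon
#' synapses (excitatory bipolar-cell drive), incoming conventional synapses
#' (inhibitory amacrine-cell drive; `bc_conventional` inputs are counted
#' with `conventional`), and all gap junctions touching the cell (coupling
#' drive, orientation-free). When only a fraction of the cell's arbor is
#' contained in the volume, counts and total areas are extrapolated to the
#' whole cell by dividing by the arbor fraction.
#'
#' The default rounding policy for extrapolated values reports values of
#' 1000 or more to the nearest ten and smaller values to the nearest
#' integer, matching the precision at which whole-cell estimates are
#' conventionally quoted.
#'
#' @param graph A [connectome()].
#' @param cell_id Neuron id.
#' @param arbor_fraction Fraction of the cell's arbor inside the volume, in
#'   (0, 1]. Defaults to the neuron's `arbor_fraction` field, else 1.
#' @param rounding `"tens"` (default policy above) or `"none"` (raw
#'   quotients).
#' @return A tibble of class `drive_table`, one row per contact kind, with
#'   columns `kind`, `n`, `mean_area_um2`, `sd_area_um2`, `min_area_um2`,
#'   `max_area_um2`, `total_area_um2`, `extrapolated_n`,
#'   `extrapolated_total_area_um2`.
#' @export
#' @examples
#' g <- rc1_summary_fixture()
#' drive_table(g, "GC606", arbor_fraction = 0.18)
drive_table <- function(graph, cell_id, arbor_fraction = NULL,
                        rounding = c("tens", "none")) {
  stopifnot(inherits(graph, "connectome"))
  rounding <- match.arg(rounding)
  if (!cell_id %in% graph$neurons$id) {
    abort(paste0("unknown cell: ", cell_id),
          class = "retcouple_referential_error")
  }
  if (is.null(arbor_fraction)) {
    af <- graph$neurons$arbor_fraction[graph$neurons$id == cell_id]
    arbor_fraction <- if (is.na(af)) 1 else af
  }
  if (arbor_fraction <= 0 || arbor_fraction > 1) {
    abort("arbor_fraction must lie in (0, 1]",
          class = "retcouple_domain_error")
  }

  cc <- graph$contacts
  rows <- dplyr::bind_rows(
    dplyr::filter(cc, .data$kind == "ribbon", .data$post_id == cell_id) |>
      dplyr::mutate(row_kind = "ribbon_in"),
    dplyr::filter(cc, .data$kind %in% c("conventional", "bc_conventional"),
                  .data$post_id == cell_id) |>
      dplyr::mutate(row_kind = "conventional_in"),
    dplyr::filter(cc, .data$kind == "gap_junction",
                  .data$pre_id == cell_id | .data$post_id == cell_id) |>
      dplyr::mutate(row_kind = "gap_junction")
  )

  summarise_kind <- function(k) {
    a <- rows$area_um2[rows$row_kind == k]
    n <- length(a)
    tibble::tibble(
      kind = k, n = n,
      mean_area_um2 = if (n > 0) mean(a) else NA_real_,
      sd_area_um2 = if (n > 1) sd(a) else NA_real_,
      min_area_um2 = if (n > 0) min(a) else NA_real_,
      max_area_um2 = if (n > 0) max(a) else NA_real_,
      total_area_um2 = sum(a)
    )
  }
  out <- dplyr::bind_rows(lapply(
    c("ribbon_in", "conventional_in", "gap_junction"), summarise_kind))

  round_policy <- switch(rounding,
    none = function(x) x,
    tens = function(x) ifelse(x >= 1000, round(x / 10) * 10, round(x))
  )
  out$extrapolated_n <- round_policy(out$n / arbor_fraction)
  out$extrapolated_total_area_um2 <-
    round_policy(out$total_area_um2 / arbor_fraction)

  structure(out, class = c("drive_table", class(tibble::tibble())),
            cell_id = cell_id, arbor_fraction = arbor_fraction)
}

#' Class-wise spectrum of a cell's presynaptic input
#'
#' Counts the incoming contacts of one kind by presynaptic class and
#' reports each class's share of the total. The exclusion fraction of a
#' class is one minus its share — e.g. "over 99% of the input excludes
#' class X" means exclusion_fraction(X) > 0.99.
#'
#' @param graph A [connectome()].
#' @param cell_id Neuron id.
#' @param kind Contact kind to tabulate (default `"ribbon"`).
#' @return A tibble of class `input_spectrum` with columns `class_label`,
#'   `n`, `fraction`, sorted by decreasing count; attributes `total` and
#'   `dominant_class`.
#' @export
input_spectrum <- function(graph, cell_id, kind = "ribbon") {
  stopifnot(inherits(graph, "connectome"))
  if (!cell_id %in% graph$neurons$id) {
    abort(paste0("unknown cell: ", cell_id),
          class = "retcouple_referential_error")
  }
  cc <- graph$contacts
  keep_kind <- if (kind == "conventional") {
    c("conventional", "bc_conventional")
  } else {
    kind
  }
  inc <- cc[cc$kind %in% keep_kind & cc$post_id == cell_id, , drop = FALSE]
  labels <- setNames(graph$neurons$class_label, graph$neurons$id)
  out <- tibble::tibble(class_label = unname(labels[inc$pre_id])) |>
    dplyr::count(.data$class_label, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$class_label)
  total <- sum(out$n)
  out$fraction <- if (total > 0) out$n / total else numeric(nrow(out))
  structure(out, class = c("input_spectrum", class(tibble::tibble())),
            total = total,
            dominant_class = if (total > 0) out$class_label[1] else NA_character_)
}

#' @rdname input_spectrum
#' @param spectrum An `input_spectrum`.
#' @param class_label Class whose exclusion fraction to report.
#' @return `exclusion_fraction()` returns 1 minus the class's input share.
#' @export
exclusion_fraction <- function(spectrum, class_label) {
  stopifnot(inherits(spectrum, "input_spectrum"))
  hit <- spectrum$fraction[spectrum$class_label == class_label]
  1 - if (length(hit) == 0) 0 else hit
}

#' Classify a cell's response polarity from its ribbon input
#'
#' A ganglion cell driven exclusively by ON bipolar classes is ON, one
#' driven exclusively by OFF classes is OFF, mixed input is ON_OFF, and a
#' cell without ribbon input is unclassifiable.
#'
#' @param graph A [connectome()].
#' @param cell_id Neuron id.
#' @return A list with `polarity` (`"ON"`, `"OFF"`, `"ON_OFF"` or
#'   `"unknown"`), `on_fraction`, `off_fraction`, `n_ribbon`.
#' @export
polarity_profile <- function(graph, cell_id) {
  stopifnot(inherits(graph, "connectome"))
  if (!cell_id %in% graph$neurons$id) {
    abort(paste0("unknown cell: ", cell_id),
          class = "retcouple_referential_error")
  }
  cc <- graph$contacts
  inc <- cc[cc$kind == "ribbon" & cc$post_id == cell_id, , drop = FALSE]
  if (nrow(inc) == 0) {
    return(list(polarity = "unknown", on_fraction = NA_real_,
                off_fraction = NA_real_, n_ribbon = 0L))
  }
  pol <- setNames(graph$neurons$polarity, graph$neurons$id)
  p <- pol[inc$pre_id]
  on_frac <- mean(p == "ON", na.rm = TRUE)
  off_frac <- mean(p == "OFF", na.rm = TRUE)
  polarity <- if (off_frac == 0 && on_frac > 0) {
    "ON"
  } else if (on_frac == 0 && off_frac > 0) {
    "OFF"
  } else if (on_frac > 0 && off_frac > 0) {
    "ON_OFF"
  } else {
    "unknown"
  }
  list(polarity = polarity, on_fraction = on_frac,
       off_fraction = off_frac, n_ribbon = nrow(inc))
}

#' Gap-junction area per unit dendrite length
#'
#' Total gap-junction area (nm^2) on a cell divided by its in-volume
#' dendrite length (um) — a size-weighted coupling density that lets cells
#' with different arbor coverage be compared.
#'
#' @param graph A [connectome()].
#' @param cell_id Neuron id; its `dendrite_length_um` field must be set
#'   (or supply `dendrite_length_um` directly).
#' @param dendrite_length_um Optional override for the stored length.
#' @return Density in nm^2 per um of dendrite.
#' @export
gj_density_per_length <- function(graph, cell_id,
                                  dendrite_length_um = NULL) {
  stopifnot(inherits(graph, "connectome"))
  nn <- graph$neurons
  if (!cell_id %in% nn$id) {
    abort(paste0("unknown cell: ", cell_id),
          class = "retcouple_referential_error")
  }
  if (is.null(dendrite_length_um)) {
    dendrite_length_um <- nn$dendrite_length_um[nn$id == cell_id]
  }
  if (is.na(dendrite_length_um) || dendrite_length_um <= 0) {
    abort("dendrite_length_um is missing or non-positive for this cell",
          class = "retcouple_domain_error")
  }
  cc <- graph$contacts
  gj <- cc[cc$kind == "gap_junction" &
             (cc$pre_id == cell_id | cc$post_id == cell_id), , drop = FALSE]
  sum(gj$area_um2) * 1e6 / dendrite_length_um
}
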