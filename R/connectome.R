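#' Build a typed connectome graph from neuron and contact tables
#'
#' A connectome is a typed attributed multigraph: a `neurons` table (one row
#' per cell) and a `contacts` table (one row per intercellular contact).
#' Chemical synapses (`ribbon`, `conventional`, `bc_conventional`) are
#' directed pre -> post; gap junctions (`gap_junction`) are undirected and
#' stored canonically with the lexicographically smaller endpoint first, so
#' every downstream census or query is invariant to the endpoint order in
#' the input.
#'
#' @param neurons Data frame with columns `id`, `class_label` and optionally
#'   `superclass`, `polarity`, `transmitter`, `gaba_mM`, `soma_diameter_um`,
#'   `arbor_fraction`, `dendrite_length_um`. Missing `superclass`/`polarity`/
#'   `transmitter` are filled from [class_roster()] where the class is known.
#' @param contacts Data frame with columns `id`, `kind`, `pre_id`, `post_id`,
#'   `area_um2` and optionally `diameter_nm`, `x_nm`, `y_nm`, `z_nm`,
#'   `validated`. When exactly one of `area_um2`/`diameter_nm` is given for a
#'   gap junction the other is derived from the circular-disc model.
#' @return An object of class `connectome`: a list with tibbles `neurons`
#'   and `contacts`.
#' @export
#' @examples
#' g <- connectome(
#'   neurons  = data.frame(id = c("a", "b"), class_label = c("CBb4w", "GC ON")),
#'   contacts = data.frame(id = "e1", kind = "ribbon", pre_id = "a",
#'                         post_id = "b", area_um2 = 0.04)
#' )
#' g
connectome <- function(neurons, contacts = NULL) {
  neurons <- tibble::as_tibble(neurons)
  req <- c("id", "class_label")
  missing_cols <- setdiff(req, names(neurons))
  if (length(missing_cols) > 0) {
    abort(paste0("neuron table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "retcouple_format_error")
  }
  neurons$id <- as.character(neurons$id)
  if (anyDuplicated(neurons$id)) {
    abort("duplicated neuron ids", class = "retcouple_format_error")
  }
  opt_chr <- c("superclass", "polarity", "transmitter")
  opt_dbl <- c("gaba_mM", "soma_diameter_um", "arbor_fraction",
               "dendrite_length_um")
  for (col in opt_chr) {
    if (!col %in% names(neurons)) neurons[[col]] <- NA_character_
    neurons[[col]] <- as.character(neurons[[col]])
  }
  for (col in opt_dbl) {
    if (!col %in% names(neurons)) neurons[[col]] <- NA_real_
    neurons[[col]] <- as.numeric(neurons[[col]])
  }
  # fill superclass/polarity/transmitter from the bundled roster;
  # explicit values in the table override the roster
  roster <- class_roster()
  idx <- match(neurons$class_label, roster$class_label)
  for (col in opt_chr) {
    fill <- roster[[col]][idx]
    take <- is.na(neurons[[col]]) & !is.na(fill)
    neurons[[col]][take] <- fill[take]
  }
  neurons <- neurons[, c(req, opt_chr, opt_dbl)]

  if (is.null(contacts) || nrow(tibble::as_tibble(contacts)) == 0) {
    contacts <- empty_contacts()
  } else {
    contacts <- tibble::as_tibble(contacts)
    creq <- c("id", "kind", "pre_id", "post_id")
    missing_cols <- setdiff(creq, names(contacts))
    if (length(missing_cols) > 0) {
      abort(paste0("contact table is missing column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "retcouple_format_error")
    }
    for (col in creq) contacts[[col]] <- as.character(contacts[[col]])
    if (anyDuplicated(contacts$id)) {
      abort("duplicated contact ids", class = "retcouple_format_error")
    }
    for (col in c("area_um2", "diameter_nm", "x_nm", "y_nm", "z_nm")) {
      if (!col %in% names(contacts)) contacts[[col]] <- NA_real_
      contacts[[col]] <- as.numeric(contacts[[col]])
    }
    if (!"validated" %in% names(contacts)) contacts$validated <- NA
    contacts$validated <- as.logical(contacts$validated)

    dangling <- !(contacts$pre_id %in% neurons$id) |
      !(contacts$post_id %in% neurons$id)
    if (any(dangling)) {
      bad <- contacts$id[dangling]
      abort(paste0("contact(s) reference unknown neurons: ",
                   paste(head(bad, 5), collapse = ", "),
                   if (length(bad) > 5) " ..." else ""),
            class = "retcouple_referential_error")
    }

    # derive the missing one of diameter/area under the disc model
    gj <- contacts$kind == "gap_junction"
    need_area <- gj & is.na(contacts$area_um2) & !is.na(contacts$diameter_nm)
    contacts$area_um2[need_area] <-
      diameter_to_area(contacts$diameter_nm[need_area])
    need_diam <- gj & is.na(contacts$diameter_nm) & !is.na(contacts$area_um2)
    contacts$diameter_nm[need_diam] <-
      area_to_diameter(contacts$area_um2[need_diam])

    # canonical endpoint order for undirected gap junctions
    swap <- gj & contacts$pre_id > contacts$post_id
    if (any(swap)) {
      tmp <- contacts$pre_id[swap]
      contacts$pre_id[swap] <- contacts$post_id[swap]
      contacts$post_id[swap] <- tmp
    }
    contacts <- contacts[, names(empty_contacts())]
  }

  structure(list(neurons = neurons, contacts = contacts),
            class = "connectome")
}

empty_contacts <- function() {
  tibble::tibble(
    id = character(), kind = character(),
    pre_id = character(), post_id = character(),
    area_um2 = numeric(), diameter_nm = numeric(),
    x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
    validated = logical()
  )
}

#' @export
print.connectome <- function(x, ...) {
  kinds <- table(factor(x$contacts$kind, levels = contact_kinds()))
  cat("<connectome> ", nrow(x$neurons), " neurons, ",
      nrow(x$contacts), " contacts\n", sep = "")
  cat("  ", paste(names(kinds), as.integer(kinds), sep = ": ",
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Convert a gap-junction diameter to a disc-model area
#'
#' Gap junctions are close to circular in en-face view, so a measured
#' diameter `d` (nm) corresponds to an area of `pi * (d/2)^2`, reported in
#' square micrometres. `area_to_diameter()` is the exact inverse.
#'
#' @param d_nm Diameter in nanometres (vectorised, must be >= 0).
#' @return Area in square micrometres.
#' @export
#' @examples
#' diameter_to_area(181) # ~0.0257 um^2
diameter_to_area <- function(d_nm) {
  if (any(d_nm < 0, na.rm = TRUE)) {
    abort("diameter must be nonnegative", class = "retcouple_domain_error")
  }
  pi * (d_nm / 2)^2 * 1e-6
}

#' @rdname diameter_to_area
#' @param area_um2 Area in square micrometres (must be >= 0).
#' @export
area_to_diameter <- function(area_um2) {
  if (any(area_um2 < 0, na.rm = TRUE)) {
    abort("area must be nonnegative", class = "retcouple_domain_error")
  }
  2 * sqrt(area_um2 * 1e6 / pi)
}

#' Validate a connectome against the data-model invariants
#'
#' Checks the soft invariants of the data model: positive contact areas,
#' arbor fractions in (0, 1], nonnegative GABA concentrations, no
#' self-looping gap junctions, diameter/area disc-model consistency within
#' 1% relative tolerance, and class labels consistent with the bundled
#' roster. Violations are returned as data, not raised as errors.
#'
#' @param graph A [connectome()].
#' @return A tibble with columns `entity_id`, `rule`, `detail`; zero rows
#'   when the graph satisfies every invariant.
#' @export
validate_connectome <- function(graph) {
  stopifnot(inherits(graph, "connectome"))
  nn <- graph$neurons
  cc <- graph$contacts
  v <- list()
  add <- function(ids, rule, detail) {
    if (length(ids) > 0) {
      v[[length(v) + 1]] <<- tibble::tibble(
        entity_id = ids, rule = rule, detail = detail)
    }
  }

  bad <- nn$id[!is.na(nn$arbor_fraction) &
                 (nn$arbor_fraction <= 0 | nn$arbor_fraction > 1)]
  add(bad, "arbor_fraction_range", "arbor_fraction must lie in (0, 1]")
  add(nn$id[!is.na(nn$gaba_mM) & nn$gaba_mM < 0],
      "gaba_nonnegative", "gaba_mM must be >= 0")

  roster <- class_roster()
  idx <- match(nn$class_label, roster$class_label)
  known <- !is.na(idx)
  mismatch <- known & !is.na(nn$superclass) &
    nn$superclass != roster$superclass[idx]
  add(nn$id[mismatch], "roster_superclass",
      "superclass disagrees with the bundled class roster")
  add(nn$id[!known], "unknown_class_label",
      "class label not in the bundled roster (allowed, flagged)")

  add(cc$id[!is.na(cc$area_um2) & cc$area_um2 <= 0],
      "area_positive", "contact area must be > 0")
  add(cc$id[!cc$kind %in% contact_kinds()],
      "known_kind", "unknown contact kind")
  gj <- cc$kind == "gap_junction"
  add(cc$id[gj & cc$pre_id == cc$post_id],
      "gap_junction_no_self", "gap junction endpoints must differ")

  both <- gj & !is.na(cc$area_um2) & !is.na(cc$diameter_nm) & cc$area_um2 > 0
  if (any(both)) {
    rel <- abs(diameter_to_area(cc$diameter_nm[both]) - cc$area_um2[both]) /
      cc$area_um2[both]
    add(cc$id[both][rel > 0.01], "disc_consistency",
        "diameter and area disagree with the disc model by > 1%")
  }

  if (length(v) == 0) {
    tibble::tibble(entity_id = character(), rule = character(),
                   detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Read and write connectome graphs
#'
#' Tab-separated node/edge tables are the lossless native format (header
#' row, UTF-8, `.` decimal separator). GraphML export routes through
#' \pkg{igraph} for interoperability with generic graph tools; gap-junction
#' canonical ordering is re-established on load.
#'
#' @param nodes_path,edges_path Paths to the neuron and contact TSV files.
#' @return `load_connectome()` returns a validated [connectome()];
#'   `save_connectome()` returns its input invisibly.
#' @export
load_connectome <- function(nodes_path, edges_path) {
  for (p in c(nodes_path, edges_path)) {
    if (!file.exists(p)) {
      abort(paste0("file not found: ", p), class = "retcouple_io_error")
    }
  }
  neurons <- readr::read_tsv(nodes_path, col_types = readr::cols(
    .default = readr::col_double(), id = readr::col_character(),
    class_label = readr::col_character(),
    superclass = readr::col_character(),
    polarity = readr::col_character(),
    transmitter = readr::col_character()
  ), progress = FALSE)
  contacts <- readr::read_tsv(edges_path, col_types = readr::cols(
    .default = readr::col_double(), id = readr::col_character(),
    kind = readr::col_character(), pre_id = readr::col_character(),
    post_id = readr::col_character(), validated = readr::col_logical()
  ), progress = FALSE)
  if (nrow(contacts) == 0) contacts <- NULL
  connectome(neurons, contacts)
}

#' @rdname load_connectome
#' @param graph A [connectome()].
#' @param format `"tsv"` (two files) or `"graphml"` (single file,
#'   `edges_path` ignored).
#' @export
save_connectome <- function(graph, nodes_path, edges_path = NULL,
                            format = c("tsv", "graphml")) {
  stopifnot(inherits(graph, "connectome"))
  format <- match.arg(format)
  if (format == "tsv") {
    if (is.null(edges_path)) {
      abort("edges_path is required for TSV output",
            class = "retcouple_io_error")
    }
    readr::write_tsv(graph$neurons, nodes_path, progress = FALSE)
    readr::write_tsv(graph$contacts, edges_path, progress = FALSE)
  } else {
    ig <- as_igraph(graph)
    igraph::write_graph(ig, nodes_path, format = "graphml")
  }
  invisible(graph)
}

#' Convert a connectome to an igraph object
#'
#' All contacts become directed edges (gap junctions keep their canonical
#' endpoint order) with their fields as edge attributes; neuron fields
#' become vertex attributes.
#'
#' @param graph A [connectome()].
#' @return An \pkg{igraph} directed graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "connectome"))
  nn <- as.data.frame(graph$neurons)
  names(nn)[1] <- "name"
  ee <- as.data.frame(graph$contacts)
  ee <- ee[, c("pre_id", "post_id",
               setdiff(names(ee), c("pre_id", "post_id")))]
  names(ee)[3] <- "contact_id"
  igraph::graph_from_data_frame(ee, directed = TRUE, vertices = nn)
}

#' Read a connectome back from a GraphML file
#'
#' @param path GraphML file written by [save_connectome()].
#' @return A [connectome()].
#' @export
load_connectome_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  vdf <- igraph::as_data_frame(ig, what = "vertices")
  edf <- igraph::as_data_frame(ig, what = "edges")
  if ("name" %in% names(vdf) && "id" %in% names(vdf)) {
    vdf$id <- NULL  # graphml node ids duplicate the stored name attribute
  }
  neurons <- tibble::as_tibble(vdf, .name_repair = "minimal")
  names(neurons)[names(neurons) == "name"] <- "id"
  neurons$id <- as.character(neurons$id)
  if (nrow(edf) > 0) {
    contacts <- tibble::as_tibble(edf)
    names(contacts)[names(contacts) == "from"] <- "pre_id"
    names(contacts)[names(contacts) == "to"] <- "post_id"
    names(contacts)[names(contacts) == "contact_id"] <- "id"
    num <- c("area_um2", "diameter_nm", "x_nm", "y_nm", "z_nm")
    for (col in num) {
      if (col %in% names(contacts)) {
        contacts[[col]][is.nan(contacts[[col]])] <- NA_real_
      }
    }
  } else {
    contacts <- NULL
  }
  num <- c("gaba_mM", "soma_diameter_um", "arbor_fraction",
           "dendrite_length_um")
  for (col in num) {
    if (col %in% names(neurons)) {
      neurons[[col]][is.nan(neurons[[col]])] <- NA_real_
    }
  }
  connectome(neurons, contacts)
}
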