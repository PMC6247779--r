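#' Parse a path-query string into a compiled pattern
#'
#' Queries describe alternating node/edge constraints for multi-hop circuit
#' mining, e.g. `"CB.*, ribbon, GC ON"` reads "any cone bipolar class, via a
#' ribbon synapse, onto the GC ON class". Tokens are comma-separated and
#' whitespace-trimmed; odd positions are regular expressions matched against
#' the *entire* class label (anchored full match), even positions are edge
#' kinds from `{ribbon, conventional, gap junction, any}`. A single token is
#' a degenerate node-only query. `bc_conventional` contacts are matched by
#' the `conventional` edge kind.
#'
#' @param text Query string.
#' @return An object of class `path_pattern` with fields `node_patterns`
#'   and `edge_kinds`.
#' @export
#' @examples
#' parse_query("CB.*, ribbon, GC ON")
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  if (length(tokens) == 0 || any(tokens == "")) {
    abort("query must contain non-empty comma-separated tokens",
          class = "retcouple_syntax_error")
  }
  if (length(tokens) %% 2 == 0) {
    abort(paste0("query needs an odd number of tokens ",
                 "(node, edge, node, ...); got ", length(tokens)),
          class = "retcouple_syntax_error")
  }
  node_patterns <- tokens[seq(1, length(tokens), by = 2)]
  edge_tokens <- if (length(tokens) > 1) {
    tokens[seq(2, length(tokens), by = 2)]
  } else {
    character()
  }
  edge_kinds <- normalize_edge_kind(edge_tokens)
  for (i in seq_along(node_patterns)) {
    ok <- tryCatch(
      {suppressWarnings(grepl(anchor_regex(node_patterns[i]), "x")); TRUE},
      error = function(e) FALSE
    )
    if (!ok) {
      abort(paste0("invalid regular expression at node position ", i, ": '",
                   node_patterns[i], "'"),
            class = "retcouple_regex_error")
    }
  }
  structure(list(node_patterns = node_patterns, edge_kinds = edge_kinds),
            class = "path_pattern")
}

normalize_edge_kind <- function(tokens) {
  if (length(tokens) == 0) return(character())
  norm <- gsub("[ -]", "_", tolower(tokens))
  vocab <- c("ribbon", "conventional", "gap_junction", "any")
  bad <- setdiff(unique(norm), vocab)
  if (length(bad) > 0) {
    abort(paste0("unknown edge kind(s): ", paste(bad, collapse = ", "),
                 "; expected one of ribbon, conventional, gap junction, any"),
          class = "retcouple_vocabulary_error")
  }
  norm
}

anchor_regex <- function(pattern) paste0("^(?:", pattern, ")$")

#' @export
print.path_pattern <- function(x, ...) {
  cat("<path_pattern> ", length(x$node_patterns) - 1, " hop(s)\n", sep = "")
  cat("  nodes: ", paste(x$node_patterns, collapse = " | "), "\n", sep = "")
  if (length(x$edge_kinds) > 0) {
    cat("  edges: ", paste(x$edge_kinds, collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

# One row per traversable (from, to, contact, direction) tuple. Directed
# synapse kinds traverse pre -> post when matched by name; gap junctions
# and the "any" wildcard traverse either direction.
traversal_edges <- function(graph) {
  cc <- graph$contacts
  if (nrow(cc) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          contact_id = character(), kind = character(),
                          forward = logical()))
  }
  kind <- ifelse(cc$kind == "bc_conventional", "conventional", cc$kind)
  dplyr::bind_rows(
    tibble::tibble(from = cc$pre_id, to = cc$post_id,
                   contact_id = cc$id, kind = kind, forward = TRUE),
    tibble::tibble(from = cc$post_id, to = cc$pre_id,
                   contact_id = cc$id, kind = kind, forward = FALSE)
  )
}

#' Find all simple paths matching a pattern
#'
#' Enumerates every simple path (no repeated neuron) whose i-th neuron's
#' class label fully matches the i-th node regex and whose i-th hop uses a
#' contact of the i-th edge kind. Directed synapses are traversed
#' pre -> post only; gap junctions and the `any` kind traverse either
#' direction. Parallel contacts between the same pair yield distinct
#' matches. Results are ordered lexicographically by the neuron-id then
#' contact-id sequence, so output is deterministic.
#'
#' @param graph A [connectome()].
#' @param pattern A [parse_query()] result, or a query string.
#' @return A tibble of class `path_matches`, one row per match, with
#'   list-columns `neuron_ids`, `contact_ids`, `classes`.
#' @export
#' @examples
#' g <- rc1_summary_fixture()
#' m <- find_paths(g, "CB.*, ribbon, GC tON DS")
#' nrow(m)
find_paths <- function(graph, pattern) {
  stopifnot(inherits(graph, "connectome"))
  if (is.character(pattern)) pattern <- parse_query(pattern)
  stopifnot(inherits(pattern, "path_pattern"))

  labels <- setNames(graph$neurons$class_label, graph$neurons$id)
  match_sets <- lapply(pattern$node_patterns, function(p) {
    ids <- names(labels)[grepl(anchor_regex(p), labels)]
    sort(ids)
  })
  n_hops <- length(pattern$edge_kinds)
  edges <- traversal_edges(graph)

  results <- list()
  extend <- function(nodes, contacts_so_far, pos) {
    if (pos > n_hops) {
      results[[length(results) + 1]] <<-
        list(neuron_ids = nodes, contact_ids = contacts_so_far)
      return(invisible(NULL))
    }
    want <- pattern$edge_kinds[pos]
    cand <- edges[edges$from == nodes[length(nodes)], , drop = FALSE]
    if (want != "any") {
      cand <- cand[cand$kind == want &
                     (cand$forward | cand$kind == "gap_junction"), ,
                   drop = FALSE]
    }
    cand <- cand[cand$to %in% match_sets[[pos + 1]] &
                   !(cand$to %in% nodes), , drop = FALSE]
    if (nrow(cand) == 0) return(invisible(NULL))
    ord <- order(cand$to, cand$contact_id)
    cand <- cand[ord, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      extend(c(nodes, cand$to[i]), c(contacts_so_far, cand$contact_id[i]),
             pos + 1)
    }
  }
  for (start in match_sets[[1]]) extend(start, character(), 1)

  out <- tibble::tibble(
    neuron_ids = lapply(results, `[[`, "neuron_ids"),
    contact_ids = lapply(results, `[[`, "contact_ids")
  )
  out$classes <- lapply(out$neuron_ids, function(ids) unname(labels[ids]))
  structure(out, class = c("path_matches", class(tibble::tibble())),
            pattern = pattern)
}

#' Tally path matches by endpoint class
#'
#' @param matches A [find_paths()] result.
#' @param group_by One of `"none"`, `"first_class"`, `"last_class"`,
#'   `"endpoint_pair"`.
#' @return A tibble of group counts; the counts sum to `nrow(matches)`.
#' @export
count_matches <- function(matches,
                          group_by = c("none", "first_class", "last_class",
                                       "endpoint_pair")) {
  stopifnot(inherits(matches, "path_matches"))
  group_by <- match.arg(group_by)
  if (nrow(matches) == 0) {
    out <- switch(group_by,
      none = tibble::tibble(n = 0L),
      first_class = tibble::tibble(first_class = character(), n = integer()),
      last_class = tibble::tibble(last_class = character(), n = integer()),
      endpoint_pair = tibble::tibble(first_class = character(),
                                     last_class = character(), n = integer())
    )
    return(out)
  }
  firsts <- vapply(matches$classes, function(x) x[1], character(1))
  lasts <- vapply(matches$classes, function(x) x[length(x)], character(1))
  tab <- switch(group_by,
    none = tibble::tibble(n = nrow(matches)),
    first_class = tibble::tibble(first_class = firsts) |>
      dplyr::count(.data$first_class),
    last_class = tibble::tibble(last_class = lasts) |>
      dplyr::count(.data$last_class),
    endpoint_pair = tibble::tibble(first_class = firsts,
                                   last_class = lasts) |>
      dplyr::count(.data$first_class, .data$last_class)
  )
  tab
}

#' Keep only matches whose classes at two positions differ
#'
#' Implements the disjoint-class constraint of coupled feedforward chains:
#' a ganglion cell coupled to an amacrine cell that inhibits a ganglion
#' cell of a *different* class (GC1 :: AC > GC2 with class 1 != class 2).
#'
#' @param matches A [find_paths()] result.
#' @param graph The [connectome()] the matches came from.
#' @param pos_a,pos_b 1-based node positions along the path.
#' @return The filtered `path_matches` tibble.
#' @export
disjoint_filter <- function(matches, graph, pos_a, pos_b) {
  stopifnot(inherits(matches, "path_matches"), inherits(graph, "connectome"))
  npos <- length(attr(matches, "pattern")$node_patterns)
  if (pos_a < 1 || pos_b < 1 || pos_a > npos || pos_b > npos) {
    abort("position out of range for this pattern",
          class = "retcouple_domain_error")
  }
  if (nrow(matches) == 0) return(matches)
  labels <- setNames(graph$neurons$class_label, graph$neurons$id)
  keep <- vapply(matches$neuron_ids, function(ids) {
    labels[[ids[pos_a]]] != labels[[ids[pos_b]]]
  }, logical(1))
  out <- matches[keep, , drop = FALSE]
  attr(out, "pattern") <- attr(matches, "pattern")
  class(out) <- class(matches)
  out
}
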