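# Exhaustive path enumeration: the independent oracle for find_paths().
# Enumerates every node sequence (no repeats) against the node regexes,
# then every admissible contact assignment per hop, with no shared code
# with the engine under test.
brute_force_paths <- function(graph, pattern) {
  labels <- stats::setNames(graph$neurons$class_label, graph$neurons$id)
  node_ok <- function(id, pat) {
    grepl(paste0("^(?:", pat, ")$"), labels[[id]])
  }
  cc <- graph$contacts
  hop_contacts <- function(from, to, kind) {
    norm <- ifelse(cc$kind == "bc_conventional", "conventional", cc$kind)
    fwd <- cc$pre_id == from & cc$post_id == to
    bwd <- cc$pre_id == to & cc$post_id == from
    usable <- switch(kind,
      any = fwd | bwd,
      gap_junction = (fwd | bwd) & norm == "gap_junction",
      fwd & norm == kind
    )
    cc$id[usable]
  }
  L <- length(pattern$node_patterns)
  out <- list()
  recurse <- function(nodes, contacts) {
    pos <- length(nodes)
    if (pos == L) {
      out[[length(out) + 1]] <<- list(nodes = nodes, contacts = contacts)
      return(invisible(NULL))
    }
    kind <- pattern$edge_kinds[pos]
    for (nxt in names(labels)) {
      if (nxt %in% nodes) next
      if (!node_ok(nxt, pattern$node_patterns[pos + 1])) next
      for (cid in hop_contacts(nodes[pos], nxt, kind)) {
        recurse(c(nodes, nxt), c(contacts, cid))
      }
    }
  }
  for (start in names(labels)) {
    if (node_ok(start, pattern$node_patterns[1])) {
      recurse(start, character())
    }
  }
  out
}

path_keys <- function(matches) {
  if (inherits(matches, "path_matches")) {
    mapply(function(n, c) paste(c(n, c), collapse = "|"),
           matches$neuron_ids, matches$contact_ids)
  } else {
    vapply(matches, function(m) {
      paste(c(m$nodes, m$contacts), collapse = "|")
    }, character(1))
  }
}

random_toy_graph <- function(n_nodes = sample(2:8, 1),
                             n_contacts = sample(0:14, 1)) {
  classes <- c("A1", "A2", "B1", "B2", "C")
  neurons <- data.frame(
    id = sprintf("n%d", seq_len(n_nodes)),
    class_label = sample(classes, n_nodes, replace = TRUE)
  )
  if (n_contacts == 0) {
    return(connectome(neurons))
  }
  kinds <- sample(c("ribbon", "conventional", "bc_conventional",
                    "gap_junction"), n_contacts, replace = TRUE)
  pre <- sample(neurons$id, n_contacts, replace = TRUE)
  post <- sample(neurons$id, n_contacts, replace = TRUE)
  # gap junctions may not self-loop
  for (i in which(kinds == "gap_junction" & pre == post)) {
    post[i] <- sample(setdiff(neurons$id, pre[i]), 1)
  }
  contacts <- data.frame(
    id = sprintf("c%d", seq_len(n_contacts)), kind = kinds,
    pre_id = pre, post_id = post,
    area_um2 = round(runif(n_contacts, 0.01, 0.2), 4)
  )
  connectome(neurons, contacts)
}

random_pattern <- function(max_hops = 3) {
  hops <- sample(0:max_hops, 1)
  node_pool <- c("A.*", ".*1", "B.*", "A1|C", ".*", "C")
  edge_pool <- c("ribbon", "conventional", "gap_junction", "any")
  nodes <- sample(node_pool, hops + 1, replace = TRUE)
  edges <- sample(edge_pool, hops, replace = TRUE)
  tokens <- character(2 * hops + 1)
  tokens[seq(1, 2 * hops + 1, by = 2)] <- nodes
  if (hops > 0) tokens[seq(2, 2 * hops, by = 2)] <- edges
  parse_query(paste(tokens, collapse = ", "))
}
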