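test_that("query strings parse into node regexes and edge kinds", {
  p <- parse_query("CB.*, ribbon, GC ON")
  expect_s3_class(p, "path_pattern")
  expect_equal(p$node_patterns, c("CB.*", "GC ON"))
  expect_equal(p$edge_kinds, "ribbon")

  p0 <- parse_query("GC.*")
  expect_equal(length(p0$edge_kinds), 0)

  expect_equal(parse_query("A, gap junction, B")$edge_kinds, "gap_junction")
  expect_error(parse_query("GC.*, gap junction"),
               class = "retcouple_syntax_error")
  expect_error(parse_query("A, teleport, B"),
               class = "retcouple_vocabulary_error")
  expect_error(parse_query("A(, ribbon, B"),
               class = "retcouple_regex_error")
})

test_that("node regexes are anchored full matches", {
  g <- connectome(data.frame(id = c("a", "b"),
                             class_label = c("GC", "GC ON")))
  expect_equal(nrow(find_paths(g, "GC")), 1)     # not a prefix match
  expect_equal(nrow(find_paths(g, "GC.*")), 2)
})

test_that("degenerate node-only query returns matching neurons", {
  g <- toy_drive_graph()
  m <- find_paths(g, "CB.*")
  expect_equal(nrow(m), 2)
  expect_equal(length(unlist(m$contact_ids)), 0)
  expect_equal(nrow(find_paths(connectome(
    data.frame(id = character(), class_label = character())), ".*")), 0)
})

test_that("engine equals exhaustive enumeration on random toy graphs", {
  withr::local_seed(421)
  for (i in 1:40) {
    g <- random_toy_graph()
    p <- random_pattern()
    got <- find_paths(g, p)
    want <- brute_force_paths(g, p)
    expect_setequal(path_keys(got), path_keys(want))
  }
})

test_that("directionality: synapses one-way, gap junctions both ways", {
  g <- connectome(
    data.frame(id = c("u", "v"), class_label = c("A1", "B1")),
    data.frame(id = c("r", "j"), kind = c("ribbon", "gap_junction"),
               pre_id = c("u", "u"), post_id = c("v", "v"),
               area_um2 = 0.1)
  )
  expect_equal(nrow(find_paths(g, "B1, ribbon, A1")), 0)
  expect_equal(nrow(find_paths(g, "A1, ribbon, B1")), 1)
  expect_equal(nrow(find_paths(g, "B1, gap junction, A1")), 1)
  # "any" ignores direction entirely
  expect_equal(nrow(find_paths(g, "B1, any, A1")), 2)
})

test_that("match sets are invariant to stored gap-junction endpoint order", {
  neurons <- data.frame(id = c("g", "a", "h"),
                        class_label = c("GC ON", "YAC ON", "GC tON DS"))
  c1 <- data.frame(id = c("j1", "j2"), kind = "gap_junction",
                   pre_id = c("g", "a"), post_id = c("a", "h"),
                   area_um2 = 0.02)
  c2 <- c1
  c2$pre_id <- c1$post_id
  c2$post_id <- c1$pre_id
  q <- "GC.*, gap junction, YAC ON, gap junction, GC.*"
  k1 <- path_keys(find_paths(connectome(neurons, c1), q))
  k2 <- path_keys(find_paths(connectome(neurons, c2), q))
  expect_setequal(k1, k2)
  expect_equal(length(k1), 2) # both directions of the chain
})

test_that("adding a contact never removes a match", {
  withr::local_seed(99)
  for (i in 1:15) {
    g <- random_toy_graph(n_nodes = 6, n_contacts = 8)
    p <- random_pattern(max_hops = 2)
    before <- path_keys(find_paths(g, p))
    extra <- g$contacts[1, ]
    extra$id <- "extra"
    extra$pre_id <- sample(g$neurons$id, 1)
    extra$post_id <- sample(setdiff(g$neurons$id, extra$pre_id), 1)
    g2 <- connectome(g$neurons, rbind(g$contacts, extra))
    after <- path_keys(find_paths(g2, p))
    expect_true(all(before %in% after))
  }
})

test_that("count_matches tallies by class and totals are conserved", {
  g <- toy_drive_graph()
  m <- find_paths(g, "CB.*, ribbon, GC.*")
  expect_equal(nrow(m), 3)
  tab <- count_matches(m, "first_class")
  expect_equal(tab$n[tab$first_class == "CBb4w"], 2)
  expect_equal(tab$n[tab$first_class == "CBb5"], 1)
  expect_equal(sum(tab$n), nrow(m))
  expect_equal(count_matches(m, "none")$n, 3)
  pair <- count_matches(m, "endpoint_pair")
  expect_equal(sum(pair$n), 3)
  empty <- find_paths(g, "ZZZ")
  expect_equal(nrow(count_matches(empty, "first_class")), 0)
})

test_that("disjoint_filter keeps only cross-class chains", {
  g <- toy_chain_graph()
  m <- find_paths(g, "GC.*, gap junction, YAC ON, conventional, GC.*")
  expect_equal(nrow(m), 2) # gc1 -> ac1 -> gc2 and gc1 -> ac1 -> gc3
  kept <- disjoint_filter(m, g, 1, 3)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$classes[[1]][3], "GC ON")
  expect_error(disjoint_filter(m, g, 1, 9),
               class = "retcouple_domain_error")
  # an all-same-class toy yields nothing
  g_same <- connectome(
    data.frame(id = c("g1", "g2", "a"),
               class_label = c("GC ON", "GC ON", "YAC ON")),
    data.frame(id = c("j", "s"), kind = c("gap_junction", "conventional"),
               pre_id = c("g1", "a"), post_id = c("a", "g2"),
               area_um2 = 0.05)
  )
  m_same <- find_paths(g_same, "GC.*, gap junction, YAC ON, conventional, GC.*")
  expect_equal(nrow(disjoint_filter(m_same, g_same, 1, 3)), 0)
})
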