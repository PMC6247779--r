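test_that("TSV round trip preserves every field including optionals", {
  g <- rc1_summary_fixture()
  nodes <- withr::local_tempfile(fileext = ".tsv")
  edges <- withr::local_tempfile(fileext = ".tsv")
  save_connectome(g, nodes, edges)
  g2 <- load_connectome(nodes, edges)
  expect_equal(as.data.frame(g2$neurons), as.data.frame(g$neurons))
  expect_equal(as.data.frame(g2$contacts), as.data.frame(g$contacts))
})

test_that("GraphML export reparses into the same graph", {
  g <- rc1_summary_fixture()
  path <- withr::local_tempfile(fileext = ".graphml")
  save_connectome(g, path, format = "graphml")
  # reparse with a generic graph reader, then rebuild
  ig <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(g$neurons))
  expect_equal(igraph::ecount(ig), nrow(g$contacts))
  g2 <- load_connectome_graphml(path)
  ord <- order(g2$neurons$id)
  expect_equal(g2$neurons$class_label[ord],
               g$neurons$class_label[order(g$neurons$id)])
  ord2 <- order(g2$contacts$id)
  expect_equal(g2$contacts$area_um2[ord2],
               g$contacts$area_um2[order(g$contacts$id)])
  expect_equal(g2$contacts$kind[ord2],
               g$contacts$kind[order(g$contacts$id)])
})

test_that("empty edge file loads as a graph with zero contacts", {
  nodes <- withr::local_tempfile(fileext = ".tsv")
  edges <- withr::local_tempfile(fileext = ".tsv")
  g0 <- connectome(data.frame(id = "a", class_label = "CBb4w"))
  save_connectome(g0, nodes, edges)
  g <- load_connectome(nodes, edges)
  expect_equal(nrow(g$contacts), 0)
  expect_equal(nrow(g$neurons), 1)
})

test_that("format and referential errors are raised with context", {
  expect_error(connectome(data.frame(id = "a")),
               class = "retcouple_format_error")
  expect_error(
    connectome(data.frame(id = "a", class_label = "CBb4w"),
               data.frame(id = "e", kind = "ribbon", pre_id = "a",
                          post_id = "ghost", area_um2 = 0.1)),
    class = "retcouple_referential_error")
  expect_error(
    connectome(data.frame(id = "a", class_label = "CBb4w"),
               data.frame(id = "e", pre_id = "a", post_id = "a")),
    class = "retcouple_format_error")
})

test_that("disc model converts diameter to area and back", {
  expect_equal(diameter_to_area(0), 0)
  expect_equal(diameter_to_area(181), pi * 90.5^2 * 1e-6)
  expect_equal(diameter_to_area(181), 0.02573, tolerance = 1e-3)
  d <- c(72, 181, 357)
  expect_equal(area_to_diameter(diameter_to_area(d)), d)
  expect_error(diameter_to_area(-1), class = "retcouple_domain_error")
})

test_that("gap junctions are canonicalized and symmetric on input", {
  g1 <- connectome(
    data.frame(id = c("x", "a"), class_label = c("GC ON", "YAC ON")),
    data.frame(id = "j", kind = "gap_junction", pre_id = "x",
               post_id = "a", area_um2 = 0.02)
  )
  g2 <- connectome(
    data.frame(id = c("x", "a"), class_label = c("GC ON", "YAC ON")),
    data.frame(id = "j", kind = "gap_junction", pre_id = "a",
               post_id = "x", area_um2 = 0.02)
  )
  expect_equal(g1$contacts, g2$contacts)
  # derived diameter obeys the disc model
  expect_equal(diameter_to_area(g1$contacts$diameter_nm),
               g1$contacts$area_um2)
})

test_that("validate_connectome reports soft violations as data", {
  g <- rc1_summary_fixture()
  expect_equal(nrow(validate_connectome(g)), 0)

  bad <- connectome(
    data.frame(id = c("a", "b"), class_label = c("CBb4w", "GC ON"),
               arbor_fraction = c(1.5, NA)),
    data.frame(id = c("e1", "e2"),
               kind = c("conventional", "gap_junction"),
               pre_id = c("a", "b"), post_id = c("b", "b"),
               area_um2 = c(0, 0.02))
  )
  v <- validate_connectome(bad)
  expect_setequal(v$rule, c("arbor_fraction_range", "area_positive",
                            "gap_junction_no_self"))
  expect_equal(v$entity_id[v$rule == "area_positive"], "e1")
})
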