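test_that("feedforward/feedback bias tallies a toy cohort correctly", {
  g <- connectome(
    data.frame(id = c("ac", "bc1", "gc1", "ac2"),
               class_label = c("YAC ON", "CBb4w", "GC ON", "wfAC")),
    data.frame(id = sprintf("s%d", 1:6), kind = "conventional",
               pre_id = "ac",
               post_id = c("bc1", "bc1", "bc1", "bc1", "gc1", "ac2"),
               area_um2 = 0.05)
  )
  b <- ff_fb_bias(g, "ac")
  expect_equal(b$feedback_synapses, 4)
  expect_equal(b$ff_gc_synapses + b$ff_ac_synapses, 2)
  expect_equal(b$ff_fb_ratio_by_synapse, 0.5)
  expect_equal(b$ff_fb_ratio_by_target, 2)
  expect_equal(b$flag, "mixed")
  # cell with no output
  b0 <- ff_fb_bias(g, "bc1")
  expect_equal(b0$feedback_synapses + b0$ff_gc_synapses +
                 b0$ff_ac_synapses, 0)
  expect_true(is.na(b0$ff_fb_ratio_by_target))
  expect_equal(b0$flag, "no_output")
  expect_error(ff_fb_bias(g, character()),
               class = "retcouple_domain_error")
})

test_that("network totals count amacrine conventional output by target", {
  g <- connectome(
    data.frame(id = c("a1", "a2", "b", "g1"),
               class_label = c("YAC ON", "wfAC", "CBb4w", "GC ON")),
    data.frame(id = sprintf("s%d", 1:6), kind = "conventional",
               pre_id = c("a1", "a1", "a1", "a1", "a1", "a2"),
               post_id = c("b", "b", "b", "b", "g1", "a1"),
               area_um2 = 0.05)
  )
  tot <- network_ff_fb_totals(g)
  expect_equal(tot$ac_to_bc, 4)
  expect_equal(tot$ac_to_gc, 1)
  expect_equal(tot$ac_to_ac, 1)
  expect_equal(tot$fb_ff_ratio, 2)
  # cohort restriction
  tot1 <- network_ff_fb_totals(g, cohort = "a2")
  expect_equal(tot1$ac_to_ac, 1)
  expect_equal(tot1$ac_to_bc, 0)
  # no amacrine synapses at all
  g0 <- toy_drive_graph()
  tot0 <- network_ff_fb_totals(g0)
  expect_equal(tot0$ac_to_bc + tot0$ac_to_gc + tot0$ac_to_ac, 0)
})

test_that("census categories partition the gap junctions", {
  g <- connectome(
    data.frame(id = c("aii1", "aii2", "cbb", "cba", "gc", "yac"),
               class_label = c("AII", "AII", "CBb4", "CBb3", "GC ON",
                               "YAC ON")),
    data.frame(id = sprintf("j%d", 1:4), kind = "gap_junction",
               pre_id = c("aii1", "aii1", "cbb", "gc"),
               post_id = c("cbb", "aii2", "cba", "yac"),
               area_um2 = 0.02)
  )
  cen <- coupling_census(g)
  cat_of <- function(id) cen$junctions$category[cen$junctions$contact_id == id]
  expect_equal(cat_of("j1"), "heterocellular")         # AII :: CBb
  expect_equal(cat_of("j2"), "homocellular_in_class")  # AII :: AII
  expect_equal(cat_of("j3"), "homocellular_cross_class") # CBb :: CBa
  expect_equal(cat_of("j4"), "heterocellular")         # GC :: AC
  expect_equal(nrow(cen$junctions), 4)
  expect_equal(sum(cen$class_pairs$n), 4)
  # empty graph -> empty census
  cen0 <- coupling_census(toy_drive_graph())
  expect_equal(nrow(cen0$junctions), 0)
})

test_that("census is invariant to stored endpoint order", {
  neurons <- data.frame(id = c("g", "a"), class_label = c("GC ON", "YAC ON"))
  j1 <- data.frame(id = "j", kind = "gap_junction", pre_id = "g",
                   post_id = "a", area_um2 = 0.02)
  j2 <- j1
  j2$pre_id <- "a"
  j2$post_id <- "g"
  c1 <- coupling_census(connectome(neurons, j1))
  c2 <- coupling_census(connectome(neurons, j2))
  expect_equal(c1$class_pairs, c2$class_pairs)
})

test_that("coupled partner listing carries transmitter signatures", {
  g <- rc1_summary_fixture()
  partners <- coupled_partners(g, "GC606")
  expect_equal(sum(partners$n_junctions), 228)
  expect_true(all(partners$transmitter == "GABA"))
  expect_equal(partners$partner_id[1], "IAC9769") # most junctions
})
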