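test_that("generator output is reproducible and validates", {
  g1 <- generate_connectome(generator_config(), seed = 11)
  g2 <- generate_connectome(generator_config(), seed = 11)
  expect_identical(g1, g2)
  v <- validate_connectome(g1)
  expect_equal(nrow(v), 0)
  g3 <- generate_connectome(generator_config(), seed = 12)
  expect_false(identical(g1$contacts, g3$contacts))
})

test_that("an all-zero roster yields an empty graph", {
  cfg <- generator_config(roster = tibble::tibble(
    class_label = "CBb4w", n_cells = 0L))
  g <- generate_connectome(cfg, seed = 1)
  expect_equal(nrow(g$neurons), 0)
  expect_equal(nrow(g$contacts), 0)
})

test_that("invalid generator configs are rejected with messages", {
  bad <- generator_config()
  bad$coupling$diam_min_nm[1] <- 500
  expect_gt(length(validate_generator_config(bad)), 0)
  expect_error(generate_connectome(bad, seed = 1),
               class = "retcouple_config_error")
  expect_error(generator_config(roster = tibble::tibble(
    class_label = "x", n_cells = -1L)), class = "retcouple_config_error")
})

test_that("motif switches control the generated coupling patterns", {
  # GC::GC coupling stays off by default even if a rule requests it
  cfg <- generator_config()
  cfg$coupling <- dplyr::bind_rows(cfg$coupling, tibble::tibble(
    class_a = "GC ON", class_b = "GC tON DS", mean_per_pair = 5,
    diam_mean_nm = 181, diam_sd_nm = 56, diam_min_nm = 72,
    diam_max_nm = 357))
  g <- generate_connectome(cfg, seed = 3)
  cen <- coupling_census(g)
  gc_gc <- cen$junctions$superclass_a == "ganglion" &
    cen$junctions$superclass_b == "ganglion"
  expect_equal(sum(gc_gc), 0)
  # ... and comes on when the switch allows it
  cfg$motifs$gc_gc_coupling <- TRUE
  g_on <- generate_connectome(cfg, seed = 3)
  cen_on <- coupling_census(g_on)
  expect_gt(sum(cen_on$junctions$superclass_a == "ganglion" &
                  cen_on$junctions$superclass_b == "ganglion"), 0)
  # coupled amacrine cells feed forward to disjoint ganglion classes
  cls <- stats::setNames(g$neurons$class_label, g$neurons$id)
  coupled_acs <- unique(unlist(
    g$contacts[g$contacts$kind == "gap_junction", c("pre_id", "post_id")]))
  coupled_acs <- coupled_acs[cls[coupled_acs] == "YAC ON"]
  ff <- g$contacts[g$contacts$kind == "conventional" &
                     g$contacts$pre_id %in% coupled_acs &
                     grepl("^GC", cls[g$contacts$post_id]), ]
  expect_gt(sum(cls[ff$post_id] != "GC tON DS"), 0)
  # disabling the switch removes the disjoint-class feedforward
  cfg2 <- generator_config()
  cfg2$motifs$feedforward_disjoint <- FALSE
  g_off <- generate_connectome(cfg2, seed = 3)
  cls2 <- stats::setNames(g_off$neurons$class_label, g_off$neurons$id)
  ff_off <- g_off$contacts[g_off$contacts$kind == "conventional" &
                             grepl("^GC", cls2[g_off$contacts$post_id]), ]
  expect_true(all(cls2[ff_off$post_id] == "GC tON DS"))
})

test_that("generated gap-junction diameters recover the configured mean", {
  g <- generate_connectome(generator_config(), seed = 17)
  d <- g$contacts$diameter_nm[g$contacts$kind == "gap_junction"]
  expect_gt(length(d), 150)
  expect_true(all(d >= 72 & d <= 357))
  se <- 56 / sqrt(length(d))
  expect_lt(abs(mean(d) - 181), 3 * se)
})

test_that("fixture reproduces its published tallies deterministically", {
  g <- rc1_summary_fixture()
  dt <- drive_table(g, "GC606", arbor_fraction = 0.18)
  expect_equal(dt$n, c(259, 783, 228))
  expect_equal(round(dt$total_area_um2, 1), c(9.8, 53.6, 6.4))
  expect_equal(sum(g$contacts$validated[g$contacts$kind == "gap_junction" &
    (g$contacts$pre_id == "GC606" | g$contacts$post_id == "GC606")]), 61)
  # totals are exact sums of the per-contact areas
  rib <- g$contacts$area_um2[g$contacts$kind == "ribbon" &
                               g$contacts$post_id == "GC606"]
  expect_equal(sum(rib), dt$total_area_um2[1])
  # byte-identical serialization run-to-run
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  e1 <- withr::local_tempfile(fileext = ".tsv")
  e2 <- withr::local_tempfile(fileext = ".tsv")
  save_connectome(rc1_summary_fixture(), f1, e1)
  save_connectome(rc1_summary_fixture(), f2, e2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(e1), readLines(e2))
})

test_that("phantoms honour their configuration and ground truth", {
  ph <- generate_cmp_phantom(phantom_config(noise_sd = 0), seed = 5)
  expect_identical(ph$stack$channels[["γ"]],
                   generate_cmp_phantom(phantom_config(noise_sd = 0),
                                        seed = 5)$stack$channels[["γ"]])
  expect_equal(nrow(ph$objects), 12)
  # zero somas -> uniform background
  empty <- generate_cmp_phantom(phantom_config(n_somas = 0L, noise_sd = 0),
                                seed = 1)
  expect_equal(length(unique(as.vector(empty$stack$channels[["γ"]]))), 1)
  # GABA histogram modes ordered SAC > gamma+ GC > gamma- GC
  gch <- ph$stack$channels[["γ"]]
  mode_of <- function(class_idx) {
    h <- masked_histogram(gch, ph$truth == class_idx)
    h$pv[which.max(h$count)]
  }
  expect_gt(mode_of(1), mode_of(2)) # SAC above coupled GC
  expect_gt(mode_of(2), mode_of(3)) # coupled GC above gamma- GC
  # shared glutamate distribution: gamma+ and gamma- GCs overlap strongly
  he1 <- masked_histogram(ph$stack$channels[["E"]], ph$truth == 2)
  he2 <- masked_histogram(ph$stack$channels[["E"]], ph$truth == 3)
  expect_gt(separability(he1, he2)$overlap, 0.9)
})

test_that("infeasible soma layouts fail cleanly", {
  cfg <- phantom_config(size = 64, n_somas = c(40L, 40L, 40L),
                        radius_range = c(10, 12), max_tries = 30)
  expect_error(generate_cmp_phantom(cfg, seed = 1),
               class = "retcouple_layout_error")
})
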