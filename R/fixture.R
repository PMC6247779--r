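#' Deterministic summary fixture of a coupled ganglion-cell network
#'
#' A hand-constructed connectome whose tallies equal the published contact
#' census of a heavily coupled transient ON DS ganglion cell and its
#' network:
#'
#' * `GC606` (class "GC tON DS", arbor fraction 0.18) receives exactly 259
#'   ribbon synapses (areas summing to 9.8 um^2; 54% from CBb4w, under 1%
#'   from CBb5), 783 conventional synapses (53.6 um^2) and 228 gap
#'   junctions (6.4 um^2), all junction partners GABAergic amacrine
#'   classes, 61 of them traced/validated.
#' * `IAC9769`, an interstitial amacrine cell, makes one conventional
#'   synapse onto each of 38 distinct amacrine cells, 13 ganglion cells
#'   and 3 cone bipolar cells (feedforward-biased >10:1 by target).
#' * Nine `AI` rod-driven amacrine cells make 837 feedback synapses onto
#'   rod bipolar cells and no feedforward synapses.
#' * An annotated ON-network amacrine cohort (the IAC, the AI cells and 20
#'   ON GABAergic amacrine cells; see [rc1_cohorts()]) whose conventional
#'   output totals 2359 synapses onto bipolar cells, 336 onto ganglion
#'   cells and 564 onto amacrine cells.
#' * `GC9787` (class "GC OFF alpha") with exclusively OFF bipolar ribbon
#'   input and 13 gap junctions at 9142 nm^2 per um of dendrite.
#' * A few bipolar/AII junctions so every coupling-census category is
#'   populated; there are no GC::GC gap junctions.
#'
#' Per-contact areas are not published, so each area list is a
#' deterministic symmetric ramp around the target mean: counts, totals
#' (and hence printed means) are exact, and construction is free of
#' randomness, so serialization is byte-identical across runs.
#'
#' @return A validated [connectome()].
#' @export
#' @examples
#' g <- rc1_summary_fixture()
#' drive_table(g, "GC606", arbor_fraction = 0.18)
rc1_summary_fixture <- function() {
  ids <- rc1_cohorts()

  neuron <- function(id, class_label, ...) {
    tibble::tibble(id = id, class_label = class_label, ...)
  }
  neurons <- dplyr::bind_rows(
    neuron("GC606", "GC tON DS", gaba_mM = 0.5, soma_diameter_um = 34,
           arbor_fraction = 0.18),
    neuron("GC9787", "GC OFF alpha", gaba_mM = 0.3,
           dendrite_length_um = 4.81e6 / 9142),
    neuron(ids$cbb4w, "CBb4w"), neuron(ids$cbb3, "CBb3"),
    neuron(ids$cbb4, "CBb4"), neuron(ids$cbb6, "CBb6"),
    neuron(ids$cbb5, "CBb5"),
    neuron(ids$cba1, "CBa1"), neuron(ids$cba2, "CBa2"),
    neuron(ids$rb, "RB"),
    neuron(ids$wfac, "wfAC", gaba_mM = 5),
    neuron(ids$gac, "GAC"),
    neuron("IAC9769", "IAC", gaba_mM = 6),
    neuron(ids$yac_coupled, "YAC ON", gaba_mM = 5),
    neuron(ids$yac_network, "YAC ON", gaba_mM = 5),
    neuron(ids$untraced_ac, "gAC", gaba_mM = 4),
    neuron(ids$yac_off, "YAC OFF", gaba_mM = 5),
    neuron(ids$ai, "AI", gaba_mM = 5),
    neuron(ids$aii, "AII"),
    neuron(ids$gc_misc, rep(c("GC ON", "GC ON OFF"), c(7, 6)))
  )

  rows <- list()
  eid <- 0L
  add <- function(kind, pre, post, area, validated = TRUE,
                  diameter = NA_real_) {
    n <- max(length(pre), length(post), length(area))
    rows[[length(rows) + 1]] <<- tibble::tibble(
      id = sprintf("E%06d", eid + seq_len(n)), kind = kind,
      pre_id = rep_len(pre, n), post_id = rep_len(post, n),
      area_um2 = rep_len(area, n), diameter_nm = rep_len(diameter, n),
      validated = rep_len(validated, n))
    eid <<- eid + n
  }
  rep_each <- function(ids, counts) rep(ids, counts)

  # --- GC606 ribbon input: 259 synapses, 9.8 um^2 total, 54% CBb4w ------
  ribbon_pre <- c(
    rep_each(ids$cbb4w, rep(14L, 10)),          # 140
    rep_each(ids$cbb3, rep(8L, 5)),             # 40
    rep_each(ids$cbb4, c(8L, 8L, 8L, 8L, 7L)),  # 39
    rep_each(ids$cbb6, c(8L, 8L, 8L, 8L, 6L)),  # 38
    rep_each(ids$cbb5, 2L)                      # 2
  )
  add("ribbon", ribbon_pre, "GC606", ramp_areas(259, 9.8))

  # --- GC606 conventional input: 783 synapses, 53.6 um^2 total ----------
  conv_pre <- c(rep_each(ids$wfac, c(rep(47L, 10), rep(46L, 5))),  # 700
                rep_each(ids$gac, c(42L, 41L)))                    # 83
  add("conventional", conv_pre, "GC606", ramp_areas(783, 53.6))

  # --- GC606 gap junctions: 228 junctions, 6.4 um^2; 61 traced ----------
  gj_areas <- ramp_areas(228, 6.4)
  gj_partners <- c(rep("IAC9769", 25L),
                   rep_each(ids$yac_coupled, c(6L, 5L, 5L, 5L, 5L, 5L, 5L)),
                   rep_each(ids$untraced_ac, c(rep(9L, 7), rep(8L, 13))))
  add("gap_junction", "GC606", gj_partners, gj_areas,
      validated = rep(c(TRUE, FALSE), c(61L, 167L)),
      diameter = area_to_diameter(gj_areas))

  # --- GC9787: OFF ribbon input and 13 larger gap junctions -------------
  add("ribbon", c(rep_each(ids$cba1, rep(3L, 5)),
                  rep_each(ids$cba2, rep(2L, 3))),
      "GC9787", ramp_areas(21, 0.63, 0.5))
  gj2 <- ramp_areas(13, 4.81, 0.5)
  add("gap_junction", "GC9787",
      rep_each(ids$yac_off, c(4L, 3L, 3L, 3L)), gj2,
      diameter = area_to_diameter(gj2))

  # --- IAC9769 output: 1 synapse each onto 38 ACs, 13 GCs, 3 BCs --------
  iac_ac_targets <- c(ids$untraced_ac, ids$wfac, ids$gac,
                      ids$yac_coupled[1])
  add("conventional", "IAC9769",
      c(iac_ac_targets, ids$gc_misc, ids$cbb4w[1:3]),
      rep(0.05, 38 + 13 + 3))

  # --- AI cohort: 837 feedback synapses onto rod bipolar cells ----------
  ai_pre <- rep_each(ids$ai, rep(93L, 9))
  add("conventional", ai_pre,
      rep_len(rep(ids$rb, length.out = 93), 837), rep(0.05, 837))

  # --- ON-network YACs: 1519 -> BC, 323 -> GC, 526 -> AC ----------------
  yac_net <- c(ids$yac_coupled, ids$yac_network)  # 20 cells
  bc_pool <- c(ids$cbb4w, ids$cbb3, ids$cbb4, ids$cbb6, ids$cbb5)
  ac_pool <- c(ids$untraced_ac, ids$wfac)
  add("conventional",
      rep_each(yac_net, c(rep(76L, 19), 75L)),               # 1519
      rep_len(bc_pool, 1519), rep(0.05, 1519))
  add("conventional",
      rep_each(yac_net, c(rep(17L, 3), rep(16L, 17))),       # 323
      rep_len(ids$gc_misc, 323), rep(0.05, 323))
  add("conventional",
      rep_each(yac_net, c(rep(27L, 6), rep(26L, 14))),       # 526
      rep_len(ac_pool, 526), rep(0.05, 526))

  # --- census completeness: AII and bipolar coupling motifs -------------
  add("gap_junction", ids$aii[1], ids$cbb4w[4], 0.02)   # heterocellular
  add("gap_junction", ids$aii[1], ids$aii[2], 0.02)     # in-class
  add("gap_junction", ids$cbb3[1], ids$cbb4[1], 0.015)  # cross-class

  connectome(neurons, dplyr::bind_rows(rows))
}

# Deterministic positive area list with an exact total: a symmetric ramp
# around the mean (pairs cancel exactly, so sum(x) == total).
ramp_areas <- function(n, total, rel_spread = 0.8) {
  m <- total / n
  if (n == 1) return(total)
  m + seq(-1, 1, length.out = n) * rel_spread * m
}

#' Named cell cohorts of the summary fixture
#'
#' Returns the id lists used to build [rc1_summary_fixture()], including
#' `on_network_acs` — the annotated ON-network amacrine cohort over which
#' the network feedback/feedforward totals (2359/336/564) are defined.
#' Published network-level tallies are scoped to one bipolar-cell network
#' rather than the whole volume, so the fixture carries that scope as an
#' explicit cohort; the amacrine cells providing GC606's inhibitory input
#' lie outside it.
#'
#' @return A named list of character vectors of cell ids.
#' @export
rc1_cohorts <- function() {
  ids <- list(
    cbb4w = sprintf("CBb4w_%02d", 1:10),
    cbb3 = sprintf("CBb3_%02d", 1:5),
    cbb4 = sprintf("CBb4_%02d", 1:5),
    cbb6 = sprintf("CBb6_%02d", 1:5),
    cbb5 = "CBb5_01",
    cba1 = sprintf("CBa1_%02d", 1:5),
    cba2 = sprintf("CBa2_%02d", 1:3),
    rb = sprintf("RB_%02d", 1:10),
    wfac = sprintf("wfAC_%02d", 1:15),
    gac = sprintf("GAC_%02d", 1:2),
    yac_coupled = sprintf("YACc_%02d", 1:7),
    yac_network = sprintf("YACn_%02d", 1:13),
    untraced_ac = sprintf("gAC_%02d", 1:20),
    yac_off = sprintf("YACo_%02d", 1:4),
    ai = sprintf("AI_%02d", 1:9),
    aii = sprintf("AII_%02d", 1:2),
    gc_misc = sprintf("GCm_%02d", 1:13)
  )
  ids$on_network_acs <- c("IAC9769", ids$ai, ids$yac_coupled,
                          ids$yac_network)
  ids
}
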