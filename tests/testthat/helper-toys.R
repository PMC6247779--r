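# Small hand-built graphs used across tests.

toy_drive_graph <- function() {
  connectome(
    neurons = data.frame(
      id = c("bc1", "bc2", "gc"),
      class_label = c("CBb4w", "CBb5", "GC ON")
    ),
    contacts = data.frame(
      id = c("r1", "r2", "r3"), kind = "ribbon",
      pre_id = c("bc1", "bc1", "bc2"), post_id = "gc",
      area_um2 = c(0.1, 0.2, 0.3)
    )
  )
}

toy_chain_graph <- function() {
  # GC1 :: AC > GC2 chain plus a same-class control
  connectome(
    neurons = data.frame(
      id = c("gc1", "gc2", "gc3", "ac1"),
      class_label = c("GC tON DS", "GC ON", "GC tON DS", "YAC ON")
    ),
    contacts = data.frame(
      id = c("j1", "s1", "s2"),
      kind = c("gap_junction", "conventional", "conventional"),
      pre_id = c("gc1", "ac1", "ac1"),
      post_id = c("ac1", "gc2", "gc3"),
      area_um2 = 0.05
    )
  )
}
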