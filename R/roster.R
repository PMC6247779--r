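#' Bundled neuron class roster
#'
#' A reference table mapping neuron class labels to their superclass,
#' response polarity and primary transmitter. The roster covers the classes
#' used by the synthetic generators and the packaged summary fixture:
#' ON and OFF cone bipolar cells (CBb*, CBa*), rod bipolar cells (RB),
#' GABAergic and glycinergic amacrine cells (YAC, wfAC, GAC, AI, AII, IAC,
#' SAC), and ganglion cell classes. Unknown labels are allowed in a graph
#' but are flagged by [validate_connectome()].
#'
#' @return A tibble with columns `class_label`, `superclass`, `polarity`,
#'   `transmitter`.
#' @export
#' @examples
#' class_roster()
class_roster <- function() {
  tribble_rows <- list(
    # bipolar cells: CBb* are ON cone BCs, CBa* OFF cone BCs, RB rod BCs
    c("CBb3",      "bipolar",   "ON",     "glutamate"),
    c("CBb3n",     "bipolar",   "ON",     "glutamate"),
    c("CBb4",      "bipolar",   "ON",     "glutamate"),
    c("CBb4w",     "bipolar",   "ON",     "glutamate"),
    c("CBb5",      "bipolar",   "ON",     "glutamate"),
    c("CBb6",      "bipolar",   "ON",     "glutamate"),
    c("CBa1",      "bipolar",   "OFF",    "glutamate"),
    c("CBa2",      "bipolar",   "OFF",    "glutamate"),
    c("RB",        "bipolar",   "ON",     "glutamate"),
    # amacrine cells
    c("YAC ON",    "amacrine",  "ON",     "GABA"),
    c("YAC OFF",   "amacrine",  "OFF",    "GABA"),
    c("wfAC",      "amacrine",  "ON_OFF", "GABA"),
    c("gAC",       "amacrine",  "unknown","GABA"),
    c("GAC",       "amacrine",  "unknown","glycine"),
    c("AI",        "amacrine",  "ON",     "GABA"),
    c("AII",       "amacrine",  "ON_OFF", "glycine"),
    c("IAC",       "amacrine",  "ON",     "GABA"),
    c("SAC ON",    "amacrine",  "ON",     "acetylcholine_GABA"),
    c("SAC OFF",   "amacrine",  "OFF",    "acetylcholine_GABA"),
    # ganglion cells
    c("GC tON DS", "ganglion",  "ON",     "glutamate"),
    c("GC OFF alpha", "ganglion", "OFF",  "glutamate"),
    c("GC ON",     "ganglion",  "ON",     "glutamate"),
    c("GC OFF",    "ganglion",  "OFF",    "glutamate"),
    c("GC ON OFF", "ganglion",  "ON_OFF", "glutamate"),
    # photoreceptors / horizontal cells (census taxonomy completeness)
    c("rod",       "photoreceptor", "unknown", "glutamate"),
    c("cone",      "photoreceptor", "unknown", "glutamate"),
    c("HC",        "horizontal", "unknown", "GABA")
  )
  m <- do.call(rbind, tribble_rows)
  tibble::tibble(
    class_label = m[, 1], superclass = m[, 2],
    polarity = m[, 3], transmitter = m[, 4]
  )
}

superclass_levels <- function() {
  c("photoreceptor", "horizontal", "bipolar", "amacrine", "ganglion")
}

polarity_levels <- function() c("ON", "OFF", "ON_OFF", "unknown")

transmitter_levels <- function() {
  c("GABA", "glycine", "glutamate", "acetylcholine_GABA", "unknown")
}

contact_kinds <- function() {
  c("ribbon", "conventional", "bc_conventional", "gap_junction")
}
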