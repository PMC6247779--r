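#' Feedforward/feedback bias of an amacrine-cell cohort
#'
#' Amacrine-cell output divides into feedback (conventional synapses onto
#' bipolar cells) and feedforward (conventional synapses onto ganglion or
#' other amacrine cells). This tallies both at synapse level and at
#' distinct-target level for a cohort of presynaptic cells and reports the
#' feedforward:feedback ratios. A cohort with zero feedback synapses is
#' flagged `"feedback_free"`; one with zero feedforward synapses is flagged
#' `"feedback_dominant"`; ratios with a zero denominator are `NA`.
#'
#' @param graph A [connectome()].
#' @param cohort Character vector of presynaptic cell ids (must be
#'   non-empty and present in the graph).
#' @return A one-row tibble of class `bias_summary` with columns
#'   `feedback_synapses`, `ff_gc_synapses`, `ff_ac_synapses`,
#'   `targets_bc`, `targets_gc`, `targets_ac`,
#'   `ff_fb_ratio_by_synapse`, `ff_fb_ratio_by_target`, `flag`.
#' @export
#' @examples
#' g <- rc1_summary_fixture()
#' ff_fb_bias(g, "IAC9769")
ff_fb_bias <- function(graph, cohort) {
  stopifnot(inherits(graph, "connectome"))
  if (length(cohort) == 0) {
    abort("cohort must contain at least one cell id",
          class = "retcouple_domain_error")
  }
  missing_ids <- setdiff(cohort, graph$neurons$id)
  if (length(missing_ids) > 0) {
    abort(paste0("unknown cell(s) in cohort: ",
                 paste(head(missing_ids, 5), collapse = ", ")),
          class = "retcouple_referential_error")
  }
  sc <- setNames(graph$neurons$superclass, graph$neurons$id)
  cc <- graph$contacts
  out_syn <- cc[cc$kind %in% c("conventional", "bc_conventional") &
                  cc$pre_id %in% cohort, , drop = FALSE]
  tgt_sc <- sc[out_syn$post_id]

  fb <- sum(tgt_sc == "bipolar", na.rm = TRUE)
  ff_gc <- sum(tgt_sc == "ganglion", na.rm = TRUE)
  ff_ac <- sum(tgt_sc == "amacrine", na.rm = TRUE)
  t_bc <- length(unique(out_syn$post_id[tgt_sc == "bipolar"]))
  t_gc <- length(unique(out_syn$post_id[tgt_sc == "ganglion"]))
  t_ac <- length(unique(out_syn$post_id[tgt_sc == "amacrine"]))

  ratio_syn <- if (fb > 0) (ff_gc + ff_ac) / fb else NA_real_
  ratio_tgt <- if (t_bc > 0) (t_gc + t_ac) / t_bc else NA_real_
  flag <- if (fb == 0 && (ff_gc + ff_ac) > 0) {
    "feedback_free"
  } else if (fb > 0 && (ff_gc + ff_ac) == 0) {
    "feedback_dominant"
  } else if (fb == 0 && (ff_gc + ff_ac) == 0) {
    "no_output"
  } else {
    "mixed"
  }
  if (flag == "feedback_dominant") ratio_syn <- 0

  structure(tibble::tibble(
    feedback_synapses = fb, ff_gc_synapses = ff_gc, ff_ac_synapses = ff_ac,
    targets_bc = t_bc, targets_gc = t_gc, targets_ac = t_ac,
    ff_fb_ratio_by_synapse = ratio_syn, ff_fb_ratio_by_target = ratio_tgt,
    flag = flag
  ), class = c("bias_summary", class(tibble::tibble())))
}

#' Network-wide amacrine feedback/feedforward totals
#'
#' Counts conventional synapses made by amacrine cells onto bipolar cells
#' (feedback), ganglion cells (feedforward) and other amacrine cells
#' (feedforward) and reports the feedback : feedforward ratio. With
#' `cohort = NULL` every amacrine cell in the graph is presynaptic;
#' passing a cohort restricts the census to a named subnetwork (e.g. the
#' amacrine cells of one bipolar-cell network), which is how published
#' network-level tallies are usually scoped.
#'
#' @param graph A [connectome()].
#' @param cohort Optional character vector of presynaptic cell ids.
#' @return A one-row tibble with columns `ac_to_bc`, `ac_to_gc`,
#'   `ac_to_ac`, `fb_ff_ratio` (`ac_to_bc / (ac_to_gc + ac_to_ac)`, `NA`
#'   when there is no feedforward output).
#' @export
network_ff_fb_totals <- function(graph, cohort = NULL) {
  stopifnot(inherits(graph, "connectome"))
  sc <- setNames(graph$neurons$superclass, graph$neurons$id)
  pre_ids <- graph$neurons$id[!is.na(sc) & sc == "amacrine"]
  if (!is.null(cohort)) pre_ids <- intersect(pre_ids, cohort)
  cc <- graph$contacts
  syn <- cc[cc$kind %in% c("conventional", "bc_conventional") &
              cc$pre_id %in% pre_ids, , drop = FALSE]
  tgt <- sc[syn$post_id]
  ac_bc <- sum(tgt == "bipolar", na.rm = TRUE)
  ac_gc <- sum(tgt == "ganglion", na.rm = TRUE)
  ac_ac <- sum(tgt == "amacrine", na.rm = TRUE)
  ff <- ac_gc + ac_ac
  tibble::tibble(
    ac_to_bc = ac_bc, ac_to_gc = ac_gc, ac_to_ac = ac_ac,
    fb_ff_ratio = if (ff > 0) ac_bc / ff else NA_real_
  )
}
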