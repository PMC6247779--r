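#' Configuration for the synthetic connectome generator
#'
#' The generator emulates the statistical structure of a retina-like
#' volume: a class roster (how many cells of each class), wiring rules
#' (expected synapse counts per ordered cell pair, with lognormal contact
#' areas), coupling rules (expected gap-junction counts per unordered cell
#' pair, with truncated-normal diameters), and motif switches controlling
#' the coupled-network motifs of interest.
#'
#' Defaults emulate an ON-layer patch: a transient ON DS ganglion cell
#' driven predominantly (54%) by one ON cone bipolar class (CBb4w) with
#' under 1% of input from CBb5; GABAergic ON amacrine cells coupled to the
#' ganglion cell through many small gap junctions (expected 228, diameters
#' with mean 181 nm, SD 56 nm, truncated to 72–357 nm); amacrine feedback
#' onto bipolar cells; and coupled-amacrine feedforward onto ganglion
#' cells of disjoint classes. Homocellular GC::GC coupling is off by
#' default, reflecting its absence among proven motifs.
#'
#' @param roster Tibble with columns `class_label`, `n_cells` (classes
#'   must appear in [class_roster()] or carry their own `superclass`,
#'   `polarity`, `transmitter` columns).
#' @param wiring Tibble with columns `pre_class`, `post_class`, `kind`,
#'   `mean_per_pair` (Poisson mean per ordered cell pair),
#'   `area_meanlog`, `area_sdlog` (lognormal on um^2).
#' @param coupling Tibble with columns `class_a`, `class_b`,
#'   `mean_per_pair`, `diam_mean_nm`, `diam_sd_nm`, `diam_min_nm`,
#'   `diam_max_nm`.
#' @param motifs List of switches: `gc_gc_coupling` (allow homocellular
#'   ganglion coupling rules), `feedforward_disjoint` (coupled amacrine
#'   cells feed ganglion classes disjoint from their coupled class),
#'   `ac_feedback` (amacrine feedback onto bipolar cells).
#' @return An object of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config()
#' g <- generate_connectome(cfg, seed = 7)
#' g
generator_config <- function(roster = default_roster(),
                             wiring = default_wiring(),
                             coupling = default_coupling(),
                             motifs = list(gc_gc_coupling = FALSE,
                                           feedforward_disjoint = TRUE,
                                           ac_feedback = TRUE)) {
  cfg <- structure(list(roster = tibble::as_tibble(roster),
                        wiring = tibble::as_tibble(wiring),
                        coupling = tibble::as_tibble(coupling),
                        motifs = motifs),
                   class = "generator_config")
  problems <- validate_generator_config(cfg)
  if (length(problems) > 0) {
    abort(paste0("invalid generator config:\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "retcouple_config_error")
  }
  cfg
}

#' @rdname generator_config
#' @param config A `generator_config`.
#' @return `validate_generator_config()` returns a character vector of
#'   problems (empty when valid).
#' @export
validate_generator_config <- function(config) {
  problems <- character()
  r <- config$roster
  if (!all(c("class_label", "n_cells") %in% names(r))) {
    problems <- c(problems, "roster needs class_label and n_cells columns")
  } else if (any(r$n_cells < 0)) {
    problems <- c(problems, "roster cell counts must be >= 0")
  }
  w <- config$wiring
  need_w <- c("pre_class", "post_class", "kind", "mean_per_pair",
              "area_meanlog", "area_sdlog")
  if (!all(need_w %in% names(w))) {
    problems <- c(problems, paste0("wiring needs columns: ",
                                   paste(need_w, collapse = ", ")))
  } else {
    if (any(w$mean_per_pair < 0)) {
      problems <- c(problems, "wiring mean_per_pair must be >= 0")
    }
    if (any(!w$kind %in% contact_kinds())) {
      problems <- c(problems, "wiring kind must be a known contact kind")
    }
  }
  cp <- config$coupling
  need_c <- c("class_a", "class_b", "mean_per_pair", "diam_mean_nm",
              "diam_sd_nm", "diam_min_nm", "diam_max_nm")
  if (!all(need_c %in% names(cp))) {
    problems <- c(problems, paste0("coupling needs columns: ",
                                   paste(need_c, collapse = ", ")))
  } else {
    if (any(cp$mean_per_pair < 0)) {
      problems <- c(problems, "coupling mean_per_pair must be >= 0")
    }
    if (any(cp$diam_min_nm >= cp$diam_max_nm)) {
      problems <- c(problems, "coupling truncation bounds must be ordered")
    }
  }
  problems
}

#' @rdname generator_config
#' @export
default_roster <- function() {
  tibble::tibble(
    class_label = c("CBb3", "CBb4", "CBb4w", "CBb5", "CBb6",
                    "GC tON DS", "GC ON", "GC ON OFF",
                    "YAC ON", "AI", "RB"),
    n_cells = c(5L, 5L, 10L, 6L, 5L, 1L, 2L, 2L, 12L, 4L, 8L)
  )
}

#' @rdname generator_config
#' @export
default_wiring <- function() {
  ribbon_area <- c(meanlog = log(0.038) - 0.5 * 0.5^2, sdlog = 0.5)
  conv_area <- c(meanlog = log(0.068) - 0.5 * 0.5^2, sdlog = 0.5)
  tibble::tibble(
    pre_class = c("CBb4w", "CBb3", "CBb4", "CBb6", "CBb5",
                  "YAC ON", "YAC ON", "AI"),
    post_class = c(rep("GC tON DS", 5), "GC tON DS", "CBb4w", "RB"),
    kind = c(rep("ribbon", 5), "conventional", "conventional",
             "conventional"),
    # per-pair Poisson means; CBb4w carries ~54% of the ribbon drive and
    # CBb5 under 1%
    mean_per_pair = c(5.4, 3.03, 3.03, 3.03, 0.0833, 2, 0.8, 2),
    area_meanlog = c(rep(ribbon_area["meanlog"], 5),
                     rep(conv_area["meanlog"], 3)),
    area_sdlog = c(rep(ribbon_area["sdlog"], 5), rep(conv_area["sdlog"], 3))
  )
}

#' @rdname generator_config
#' @export
default_coupling <- function() {
  tibble::tibble(
    class_a = c("GC tON DS", "AII"),
    class_b = c("YAC ON", "CBb4w"),
    # 1 GC x 12 YAC ON pairs x 19 junctions/pair -> expected 228
    mean_per_pair = c(19, 0),
    diam_mean_nm = c(181, 181), diam_sd_nm = c(56, 56),
    diam_min_nm = c(72, 72), diam_max_nm = c(357, 357)
  )
}

# Truncated-normal sampler by inverse CDF, with the parent location
# calibrated so the *truncated* distribution has the requested mean.
rtruncnorm_meancal <- function(n, mean, sd, lower, upper) {
  if (n == 0) return(numeric())
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    b <- (upper - mu) / sd
    z <- pnorm(b) - pnorm(a)
    mu + sd * (dnorm(a) - dnorm(b)) / z
  }
  mu <- uniroot(function(m) trunc_mean(m) - mean,
                interval = c(lower - 5 * sd, upper + 5 * sd),
                tol = 1e-8)$root
  a <- pnorm((lower - mu) / sd)
  b <- pnorm((upper - mu) / sd)
  qnorm(a + runif(n) * (b - a)) * sd + mu
}

#' Generate a retina-like synthetic connectome
#'
#' Draws a typed multigraph from a [generator_config()]: per ordered cell
#' pair, synapse counts are Poisson with the rule's mean and areas are
#' lognormal; per unordered cell pair, gap-junction counts are Poisson and
#' diameters are truncated-normal (location-calibrated so the sample mean
#' recovers the configured mean), with areas derived from the disc model.
#' All randomness flows from `seed`; identical seeds give bit-identical
#' graphs.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A [connectome()].
#' @export
generate_connectome <- function(config = generator_config(), seed = 1) {
  problems <- validate_generator_config(config)
  if (length(problems) > 0) {
    abort(paste0("invalid generator config:\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "retcouple_config_error")
  }
  withr::with_seed(as.integer(seed), generate_connectome_impl(config))
}

generate_connectome_impl <- function(config) {
  roster <- config$roster
  neurons <- purrr::pmap_dfr(roster, function(class_label, n_cells, ...) {
    if (n_cells == 0) return(NULL)
    tibble::tibble(
      id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", class_label),
                   seq_len(n_cells)),
      class_label = class_label, ...
    )
  })
  if (nrow(neurons) == 0) {
    return(connectome(tibble::tibble(id = character(),
                                     class_label = character())))
  }
  ids_of <- split(neurons$id, neurons$class_label)
  contact_rows <- list()
  eid <- 0L
  next_ids <- function(n) {
    out <- sprintf("E%06d", eid + seq_len(n))
    eid <<- eid + n
    out
  }

  # chemical synapses
  wiring <- config$wiring
  if (!isTRUE(config$motifs$ac_feedback)) {
    roster_tbl <- class_roster()
    sup <- setNames(roster_tbl$superclass, roster_tbl$class_label)
    drop <- !is.na(sup[wiring$pre_class]) & sup[wiring$pre_class] == "amacrine" &
      !is.na(sup[wiring$post_class]) & sup[wiring$post_class] == "bipolar"
    wiring <- wiring[!drop, , drop = FALSE]
  }
  for (i in seq_len(nrow(wiring))) {
    rule <- wiring[i, ]
    pre <- ids_of[[rule$pre_class]]
    post <- ids_of[[rule$post_class]]
    if (is.null(pre) || is.null(post)) next
    pairs <- expand.grid(pre = pre, post = post,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$pre != pairs$post, , drop = FALSE]
    counts <- rpois(nrow(pairs), rule$mean_per_pair)
    total <- sum(counts)
    if (total == 0) next
    contact_rows[[length(contact_rows) + 1]] <- tibble::tibble(
      id = next_ids(total), kind = rule$kind,
      pre_id = rep(pairs$pre, counts), post_id = rep(pairs$post, counts),
      area_um2 = rlnorm(total, rule$area_meanlog, rule$area_sdlog),
      validated = TRUE
    )
  }

  # gap junctions
  coupling <- config$coupling
  if (!isTRUE(config$motifs$gc_gc_coupling)) {
    roster_tbl <- class_roster()
    sup <- setNames(roster_tbl$superclass, roster_tbl$class_label)
    gc_gc <- !is.na(sup[coupling$class_a]) &
      sup[coupling$class_a] == "ganglion" &
      !is.na(sup[coupling$class_b]) & sup[coupling$class_b] == "ganglion"
    coupling <- coupling[!gc_gc, , drop = FALSE]
  }
  coupled_pairs <- list()
  for (i in seq_len(nrow(coupling))) {
    rule <- coupling[i, ]
    a <- ids_of[[rule$class_a]]
    b <- ids_of[[rule$class_b]]
    if (is.null(a) || is.null(b)) next
    pairs <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    counts <- rpois(nrow(pairs), rule$mean_per_pair)
    total <- sum(counts)
    if (total == 0) next
    diam <- rtruncnorm_meancal(total, rule$diam_mean_nm, rule$diam_sd_nm,
                               rule$diam_min_nm, rule$diam_max_nm)
    contact_rows[[length(contact_rows) + 1]] <- tibble::tibble(
      id = next_ids(total), kind = "gap_junction",
      pre_id = rep(pairs$a, counts), post_id = rep(pairs$b, counts),
      area_um2 = diameter_to_area(diam), diameter_nm = diam,
      validated = TRUE
    )
    coupled_pairs[[length(coupled_pairs) + 1]] <-
      unique(tibble::tibble(ac = rep(pairs$b, counts),
                            gc_class = rule$class_a))
  }

  # coupled-amacrine feedforward onto disjoint ganglion classes
  if (isTRUE(config$motifs$feedforward_disjoint) &&
      length(coupled_pairs) > 0) {
    roster_tbl <- class_roster()
    sup <- setNames(roster_tbl$superclass, roster_tbl$class_label)
    cp <- dplyr::distinct(dplyr::bind_rows(coupled_pairs))
    cp <- cp[!is.na(sup[cp$gc_class]) & sup[cp$gc_class] == "ganglion", ,
             drop = FALSE]
    cls <- setNames(neurons$class_label, neurons$id)
    cp <- cp[sup[cls[cp$ac]] == "amacrine", , drop = FALSE]
    if (nrow(cp) > 0) {
      gc_ids <- neurons$id[!is.na(sup[neurons$class_label]) &
                             sup[neurons$class_label] == "ganglion"]
      for (i in seq_len(nrow(cp))) {
        targets <- gc_ids[cls[gc_ids] != cp$gc_class[i]]
        if (length(targets) == 0) next
        counts <- rpois(length(targets), 0.5)
        total <- sum(counts)
        if (total == 0) next
        conv <- default_wiring()
        ml <- conv$area_meanlog[conv$kind == "conventional"][1]
        sl <- conv$area_sdlog[conv$kind == "conventional"][1]
        contact_rows[[length(contact_rows) + 1]] <- tibble::tibble(
          id = next_ids(total), kind = "conventional",
          pre_id = cp$ac[i], post_id = rep(targets, counts),
          area_um2 = rlnorm(total, ml, sl), validated = TRUE
        )
      }
    }
  }

  contacts <- if (length(contact_rows) > 0) {
    dplyr::bind_rows(contact_rows)
  } else {
    NULL
  }
  connectome(neurons, contacts)
}
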