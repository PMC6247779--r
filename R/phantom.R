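#' Configuration for multichannel CMP image phantoms
#'
#' The phantom emulates a molecular-phenotyping field through the ganglion
#' cell layer: non-overlapping soma discs on a dim background, each soma
#' drawn from one signature class with per-channel concentrations mapped
#' to pixel values by a log-linear [calibration_model()], plus clipped
#' additive Gaussian pixel noise.
#'
#' Default classes follow the field's GABA/glutamate taxonomy: starburst
#' amacrine cells (GABA 5–10 mM, low glutamate), provisionally coupled
#' gamma+ ganglion cells (GABA 0.3–0.6 mM — an order of magnitude below
#' amacrine levels — with high glutamate), and gamma- ganglion cells (no
#' measurable GABA, same glutamate distribution as the gamma+ class, so
#' the two are separable only in the GABA channel).
#'
#' @param size Image edge length in pixels (square image).
#' @param classes Tibble with columns `class` and per-channel
#'   concentration ranges `gaba_min_mM`, `gaba_max_mM`, `glut_min_mM`,
#'   `glut_max_mM`; one row per signature class.
#' @param n_somas Integer vector of soma counts per class (recycled).
#' @param radius_range Soma radius range in pixels.
#' @param background_mM Named numeric: background concentration per
#'   channel.
#' @param model A [calibration_model()].
#' @param noise_sd Gaussian pixel-value noise SD (0 = noiseless).
#' @param max_tries Placement attempts per soma before giving up.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(size = 160,
                           classes = default_phantom_classes(),
                           n_somas = c(4L, 4L, 4L),
                           radius_range = c(8, 13),
                           background_mM = c(gaba = 0.01, glut = 0.1),
                           model = calibration_model(),
                           noise_sd = 4,
                           max_tries = 2000) {
  stopifnot(size > 2 * max(radius_range), all(radius_range > 0),
            noise_sd >= 0)
  classes <- tibble::as_tibble(classes)
  need <- c("class", "gaba_min_mM", "gaba_max_mM", "glut_min_mM",
            "glut_max_mM")
  if (!all(need %in% names(classes))) {
    abort(paste0("classes needs columns: ", paste(need, collapse = ", ")),
          class = "retcouple_config_error")
  }
  if (any(unlist(classes[, need[-1]]) < 0)) {
    abort("concentrations must be nonnegative",
          class = "retcouple_config_error")
  }
  structure(list(size = as.integer(size), classes = classes,
                 n_somas = rep_len(as.integer(n_somas), nrow(classes)),
                 radius_range = radius_range,
                 background_mM = background_mM, model = model,
                 noise_sd = noise_sd, max_tries = max_tries),
            class = "phantom_config")
}

#' @rdname phantom_config
#' @export
default_phantom_classes <- function() {
  # glutamate is identical for the two ganglion-cell classes (a coupled
  # gamma+ GC keeps the classic high-glutamate GC signature), so only the
  # GABA channel separates them; amacrine glutamate sits a log unit lower
  tibble::tibble(
    class = c("SAC", "gamma_pos_GC", "gamma_neg_GC"),
    gaba_min_mM = c(5, 0.3, 0.01), gaba_max_mM = c(10, 0.6, 0.01),
    glut_min_mM = c(0.5, 5, 5), glut_max_mM = c(0.5, 5, 5)
  )
}

#' Generate a multichannel CMP image phantom with ground truth
#'
#' Places non-overlapping soma discs, samples each soma's per-channel
#' concentration uniformly within its class range (the glutamate range is
#' shared between the two ganglion-cell classes by default), converts
#' concentration to pixel value through the calibration model, and adds
#' clipped Gaussian noise. All randomness flows from `seed`.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed.
#' @return A list with `stack` (a [channel_stack()] with channels
#'   `"γ"` (GABA) and `"E"` (glutamate)), `truth` (integer matrix; 0
#'   background, i = i-th class row), `objects` (tibble: one row per soma
#'   with class, centre, radius, true concentrations).
#' @export
#' @examples
#' ph <- generate_cmp_phantom(phantom_config(noise_sd = 0), seed = 7)
#' table(ph$truth)
generate_cmp_phantom <- function(config = phantom_config(), seed = 1) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(as.integer(seed), generate_cmp_phantom_impl(config))
}

generate_cmp_phantom_impl <- function(config) {
  n <- config$size
  truth <- matrix(0L, n, n)
  gaba_c <- matrix(config$background_mM[["gaba"]], n, n)
  glut_c <- matrix(config$background_mM[["glut"]], n, n)

  placed <- list()
  coords <- expand.grid(row = seq_len(n), col = seq_len(n))
  for (ci in seq_len(nrow(config$classes))) {
    cls <- config$classes[ci, ]
    for (s in seq_len(config$n_somas[ci])) {
      ok <- FALSE
      for (try in seq_len(config$max_tries)) {
        r <- runif(1, config$radius_range[1], config$radius_range[2])
        cx <- runif(1, r + 1, n - r)
        cy <- runif(1, r + 1, n - r)
        clear <- TRUE
        for (p in placed) {
          if ((p$cx - cx)^2 + (p$cy - cy)^2 < (p$r + r + 1)^2) {
            clear <- FALSE
            break
          }
        }
        if (clear) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort("could not place non-overlapping somas; reduce counts or radii",
              class = "retcouple_layout_error")
      }
      gaba <- runif(1, cls$gaba_min_mM, cls$gaba_max_mM)
      glut <- runif(1, cls$glut_min_mM, cls$glut_max_mM)
      inside <- (coords$row - cy)^2 + (coords$col - cx)^2 <= r^2
      truth[cbind(coords$row[inside], coords$col[inside])] <- ci
      gaba_c[cbind(coords$row[inside], coords$col[inside])] <- gaba
      glut_c[cbind(coords$row[inside], coords$col[inside])] <- glut
      placed[[length(placed) + 1]] <-
        list(class = cls$class, cx = cx, cy = cy, r = r,
             gaba_mM = gaba, glut_mM = glut)
    }
  }

  to_pv <- function(conc) {
    pv <- conc_to_pv(conc, config$model)
    if (config$noise_sd > 0) {
      pv <- pv + rnorm(length(pv), 0, config$noise_sd)
    }
    matrix(round(pmin(pmax(pv, 0), 255)), n, n)
  }
  stack <- channel_stack(
    list("γ" = to_pv(gaba_c), "E" = to_pv(glut_c)),
    registered = TRUE
  )
  objects <- dplyr::bind_rows(lapply(placed, tibble::as_tibble))
  list(stack = stack, truth = truth, objects = objects)
}
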