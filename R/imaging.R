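#' Bundle registered image channels into a stack
#'
#' A channel stack holds co-registered single-molecule 8-bit images
#' (conventionally named with the field's Greek letters: GABA "γ",
#' glutamate "E", glutamine "Q", aspartate "D", glycine "G", taurine
#' "τ", AGB "B"). All channels must share one shape; values must lie
#' in [0, 255].
#'
#' @param channels Named list of numeric matrices.
#' @param pixel_size_um Optional pixel edge length in micrometres.
#' @param registered Logical; whether the channels are already aligned.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size_um = NULL,
                          registered = TRUE) {
  stopifnot(is.list(channels), length(channels) > 0)
  if (is.null(names(channels)) || any(names(channels) == "")) {
    abort("all channels must be named", class = "retcouple_format_error")
  }
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1) {
    abort("all channels must share the same dimensions",
          class = "retcouple_format_error")
  }
  for (ch in channels) {
    if (any(ch < 0 | ch > 255, na.rm = TRUE)) {
      abort("pixel values must lie in [0, 255]",
            class = "retcouple_domain_error")
    }
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 registered = registered),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<channel_stack> ", d[1], "x", d[2], " px, channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Estimate the integer translation aligning two images
#'
#' Exhaustive search over integer shifts within `max_shift` pixels,
#' scoring each candidate by the Pearson correlation of the overlapping
#' region; the best-scoring shift is returned. The result is the
#' displacement of `img_b` relative to `img_a` — if `img_b` was produced
#' by `shift_image(img_a, dx, dy)` the same `(dx, dy)` is recovered, and
#' `shift_image(img_b, -dx, -dy)` re-aligns `img_b` to `img_a`. A peak
#' correlation below `min_correlation` sets `low_confidence = TRUE`
#' (e.g. for structureless noise pairs). Ties prefer the smallest shift.
#'
#' @param img_a,img_b Numeric matrices of identical shape.
#' @param max_shift_px Maximum absolute shift searched per axis.
#' @param min_correlation Confidence threshold on the peak correlation.
#' @return A list with `dx` (columns), `dy` (rows), `correlation`,
#'   `low_confidence`.
#' @export
register_translation <- function(img_a, img_b, max_shift_px = 10,
                                 min_correlation = 0.5) {
  if (!all(dim(img_a) == dim(img_b))) {
    abort("images must have identical dimensions",
          class = "retcouple_format_error")
  }
  stopifnot(max_shift_px >= 0)
  nr <- nrow(img_a)
  nc <- ncol(img_a)
  best <- list(dx = 0L, dy = 0L, score = -Inf)
  for (dy in -max_shift_px:max_shift_px) {
    for (dx in -max_shift_px:max_shift_px) {
      # overlap of a with b shifted by (dx, dy)
      ra <- max(1, 1 + dy):min(nr, nr + dy)
      ca <- max(1, 1 + dx):min(nc, nc + dx)
      if (length(ra) < 2 || length(ca) < 2) next
      a <- img_a[ra, ca]
      b <- img_b[ra - dy, ca - dx]
      if (sd(a) == 0 || sd(b) == 0) {
        score <- if (sd(a) == 0 && sd(b) == 0) 1 else 0
      } else {
        score <- cor(as.vector(a), as.vector(b))
      }
      better <- score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
           abs(dx) + abs(dy) < abs(best$dx) + abs(best$dy))
      if (better) best <- list(dx = as.integer(dx), dy = as.integer(dy),
                               score = score)
    }
  }
  list(dx = -best$dx, dy = -best$dy, correlation = best$score,
       low_confidence = best$score < min_correlation)
}

#' @rdname register_translation
#' @param img Matrix to translate.
#' @param dx,dy Integer shift in columns / rows; vacated pixels are filled
#'   with `fill`.
#' @param fill Fill value for exposed borders.
#' @return `shift_image()` returns the translated matrix.
#' @export
shift_image <- function(img, dx, dy, fill = 0) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  rows <- max(1, 1 + dy):min(nr, nr + dy)
  cols <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(rows) > 0 && length(cols) > 0) {
    out[rows, cols] <- img[rows - dy, cols - dx]
  }
  out
}

#' Cluster a channel stack into a theme map
#'
#' Treats each pixel as a point in channel space and partitions the pixels
#' with k-means (best of `restarts` random starts by total within-cluster
#' sum of squares, deterministic under `seed`). Cluster labels are
#' renumbered 0..k-1 in lexicographic order of their mean signatures so
#' label identity is stable. The resulting label image — a theme map —
#' assigns each pixel to a molecular signature class.
#'
#' @param stack A [channel_stack()].
#' @param k Number of signature classes (>= 1, at most the number of
#'   distinct pixel vectors).
#' @param seed Integer seed for the restarts.
#' @param restarts Number of random initialisations.
#' @return An object of class `theme_map`: list with `labels` (integer
#'   matrix, 0-based), `signatures` (tibble of per-label channel means and
#'   pixel counts), `k`, `seed`, `inertia`.
#' @export
cluster_theme_map <- function(stack, k, seed = 1, restarts = 10) {
  stopifnot(inherits(stack, "channel_stack"), k >= 1)
  x <- vapply(stack$channels, as.vector,
              numeric(length(stack$channels[[1]])))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    abort(paste0("k = ", k, " exceeds the number of distinct pixel ",
                 "vectors (", n_distinct, ")"),
          class = "retcouple_domain_error")
  }
  km <- withr::with_seed(seed, {
    if (k == 1) {
      centers <- matrix(colMeans(x), 1)
      list(cluster = rep(1L, nrow(x)), centers = centers,
           tot.withinss = sum(sweep(x, 2, centers[1, ])^2))
    } else {
      kmeans(x, centers = k, nstart = restarts, iter.max = 200)
    }
  })
  # canonical label order: lexicographic by centre signature
  ord <- do.call(order, as.data.frame(km$centers))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k) - 1L
  labels <- matrix(relabel[km$cluster], nrow(stack$channels[[1]]),
                   ncol(stack$channels[[1]]))
  centers <- km$centers[ord, , drop = FALSE]
  signatures <- tibble::as_tibble(as.data.frame(centers))
  names(signatures) <- names(stack$channels)
  signatures <- dplyr::mutate(signatures,
                              label = seq_len(k) - 1L,
                              n_pixels = as.integer(table(
                                factor(labels, levels = seq_len(k) - 1L))),
                              .before = 1)
  structure(list(labels = labels, signatures = signatures, k = k,
                 seed = seed, inertia = km$tot.withinss),
            class = "theme_map")
}

#' @export
print.theme_map <- function(x, ...) {
  cat("<theme_map> k =", x$k, " inertia =", signif(x$inertia, 5), "\n")
  print(x$signatures)
  invisible(x)
}

#' Peak-normalized histogram of a masked channel
#'
#' Tabulates the 256 possible 8-bit pixel values inside a mask and adds a
#' peak-normalized column (maximum count scaled to 1), the conventional
#' display for comparing signature distributions across cell classes of
#' very different pixel areas.
#'
#' @param channel Numeric matrix with values in [0, 255].
#' @param mask Optional logical/0-1 matrix of the same shape; `NULL` uses
#'   every pixel.
#' @return A tibble of class `signature_histogram` with columns `pv`
#'   (0:255), `count`, `normalized`; attributes `n` (pixels used) and
#'   `empty` (TRUE when the mask selects nothing, in which case
#'   `normalized` is all zero).
#' @export
masked_histogram <- function(channel, mask = NULL) {
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(channel))) {
      abort("mask must match the channel dimensions",
            class = "retcouple_format_error")
    }
    values <- channel[as.logical(mask)]
  } else {
    values <- as.vector(channel)
  }
  values <- round(values)
  counts <- tabulate(values + 1L, nbins = 256L)
  n <- sum(counts)
  out <- tibble::tibble(
    pv = 0:255, count = counts,
    normalized = if (n > 0) counts / max(counts) else rep(0, 256)
  )
  structure(out, class = c("signature_histogram", class(tibble::tibble())),
            n = n, empty = n == 0)
}

#' Segment a calibrated GABA channel into three content classes
#'
#' Pixels are classified by inferred GABA concentration into: class 1,
#' no measurable GABA (c below the first threshold — uncoupled ganglion
#' cells); class 2, intermediate GABA (provisionally coupled gamma+
#' ganglion cells); class 3, amacrine-range GABA (at or above the second
#' threshold; content above the third, nominal upper bound is also class
#' 3). Boundaries follow the half-open convention `[low, high)`, so a
#' pixel exactly at a threshold joins the upper class. Classification is
#' performed in pixel-value space using the calibration model, making
#' boundary behaviour exact for 8-bit data.
#'
#' @param gaba_channel Numeric matrix of pixel values.
#' @param model A [calibration_model()].
#' @param thresholds_mM Increasing concentrations `(low, mid, high)` in
#'   mM; defaults to `c(0.1, 1, 10)`.
#' @return Integer matrix of class labels 1/2/3 with attribute `classes =
#'   c("gamma_negative", "gamma_positive_gc", "amacrine")`.
#' @export
segment_gaba_classes <- function(gaba_channel,
                                 model = calibration_model(),
                                 thresholds_mM = c(0.1, 1, 10)) {
  if (length(thresholds_mM) != 3 || any(diff(thresholds_mM) <= 0)) {
    abort("thresholds_mM must be three strictly increasing concentrations",
          class = "retcouple_domain_error")
  }
  pv_lo <- conc_to_pv(thresholds_mM[1], model)
  pv_mid <- conc_to_pv(thresholds_mM[2], model)
  labels <- matrix(1L, nrow(gaba_channel), ncol(gaba_channel))
  labels[gaba_channel >= pv_lo] <- 2L
  labels[gaba_channel >= pv_mid] <- 3L
  attr(labels, "classes") <- c("gamma_negative", "gamma_positive_gc",
                               "amacrine")
  labels
}

#' Map stack channels onto RGB display planes
#'
#' The mapping grammar is `"<channels>::<letters>"`: the i-th channel name
#' on the left is assigned to the i-th display letter on the right, where
#' `r`, `g`, `b` are single planes and `y` (yellow) duplicates a channel
#' into both R and G. Contributions are additive and clamped at 255. For
#' example `"γE::yb"` renders GABA as yellow and glutamate as blue.
#'
#' @param stack A [channel_stack()].
#' @param mapping Mapping string; channel names on the left must be single
#'   characters present in the stack.
#' @return Numeric array `height x width x 3` with values in [0, 255].
#' @export
colocalization_rgb <- function(stack, mapping) {
  stopifnot(inherits(stack, "channel_stack"))
  parts <- strsplit(mapping, "::", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    abort("mapping must have the form '<channels>::<rgb-letters>'",
          class = "retcouple_syntax_error")
  }
  chans <- strsplit(parts[1], "")[[1]]
  letters_ <- strsplit(parts[2], "")[[1]]
  if (length(chans) != length(letters_)) {
    abort("channel list and display letters must have equal length",
          class = "retcouple_syntax_error")
  }
  bad <- setdiff(chans, names(stack$channels))
  if (length(bad) > 0) {
    abort(paste0("unknown channel(s): ", paste(bad, collapse = ", ")),
          class = "retcouple_vocabulary_error")
  }
  plane_sets <- list(r = 1L, g = 2L, b = 3L, y = c(1L, 2L))
  bad <- setdiff(letters_, names(plane_sets))
  if (length(bad) > 0) {
    abort(paste0("unknown display letter(s): ",
                 paste(bad, collapse = ", "), "; use r, g, b or y"),
          class = "retcouple_vocabulary_error")
  }
  d <- dim(stack$channels[[1]])
  rgb <- array(0, c(d[1], d[2], 3))
  for (i in seq_along(chans)) {
    for (p in plane_sets[[letters_[i]]]) {
      rgb[, , p] <- rgb[, , p] + stack$channels[[chans[i]]]
    }
  }
  pmin(rgb, 255)
}

#' Count labelled objects in a segmentation
#'
#' Extracts the 8-connected components of one label in an integer label
#' map and keeps those of at least `min_area_px` pixels — the size filter
#' removes small fragments such as cross-sectioned dendrites, leaving
#' soma-scale objects.
#'
#' @param label_map Integer matrix.
#' @param target_label Label value to extract.
#' @param min_area_px Minimum component area in pixels.
#' @return A tibble with one row per object: `object_id`, `area_px`,
#'   `centroid_x` (column), `centroid_y` (row), `equivalent_diameter_px`.
#' @export
count_objects <- function(label_map, target_label, min_area_px = 1) {
  comp <- label_components(label_map == target_label)
  n_comp <- attr(comp, "n")
  if (n_comp == 0) {
    return(tibble::tibble(object_id = integer(), area_px = integer(),
                          centroid_x = numeric(), centroid_y = numeric(),
                          equivalent_diameter_px = numeric()))
  }
  idx <- which(comp > 0, arr.ind = TRUE)
  labels <- comp[comp > 0]
  out <- tibble::tibble(lab = labels,
                        row = idx[, 1], col = idx[, 2]) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(area_px = dplyr::n(),
                     centroid_x = mean(.data$col),
                     centroid_y = mean(.data$row), .groups = "drop") |>
    dplyr::filter(.data$area_px >= min_area_px) |>
    dplyr::arrange(dplyr::desc(.data$area_px), .data$centroid_y)
  out |>
    dplyr::mutate(object_id = dplyr::row_number(),
                  equivalent_diameter_px = 2 * sqrt(.data$area_px / pi)) |>
    dplyr::select("object_id", "area_px", "centroid_x", "centroid_y",
                  "equivalent_diameter_px")
}

# 8-connected component labelling of a logical matrix (stack-based flood
# fill; adequate for soma-scale phantoms).
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  current <- 0L
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  todo <- which(mask)
  for (start in todo) {
    if (comp[start] != 0L) next
    current <- current + 1L
    stack_ <- start
    comp[start] <- current
    while (length(stack_) > 0) {
      p <- stack_[length(stack_)]
      stack_ <- stack_[-length(stack_)]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(offsets))) {
        rr <- r + offsets$dr[k]
        cc <- c + offsets$dc[k]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && comp[q] == 0L) {
            comp[q] <- current
            stack_ <- c(stack_, q)
          }
        }
      }
    }
  }
  attr(comp, "n") <- current
  comp
}

#' Distributional separability of two signature histograms
#'
#' Two-sample Kolmogorov–Smirnov statistic (maximum ECDF difference over
#' the 256 bins, equivalent to the KS D of the bin-expanded samples) and
#' the overlap coefficient (sum of bin-wise minima of the unit-area
#' histograms). Indistinguishable signatures give D near 0 and overlap
#' near 1.
#'
#' @param hist_a,hist_b [masked_histogram()] results (non-empty).
#' @return A list with `ks_D` and `overlap`.
#' @export
separability <- function(hist_a, hist_b) {
  for (h in list(hist_a, hist_b)) {
    if (isTRUE(attr(h, "empty"))) {
      abort("histograms must be non-empty",
            class = "retcouple_domain_error")
    }
  }
  pa <- hist_a$count / sum(hist_a$count)
  pb <- hist_b$count / sum(hist_b$count)
  list(ks_D = max(abs(cumsum(pa) - cumsum(pb))),
       overlap = sum(pmin(pa, pb)))
}

#' Read and write single-channel 8-bit images
#'
#' Thin wrappers over the \pkg{png} and \pkg{tiff} packages: images are
#' exchanged as matrices of pixel values in [0, 255].
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_channel()` returns a numeric matrix in [0, 255].
#' @export
read_channel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      rlang::check_installed("png")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      rlang::check_installed("tiff")
      tiff::readTIFF(path)
    },
    abort(paste0("unsupported image format: .", ext),
          class = "retcouple_io_error")
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 255)
}

#' @rdname read_channel
#' @param channel Numeric matrix in [0, 255].
#' @export
write_channel <- function(channel, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(channel / 255, 0), 1)
  switch(ext,
    png = {
      rlang::check_installed("png")
      png::writePNG(img, path)
    },
    tif = ,
    tiff = {
      rlang::check_installed("tiff")
      tiff::writeTIFF(img, path, bits.per.sample = 8)
    },
    abort(paste0("unsupported image format: .", ext),
          class = "retcouple_io_error")
  )
  invisible(path)
}
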