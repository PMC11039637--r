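# Seeded generator of dermoscopy-like images with ground-truth masks.
#
# The generator composes, in order: a lighter textured skin background,
# a darker roughly elliptical lesion with an irregular (low-frequency
# perturbed) border, optional dark curvilinear hair strokes, and then
# impulse (salt-and-pepper) and multiplicative speckle noise on the full
# composite.  Each stage draws from its own derived seed, so the mask is
# a pure function of (geometry seed) and is bit-identical across images
# that differ only in hair or noise settings.

#' Specification of one synthetic lesion image
#'
#' @param height,width image size in pixels (>= 16).
#' @param foreground_fraction target lesion pixel fraction, in (0, 1).
#' @param hair_count number of synthetic hair strokes (>= 0).
#' @param impulse_noise_prob per-pixel salt-and-pepper probability in \[0, 1).
#' @param speckle_variance variance of multiplicative speckle noise (>= 0).
#' @param class_id integer class label; also selects the lesion colour
#'   from a fixed palette so that classes are visually separable.
#' @param seed integer seed; identical specs produce bit-identical images.
#' @return a validated `lesion_spec` object.
#' @examples
#' spec <- lesion_spec(64, 64, foreground_fraction = 0.2, seed = 7)
#' img <- generate_lesion(spec)
#' mean(img$mask)
#' @export
lesion_spec <- function(height = 64L, width = 64L, foreground_fraction = 0.2,
                        hair_count = 0L, impulse_noise_prob = 0,
                        speckle_variance = 0, class_id = 0L, seed = 1L) {
  lf_check(is_count(height, 16), "height", "must be an integer >= 16")
  lf_check(is_count(width, 16), "width", "must be an integer >= 16")
  lf_check(
    is_scalar_num(foreground_fraction) &&
      foreground_fraction > 0 && foreground_fraction < 1,
    "foreground_fraction", "must lie strictly between 0 and 1"
  )
  lf_check(is_count(hair_count, 0), "hair_count", "must be a nonnegative integer")
  lf_check(
    is_prob(impulse_noise_prob) && impulse_noise_prob < 1,
    "impulse_noise_prob", "must be a probability in [0, 1)"
  )
  lf_check(
    is_scalar_num(speckle_variance) && speckle_variance >= 0,
    "speckle_variance", "must be a nonnegative real"
  )
  lf_check(is_count(class_id, 0), "class_id", "must be a nonnegative integer")
  lf_check(is_count(abs(seed), 0), "seed", "must be an integer")
  structure(
    list(
      height = as.integer(height), width = as.integer(width),
      foreground_fraction = foreground_fraction,
      hair_count = as.integer(hair_count),
      impulse_noise_prob = impulse_noise_prob,
      speckle_variance = speckle_variance,
      class_id = as.integer(class_id), seed = as.integer(seed)
    ),
    class = "lesion_spec"
  )
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat(sprintf(
    "lesion_spec: %dx%d, fraction %.3f, hairs %d, impulse %.3f, speckle %.3f, class %d, seed %d\n",
    x$height, x$width, x$foreground_fraction, x$hair_count,
    x$impulse_noise_prob, x$speckle_variance, x$class_id, x$seed
  ))
  invisible(x)
}

# Lesion colour palette indexed by class_id %% 6; all darker than the
# ~(205, 170, 155) skin base so masks are always the darker region.
lesion_palette <- function(class_id) {
  pal <- list(
    c(105, 70, 55),   # dark brown
    c(150, 75, 65),   # reddish
    c(95, 95, 115),   # blue-grey
    c(160, 125, 90),  # light tan
    c(60, 45, 40),    # near-black
    c(165, 95, 110)   # pink
  )
  pal[[(class_id %% 6L) + 1L]]
}

#' Generate one synthetic dermoscopy-like image
#'
#' @param spec a [lesion_spec()].
#' @return a `lesion_image`: list with `pixels` (HxWx3 array in
#'   \[0, 255\]), `mask` (HxW 0/1 matrix, 1 = lesion; hairs and noise are
#'   never recorded in the mask) and `label` (the spec's `class_id`).
#' @export
generate_lesion <- function(spec) {
  if (!inherits(spec, "lesion_spec")) spec <- do.call(lesion_spec, spec)
  h <- spec$height; w <- spec$width

  bg <- with_seed(derive_seed(spec$seed, 1L), synth_background(h, w))
  les <- with_seed(
    derive_seed(spec$seed, 2L),
    synth_lesion_field(h, w, spec$foreground_fraction, spec$class_id)
  )
  alpha <- les$alpha
  col <- lesion_palette(spec$class_id)
  px <- bg
  for (ch in 1:3) {
    px[, , ch] <- bg[, , ch] * (1 - alpha) + (col[ch] + les$texture) * alpha
  }

  if (spec$hair_count > 0) {
    px <- with_seed(
      derive_seed(spec$seed, 3L),
      synth_hairs(px, spec$hair_count)
    )
  }

  px <- with_seed(
    derive_seed(spec$seed, 4L),
    synth_noise(px, spec$impulse_noise_prob, spec$speckle_variance)
  )

  structure(
    list(pixels = clip(px, 0, 255), mask = les$mask, label = spec$class_id),
    class = "lesion_image"
  )
}

#' @export
print.lesion_image <- function(x, ...) {
  cat(sprintf(
    "lesion_image: %dx%d, mask %s (%.1f%% foreground), label %s\n",
    dim(x$pixels)[1], dim(x$pixels)[2],
    if (is.null(x$mask)) "absent" else "present",
    if (is.null(x$mask)) NA_real_ else 100 * mean(x$mask),
    if (is.null(x$label)) "absent" else x$label
  ))
  invisible(x)
}

#' Display a lesion image (and optionally its mask outline)
#'
#' @param x a `lesion_image`.
#' @param show_mask overlay the mask boundary in green.
#' @param ... ignored.
#' @export
plot.lesion_image <- function(x, show_mask = FALSE, ...) {
  px <- x$pixels / 255
  if (show_mask && !is.null(x$mask)) {
    edge <- x$mask - EBImage::erode(x$mask, EBImage::makeBrush(3, "box"))
    px[, , 1][edge > 0] <- 0
    px[, , 2][edge > 0] <- 1
    px[, , 3][edge > 0] <- 0
  }
  op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(px), 0, 0, 1, 1)
  invisible(x)
}

# Low-frequency random field: coarse Gaussian grid bilinearly upscaled.
smooth_field <- function(h, w, coarse = 8L, sd = 1) {
  g <- matrix(rnorm(coarse * coarse, sd = sd), coarse, coarse)
  as.matrix(EBImage::resize(EBImage::Image(g), w = h, h = w, filter = "bilinear"))
}

synth_background <- function(h, w) {
  base <- c(205, 170, 155)
  tex <- smooth_field(h, w, coarse = 8L, sd = 6)
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    px[, , ch] <- base[ch] + tex + matrix(rnorm(h * w, sd = 2), h, w)
  }
  px
}

# Irregular ellipse via radial Fourier perturbation; the scale is found
# by bisection so the mask hits the requested pixel count almost exactly.
synth_lesion_field <- function(h, w, fraction, class_id) {
  cy <- h / 2 + runif(1, -0.08, 0.08) * h
  cx <- w / 2 + runif(1, -0.08, 0.08) * w
  theta <- runif(1, 0, pi)
  aspect <- runif(1, 0.6, 1)
  k <- 2:5
  amp <- runif(4, 0, 0.08)
  phase <- runif(4, 0, 2 * pi)

  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- (-sin(theta) * xx + cos(theta) * yy) / aspect
  rho <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  pert <- 1 + Reduce(`+`, lapply(seq_along(k), function(i) {
    amp[i] * cos(k[i] * phi + phase[i])
  }))

  target <- round(fraction * h * w)
  # normalized radius field: lesion = rho <= s * pert; area monotone in s
  f <- function(s) sum(rho <= s * pert)
  lo <- 0; hi <- max(h, w)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  s <- hi
  mask <- (rho <= s * pert) * 1L
  # soft edge for compositing only; the binary mask is authoritative
  edge_w <- max(1, 0.04 * s)
  alpha <- clip((s * pert - rho) / edge_w + 0.5, 0, 1)
  texture <- smooth_field(h, w, coarse = 6L, sd = 7)
  list(mask = mask, alpha = alpha, texture = texture)
}

# Dark curvilinear strokes from random cubic Bezier curves, width 1-3 px.
synth_hairs <- function(px, n_hairs) {
  h <- dim(px)[1]; w <- dim(px)[2]
  for (i in seq_len(n_hairs)) {
    p <- matrix(c(runif(4, 1, h), runif(4, 1, w)), 4, 2)
    width <- sample(1:3, 1)
    shade <- runif(1, 10, 60)
    t <- seq(0, 1, length.out = 4L * max(h, w))
    b <- outer((1 - t)^3, p[1, ]) + outer(3 * t * (1 - t)^2, p[2, ]) +
      outer(3 * t^2 * (1 - t), p[3, ]) + outer(t^3, p[4, ])
    ys <- round(b[, 1]); xs <- round(b[, 2])
    offs <- expand.grid(
      dy = -(width - 1):(width - 1),
      dx = -(width - 1):(width - 1)
    )
    offs <- offs[offs$dy^2 + offs$dx^2 <= ((width - 1) / 1.2)^2 + 0.1, , drop = FALSE]
    for (j in seq_len(nrow(offs))) {
      y <- ys + offs$dy[j]; x <- xs + offs$dx[j]
      ok <- y >= 1 & y <= h & x >= 1 & x <= w
      idx <- cbind(y[ok], x[ok])
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[idx] <- 0.15 * plane[idx] + 0.85 * shade
        px[, , ch] <- plane
      }
    }
  }
  px
}

synth_noise <- function(px, impulse_prob, speckle_var) {
  h <- dim(px)[1]; w <- dim(px)[2]
  if (speckle_var > 0) {
    mult <- 1 + sqrt(speckle_var) * matrix(rnorm(h * w), h, w)
    for (ch in 1:3) px[, , ch] <- px[, , ch] * mult
  }
  if (impulse_prob > 0) {
    u <- matrix(runif(h * w), h, w)
    pepper <- u < impulse_prob / 2
    salt <- u >= impulse_prob / 2 & u < impulse_prob
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[pepper] <- 0
      plane[salt] <- 255
      px[, , ch] <- plane
    }
  }
  clip(px, 0, 255)
}

#' Generate a dataset of synthetic lesion images
#'
#' Cycles through `specs` (round-robin, so every class is represented)
#' and derives one child seed per image from the master seed.
#'
#' @param n number of images (>= 1).
#' @param specs a single [lesion_spec()] or list of them.
#' @param seed master integer seed.
#' @return list of `lesion_image` objects of length `n`.
#' @export
generate_dataset <- function(n, specs, seed = 1L) {
  lf_check(is_count(n), "n", "must be a positive integer")
  if (inherits(specs, "lesion_spec")) specs <- list(specs)
  lf_check(
    is.list(specs) && length(specs) >= 1 &&
      all(vapply(specs, inherits, TRUE, "lesion_spec")),
    "specs", "must be a nonempty list of lesion_spec objects"
  )
  lapply(seq_len(n), function(i) {
    base <- specs[[((i - 1L) %% length(specs)) + 1L]]
    base$seed <- derive_seed(seed, i)
    generate_lesion(base)
  })
}

#' Write images, masks and a CSV manifest to a directory
#'
#' Writes `<stem>.png` and, when a mask is present, `<stem>_mask.png`
#' for every image, plus `manifest.csv` with columns path, mask_path,
#' label and index.
#'
#' @param images list of `lesion_image` objects.
#' @param dir output directory (created if missing).
#' @param prefix filename stem prefix (default `"img"`).
#' @return invisibly, the manifest data.frame.
#' @export
write_dataset <- function(images, dir, prefix = "img") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(images), function(i) {
    stem <- sprintf("%s%04d", prefix, i)
    path <- file.path(dir, paste0(stem, ".png"))
    png::writePNG(images[[i]]$pixels / 255, path)
    mask_path <- NA_character_
    if (!is.null(images[[i]]$mask)) {
      mask_path <- file.path(dir, paste0(stem, "_mask.png"))
      png::writePNG(images[[i]]$mask * 1.0, mask_path)
    }
    data.frame(
      index = i, path = path, mask_path = mask_path,
      label = images[[i]]$label %||% NA_integer_
    )
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an image (and optional mask) from PNG files
#'
#' @param path PNG image path.
#' @param mask_path optional mask PNG path.
#' @param label optional integer label.
#' @return a `lesion_image`.
#' @export
read_lesion_image <- function(path, mask_path = NULL, label = NULL) {
  px <- png::readPNG(path) * 255
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  mask <- NULL
  if (!is.null(mask_path) && !is.na(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    mask <- (m >= 0.5) * 1L
  }
  structure(list(pixels = px, mask = mask, label = label), class = "lesion_image")
}
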