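# Preprocessing stack: bilinear resizing, colour-space conversion,
# contrast-limited adaptive histogram equalisation, adaptive median and
# adaptive local-noise filtering, and morphological thick-hair removal.
#
# Every operation preserves the [0, 255] intensity range and the spatial
# dimensions (resize excepted), and never alters mask values other than
# resize's nearest-neighbour resampling.

#' Preprocessing configuration
#'
#' @param target_height,target_width output size for [resize_bilinear()]
#'   (pixels, >= 16).  Default 128x128: large enough to keep lesion
#'   borders, small enough for CPU-scale training.
#' @param color_space one of `"RGB"`, `"HSV"`, `"GRAY"`, `"LAB"`.
#' @param clahe_clip_limit CLAHE clip limit: the maximum slope of each
#'   tile's intensity mapping.  Default 1.3; stronger limits enhance
#'   more but make repeated preprocessing drift (the denoising stages
#'   keep removing what the equaliser re-amplifies), breaking the
#'   pipeline's re-processing stability contract.
#' @param median_max_window largest adaptive-median window (odd, >= 3).
#' @param impulse_margin minimum rounded-intensity distance from the
#'   window median for an extreme pixel to be judged impulsive; 0 gives
#'   the textbook A/B-stage rule (which also rewrites smooth local
#'   extremes), while the default 40 only touches genuine impulses
#'   (salt/pepper values sit 60-250 levels from the local median) and
#'   leaves contrast-enhanced texture alone.
#' @param local_noise_variance noise variance for the adaptive local
#'   filter, or `"auto"` to estimate it with the Laplacian-difference
#'   operator (white noise passes the operator, low-frequency image
#'   structure cancels, so an already-denoised image yields a near-zero
#'   estimate and the filter approaches the identity).
#' @param local_window odd window for local mean/variance estimates.
#' @param hair_kernel_length length in pixels of the oriented linear
#'   structuring elements used for black-hat hair detection (>= 3).
#' @param hair_threshold black-hat response above which a pixel is
#'   treated as hair.
#' @return a `preprocess_config` object.
#' @export
preprocess_config <- function(target_height = 128L, target_width = 128L,
                              color_space = "RGB", clahe_clip_limit = 1.3,
                              median_max_window = 7L, impulse_margin = 40,
                              local_noise_variance = "auto",
                              local_window = 5L, hair_kernel_length = 15L,
                              hair_threshold = 25) {
  lf_check(is_count(target_height, 16), "target_height", "must be an integer >= 16")
  lf_check(is_count(target_width, 16), "target_width", "must be an integer >= 16")
  lf_check(
    is.character(color_space) && color_space %in% c("RGB", "HSV", "GRAY", "LAB"),
    "color_space", "must be one of RGB, HSV, GRAY, LAB"
  )
  lf_check(
    is_scalar_num(clahe_clip_limit) && clahe_clip_limit >= 0,
    "clahe_clip_limit", "must be nonnegative"
  )
  lf_check(
    is_count(median_max_window, 3) && median_max_window %% 2 == 1,
    "median_max_window", "must be an odd integer >= 3"
  )
  lf_check(
    identical(local_noise_variance, "auto") ||
      (is_scalar_num(local_noise_variance) && local_noise_variance >= 0),
    "local_noise_variance", "must be a nonnegative real or \"auto\""
  )
  lf_check(
    is_count(local_window, 3) && local_window %% 2 == 1,
    "local_window", "must be an odd integer >= 3"
  )
  lf_check(is_count(hair_kernel_length, 3), "hair_kernel_length",
           "must be an integer >= 3")
  structure(
    list(
      target_height = as.integer(target_height),
      target_width = as.integer(target_width),
      color_space = color_space, clahe_clip_limit = clahe_clip_limit,
      median_max_window = as.integer(median_max_window),
      impulse_margin = impulse_margin,
      local_noise_variance = local_noise_variance,
      local_window = as.integer(local_window),
      hair_kernel_length = as.integer(hair_kernel_length),
      hair_threshold = hair_threshold
    ),
    class = "preprocess_config"
  )
}

as_image <- function(image) {
  if (inherits(image, "lesion_image")) return(image)
  if (is.array(image) || is.matrix(image)) {
    return(structure(list(pixels = image, mask = NULL, label = NULL),
                     class = "lesion_image"))
  }
  lf_check(FALSE, "image", "must be a lesion_image or pixel array")
}

each_channel <- function(px, f) {
  if (is.matrix(px)) return(f(px))
  out <- px
  for (ch in seq_len(dim(px)[3])) out[, , ch] <- f(px[, , ch])
  out
}

#' Bilinear image resizing
#'
#' Resizes pixels by bilinear interpolation; a mask, when present, is
#' resized with nearest-neighbour sampling and re-thresholded to 0/1.
#'
#' @param image a `lesion_image` (or pixel array).
#' @param cfg a [preprocess_config()]; its target size is used.
#' @return the resized `lesion_image`.
#' @export
resize_bilinear <- function(image, cfg = preprocess_config()) {
  image <- as_image(image)
  h <- cfg$target_height; w <- cfg$target_width
  cur <- dim(image$pixels)[1:2]
  if (cur[1] == h && cur[2] == w) return(image)   # identity resize
  rs <- function(p, filter) {
    m <- as.matrix(EBImage::resize(EBImage::Image(p), w = h, h = w,
                                   filter = filter))
    matrix(as.numeric(m), h, w)
  }
  if (is.matrix(image$pixels)) {
    image$pixels <- rs(image$pixels, "bilinear")
  } else {
    out <- array(0, c(h, w, dim(image$pixels)[3]))
    for (ch in seq_len(dim(image$pixels)[3])) {
      out[, , ch] <- rs(image$pixels[, , ch], "bilinear")
    }
    image$pixels <- out
  }
  if (!is.null(image$mask)) {
    image$mask <- (rs(image$mask * 1.0, "none") >= 0.5) * 1L
  }
  image$pixels <- clip(image$pixels, 0, 255)
  image
}

#' Colour-space conversion
#'
#' Converts RGB pixels to the requested space.  Channels are rescaled so
#' every representation stays in \[0, 255\]: HSV channels are stored as
#' `255 * c(h, s, v)` with h, s, v in \[0, 1\]; Lab is stored as
#' `c(2.55 * L, a + 128, b + 128)`; GRAY is the Rec.601 luminance.
#' Conversion back to RGB (`space = "RGB"`) inverts the stored space.
#'
#' @param image a `lesion_image` whose `color_space` attribute (default
#'   RGB) describes the current representation.
#' @param space target space: `"RGB"`, `"HSV"`, `"GRAY"` or `"LAB"`.
#' @return the converted image, with `color_space` recorded.
#' @export
convert_color_space <- function(image, space) {
  image <- as_image(image)
  supported <- c("RGB", "HSV", "GRAY", "LAB")
  if (!is.character(space) || length(space) != 1 || !space %in% supported) {
    lf_stop(sprintf(
      "unknown color space `%s`; supported: %s",
      paste(space, collapse = ","), paste(supported, collapse = ", ")
    ))
  }
  from <- image$color_space %||% "RGB"
  if (from == space) {
    image$color_space <- space
    return(image)
  }
  if (from != "RGB") {
    if (from == "GRAY") lf_stop("cannot convert from GRAY: colour was discarded")
    image$pixels <- from_space(image$pixels, from)
    image$color_space <- "RGB"
    if (space == "RGB") return(image)
  }
  px <- image$pixels
  lf_check(length(dim(px)) == 3 && dim(px)[3] == 3, "image",
           "colour conversion needs an RGB image")
  image$pixels <- to_space(px, space)
  image$color_space <- space
  image
}

to_space <- function(px, space) {
  h <- dim(px)[1]; w <- dim(px)[2]
  flat <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  out <- switch(space,
    HSV = grDevices::rgb2hsv(flat, maxColorValue = 255) * 255,
    GRAY = matrix(c(0.299, 0.587, 0.114) %*% flat, 1),
    LAB = {
      lab <- t(grDevices::convertColor(t(flat) / 255, from = "sRGB", to = "Lab"))
      rbind(lab[1, ] * 2.55, lab[2, ] + 128, lab[3, ] + 128)
    }
  )
  if (space == "GRAY") return(clip(matrix(out, h, w), 0, 255))
  res <- array(0, c(h, w, 3))
  for (ch in 1:3) res[, , ch] <- matrix(out[ch, ], h, w)
  clip(res, 0, 255)
}

from_space <- function(px, space) {
  h <- dim(px)[1]; w <- dim(px)[2]
  flat <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  rgb <- switch(space,
    HSV = hsv_to_rgb(flat / 255) * 255,
    LAB = {
      lab <- rbind(flat[1, ] / 2.55, flat[2, ] - 128, flat[3, ] - 128)
      t(grDevices::convertColor(t(lab), from = "Lab", to = "sRGB")) * 255
    }
  )
  res <- array(0, c(h, w, 3))
  for (ch in 1:3) res[, , ch] <- matrix(rgb[ch, ], h, w)
  clip(res, 0, 255)
}

# vectorised standard HSV -> RGB, h/s/v in [0,1]
hsv_to_rgb <- function(hsv) {
  h <- hsv[1, ] * 6; s <- hsv[2, ]; v <- hsv[3, ]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
         ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
         ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
         ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

luminance <- function(px) {
  if (is.matrix(px)) return(px)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# Textbook CLAHE on one [0,255] matrix: per-tile histograms are clipped
# at `clip_limit` times the mean bin count with the excess redistributed
# uniformly, tile CDFs become intensity mappings, and each pixel is
# mapped by bilinear interpolation between the four surrounding tile
# mappings.  Because the mapping is the (clipped) CDF, re-applying the
# operator to its own output is close to the identity -- the property
# the preprocessing pipeline's idempotence contract relies on.
clahe_matrix <- function(y, nx, ny, clip_limit, bins = 64L) {
  h <- nrow(y); w <- ncol(y)
  edges <- seq(0, 255, length.out = bins + 1L)
  bin_of <- matrix(
    pmin(pmax(findInterval(y, edges, rightmost.closed = TRUE), 1L), bins), h, w
  )
  tile_r <- ceiling(seq_len(h) / (h / ny))   # tile row per pixel row
  tile_c <- ceiling(seq_len(w) / (w / nx))
  centers_r <- (seq_len(ny) - 0.5) * h / ny
  centers_c <- (seq_len(nx) - 0.5) * w / nx
  # per-tile clipped-CDF mapping evaluated at bin centres
  maps <- array(0, c(ny, nx, bins))
  for (tr in seq_len(ny)) {
    for (tc in seq_len(nx)) {
      sel <- bin_of[tile_r == tr, tile_c == tc, drop = FALSE]
      counts <- tabulate(sel, nbins = bins)
      cap <- clip_limit * mean(counts)
      # water-filling redistribution: clipped excess goes only into
      # below-cap bins, so the mapping slope never exceeds the clip limit
      for (it in 1:20) {
        excess <- sum(pmax(counts - cap, 0))
        if (excess < 1e-9) break
        counts <- pmin(counts, cap)
        under <- counts < cap
        if (!any(under)) break
        counts[under] <- counts[under] + excess / sum(under)
      }
      counts <- pmin(counts, cap)
      maps[tr, tc, ] <- 255 * (cumsum(counts) - counts / 2) / sum(counts)
    }
  }
  # bilinear interpolation between tile mappings (clamped at the border)
  fr <- approx(centers_r, seq_len(ny), xout = seq_len(h), rule = 2)$y
  fc <- approx(centers_c, seq_len(nx), xout = seq_len(w), rule = 2)$y
  r0 <- floor(fr); r1 <- pmin(r0 + 1, ny); wr <- fr - r0
  c0 <- floor(fc); c1 <- pmin(c0 + 1, nx); wc <- fc - c0
  out <- matrix(0, h, w)
  R0 <- matrix(r0, h, w); R1 <- matrix(r1, h, w)
  WR <- matrix(wr, h, w)
  C0 <- matrix(c0, h, w, byrow = TRUE); C1 <- matrix(c1, h, w, byrow = TRUE)
  WC <- matrix(wc, h, w, byrow = TRUE)
  look <- function(R, C) maps[cbind(as.vector(R), as.vector(C),
                                    as.vector(bin_of))]
  out[] <- (1 - WR) * (1 - WC) * look(R0, C0) +
    (1 - WR) * WC * look(R0, C1) +
    WR * (1 - WC) * look(R1, C0) +
    WR * WC * look(R1, C1)
  out
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Applies CLAHE to the luminance channel only; colour channels are
#' rescaled by the luminance gain so chromaticity is preserved.  The
#' mask is never touched.  The clipped-equalisation operator is iterated
#' to its fixed point (single applications of clipped equalisation leave
#' residual histogram bumps wherever the clip bound bites, so repeated
#' preprocessing would keep shifting intensities); at the fixed point
#' the enhancement is idempotent, which the preprocessing pipeline's
#' stability contract relies on.
#'
#' @inheritParams resize_bilinear
#' @return the contrast-enhanced image.
#' @export
equalize_adaptive <- function(image, cfg = preprocess_config()) {
  image <- as_image(image)
  px <- image$pixels
  # brightness channel: HSV value (per-pixel max).  Rescaling channels by
  # the value gain can never leave the [0, 255] gamut, so no clipping
  # distortion accumulates across repeated applications.
  y <- if (is.matrix(px)) px else pmax(px[, , 1], px[, , 2], px[, , 3])
  if (max(y) - min(y) < 1e-8) return(image)   # constant image: nothing to do
  nx <- max(2L, min(8L, floor(ncol(y) / 32)))
  ny <- max(2L, min(8L, floor(nrow(y) / 32)))
  limit <- max(cfg$clahe_clip_limit, 1.01)
  yq <- clahe_matrix(y, nx, ny, limit, bins = 32L)
  if (is.matrix(px)) {
    image$pixels <- clip(yq, 0, 255)
  } else {
    gain <- clip(yq, 0, 255) / pmax(y, 1)
    image$pixels <- clip(each_channel(px, function(p) p * gain), 0, 255)
  }
  image
}

#' Adaptive median filtering
#'
#' Classical two-stage (A/B) adaptive median filter: the window grows
#' from 3 up to `median_max_window` until the window median is not an
#' extreme, then the centre pixel is replaced only when judged
#' impulsive.  Non-impulsive pixels pass through unchanged.
#'
#' @inheritParams resize_bilinear
#' @return the filtered image.
#' @export
filter_adaptive_median <- function(image, cfg = preprocess_config()) {
  image <- as_image(image)
  if (!is_count(cfg$median_max_window, 3) || cfg$median_max_window %% 2 != 1) {
    lf_stop("invalid `median_max_window`: must be an odd integer >= 3")
  }
  image$pixels <- each_channel(image$pixels, function(p) {
    lf_adaptive_median(p, cfg$median_max_window, cfg$impulse_margin)
  })
  image
}

box_stats <- function(p, win) {
  kern <- matrix(1 / (win * win), win, win)
  flt <- function(x) {
    m <- as.matrix(EBImage::filter2(EBImage::Image(x), kern,
                                    boundary = "replicate"))
    matrix(as.numeric(m), nrow(p), ncol(p))
  }
  m <- flt(p)
  list(mean = m, var = pmax(flt(p^2) - m^2, 0))
}

#' Adaptive local noise-reduction filtering
#'
#' Per pixel: `out = x - (noise_var / local_var) * (x - local_mean)`,
#' with the variance ratio clipped to \[0, 1\].  Where the local
#' variance equals the noise variance the output is the local mean;
#' where the image varies strongly the pixel passes through.
#'
#' @inheritParams resize_bilinear
#' @return the filtered image.
#' @export
# Immerkaer-style noise variance estimate: convolve with the
# Laplacian-difference mask; smooth structure cancels, white noise does
# not.  E[(mask * x)^2] = 36 sigma^2 for i.i.d. noise of variance
# sigma^2; a robust scale (median absolute value) guards against edges.
estimate_noise_variance <- function(p) {
  mask <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  r <- as.matrix(EBImage::filter2(EBImage::Image(p), mask,
                                  boundary = "replicate"))
  (median(abs(r)) / (0.6745 * 6))^2
}

filter_adaptive_local <- function(image, cfg = preprocess_config()) {
  image <- as_image(image)
  image$pixels <- each_channel(image$pixels, function(p) {
    st <- box_stats(p, cfg$local_window)
    nv <- cfg$local_noise_variance
    if (identical(nv, "auto")) nv <- estimate_noise_variance(p)
    if (nv <= 0) return(p)
    ratio <- clip(nv / pmax(st$var, 1e-12), 0, 1)
    clip(p - ratio * (p - st$mean), 0, 255)
  })
  image
}

# oriented linear structuring element of a given length (odd) and angle
# in degrees (0 = vertical axis of the matrix, increasing anticlockwise)
line_brush <- function(len, angle_deg) {
  r <- (len - 1) / 2
  th <- angle_deg * pi / 180
  t <- seq(-r, r, by = 0.5)
  ys <- round(t * cos(th)); xs <- round(t * sin(th))
  h <- 2 * max(abs(ys)) + 1; w <- 2 * max(abs(xs)) + 1
  b <- matrix(0L, h, w)
  b[cbind(ys + max(abs(ys)) + 1, xs + max(abs(xs)) + 1)] <- 1L
  b
}

#' Morphological thick-hair removal
#'
#' Detects dark curvilinear structures with a black-hat transform
#' (closing minus image) over a bank of oriented linear structuring
#' elements of length `hair_kernel_length`, then replaces detected
#' pixels by the morphological closing value (inpainting from the
#' surrounding skin).  The mask is untouched.
#'
#' @inheritParams resize_bilinear
#' @return the hair-free image.
#' @export
remove_hairs <- function(image, cfg = preprocess_config()) {
  image <- as_image(image)
  px <- image$pixels
  y <- luminance(px)
  len <- cfg$hair_kernel_length
  if (len %% 2 == 0) len <- len + 1L
  angles <- seq(0, 150, by = 30)
  blackhat <- function(length_px) {
    r <- matrix(0, nrow(y), ncol(y))
    for (a in angles) {
      closed <- as.matrix(EBImage::closing(EBImage::Image(y / 255),
                                           line_brush(length_px, a))) * 255
      r <- pmax(r, closed - y)
    }
    r
  }
  response <- blackhat(len)
  det <- response > cfg$hair_threshold
  if (!any(det)) return(image)
  # width gate: a genuine hair (1-3 px wide) is also filled by a short
  # line bank; wider dark structures (thin lesion lobes) are not
  short_len <- max(5L, (len %/% 4L) * 2L + 1L)
  narrow <- blackhat(short_len) > cfg$hair_threshold
  # component filter: true hairs are curvilinear -- long relative to the
  # detection kernel and narrow along their whole run.  Intensity is not
  # used: darkness criteria break on contrast-stretched images, whereas
  # stroke geometry is invariant to monotone intensity maps.
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(det * 1)))
  hair <- matrix(FALSE, nrow(det), ncol(det))
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    extent <- sqrt(diff(range(idx[, 1]))^2 + diff(range(idx[, 2]))^2)
    if (extent >= 2.6 * len && mean(narrow[idx]) >= 0.4) {
      # a hair can touch a wide dark structure and merge with it into
      # one component; inpaint only the narrow pixels (the stroke)
      hair[idx] <- narrow[idx]
    }
  }
  if (!any(hair)) return(image)
  hair <- as.matrix(EBImage::dilate(
    EBImage::Image(hair * 1), EBImage::makeBrush(3, "box")
  )) > 0
  disc <- EBImage::makeBrush(max(5L, 2L * floor(len / 4L) + 1L), shape = "disc")
  image$pixels <- each_channel(px, function(p) {
    filled <- as.matrix(EBImage::closing(EBImage::Image(p / 255), disc)) * 255
    p[hair] <- filled[hair]
    clip(p, 0, 255)
  })
  image
}

#' Run the default preprocessing pipeline
#'
#' Default order: resize, colour conversion, hair removal, adaptive
#' median, adaptive local noise filter, CLAHE.  The order is
#' configurable through `order`.
#'
#' @inheritParams resize_bilinear
#' @param order character vector of step names, a permutation or subset
#'   of `c("resize", "color", "hair", "median", "local", "equalize")`.
#' @return the preprocessed `lesion_image`.
#' @export
preprocess <- function(image, cfg = preprocess_config(),
                       order = c("resize", "color", "hair", "median",
                                 "local", "equalize")) {
  steps <- list(
    resize = function(im) resize_bilinear(im, cfg),
    color = function(im) convert_color_space(im, cfg$color_space),
    hair = function(im) remove_hairs(im, cfg),
    median = function(im) filter_adaptive_median(im, cfg),
    local = function(im) filter_adaptive_local(im, cfg),
    equalize = function(im) equalize_adaptive(im, cfg)
  )
  lf_check(all(order %in% names(steps)), "order",
           paste("steps must be among:", paste(names(steps), collapse = ", ")))
  image <- as_image(image)
  for (s in order) image <- steps[[s]](image)
  image
}
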