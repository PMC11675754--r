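# Synthetic panoramic-radiograph fixtures.
#
# Generates paired radiograph-like images and binary tooth masks plus a
# 10-category manifest emulating the structure of the public UFBA-UESC
# panoramic collection: two dental arches of up to 16 teeth each, optional
# missing teeth, bright restoration blobs, dental-appliance bands, low
# contrast and additive noise.  Teeth are rendered as rounded trapezoids
# with root prongs along two parabolic arches; adjacent teeth may overlap
# slightly, mimicking anatomical overlap.

#' Scene configuration for one synthetic radiograph
#'
#' @param seed integer; identical configurations render bit-identically.
#' @param size square image side in pixels (>= 64).
#' @param teeth_upper,teeth_lower tooth counts per arch, 0-16.
#' @param missing integer indices (1-16 upper, 17-32 lower) of teeth removed
#'   from the rendered set.
#' @param restoration draw a small high-intensity blob inside a random
#'   tooth (image only; the mask is unaffected).
#' @param appliance draw a horizontal high-intensity band across the bite
#'   line (image only).
#' @param noise_sd additive Gaussian noise level in `[0, 0.2]`.
#' @param contrast gamma-like compression factor in `(0, 1]`; 1 = identity.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(seed = 0L, size = 512L, teeth_upper = 16L,
                         teeth_lower = 16L, missing = integer(),
                         restoration = FALSE, appliance = FALSE,
                         noise_sd = 0.05, contrast = 0.9) {
  if (size < 64) stop("size below 64 px is unrenderable", call. = FALSE)
  if (teeth_upper < 0 || teeth_upper > 16 || teeth_lower < 0 ||
      teeth_lower > 16)
    stop("teeth counts must lie in 0..16", call. = FALSE)
  if (noise_sd < 0 || noise_sd > 0.2)
    stop("noise_sd must lie in [0, 0.2]", call. = FALSE)
  if (contrast <= 0 || contrast > 1)
    stop("contrast must lie in (0, 1]", call. = FALSE)
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 teeth_upper = as.integer(teeth_upper),
                 teeth_lower = as.integer(teeth_lower),
                 missing = as.integer(missing),
                 restoration = isTRUE(restoration),
                 appliance = isTRUE(appliance),
                 noise_sd = noise_sd, contrast = contrast),
            class = "scene_config")
}

#' Contrast compression and additive noise
#'
#' Applies the gamma-like map `x^contrast` followed by additive Gaussian
#' noise, clipped to `[0, 1]`.  `noise_sd = 0, contrast = 1` is the
#' identity.  Noise uses the current RNG state.
#'
#' @param image numeric array with values in `[0, 1]`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param contrast factor in `(0, 1]`.
#' @return degraded array, same shape, clipped to `[0, 1]`.
#' @export
degrade <- function(image, noise_sd, contrast) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (contrast <= 0 || contrast > 1)
    stop("contrast must lie in (0, 1]", call. = FALSE)
  out <- image^contrast
  if (noise_sd > 0)
    out <- out + stats::rnorm(length(out), sd = noise_sd)
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

# Render one tooth into mask/intensity layers (in place via returned list).
render_tooth <- function(mask, tooth, S, cx, cy, ang, hw, cl, rl, prongs,
                         bright, layer) {
  # local frame: v along the tooth axis (towards the crown tip), u across
  reach <- (cl + rl) * 1.3 + 2 * hw
  x0 <- max(1L, floor((cx - reach) * S)); x1 <- min(S, ceiling((cx + reach) * S))
  y0 <- max(1L, floor((cy - reach) * S)); y1 <- min(S, ceiling((cy + reach) * S))
  if (x0 > x1 || y0 > y1) return(list(mask = mask, layer = layer))
  px <- (seq(x0, x1) - 0.5) / S - cx
  py <- (seq(y0, y1) - 0.5) / S - cy
  # grid: rows = y (image rows), cols = x
  U <- outer(py, px, function(yy, xx) -sin(ang) * xx + cos(ang) * yy)
  V <- outer(py, px, function(yy, xx) cos(ang) * xx + sin(ang) * yy)
  wv <- hw * (1 - 0.30 * pmax(0, pmin(1, V / cl)))
  crown <- V >= 0 & V <= cl & abs(U) <= wv
  tipc <- V > cl & ((V - cl) / (0.45 * hw))^2 + (U / (0.7 * hw))^2 <= 1
  inside <- crown | tipc
  taper <- 1 + 0.65 * pmax(-1, pmin(0, V / rl))
  if (prongs == 2L) {
    root <- V < 0 & V >= -rl &
      (abs(U - 0.52 * hw) <= 0.30 * hw * taper |
       abs(U + 0.52 * hw) <= 0.30 * hw * taper)
  } else {
    root <- V < 0 & V >= -rl & abs(U) <= 0.42 * hw * taper
  }
  inside <- inside | root
  if (any(inside)) {
    sub <- mask[y0:y1, x0:x1]
    sub[inside] <- 1L
    mask[y0:y1, x0:x1] <- sub
    lay <- layer[y0:y1, x0:x1]
    lay[inside] <- pmax(lay[inside], bright)
    layer[y0:y1, x0:x1] <- lay
  }
  list(mask = mask, layer = layer)
}

# Arch geometry: position and axis angle for tooth slot i of n on one arch.
arch_point <- function(i, n, upper) {
  t <- (i - 0.5) / n
  x <- 0.13 + 0.74 * t
  dev <- (2 * t - 1)
  # both arches follow the upward-curving bite line of a panoramic view
  if (upper) {
    y <- 0.42 - 0.15 * dev^2
    dydx <- -0.30 * dev * 2 / 0.74
    ang <- pi / 2 + 0.5 * atan(dydx)      # axis points down (towards +y)
  } else {
    y <- 0.71 - 0.13 * dev^2
    dydx <- -0.26 * dev * 2 / 0.74
    ang <- -pi / 2 - 0.5 * atan(dydx)     # axis points up
  }
  list(x = x, y = y, ang = ang)
}

#' Render one synthetic radiograph and its tooth mask
#'
#' Deterministic in `config$seed`.  The mask is the union of the rendered
#' tooth shapes only; restoration blobs and appliance bands brighten the
#' image but never enter the mask.
#'
#' @param config a [scene_config()].
#' @return list with `image` (array `(S, S, 3, 1)`, values in `[0, 1]`) and
#'   `mask` (integer array `(S, S, 1)`, values in `{0, 1}`).
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  S <- config$size
  with_seed(config$seed, {
    mask <- matrix(0L, S, S)
    layer <- matrix(0, S, S)
    # draw all random quantities up front so that toggling the appliance /
    # restoration flags never shifts the RNG stream (mask invariance)
    jit <- matrix(stats::rnorm(32 * 4, sd = 1), 32, 4)
    resto_pick <- stats::runif(1)
    resto_off <- stats::runif(2, -0.3, 0.3)
    appl_y <- 0.5 + stats::runif(1, -0.015, 0.015)
    bggrid_n <- floor(S / 16) + 2L
    bggrid <- matrix(stats::rnorm(bggrid_n^2, sd = 1), bggrid_n, bggrid_n)

    present <- logical(32)
    present[seq_len(config$teeth_upper)] <- TRUE
    present[16L + seq_len(config$teeth_lower)] <- TRUE
    present[config$missing[config$missing >= 1 & config$missing <= 32]] <- FALSE
    slots <- vector("list", 32)
    for (i in which(present)) {
      upper <- i <= 16
      slot <- if (upper) i else i - 16L
      n <- if (upper) max(config$teeth_upper, 1L) else
        max(config$teeth_lower, 1L)
      ap <- arch_point(slot, n, upper)
      molar <- abs((slot - 0.5) / n - 0.5) > 0.28
      hw <- (0.020 + 0.006 * molar) * (1 + 0.10 * jit[i, 1])
      cl <- 0.085 * (1 + 0.10 * jit[i, 2])
      rl <- 0.065 * (1 + 0.12 * jit[i, 3])
      bright <- 0.58 + 0.06 * jit[i, 4] / 2
      r <- render_tooth(mask, i, S, ap$x, ap$y,
                        ap$ang + 0.06 * jit[i, 4], hw, cl, rl,
                        prongs = if (molar) 2L else 1L,
                        bright = min(0.72, max(0.5, bright)), layer = layer)
      mask <- r$mask; layer <- r$layer
      slots[[i]] <- list(ap = ap, hw = hw, cl = cl)
    }

    # background: vertical gradient + jaw band + low-frequency texture
    yy <- (seq_len(S) - 0.5) / S
    bg <- matrix(0.16 + 0.08 * yy, S, S) +
      matrix(0.10 * exp(-((yy - 0.5) / 0.23)^2), S, S)
    gi <- pmin(bggrid_n, floor((seq_len(S) - 0.5) / 16) + 1L)
    bg <- bg + 0.04 * bggrid[gi, gi]
    img <- pmax(bg, layer)

    if (config$restoration) {
      cand <- which(present)
      if (length(cand) > 0) {
        pick <- cand[1L + floor(resto_pick * 0.999 * length(cand))]
        sl <- slots[[pick]]
        ang <- sl$ap$ang
        cx <- sl$ap$x + cos(ang) * sl$cl * (0.5 + 0.2 * resto_off[1])
        cy <- sl$ap$y + sin(ang) * sl$cl * (0.5 + 0.2 * resto_off[2])
        rr <- 0.45 * sl$hw
        xs <- (seq_len(S) - 0.5) / S
        D2 <- outer((xs - cy)^2, (xs - cx)^2, "+")
        img[D2 <= rr^2] <- 0.95
      }
    }
    if (config$appliance) {
      rows <- which(abs(yy - appl_y) <= 0.012)
      img[rows, ] <- pmax(img[rows, ], 0.90)
    }

    img <- degrade(img, config$noise_sd, config$contrast)
    image <- array(0, c(S, S, 3, 1))
    for (ch in 1:3) image[, , ch, 1] <- img
    list(image = image, mask = array(mask, c(S, S, 1)))
  })
}

#' Category attribute grid of the emulated dataset structure
#'
#' Ten categories over the attribute flags (32 teeth / restoration /
#' dental appliance), with the published per-category image counts and the
#' used-image quotas of the 425-image selection.
#'
#' @return data.frame with columns category, teeth32, restoration,
#'   appliance, images, used_images.
#' @export
category_attributes <- function() {
  data.frame(
    category = 1:10,
    teeth32 = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                FALSE, FALSE),
    restoration = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                    FALSE, FALSE),
    appliance = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE,
                  FALSE, FALSE),
    images = c(73L, 220L, 45L, 140L, 120L, 170L, 115L, 457L, 45L, 115L),
    used_images = c(24L, 72L, 15L, 32L, 37L, 30L, 33L, 140L, 7L, 35L))
}

#' @rdname category_attributes
#' @export
default_category_quotas <- function() {
  stats::setNames(category_attributes()$used_images, 1:10)
}

#' Generate a fixture dataset with a category manifest
#'
#' Writes one image/mask PNG pair per manifest row and `manifest.csv` with
#' columns `image_id, category, teeth32, restoration, appliance, split`.
#' Quotas are honored exactly; categories without the 32-teeth flag get a
#' random number of missing teeth.  Splits are assigned deterministically
#' within each category (70/15/15 train/val/test).
#'
#' @param manifest_spec named integer vector of per-category quotas
#'   (names in 1..10); defaults to the published used-image quotas.
#' @param out_dir output directory (created).
#' @param size image side in pixels.
#' @param seed base seed; every scene derives its own from it.
#' @param noise_sd,contrast degradation settings passed to every scene.
#' @return the manifest data.frame (invisibly written to disk as well).
#' @export
make_dataset <- function(manifest_spec = default_category_quotas(), out_dir,
                         size = 512L, seed = 0L, noise_sd = 0.05,
                         contrast = 0.9) {
  quotas <- manifest_spec
  if (is.null(names(quotas))) names(quotas) <- seq_along(quotas)
  cats <- as.integer(names(quotas))
  if (anyNA(cats) || any(cats < 1 | cats > 10))
    stop("quota with unknown category (must be 1..10)", call. = FALSE)
  if (any(quotas < 0)) stop("quotas must be >= 0", call. = FALSE)
  attrs <- category_attributes()
  manifest <- NULL
  total <- sum(quotas)
  if (total > 0) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  }
  for (ci in seq_along(quotas)) {
    cat_ <- cats[ci]; nq <- quotas[ci]
    if (nq == 0) next
    at <- attrs[attrs$category == cat_, ]
    ntr <- ceiling(0.7 * nq); nva <- ceiling(0.15 * nq)
    for (j in seq_len(nq)) {
      sseed <- seed * 100000L + cat_ * 1000L + j
      missing <- integer()
      if (!at$teeth32)
        missing <- with_seed(sseed + 500L,
                             sample.int(32, size = sample(1:6, 1)))
      cfg <- scene_config(seed = sseed, size = size,
                          missing = missing,
                          restoration = at$restoration,
                          appliance = at$appliance,
                          noise_sd = noise_sd, contrast = contrast)
      sc <- make_scene(cfg)
      id <- sprintf("c%02d_%03d", cat_, j)
      png::writePNG(sc$image[, , , 1], file.path(out_dir, "images",
                                                 paste0(id, ".png")))
      png::writePNG(sc$mask[, , 1] * 1.0, file.path(out_dir, "masks",
                                                    paste0(id, ".png")))
      split <- if (j <= ntr) "train" else if (j <= ntr + nva) "val" else
        "test"
      manifest <- rbind(manifest, data.frame(
        image_id = id, category = cat_, teeth32 = at$teeth32,
        restoration = at$restoration, appliance = at$appliance,
        split = split))
    }
  }
  if (is.null(manifest))
    manifest <- data.frame(image_id = character(), category = integer(),
                           teeth32 = logical(), restoration = logical(),
                           appliance = logical(), split = character())
  if (total > 0)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  manifest
}

#' Load a fixture dataset from disk
#'
#' Masks are binarized at > 127/255.
#'
#' @param dir directory written by [make_dataset()].
#' @param ids optional subset of image ids.
#' @return list with `images` `(H, W, 3, N)`, `masks` `(H, W, N)`,
#'   `image_id`, `manifest`.
#' @export
load_dataset <- function(dir, ids = NULL) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  if (is.null(ids)) ids <- manifest$image_id
  n <- length(ids)
  stopifnot(n > 0)
  first <- png::readPNG(file.path(dir, "images", paste0(ids[1], ".png")))
  S <- dim(first)[1]
  images <- array(0, c(S, S, 3, n))
  masks <- array(0L, c(S, S, n))
  for (i in seq_len(n)) {
    im <- png::readPNG(file.path(dir, "images", paste0(ids[i], ".png")))
    if (length(dim(im)) == 2) im <- array(rep(im, 3), c(dim(im), 3))
    images[, , , i] <- im[, , 1:3]
    mk <- png::readPNG(file.path(dir, "masks", paste0(ids[i], ".png")))
    if (length(dim(mk)) == 3) mk <- mk[, , 1]
    masks[, , i] <- (mk > 127 / 255) * 1L
  }
  list(images = images, masks = masks, image_id = ids,
       manifest = manifest[match(ids, manifest$image_id), ])
}

#' In-memory batch of synthetic scenes
#'
#' Convenience wrapper rendering `n` scenes with consecutive seeds into the
#' array layout the training and evaluation functions consume.
#'
#' @param n scene count.
#' @param size image side in pixels.
#' @param seed base seed; scene `i` uses `seed + i`.
#' @param ... further [scene_config()] fields.
#' @return list with `images` `(size, size, 3, n)`, `masks`
#'   `(size, size, n)` and `image_id`.
#' @export
scene_batch <- function(n, size = 128L, seed = 0L, ...) {
  images <- array(0, c(size, size, 3, n))
  masks <- array(0L, c(size, size, n))
  for (i in seq_len(n)) {
    sc <- make_scene(scene_config(seed = seed + i, size = size, ...))
    images[, , , i] <- sc$image[, , , 1]
    masks[, , i] <- sc$mask[, , 1]
  }
  list(images = images, masks = masks,
       image_id = sprintf("s%04d", seq_len(n)))
}
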