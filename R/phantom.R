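#' Parameters of the synthetic corpus-callosum phantom
#'
#' The phantom emulates the features of a cropped midsagittal T1 slice that
#' matter for this method: an arc-shaped bright structure whose thickness
#' varies along its length (genu and splenium thick, body and isthmus thin),
#' a thin same-intensity distractor attached at the posterior-inferior end
#' (the "fornix", the classic false-positive source for intensity-based
#' segmentation), smooth per-subject shape deformation, a multiplicative
#' smooth intensity-inhomogeneity field, and additive Gaussian noise.
#'
#' @param canvas integer (H, W) canvas size in pixels, both >= 32.
#' @param arc_center (row, col) centre of the parametric arc, pixels.
#' @param arc_radii (row-radius, col-radius) of the arc ellipse, pixels.
#' @param arc_span angular span (start, end) in radians; ends dipping below
#'   the horizontal give the genu/splenium hooks.
#' @param thickness_profile numeric vector of half-thicknesses (pixels)
#'   sampled evenly along the arc and spline-interpolated; the default is
#'   thick at both ends and thin in the body.
#' @param deform_amplitude RMS amplitude (pixels) of the smooth random
#'   displacement applied to the arc geometry. The displacement is applied
#'   to the centreline before rasterization, so image and mask stay
#'   perfectly consistent.
#' @param deform_scale correlation length (pixels) of the deformation;
#'   smaller values admit higher spatial frequencies.
#' @param fg_intensity,bg_intensity mean foreground/background intensities
#'   in \[0, 255\]; `fg_intensity > bg_intensity`.
#' @param noise_sd additive Gaussian noise standard deviation, >= 0.
#' @param bias_amplitude fractional amplitude of the multiplicative smooth
#'   inhomogeneity field (0 disables it).
#' @param fornix logical: paint the distractor strip?
#' @param fornix_length length of the strip in pixels.
#' @param fornix_halfwidth half-width of the strip in pixels.
#' @param seed integer RNG seed; generation is a pure function of the
#'   parameters including the seed.
#' @return an object of class `cc_phantom_params` (a validated list).
#' @export
phantom_params <- function(canvas = c(64L, 96L),
                           arc_center = c(30, 48),
                           arc_radii = c(17, 30),
                           arc_span = c(-0.12 * pi, 1.12 * pi),
                           thickness_profile = c(5, 3.2, 2.6, 2.4, 3, 5.5),
                           deform_amplitude = 0.6,
                           deform_scale = 24,
                           fg_intensity = 180,
                           bg_intensity = 110,
                           noise_sd = 12,
                           bias_amplitude = 0.1,
                           fornix = TRUE,
                           fornix_length = 11,
                           fornix_halfwidth = 1,
                           seed = 1L) {
  p <- list(canvas = as.integer(canvas), arc_center = arc_center,
            arc_radii = arc_radii, arc_span = arc_span,
            thickness_profile = thickness_profile,
            deform_amplitude = deform_amplitude, deform_scale = deform_scale,
            fg_intensity = fg_intensity, bg_intensity = bg_intensity,
            noise_sd = noise_sd, bias_amplitude = bias_amplitude,
            fornix = isTRUE(fornix), fornix_length = fornix_length,
            fornix_halfwidth = fornix_halfwidth, seed = as.integer(seed))
  if (any(p$canvas < 32L)) stop_input("canvas dimensions must be >= 32")
  if (p$fg_intensity <= p$bg_intensity)
    stop_input("fg_intensity must exceed bg_intensity")
  if (p$noise_sd < 0 || p$deform_amplitude < 0)
    stop_input("noise_sd and deform_amplitude must be >= 0")
  if (length(p$thickness_profile) < 2L || any(p$thickness_profile <= 0))
    stop_input("thickness_profile must be positive, length >= 2")
  structure(p, class = "cc_phantom_params")
}

## Band-limited random 1D field over u in [0,1]: a few low-frequency Fourier
## terms, rescaled to the requested RMS amplitude. With a fixed RNG stream the
## field is proportional to `amplitude`, so cohorts of increasing amplitude
## share a deformation "direction".
band_limited_field <- function(u, amplitude, n_freq) {
  if (amplitude == 0) {
    stats::rnorm(2 * n_freq)  # keep the draw count fixed for reproducibility
    return(numeric(length(u)))
  }
  g <- numeric(length(u))
  for (k in seq_len(n_freq)) {
    ab <- stats::rnorm(2) / k
    g <- g + ab[1] * sin(2 * pi * k * u) + ab[2] * cos(2 * pi * k * u)
  }
  s <- stats::sd(g)
  if (s > 0) g <- g / s * amplitude
  g
}

## Rasterize a tube: union of disks of per-sample radius h centred on the
## (row, col) samples. Returns a logical H x W matrix.
paint_tube <- function(H, W, rows, cols, half) {
  m <- matrix(FALSE, H, W)
  for (i in seq_along(rows)) {
    h <- half[i]
    r0 <- max(1L, floor(rows[i] - h)); r1 <- min(H, ceiling(rows[i] + h))
    c0 <- max(1L, floor(cols[i] - h)); c1 <- min(W, ceiling(cols[i] + h))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - rows[i])^2, (cc - cols[i])^2, "+")
    m[rr, cc] <- m[rr, cc] | (d2 <= h^2)
  }
  m
}

generate_phantom_once <- function(p, seed) {
  with_seed(seed, {
    H <- p$canvas[1]; W <- p$canvas[2]
    n_samp <- 400L
    u <- seq(0, 1, length.out = n_samp)
    theta <- p$arc_span[1] + u * (p$arc_span[2] - p$arc_span[1])
    rows <- p$arc_center[1] - p$arc_radii[1] * sin(theta)
    cols <- p$arc_center[2] + p$arc_radii[2] * cos(theta)

    ## half-thickness along the arc
    k <- length(p$thickness_profile)
    half <- stats::spline(seq(0, 1, length.out = k), p$thickness_profile,
                          xout = u)$y
    half <- pmax(half, 1.2)

    ## smooth shape deformation of the centreline
    arc_len <- sum(sqrt(diff(rows)^2 + diff(cols)^2))
    n_freq <- max(1L, as.integer(round(arc_len / (2 * p$deform_scale))))
    rows <- rows + band_limited_field(u, p$deform_amplitude, n_freq)
    cols <- cols + band_limited_field(u, p$deform_amplitude, n_freq)

    margin <- half + 1
    if (any(rows - margin < 1) || any(rows + margin > H) ||
        any(cols - margin < 1) || any(cols + margin > W))
      stop_geometry("arc exits the canvas; enlarge it or reduce radii/deformation")

    m <- paint_tube(H, W, rows, cols, half)

    ## fornix: a thin strip at foreground intensity, 4-adjacent to the mask
    ## at the posterior-inferior (splenium) end but labelled background
    fx <- matrix(FALSE, H, W)
    if (p$fornix) {
      end_col <- cols[1L]  # u = 0 end of the arc (posterior)
      cand <- which(m[, clamp(round(end_col) + (-2:2), 1L, W), drop = FALSE],
                    arr.ind = TRUE)
      if (nrow(cand) > 0) {
        anchor_r <- max(cand[, 1])
        anchor_c <- clamp(round(end_col) + (-2:2), 1L, W)[
          cand[which.max(cand[, 1]), 2]]
        dirv <- c(1, -0.35); dirv <- dirv / sqrt(sum(dirv^2))
        tt <- seq(0, p$fornix_length, by = 0.5)
        fr <- anchor_r + 1 + dirv[1] * tt
        fc <- anchor_c + dirv[2] * tt
        keep <- fr >= 1 & fr <= H & fc >= 1 & fc <= W
        fx <- paint_tube(H, W, fr[keep], fc[keep],
                         rep(p$fornix_halfwidth, sum(keep)))
        fx <- fx & !m
      }
    }

    ## image: bias field x two-level painting + noise, clipped to [0, 255]
    base <- matrix(p$bg_intensity, H, W)
    base[m | fx] <- p$fg_intensity
    phase <- stats::runif(2, 0, 2 * pi)
    if (p$bias_amplitude > 0) {
      bias <- 1 + p$bias_amplitude *
        outer(cos(pi * seq_len(H) / H + phase[1]),
              cos(pi * seq_len(W) / W + phase[2]))
      base <- base * bias
    }
    if (p$noise_sd > 0)
      base <- base + matrix(stats::rnorm(H * W, 0, p$noise_sd), H, W)
    img <- clamp(base, 0, 255)

    list(image = img, mask = m, fornix = fx)
  })
}

#' Generate one synthetic phantom atlas
#'
#' Deterministic given the parameters (including the seed). The returned
#' mask is the arc region before noise; the fornix strip is painted at
#' foreground intensity but labelled background. If the rasterized mask is
#' not a single 4-connected, hole-free region the phantom is redrawn with a
#' derived seed (bounded retries).
#'
#' @param p a [phantom_params()] object.
#' @param id atlas identifier (default `"phantom"`).
#' @return a `cc_atlas`; the fornix footprint is attached as attribute
#'   `"fornix"` (logical matrix) for inspection.
#' @export
generate_phantom <- function(p, id = "phantom") {
  if (!inherits(p, "cc_phantom_params")) p <- do.call(phantom_params, p)
  for (attempt in 0:24) {
    seed <- (p$seed + attempt * 10007L) %% .Machine$integer.max
    g <- generate_phantom_once(p, seed)
    if (count_components(g$mask) == 1L && euler_number(g$mask) == 1L) {
      a <- atlas(id, slice(g$image), mask(g$mask))
      attr(a, "fornix") <- g$fornix
      attr(a, "params") <- p
      return(a)
    }
  }
  stop_geometry("could not draw a single-component, hole-free phantom in 25 attempts")
}

#' Generate a cohort of phantoms with jittered geometry
#'
#' Member seeds and geometric jitters are derived deterministically from the
#' master seed, so the cohort is reproducible bit-for-bit. Members are
#' generated "pre-aligned": they share the base arc centre up to jitter,
#' standing in for the output of affine plus non-linear registration.
#'
#' @param n number of members, >= 1.
#' @param base a [phantom_params()] object giving the shared geometry.
#' @param jitter list of jitter standard deviations:
#'   `center_sd` (pixels, both axes), `radii_sd` (pixels),
#'   `thickness_sd` (multiplicative log-scale sd). Zero disables a jitter.
#' @param seed master integer seed.
#' @return an object of class `cc_cohort`: a list with `atlases`
#'   (ids `"phantom_000"` ...) and `params` (per-member parameters).
#' @export
generate_cohort <- function(n, base = phantom_params(),
                            jitter = list(center_sd = 0.4, radii_sd = 0.5,
                                          thickness_sd = 0.04),
                            seed = 1L) {
  if (n < 1L) stop_input("n must be >= 1")
  if (!inherits(base, "cc_phantom_params")) base <- do.call(phantom_params, base)
  jit <- utils::modifyList(list(center_sd = 0, radii_sd = 0, thickness_sd = 0),
                           jitter)
  draws <- with_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, n),
         jc = matrix(stats::rnorm(2 * n, 0, max(jit$center_sd, 1e-12)), n, 2),
         jr = matrix(stats::rnorm(2 * n, 0, max(jit$radii_sd, 1e-12)), n, 2),
         jt = stats::rnorm(n, 0, max(jit$thickness_sd, 1e-12)))
  })
  if (jit$center_sd == 0) draws$jc[] <- 0
  if (jit$radii_sd == 0) draws$jr[] <- 0
  if (jit$thickness_sd == 0) draws$jt[] <- 0
  atlases <- vector("list", n)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- base
    pi$arc_center <- base$arc_center + draws$jc[i, ]
    pi$arc_radii <- pmax(base$arc_radii + draws$jr[i, ], 4)
    pi$thickness_profile <- base$thickness_profile * exp(draws$jt[i])
    pi$seed <- draws$seeds[i]
    id <- sprintf("phantom_%03d", i - 1L)
    atlases[[i]] <- generate_phantom(pi, id = id)
    params[[i]] <- pi
  }
  structure(list(atlases = atlases, params = params, seed = as.integer(seed)),
            class = "cc_cohort")
}

#' @export
print.cc_cohort <- function(x, ...) {
  d <- dim(x$atlases[[1]]$image$pixels)
  cat(sprintf("<cc_cohort of %d phantoms, canvas %d x %d, master seed %d>\n",
              length(x$atlases), d[1], d[2], x$seed))
  invisible(x)
}

#' @export
length.cc_cohort <- function(x) length(x$atlases)
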