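# Synthetic multi-site mammogram-like data: textured optical-density
# backgrounds, parametric masses (shape x margin taxonomy), Freeman
# chain-code annotations and per-scanner digitization.

#' Generate a textured optical-density background
#'
#' Produces `mean_od` plus low-pass-filtered Gaussian noise: white noise is
#' smoothed with a separable Gaussian kernel of standard deviation
#' `texture_scale` pixels (half-width `ceiling(3 * texture_scale)`) and
#' scaled so the marginal standard deviation equals `od_sd`.  The noise
#' field is padded by the kernel half-width before smoothing and cropped
#' afterwards, so the texture is stationary out to the image border.
#'
#' @param height,width Image dimensions in pixels (>= 32).
#' @param texture_scale Gaussian correlation scale of the texture, pixels.
#' @param mean_od Mean background optical density.
#' @param od_sd Marginal standard deviation of the texture, OD units.
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return `height x width` numeric matrix of optical densities.
#' @export
generate_background <- function(height, width, texture_scale = 6, mean_od = 1.8,
                                od_sd = 0.25, seed = NULL) {
  if (height < 32 || width < 32) stop("height and width must be >= 32")
  if (texture_scale <= 0) stop("texture_scale must be positive")
  if (!is.null(seed)) set.seed(seed)
  r <- ceiling(3 * texture_scale)
  noise <- matrix(stats::rnorm((height + 2 * r) * (width + 2 * r)),
                  height + 2 * r, width + 2 * r)
  kr <- gauss_band(height, texture_scale)
  kc <- gauss_band(width, texture_scale)
  sm <- kr %*% noise %*% t(kc)
  # the marginal sd of the separably smoothed stationary field is sum(w^2)
  w <- gauss_weights(texture_scale)
  sm <- sm / sum(w^2)
  mean_od + od_sd * sm
}

# normalized 1-D Gaussian kernel weights, half-width 3 sd
gauss_weights <- function(scale) {
  r <- ceiling(3 * scale)
  w <- stats::dnorm(-r:r, sd = scale)
  w / sum(w)
}

# n x (n + 2r) banded smoothing matrix acting on an r-padded axis
gauss_band <- function(n, scale) {
  r <- ceiling(3 * scale)
  w <- gauss_weights(scale)
  k <- matrix(0, n, n + 2 * r)
  for (i in seq_len(n)) k[i, i:(i + 2 * r)] <- w
  k
}

#' Mass specification
#'
#' Parametric description of one synthetic mass following the standard
#' clinical taxonomy of shape (round, oval, lobulated, irregular) and
#' margin (circumscribed, ill-defined, spiculated).
#'
#' @param shape One of `"round"`, `"oval"`, `"lobulated"`, `"irregular"`.
#' @param margin One of `"circumscribed"`, `"ill_defined"`, `"spiculated"`.
#' @param diameter_px Nominal diameter in pixels (integer > 4).
#' @param contrast Optical-density elevation of the mass core over the
#'   background (> 0, or 0 for a null mass).
#' @param center `(row, col)` of the mass center, 1-based pixel indices.
#' @return An object of class `mass_spec`.
#' @export
mass_spec <- function(shape = c("round", "oval", "lobulated", "irregular"),
                      margin = c("circumscribed", "ill_defined", "spiculated"),
                      diameter_px, contrast, center) {
  shape <- match.arg(shape)
  margin <- match.arg(margin)
  stopifnot(diameter_px > 4, contrast >= 0, length(center) == 2)
  structure(list(shape = shape, margin = margin,
                 diameter_px = as.integer(diameter_px),
                 contrast = contrast, center = as.numeric(center)),
            class = "mass_spec")
}

#' Render a mass onto an optical-density background
#'
#' Adds a radially symmetric raised intensity profile whose boundary radius
#' varies with polar angle according to `shape` and whose falloff is set by
#' `margin`: circumscribed masses have a sharp edge, ill-defined masses a
#' wide ramp extending past the boundary, and spiculated masses a sharp core
#' with additive radial spikes.  The returned mask is the core region
#' (distance <= shape radius), star-shaped about the center and hence
#' 8-connected and simply connected.
#'
#' @param spec A [mass_spec()].
#' @param background Optical-density matrix to draw on.
#' @param seed Integer seed for the shape/spike randomness; `NULL` continues
#'   the current stream.
#' @return List with `image` (background plus mass) and `mask` (logical
#'   matrix).
#' @export
render_mass <- function(spec, background, seed = NULL) {
  stopifnot(inherits(spec, "mass_spec"), is.matrix(background))
  if (!is.null(seed)) set.seed(seed)
  h <- nrow(background); w <- ncol(background)
  R <- spec$diameter_px / 2
  r0 <- spec$center[1]; c0 <- spec$center[2]
  if (r0 - R < 1 || r0 + R > h || c0 - R < 1 || c0 + R > w)
    stop("mass does not fit inside the image")
  dr <- outer(seq_len(h) - r0, rep(1, w))
  dc <- outer(rep(1, h), seq_len(w) - c0)
  dist <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)

  # angular boundary radius r(theta) per shape
  rad <- switch(spec$shape,
    round = rep_len(R, length(theta)),
    oval = {
      phi <- stats::runif(1, 0, pi)
      a <- R; b <- 0.65 * R
      tt <- theta - phi
      (a * b) / sqrt((b * cos(tt))^2 + (a * sin(tt))^2)
    },
    lobulated = {
      k <- sample(3:5, 1); phi <- stats::runif(1, 0, 2 * pi)
      R * (1 + 0.18 * cos(k * theta + phi))
    },
    irregular = {
      ks <- 2:6
      amp <- stats::rnorm(length(ks), 0, 0.12 / sqrt(ks))
      phs <- stats::runif(length(ks), 0, 2 * pi)
      f <- Reduce(`+`, Map(function(k, a, p) a * cos(k * theta + p),
                           ks, amp, phs))
      R * pmin(pmax(1 + f, 0.6), 1.4)
    })
  rad <- matrix(rad, h, w)
  rho <- dist / rad
  mask <- rho <= 1

  # margin-dependent elevation factor of the core
  f <- switch(spec$margin,
    circumscribed = pmin(pmax((1 - rho) / 0.08, 0), 1),
    ill_defined   = pmin(pmax((1.3 - rho) / 0.9, 0), 1),
    spiculated    = pmin(pmax((0.95 - rho) / 0.25, 0), 1))
  if (spec$margin == "spiculated") {
    n_sp <- sample(8:14, 1)
    ang <- stats::runif(n_sp, -pi, pi)
    spikes <- matrix(0, h, w)
    for (a in ang) {
      d <- abs(((theta - a + pi) %% (2 * pi)) - pi)
      spikes <- pmax(spikes,
                     0.7 * exp(-d^2 / 0.004) *
                       pmin(pmax((1.7 - rho) / 1.0, 0), 1))
    }
    f <- pmax(f, spikes * (rho > 0.6))
  }
  list(image = background + spec$contrast * f, mask = mask)
}

#' Boundary pixels of a binary mask
#'
#' Foreground pixels having at least one 4-neighbor (or the image border)
#' outside the mask — the pixel set visited by Moore-neighbor contour
#' tracing ([trace_chain_code()]).
#'
#' @param mask Logical matrix.
#' @return Two-column integer matrix of (row, col) boundary pixels.
#' @export
boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  which(mask & !inner, arr.ind = TRUE)
}

# Freeman 8-direction table, row/col coordinates with row increasing
# downward: 0=E, 1=SE, 2=S, 3=SW, 4=W, 5=NW, 6=N, 7=NE.
freeman_steps <- function() {
  cbind(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
        dc = c(1, 1, 0, -1, -1, -1, 0, 1))
}

#' Trace a mask boundary as a Freeman chain code
#'
#' Moore-neighbor boundary tracing, clockwise, starting at the topmost of
#' the leftmost-in-that-row foreground pixels.  The traced pixel set equals
#' [boundary_pixels()] of the mask.  Decoding with [decode_chain_code()]
#' reproduces the traced path exactly.
#'
#' @param mask Logical matrix with exactly one 8-connected foreground
#'   component.
#' @param label Pathology label to attach (`"malignant"`, `"benign"`, or
#'   `NA`).
#' @return A `chain_code` object: list with `start` (row, col; 1-based),
#'   `codes` (integer vector of Freeman directions) and `label`.
#' @export
trace_chain_code <- function(mask, label = NA_character_) {
  if (!any(mask)) stop("mask is empty")
  comp <- flood_count(mask)
  if (comp > 1L) stop("mask has ", comp, " 8-connected components; expected 1")
  steps <- freeman_steps()
  fg <- which(mask, arr.ind = TRUE)
  ord <- order(fg[, 1], fg[, 2])
  start <- fg[ord[1], ]           # topmost, then leftmost
  h <- nrow(mask); w <- ncol(mask)
  is_fg <- function(p) p[1] >= 1 && p[1] <= h && p[2] >= 1 && p[2] <= w &&
    mask[p[1], p[2]]
  # Moore-neighbor tracing with backtracking: scan the 8-neighborhood of
  # the current pixel clockwise starting from the background neighbor we
  # entered from; Jacob's criterion stops on re-entering the start pixel
  # from the same background neighbor.
  codes <- integer(0)
  cur <- start
  db <- 4L                         # backtrack neighbor: West of the start
  repeat {
    found <- FALSE
    for (k in 1:8) {
      d <- (db + k) %% 8L          # clockwise scan from the backtrack
      nxt <- cur + steps[d + 1L, ]
      if (is_fg(nxt)) { found <- TRUE; break }
    }
    if (!found) break              # isolated pixel: empty code
    codes <- c(codes, d)
    # new backtrack: the (background) ring position examined just before
    bprev <- cur + steps[((db + k - 1L) %% 8L) + 1L, ]
    delta <- bprev - nxt
    db <- which(steps[, 1] == delta[1] & steps[, 2] == delta[2]) - 1L
    cur <- nxt
    if (all(cur == start) && db == 4L) break   # Jacob's criterion
    if (length(codes) > 8L * (h * w)) stop("boundary tracing did not close")
  }
  structure(list(start = as.integer(start), codes = codes, label = label),
            class = "chain_code")
}

# number of 8-connected foreground components (iterative flood fill)
flood_count <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  h <- nrow(mask); w <- ncol(mask)
  n <- 0L
  fg <- which(mask)
  for (p in fg) {
    if (lab[p] > 0L) next
    n <- n + 1L
    stack <- p
    lab[p] <- n
    while (length(stack)) {
      q <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (q - 1L) %% h + 1L; cc <- (q - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > h || c2 < 1 || c2 > w) next
        q2 <- (c2 - 1L) * h + rr
        if (mask[q2] && lab[q2] == 0L) { lab[q2] <- n; stack <- c(stack, q2) }
      }
    }
  }
  n
}

#' Default multi-site study design
#'
#' Four scanner profiles (three linear, one logarithmic; resolutions 42,
#' 43.5, 43.5 and 50 um/px) with per-site prototype counts shaped like a
#' heterogeneous multi-clinic screening archive: the logarithmic-response
#' site (`dba`) contributes the majority of normal prototypes, few
#' malignant masses and no benign masses at all, and carries the heaviest
#' gray-level noise.  In the leave-one-site-in protocol each site's entire
#' holding forms its learning set, so these counts are also the per-site
#' learning designations.  The background density is common to all sites:
#' the calibration-to-OD conversion is what normalizes scanner brightness.
#'
#' @param scale Multiplier applied to all counts (default 1, ~680
#'   prototypes).
#' @return List with `profiles` (named list of [scanner_profile()]),
#'   `counts` (data frame of per-site prototype counts) and `mean_od`
#'   (background density, OD).
#' @export
default_study_design <- function(scale = 1) {
  profiles <- list(
    howtek960 = scanner_profile("howtek960", 43.5, "linear",
                                cal_a = 3.789, cal_b = -0.00090,
                                max_gray = 4095, noise_sd = 8),
    howtek850 = scanner_profile("howtek850", 43.5, "linear",
                                cal_a = 3.960, cal_b = -0.00094,
                                max_gray = 4095, noise_sd = 5),
    dba = scanner_profile("dba", 42, "logarithmic",
                          cal_a = 4.82, cal_b = -1.00,
                          max_gray = 65535, noise_sd = 60),
    lumisys = scanner_profile("lumisys", 50, "linear",
                              cal_a = 4.050, cal_b = -0.00098,
                              max_gray = 4095, noise_sd = 10))
  counts <- data.frame(
    site = c("howtek960", "howtek850", "dba", "lumisys"),
    n_malignant = c(47, 14, 14, 86),
    n_benign = c(66, 21, 0, 67),
    n_normal = c(42, 56, 225, 44))
  if (scale != 1) {
    num <- vapply(counts, is.numeric, logical(1))
    counts[num] <- lapply(counts[num], function(x) pmax(round(x * scale),
                                                        ifelse(x > 0, 1, 0)))
  }
  list(profiles = profiles, counts = counts, mean_od = 1.85)
}

#' Generate one site's synthetic dataset
#'
#' Produces raw gray-level cases for a single scanner: mass cases carry one
#' annotated mass each (diameter drawn uniformly over `diam_range` scaled by
#' the site's resolution relative to 45 um/px), normal cases carry none.
#' Shape and margin are sampled with pathology-dependent frequencies
#' (malignant masses favor irregular/spiculated, benign round/circumscribed)
#' and benign masses present more subtly, at `benign_contrast_frac` of the
#' malignant core contrast.  Mass contrast is `effect * base_contrast`
#' times a uniform (0.8, 1.2) jitter, so `effect = 0` yields masses
#' indistinguishable from background.
#'
#' @param profile A [scanner_profile()].
#' @param n_malignant,n_benign,n_normal Case counts (>= 0).
#' @param effect Separability parameter scaling mass contrast (>= 0).
#' @param seed Integer seed; one RNG stream drives the whole call.
#' @param mean_od Background density for this site.
#' @param base_contrast Core OD elevation of malignant masses at
#'   `effect = 1`.
#' @param benign_contrast_frac Benign-to-malignant contrast ratio.
#' @param diam_range Mass diameter range in pixels at 45 um/px.
#' @param texture_scale,od_sd Background texture parameters
#'   (see [generate_background()]).
#' @param normal_side Side of normal (mass-free) case images.
#' @return List of `synthetic_case` objects (image, annotations, site,
#'   truth labels).
#' @export
generate_site_dataset <- function(profile, n_malignant, n_benign, n_normal,
                                  effect = 1, seed = 1L, mean_od = 1.85,
                                  base_contrast = 0.55,
                                  benign_contrast_frac = 0.65,
                                  diam_range = c(16, 44),
                                  texture_scale = 6, od_sd = 0.25,
                                  normal_side = 96) {
  stopifnot(inherits(profile, "scanner_profile"),
            n_malignant >= 0, n_benign >= 0, n_normal >= 0, effect >= 0)
  set.seed(seed)
  res_scale <- 45 / profile$resolution_um
  dmin <- max(6L, round(diam_range[1] * res_scale))
  dmax <- round(diam_range[2] * res_scale)
  rng <- od_range(profile)
  clamp <- function(od) pmin(pmax(od, rng[1] + 0.02), rng[2] - 0.02)

  shape_p <- list(
    malignant = c(round = 0.10, oval = 0.10, lobulated = 0.30, irregular = 0.50),
    benign = c(round = 0.40, oval = 0.40, lobulated = 0.15, irregular = 0.05))
  margin_p <- list(
    malignant = c(circumscribed = 0.15, ill_defined = 0.35, spiculated = 0.50),
    benign = c(circumscribed = 0.60, ill_defined = 0.30, spiculated = 0.10))

  make_mass_case <- function(pathology, idx) {
    diam <- sample(dmin:dmax, 1)
    side <- diam + 40L
    ctr <- side / 2 + stats::runif(2, -4, 4)
    bg <- generate_background(side, side, texture_scale, mean_od, od_sd)
    sp <- mass_spec(sample(names(shape_p[[pathology]]), 1,
                           prob = shape_p[[pathology]]),
                    sample(names(margin_p[[pathology]]), 1,
                           prob = margin_p[[pathology]]),
                    diameter_px = diam,
                    contrast = effect * base_contrast *
                      (if (pathology == "benign") benign_contrast_frac else 1) *
                      stats::runif(1, 0.8, 1.2),
                    center = ctr)
    rm <- render_mass(sp, bg)
    img <- digitize(clamp(rm$image), profile,
                    seed = sample.int(.Machine$integer.max, 1))
    ann <- trace_chain_code(rm$mask, label = pathology)
    structure(list(image = img, annotations = list(ann), site = profile$name,
                   id = sprintf("%s_%s_%03d", profile$name,
                                substr(pathology, 1, 3), idx)),
              class = "synthetic_case")
  }
  make_normal_case <- function(idx) {
    bg <- generate_background(normal_side, normal_side, texture_scale,
                              mean_od, od_sd)
    img <- digitize(clamp(bg), profile,
                    seed = sample.int(.Machine$integer.max, 1))
    structure(list(image = img, annotations = list(), site = profile$name,
                   id = sprintf("%s_nor_%03d", profile$name, idx)),
              class = "synthetic_case")
  }
  c(lapply(seq_len(n_malignant), function(i) make_mass_case("malignant", i)),
    lapply(seq_len(n_benign), function(i) make_mass_case("benign", i)),
    lapply(seq_len(n_normal), function(i) make_normal_case(i)))
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("synthetic_case %s [%s]: %dx%d, %d annotation(s)\n",
              x$id, x$site, nrow(x$image$pixels), ncol(x$image$pixels),
              length(x$annotations)))
  invisible(x)
}

#' Simulate the full multi-site study
#'
#' Runs [generate_site_dataset()] for every site of a study design with a
#' per-site seed derived deterministically from `seed`.
#'
#' @param design A study design as returned by [default_study_design()].
#' @param effect Separability parameter (see [generate_site_dataset()]).
#' @param seed Integer root seed.
#' @param ... Passed through to [generate_site_dataset()].
#' @return List of `synthetic_case` across all sites.
#' @export
simulate_study <- function(design, effect = 1, seed = 1L, ...) {
  out <- list()
  for (i in seq_len(nrow(design$counts))) {
    row <- design$counts[i, ]
    prof <- design$profiles[[row$site]]
    mo <- design$mean_od
    if (!is.null(names(mo))) mo <- mo[[row$site]]
    out <- c(out, generate_site_dataset(
      prof, row$n_malignant, row$n_benign, row$n_normal,
      effect = effect, seed = (seed + 7919L * i) %% .Machine$integer.max,
      mean_od = mo, ...))
  }
  out
}
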