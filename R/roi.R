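# ROI extraction: chain-code decoding, centered bounding squares with the
# border-discard rule, and bilinear patch resizing.

#' Decode a Freeman chain code into boundary pixels
#'
#' Starting at `ann$start`, each code moves one pixel in the Freeman
#' direction (0=E, 1=SE, 2=S, 3=SW, 4=W, 5=NW, 6=N, 7=NE; row index grows
#' downward).  Coordinates are 1-based (row, col).
#'
#' @param ann A `chain_code` (see [trace_chain_code()]) or a list with
#'   `start` and `codes`.
#' @param image_shape Optional `c(H, W)`; when given, a step leaving the
#'   image raises an error.
#' @return Integer matrix of (row, col) path pixels in order, starting at
#'   `start`.
#' @export
decode_chain_code <- function(ann, image_shape = NULL) {
  codes <- as.integer(ann$codes)
  if (length(codes) && (any(codes < 0) || any(codes > 7)))
    stop("chain codes must be in 0..7")
  steps <- freeman_steps()
  rows <- cumsum(c(ann$start[1], steps[codes + 1L, "dr"]))
  cols <- cumsum(c(ann$start[2], steps[codes + 1L, "dc"]))
  if (!is.null(image_shape) &&
      (any(rows < 1) || any(rows > image_shape[1]) ||
       any(cols < 1) || any(cols > image_shape[2])))
    stop("chain code leaves the image bounds")
  cbind(row = as.integer(rows), col = as.integer(cols))
}

#' Smallest centered enclosing square of a boundary
#'
#' The square's side is the larger dimension of the boundary's axis-aligned
#' bounding box, and the square is centered on the bounding-box center with
#' origin `floor(center - (side - 1) / 2)` in each axis (ties broken toward
#' smaller indices).  If the centered square extends past any image edge the
#' lesion cannot be taken centered in a square without stretching and is
#' discarded.
#'
#' @param boundary Two-column (row, col) matrix of boundary pixels, 1-based.
#' @param image_shape `c(H, W)` of the host image.
#' @return List `(row0, col0, side)` (1-based origin, half-open box
#'   `[row0, row0 + side)`), or `NULL` when the square does not fit
#'   (discard rule).
#' @export
bounding_square <- function(boundary, image_shape) {
  if (is.null(dim(boundary))) boundary <- matrix(boundary, ncol = 2)
  if (nrow(boundary) == 0) stop("empty boundary")
  r0 <- min(boundary[, 1]); r1 <- max(boundary[, 1])
  c0 <- min(boundary[, 2]); c1 <- max(boundary[, 2])
  side <- max(r1 - r0 + 1L, c1 - c0 + 1L)
  ctr_r <- (r0 + r1) / 2
  ctr_c <- (c0 + c1) / 2
  row0 <- floor(ctr_r - (side - 1) / 2)
  col0 <- floor(ctr_c - (side - 1) / 2)
  if (row0 < 1 || col0 < 1 ||
      row0 + side - 1 > image_shape[1] || col0 + side - 1 > image_shape[2])
    return(NULL)
  list(row0 = as.integer(row0), col0 = as.integer(col0),
       side = as.integer(side))
}

#' Bilinear resize of a square patch
#'
#' Separable bilinear interpolation on a corner-aligned sampling grid:
#' output sample `i` (0-based) maps to source coordinate
#' `i * (S - 1) / (T - 1)`.  Exact on constant and affine intensity
#' surfaces.
#'
#' @param patch Square numeric matrix, side >= 2.
#' @param target Output side length (integer >= 2).
#' @return `target x target` numeric matrix.
#' @export
resize_bilinear <- function(patch, target) {
  stopifnot(is.matrix(patch), nrow(patch) == ncol(patch), nrow(patch) >= 2)
  if (target < 2) stop("target size must be >= 2")
  s <- nrow(patch)
  w <- bilinear_weights(s, target)
  w %*% patch %*% t(w)
}

# target x source interpolation weight matrix, corner-aligned
bilinear_weights <- function(s, target) {
  pos <- (seq_len(target) - 1) * (s - 1) / (target - 1)
  lo <- pmin(floor(pos), s - 2)
  frac <- pos - lo
  w <- matrix(0, target, s)
  w[cbind(seq_len(target), lo + 1)] <- 1 - frac
  w[cbind(seq_len(target), lo + 2)] <- frac
  w
}

#' Extract mass and normal-tissue prototypes from cases
#'
#' For each annotated mass the chain code is decoded, the centered bounding
#' square computed (masses whose square leaves the image are discarded per
#' the border rule), the gray-level square converted to optical density with
#' the case's scanner profile, and resized bilinearly to each requested
#' working size.  Normal-tissue prototypes are random squares fully inside
#' mass-free images with sides drawn uniformly over `size_range`, converted
#' and resized identically.
#'
#' @param cases List of `synthetic_case` objects (see
#'   [generate_site_dataset()]).
#' @param profiles Named list of [scanner_profile()] keyed by site name.
#' @param sizes Integer vector of working patch sides (default `c(32, 64)`).
#' @param normal_per_case Normal prototypes sampled per mass-free case.
#' @param size_range `(min, max)` side range for normal squares; min >= 8.
#'   The default `NULL` draws each normal side from the empirical
#'   distribution of mass ROI sides extracted at the same site (normal
#'   tissue is captured with sizes ranging from the smallest to the largest
#'   mass sizes found, and matching the size distribution keeps patch
#'   resizing from becoming a class cue), falling back to the global mass
#'   sides and then to `c(16, 48)`.
#' @param seed Integer seed for the normal-square sampling.
#' @return Named list (one element per size) of `prototype_set` objects:
#'   `x` is an N x side^2 matrix of row-major flattened OD patches and
#'   `meta` a data frame with `id`, `label` (mass/normal), `pathology`
#'   (malignant/benign/normal), `site`, `source_case`, `side_px`.
#' @export
extract_prototypes <- function(cases, profiles, sizes = c(32L, 64L),
                               normal_per_case = 1L, size_range = NULL,
                               seed = 1L) {
  if (!is.null(size_range))
    stopifnot(size_range[1] >= 8, size_range[2] >= size_range[1])
  set.seed(seed)
  patches <- list()   # per prototype: OD matrix at native size
  meta <- list()
  n_discard <- 0L
  get_profile <- function(site) {
    prof <- profiles[[site]]
    if (is.null(prof)) stop("no scanner profile for site '", site, "'")
    prof
  }
  # pass 1: mass ROIs via the centered bounding square
  for (cs in cases) {
    if (!length(cs$annotations)) next
    prof <- get_profile(cs$site)
    shp <- dim(cs$image$pixels)
    for (ann in cs$annotations) {
      bnd <- decode_chain_code(ann, shp)
      box <- bounding_square(bnd, shp)
      if (is.null(box)) { n_discard <- n_discard + 1L; next }
      g <- cs$image$pixels[box$row0:(box$row0 + box$side - 1),
                           box$col0:(box$col0 + box$side - 1), drop = FALSE]
      patches[[length(patches) + 1L]] <- to_optical_density(g, prof)
      meta[[length(meta) + 1L]] <- data.frame(
        id = sprintf("%s_m%d", cs$id, length(patches)),
        label = "mass", pathology = ann$label, site = cs$site,
        source_case = cs$id, side_px = box$side)
    }
  }
  mass_sides <- vapply(meta, function(m) m$side_px, integer(1))
  mass_sites <- vapply(meta, function(m) m$site, character(1))
  draw_side <- function(site, hw) {
    if (is.null(size_range)) {
      pool <- mass_sides[mass_sites == site]
      if (!length(pool)) pool <- mass_sides
      if (!length(pool)) pool <- 16:48
      pool <- pmax(pool, 8L)
      min(pool[sample.int(length(pool), 1)], min(hw))
    } else {
      sample(seq(size_range[1], min(size_range[2], min(hw))), 1)
    }
  }
  min_side <- if (is.null(size_range)) 8L else size_range[1]
  # pass 2: normal tissue as random squares, sides matching the mass sizes
  for (cs in cases) {
    if (length(cs$annotations)) next
    prof <- get_profile(cs$site)
    hw <- dim(cs$image$pixels)
    if (min(hw) < min_side) {
      warning("normal case ", cs$id, " smaller than minimum patch size; skipped")
      next
    }
    for (j in seq_len(normal_per_case)) {
      side <- draw_side(cs$site, hw)
      r0 <- sample.int(hw[1] - side + 1L, 1)
      c0 <- sample.int(hw[2] - side + 1L, 1)
      g <- cs$image$pixels[r0:(r0 + side - 1), c0:(c0 + side - 1),
                           drop = FALSE]
      patches[[length(patches) + 1L]] <- to_optical_density(g, prof)
      meta[[length(meta) + 1L]] <- data.frame(
        id = sprintf("%s_n%d", cs$id, j),
        label = "normal", pathology = "normal", site = cs$site,
        source_case = cs$id, side_px = side)
    }
  }
  meta <- do.call(rbind, meta)
  out <- lapply(sizes, function(sz) {
    x <- t(vapply(patches,
                  function(p) as.vector(t(resize_bilinear(p, sz))),
                  numeric(sz * sz)))
    structure(list(x = x, meta = meta, size = as.integer(sz),
                   n_discarded = n_discard),
              class = "prototype_set")
  })
  names(out) <- paste0("s", sizes)
  out
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("prototype_set: %d prototypes of %dx%d (%d mass / %d normal; %d discarded at extraction)\n",
              nrow(x$x), x$size, x$size, sum(x$meta$label == "mass"),
              sum(x$meta$label == "normal"), x$n_discarded))
  print(table(site = x$meta$site, pathology = x$meta$pathology))
  invisible(x)
}
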