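test_that("chain-code decoding follows the Freeman direction table", {
  expect_identical(
    decode_chain_code(list(start = c(5L, 5L), codes = integer(0))),
    cbind(row = 5L, col = 5L))
  path <- decode_chain_code(list(start = c(1L, 1L), codes = c(0, 2, 4, 6)))
  expect_identical(path,
                   cbind(row = c(1L, 1L, 2L, 2L, 1L),
                         col = c(1L, 2L, 2L, 1L, 1L)))
  expect_error(
    decode_chain_code(list(start = c(1L, 1L), codes = c(6)), c(10, 10)),
    "bounds")
  expect_error(decode_chain_code(list(start = c(1L, 1L), codes = 9)), "0..7")
})

test_that("bounding square centers the smallest enclosing square", {
  expect_equal(bounding_square(cbind(10, 10), c(100, 100)),
               list(row0 = 10L, col0 = 10L, side = 1L))
  # bbox rows 11..30 (h 20), cols 41..50 (w 10): side 20 centered on col 45.5
  bnd <- rbind(c(11, 41), c(30, 50))
  expect_equal(bounding_square(bnd, c(100, 100)),
               list(row0 = 11L, col0 = 36L, side = 20L))
  expect_error(bounding_square(matrix(numeric(0), ncol = 2), c(10, 10)),
               "empty")
})

test_that("border-adjacent lesions are discarded when centering leaves the image", {
  # bbox touching row 1 with height < width: centering pushes row0 < 1
  bnd <- rbind(c(1, 10), c(3, 20))
  expect_null(bounding_square(bnd, c(100, 100)))
  expect_null(bounding_square_oracle(bnd, c(100, 100)))
})

test_that("bounding square equals the brute-force centered-square oracle on random masks", {
  set.seed(21)
  n_discard <- 0L
  for (i in 1:50) {
    h <- sample(12:40, 1); w <- sample(12:40, 1)
    sp <- mass_spec(sample(c("round", "oval", "lobulated", "irregular"), 1),
                    "circumscribed",
                    diameter_px = sample(5:10, 1), contrast = 1,
                    center = c(runif(1, 4, h - 3), runif(1, 4, w - 3)))
    rm <- try(render_mass(sp, matrix(0, h, w)), silent = TRUE)
    if (inherits(rm, "try-error")) next
    bnd <- boundary_pixels(rm$mask)
    got <- bounding_square(bnd, c(h, w))
    ora <- bounding_square_oracle(bnd, c(h, w))
    expect_identical(got, ora)
    if (is.null(got)) { n_discard <- n_discard + 1L; next }
    # structural invariants: square, contains all boundary pixels
    expect_true(all(bnd[, 1] >= got$row0 & bnd[, 1] < got$row0 + got$side))
    expect_true(all(bnd[, 2] >= got$col0 & bnd[, 2] < got$col0 + got$side))
    expect_identical(got$side,
                     max(diff(range(bnd[, 1])), diff(range(bnd[, 2]))) + 1L)
  }
})

test_that("bilinear resize preserves constants and hits corner values", {
  expect_equal(resize_bilinear(matrix(7, 5, 5), 9), matrix(7, 9, 9))
  out <- resize_bilinear(matrix(c(0, 2, 1, 3), 2), 4)  # [[0,1],[2,3]]
  expect_equal(out[1, 1], 0)
  expect_equal(out[1, 4], 1)
  expect_equal(out[4, 1], 2)
  expect_equal(out[4, 4], 3)
  expect_error(resize_bilinear(matrix(0, 4, 4), 1), ">= 2")
})

test_that("bilinear resize is exact on affine intensity surfaces", {
  s <- 13
  aff <- outer(1:s, 1:s, function(r, c) 0.3 + 1.7 * r - 0.4 * c)
  for (target in c(5, 8, 32)) {
    got <- resize_bilinear(aff, target)
    pos <- (seq_len(target) - 1) * (s - 1) / (target - 1) + 1
    want <- outer(pos, pos, function(r, c) 0.3 + 1.7 * r - 0.4 * c)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("downscale-then-upscale of a smooth ramp is bounded by its increment", {
  s <- 33
  ramp <- outer(1:s, 1:s, function(r, c) 0.05 * r + 0.02 * c)
  down <- resize_bilinear(ramp, 17)
  up <- resize_bilinear(down, s)
  expect_lt(max(abs(up - ramp)), 0.05 + 0.02)
})

test_that("prototype extraction honors the discard rule and bookkeeping", {
  prof <- scanner_profile("s", 45, "linear", cal_a = 3.8, cal_b = -0.0009,
                          max_gray = 4095)
  profs <- list(s = prof)
  # mass hugging the top border -> bounding square pushed out -> discarded
  mask <- matrix(FALSE, 40, 40); mask[1:3, 10:20] <- TRUE
  border_case <- structure(
    list(image = gray_image(matrix(1000L, 40, 40), 4095),
         annotations = list(trace_chain_code(mask, "malignant")),
         site = "s", id = "border"),
    class = "synthetic_case")
  normals <- generate_site_dataset(prof, 0, 0, 3, seed = 4)
  out <- extract_prototypes(c(list(border_case), normals), profs,
                            sizes = 16, normal_per_case = 2,
                            size_range = c(16, 40), seed = 1)
  expect_identical(out$s16$n_discarded, 1L)
  expect_identical(sum(out$s16$meta$label == "mass"), 0L)
  expect_identical(sum(out$s16$meta$label == "normal"), 6L)
})

test_that("extracted prototype counts match the generator request minus discards", {
  d <- tiny_design()
  cases <- simulate_study(d, effect = 1, seed = 31)
  out <- extract_prototypes(cases, d$profiles, sizes = c(16, 32), seed = 2)
  want <- colSums(d$counts[c("n_malignant", "n_benign", "n_normal")])
  n_mass <- sum(out$s32$meta$label == "mass")
  n_normal <- sum(out$s32$meta$label == "normal")
  expect_identical(n_mass + out$s32$n_discarded,
                   as.integer(want[["n_malignant"]] + want[["n_benign"]]))
  expect_identical(n_normal, as.integer(want[["n_normal"]]))
  # both sizes share metadata and counts
  expect_identical(out$s16$meta, out$s32$meta)
})

test_that("prototype patches stay within the profile's OD range", {
  d <- tiny_design()
  cases <- simulate_study(d, effect = 1, seed = 31)
  out <- extract_prototypes(cases, d$profiles, sizes = 32, seed = 2)
  for (site in unique(out$s32$meta$site)) {
    rng <- od_range(d$profiles[[site]])
    x <- out$s32$x[out$s32$meta$site == site, , drop = FALSE]
    expect_true(all(x >= rng[1] - 1e-9 & x <= rng[2] + 1e-9))
  }
})
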