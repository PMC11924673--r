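# Texture-matrix construction and feature formulas.

disc_of <- function(lev, ng) list(levels = lev, n_levels = as.integer(ng))

test_that("GLCM construction matches hand enumeration on tiny images", {
  # constant 3x3: all mass at (1,1)
  d <- disc_of(matrix(1L, 3, 3), 1L)
  g <- compute_glcm(d)
  for (P in g$p) expect_equal(as.vector(P), 1)

  # 2x2 image [[1,2],[1,2]] (rows): horizontal pairs are (1,2),(1,2)
  lev <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  g2 <- compute_glcm(disc_of(lev, 2L))
  P_h <- g2$p[[1]]  # angle (0,1)
  expect_equal(P_h[1, 2], 0.5)
  expect_equal(P_h[2, 1], 0.5)
  expect_equal(P_h[1, 1], 0)
  expect_true(all(abs(vapply(g2$p, sum, numeric(1)) - 1) < 1e-12))
  for (P in g2$p) expect_equal(P, t(P))
})

test_that("IDMN and sum entropy follow their closed forms", {
  d1 <- disc_of(matrix(1L, 3, 3), 1L)
  g1 <- compute_glcm(d1)
  expect_equal(glcm_idmn(g1), 1)
  expect_equal(glcm_sum_entropy(g1), 0)

  lev <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  # restrict to the horizontal angle for the worked example
  g <- structure(list(p = list(compute_glcm(disc_of(lev, 2L))$p[[1]]),
                      n_levels = 2L), class = "glcm")
  expect_equal(glcm_idmn(g), 1 / (1 + 1 / 4))  # 0.8
  expect_equal(glcm_sum_entropy(g), 0)         # all pair sums equal 3

  # uniform 2x2 GLCM: p_(x+y) = (1/4, 1/2, 1/4) -> 1.5 bits
  gu <- structure(list(p = list(matrix(0.25, 2, 2)), n_levels = 2L),
                  class = "glcm")
  expect_equal(glcm_sum_entropy(gu), 1.5)

  # moving diagonal mass to the far corner strictly lowers IDMN
  pd <- matrix(0, 4, 4); diag(pd) <- 0.25
  gd <- structure(list(p = list(pd), n_levels = 4L), class = "glcm")
  poff <- pd
  poff[1, 1] <- 0; poff[1, 4] <- poff[4, 1] <- 0.125
  goff <- structure(list(p = list(poff), n_levels = 4L), class = "glcm")
  expect_lt(glcm_idmn(goff), glcm_idmn(gd))
  expect_equal(glcm_idmn(gd), 1)
})

test_that("first-order features: constants, symmetry, direct arithmetic", {
  mask <- matrix(TRUE, 2, 2)
  img <- matrix(5, 2, 2)
  d <- discretize(img, mask)
  f <- firstorder_features(img, mask, d)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["rms"]), 5)
  expect_equal(unname(f["variance"]), 0)

  img2 <- matrix(c(0, 0, 1, 1), 2, 2)
  d2 <- discretize(img2, mask, 2L)
  f2 <- firstorder_features(img2, mask, d2)
  expect_equal(unname(f2["entropy"]), 1)     # two equal-count levels
  expect_equal(unname(f2["uniformity"]), 0.5)

  img3 <- matrix(c(3, 4, 3, 4), 2, 2)
  f3 <- firstorder_features(img3, mask, discretize(img3, mask, 2L))
  expect_equal(unname(f3["rms"]), sqrt(12.5))
  expect_equal(unname(f3["mean"]), 3.5)
  expect_equal(unname(f3["energy"]), 50)
})

test_that("GLSZM zones and zone percentage match flood-fill enumeration", {
  mask4 <- matrix(TRUE, 2, 2)
  const <- disc_of(matrix(1L, 2, 2), 1L)
  z <- compute_glszm(const)
  expect_equal(z$n_zones, 1L)
  expect_equal(glszm_zone_percentage(z), 0.25)  # 1 zone / 4 pixels

  lev <- matrix(c(1L, 1L, 2L, 2L), 2, 2)  # [[1,2],[1,2]]
  z2 <- compute_glszm(disc_of(lev, 2L))
  expect_equal(z2$n_zones, 2L)
  expect_equal(sort(z2$zone_size), c(2, 2))
  expect_equal(glszm_zone_percentage(z2), 0.5)

  set.seed(9)
  for (k in 1:5) {
    d <- random_disc_image(8, 8, 3)
    got <- compute_glszm(d)
    ref <- oracle_zones(d$levels)
    expect_equal(got$n_zones, nrow(ref))
    expect_equal(sort(got$zone_size), sort(ref[, "size"]))
  }
})

test_that("GLRLM runs: constant-image extremes and maximal long-run emphasis", {
  const <- disc_of(matrix(1L, 4, 4), 1L)
  rl <- compute_glrlm(const)
  # horizontal angle: one run of length 4 per row
  expect_equal(rl$R[[1]][1, 4], 4)
  f <- glrlm_features(rl)
  set.seed(10)
  for (k in 1:5) {
    lev <- matrix(sample.int(3L, 16, replace = TRUE), 4, 4)
    f2 <- glrlm_features(compute_glrlm(disc_of(lev, 3L)))
    expect_lte(f2["long_run_emphasis"], f["long_run_emphasis"])
  }
})

test_that("family panels have the printed cardinalities", {
  set.seed(11)
  d <- random_disc_image(8, 8, 4)
  img <- matrix(rnorm(64), 8, 8)
  mask <- !is.na(d$levels)
  expect_length(glcm_features(compute_glcm(d)), 24L)
  expect_length(gldm_features(compute_gldm(d)), 14L)
  expect_length(glrlm_features(compute_glrlm(d)), 16L)
  expect_length(glszm_features(compute_glszm(d)), 16L)
  expect_length(ngtdm_features(compute_ngtdm(d)), 5L)
  expect_length(firstorder_features(img, mask, d), 18L)
  expect_length(shape_features(mask), 9L)
})

test_that("GLCM features are invariant under 90-degree rotation", {
  set.seed(12)
  d <- random_disc_image(7, 7, 4, mask_prob = 1)
  rot <- list(levels = t(d$levels[nrow(d$levels):1, ]), n_levels = d$n_levels)
  f1 <- glcm_features(compute_glcm(d))
  f2 <- glcm_features(compute_glcm(rot))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("feature ranges: IDMN and zone% in (0,1], entropy bounded by log2(Ng)", {
  set.seed(13)
  for (k in 1:20) {
    d <- random_disc_image(8, 8, sample(2:6, 1))
    idmn <- glcm_idmn(compute_glcm(d))
    zp <- glszm_zone_percentage(compute_glszm(d))
    expect_gt(idmn, 0); expect_lte(idmn, 1)
    expect_gt(zp, 0); expect_lte(zp, 1)
    img <- matrix(rnorm(64), 8, 8)
    f <- firstorder_features(img, !is.na(d$levels), d)
    expect_lte(f[["entropy"]], log2(d$n_levels) + 1e-12)
  }
})

test_that("circular masks give elongation near 1 and sensible shape values", {
  n <- 41
  rr <- matrix(seq_len(n), n, n) - 21
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - 21
  disk <- rr^2 + cc^2 <= 15^2
  s <- shape_features(disk, c(1, 1))
  expect_gt(s[["elongation"]], 0.97)
  expect_lt(abs(s[["pixel_surface"]] - pi * 15^2) / (pi * 15^2), 0.05)
  expect_lt(abs(s[["perimeter"]] - 2 * pi * 15) / (2 * pi * 15), 0.08)
  expect_lt(abs(s[["maximum_diameter"]] - 30) / 30, 0.05)
  expect_lte(s[["sphericity"]], 1.02)
})

test_that("extraction yields the full stable catalog and is deterministic", {
  cfg <- pipeline_config(synthetic = small_config(),
                         filters = c("original", "gradient"))
  case <- generate_case(cfg$synthetic, 1L, seed = 21L)
  f1 <- extract_features(case, cfg)
  f2 <- extract_features(case, cfg)
  expect_identical(f1, f2)
  expect_length(f1, 204L)
  expect_identical(names(f1), feature_catalog(cfg$filters)$name)
})

test_that("jointly translating image and contours leaves features unchanged", {
  # unit target spacing so the translation is an exact grid shift
  cfg <- pipeline_config(synthetic = small_config(), filters = "original",
                         target_spacing_mm = 1)
  case <- generate_case(cfg$synthetic, 0L, seed = 22L)
  f1 <- extract_features(case, cfg)
  shifted <- case
  npix <- dim(case$t1_map$pixels)
  shift <- 6L
  pix <- matrix(median(case$t1_map$pixels), npix[1], npix[2])
  pix[(shift + 1):npix[1], (shift + 1):npix[2]] <-
    case$t1_map$pixels[1:(npix[1] - shift), 1:(npix[2] - shift)]
  shifted$t1_map$pixels <- pix
  shifted$contours$endo <- case$contours$endo + shift
  shifted$contours$epi <- case$contours$epi + shift
  f2 <- extract_features(shifted, cfg)
  expect_equal(f1, f2, tolerance = 1e-9)
})
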