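# Synthetic T1-map generator: determinism, class symmetry, calibration,
# reader variants, and longitudinal structure.

test_that("identical (config, status, seed) reproduces a case bit for bit", {
  cfg <- small_config()
  a <- generate_case(cfg, 1L, seed = 11L)
  b <- generate_case(cfg, 1L, seed = 11L)
  expect_identical(a$t1_map$pixels, b$t1_map$pixels)
  expect_identical(a$contours, b$contours)
  expect_identical(a$age, b$age)
  c2 <- generate_case(cfg, 1L, seed = 12L)
  expect_false(identical(a$t1_map$pixels, c2$t1_map$pixels))
})

test_that("equal class parameters make the two classes identical in law", {
  cfg <- small_config(t1_mean_pos = 1032, t1_mean_neg = 1032,
                      texture_corr_len_pos = 2, texture_corr_len_neg = 2,
                      lesion_rate_pos = 0)
  pos <- generate_case(cfg, 1L, seed = 5L)
  neg <- generate_case(cfg, 0L, seed = 5L)
  # same parameters and same seed: the generative path coincides exactly
  expect_identical(pos$t1_map$pixels, neg$t1_map$pixels)
})

test_that("T1 values are positive and contours lie inside the grid", {
  cfg <- small_config()
  for (st in 0:1) {
    cs <- generate_case(cfg, st, seed = 3L + st)
    expect_true(all(cs$t1_map$pixels > 0))
    ext <- cfg$grid_size * cfg$pixel_spacing_mm
    expect_true(all(cs$contours$epi >= 0 & cs$contours$epi <= ext))
  }
})

test_that("degenerate annulus geometry is rejected", {
  expect_error(synthetic_config(endo_radius_px = 20, epi_radius_px = 16),
               "annulus")
  expect_error(synthetic_config(t1_sd = 0), "t1_sd")
})

test_that("class means calibrate to the configured global T1 (50+50 cases)", {
  cfg <- synthetic_config()
  mean_t1 <- function(status, seeds) {
    vapply(seeds, function(s) {
      cs <- generate_case(cfg, status, seed = s)
      mask <- rasterize_ring_mask(cs$contours, dim(cs$t1_map$pixels),
                                  cs$t1_map$spacing)
      mean(cs$t1_map$pixels[mask])
    }, numeric(1))
  }
  neg <- mean_t1(0L, 1:50)
  pos <- mean_t1(1L, 1001:1050)
  expect_lt(abs(mean(neg) - cfg$t1_mean_neg), 2 * sd(neg) / sqrt(50))
  expect_lt(abs(mean(pos) - cfg$t1_mean_pos), 2 * sd(pos) / sqrt(50))
})

test_that("gaussian random field has the requested marginal and correlation", {
  set.seed(42)
  f <- gaussian_random_field(128, 3)
  expect_lt(abs(mean(f)), 0.1)
  expect_lt(abs(sd(f) - 1), 0.1)
  # lag-2 correlation along rows should be near exp(-4 / (2 * 9))
  r <- cor(as.vector(f[, 1:126]), as.vector(f[, 3:128]))
  expect_lt(abs(r - exp(-4 / 18)), 0.12)
})

test_that("reader variants: count, zero-jitter copies, and Dice overlap", {
  cfg <- small_config()
  cs <- generate_case(cfg, 0L, seed = 9L)
  v0 <- generate_reader_variants(cs, 2L, 2L, jitter_px = 0, seed = 1L)
  expect_length(v0, 4L)
  for (v in v0) {
    expect_equal(v$endo, cs$contours$endo, ignore_attr = TRUE)
    expect_equal(v$epi, cs$contours$epi, ignore_attr = TRUE)
  }
  v1 <- generate_reader_variants(cs, 2L, 1L, jitter_px = 1, seed = 2L)
  shape <- dim(cs$t1_map$pixels)
  m0 <- rasterize_ring_mask(cs$contours, shape, cs$t1_map$spacing)
  for (v in v1) {
    m <- rasterize_ring_mask(v, shape, cs$t1_map$spacing)
    expect_false(identical(m, m0))
    dice <- 2 * sum(m & m0) / (sum(m) + sum(m0))
    expect_gt(dice, 0.8)
  }
})

test_that("rasterized masks are single annular connected components", {
  cfg <- small_config()
  for (s in 1:5) {
    cs <- generate_case(cfg, s %% 2L, seed = 100L + s)
    m <- rasterize_ring_mask(cs$contours, dim(cs$t1_map$pixels),
                             cs$t1_map$spacing)
    ones <- matrix(NA_integer_, nrow(m), ncol(m))
    ones[m] <- 1L
    zones <- oracle_zones(ones)
    expect_equal(nrow(zones), 1L)  # one connected in-mask component
    # the hole: background inside the bounding box splits into outside + hole
    inv <- matrix(NA_integer_, nrow(m), ncol(m))
    inv[!m] <- 1L
    expect_equal(nrow(oracle_zones(inv)), 2L)
  }
})

test_that("longitudinal cohorts have the right size and monotone progression", {
  cfg <- small_config()
  cases <- generate_longitudinal_cohort(cfg, n_patients = 15L, n_years = 3L,
                                        effect_size = 2, seed = 4L)
  expect_length(cases, 45L)
  stat <- data.frame(pid = vapply(cases, function(cs) cs$patient_id, character(1)),
                     year = vapply(cases, function(cs) cs$exam_year, integer(1)),
                     lge = vapply(cases, function(cs) cs$lge_status, integer(1)))
  for (p in unique(stat$pid)) {
    s <- stat$lge[stat$pid == p][order(stat$year[stat$pid == p])]
    expect_true(all(diff(s) >= 0))
  }
  expect_error(generate_longitudinal_cohort(cfg, 5L, n_years = 2L), "n_years")
})

test_that("effect_size = 0 decouples LGE status from the texture driver", {
  cfg <- small_config()
  cases <- generate_longitudinal_cohort(cfg, n_patients = 120L, n_years = 3L,
                                        effect_size = 0, seed = 8L)
  d <- vapply(cases, function(cs) cs$driver, numeric(1))
  y <- vapply(cases, function(cs) cs$lge_status, integer(1))
  fit <- glm(y ~ d, family = binomial())
  expect_gt(summary(fit)$coefficients["d", "Pr(>|z|)"], 0.01)
  expect_lt(abs(coef(fit)["d"]), 0.3)
})

test_that("entropy and zone percentage separate the classes at n = 24 + 24", {
  cfg <- pipeline_config(filters = c("original", "lbp_8_1"))
  scfg <- cfg$synthetic
  reps <- 5L
  hits_entropy <- 0L
  hits_zone <- 0L
  for (r in seq_len(reps)) {
    get <- function(status, seeds) {
      t(vapply(seeds, function(s) {
        fv <- extract_features(generate_case(scfg, status, s), cfg)
        c(fv["original__firstorder__entropy"],
          fv["lbp_8_1__glszm__zone_percentage"])
      }, numeric(2)))
    }
    base <- 10000L * r
    neg <- get(0L, base + 1:24)
    pos <- get(1L, base + 5000L + 1:24)
    p_ent <- t.test(neg[, 1], pos[, 1])$p.value
    p_zon <- t.test(neg[, 2], pos[, 2])$p.value
    hits_entropy <- hits_entropy + (p_ent < 0.05 && mean(pos[, 1]) > mean(neg[, 1]))
    hits_zone <- hits_zone + (p_zon < 0.05 && mean(pos[, 2]) < mean(neg[, 2]))
  }
  expect_gte(hits_entropy, 0.8 * reps)
  expect_gte(hits_zone, 0.8 * reps)
})
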