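test_that("positive-control factors equal the cohort mean over lane geometric means", {
  m <- tiny_matrix(pos_gm = c(100, 200, 400), neg = 10, end = 100)
  tn <- technical_normalize(m)
  expect_equal(tn$factors$factor, c(7 / 3, 7 / 6, 7 / 12))
  expect_equal(tn$factors$pos_geo_mean, c(100, 200, 400))

  # identical lanes: factors 1, output is the background-subtracted input
  m2 <- tiny_matrix(pos_gm = c(100, 100, 100), neg = 10,
                    end = matrix(c(25, 8, 100, 0), 4, 3))
  tn2 <- technical_normalize(m2)
  expect_equal(tn2$factors$factor, rep(1, 3))
  # negatives {10,10,10,10}: mu 10, sd 0, tau 10 -> 25 becomes 15, 8 floors to 0
  expect_equal(unname(tn2$matrix$values["G01", ]), rep(15, 3))
  expect_equal(unname(tn2$matrix$values["G02", ]), rep(0, 3))
  # control probes are carried through unsubtracted
  expect_equal(unname(tn2$matrix$values["NEG_A", ]), rep(10, 3))

  # a zero positive-control count leaves the geometric mean undefined
  bad <- tiny_matrix(pos_gm = c(100, 100, 0))
  expect_error(technical_normalize(bad), "factor error")
})

test_that("lane factors absorb a rescaled lane up to the cohort constant", {
  m <- tiny_matrix(pos_gm = c(100, 150, 250), neg = c(8),
                   end = matrix(c(50, 120, 300, 70), 4, 3) + 1:4)
  tn <- technical_normalize(m)
  vals <- m$values
  vals[, 2] <- vals[, 2] * 5
  m2 <- count_matrix(vals, m$codeset, raw = FALSE)
  tn2 <- technical_normalize(m2)
  # the rescaled lane's factor absorbs c; only the cohort-wide anchor
  # (the arithmetic mean over lane geometric means) shifts, so the two
  # normalized matrices agree up to one global constant
  ratio <- mean(tn2$factors$pos_geo_mean) / mean(tn$factors$pos_geo_mean)
  expect_equal(tn2$matrix$values, tn$matrix$values * ratio,
               tolerance = 1e-12)
  expect_equal(tn2$factors$factor[2] * 5 / ratio, tn$factors$factor[2],
               tolerance = 1e-12)
  # rescaling every lane by the same c is fully absorbed in the factors
  m3 <- count_matrix(m$values * 4, m$codeset, raw = FALSE)
  tn3 <- technical_normalize(m3)
  expect_equal(tn3$factors$factor, tn$factors$factor)
  expect_true(all(tn$matrix$values >= 0))
})

test_that("reference normalization equalizes housekeeping geometric means", {
  m <- tiny_matrix(pos_gm = c(100, 100), neg = 10,
                   hk = matrix(c(100, 100, 200, 200), 2, 2))
  rn <- reference_normalize(m)
  expect_equal(rn$factors$factor, c(1.5, 0.75))
  gm <- function(x) exp(mean(log(x)))
  hk_after <- rn$matrix$values[c("HK01", "HK02"), ]
  expect_equal(unname(apply(hk_after, 2, gm)), c(150, 150))

  # single lane is the identity
  m1 <- tiny_matrix(pos_gm = 100, hk = matrix(c(80, 120), 2, 1))
  expect_equal(reference_normalize(m1)$factors$factor, 1)

  # all-zero housekeeping in one lane is an error naming the lane
  m3 <- tiny_matrix(pos_gm = c(100, 100, 100),
                    hk = matrix(c(50, 50, 50, 50, 0, 0), 2, 3))
  expect_error(reference_normalize(m3), "lane S3")
})

test_that("the noise filter is a one-sided t-test with limit conventions", {
  cs <- tiny_codeset(n_end = 3, n_hk = 1)
  vals <- rbind(
    G01 = c(20, 22, 18, 21, 19),   # clearly above mu0 = 10
    G02 = rep(10, 5),              # exactly at mu0, zero variance
    G03 = rep(15, 5),              # above mu0, zero variance
    HK01 = rep(50, 5),
    matrix(100, 6, 5, dimnames = list(paste0("POS_", LETTERS[1:6]), NULL)),
    matrix(5, 4, 5, dimnames = list(paste0("NEG_", LETTERS[1:4]), NULL))
  )
  m <- count_matrix(vals, cs, raw = TRUE)
  bg <- data.frame(sample_id = colnames(m$values), mean = 10, sd = 0,
                   threshold = 10)
  nc <- noise_filter(m, bg)
  expect_equal(nc$t[nc$gene == "G01"], 14.142, tolerance = 1e-3)
  expect_equal(nc$p[nc$gene == "G01"], 7.2564e-05, tolerance = 1e-3)
  expect_true(nc$above_noise[nc$gene == "G01"])
  expect_equal(nc$t[nc$gene == "G02"], 0)
  expect_equal(nc$p[nc$gene == "G02"], 0.5)
  expect_false(nc$above_noise[nc$gene == "G02"])
  expect_equal(nc$p[nc$gene == "G03"], 0)
  expect_true(nc$above_noise[nc$gene == "G03"])
})

test_that("raising a gene's counts never lowers its noise statistic", {
  set.seed(40)
  m <- tiny_matrix(pos_gm = rep(100, 6), neg = 8,
                   end = matrix(rpois(24, 40), 4, 6))
  bg <- data.frame(sample_id = paste0("S", 1:6), mean = 8, sd = 2,
                   threshold = 12)
  t0 <- noise_filter(m, bg)$t
  for (delta in c(1, 5, 20)) {
    vals <- m$values
    vals["G01", ] <- vals["G01", ] + delta
    t1 <- noise_filter(count_matrix(vals, m$codeset), bg)$t
    expect_gte(t1[1], t0[1])
    t0 <- t1
  }
})

test_that("the full pipeline recovers lane factors and the background stratum", {
  cfg <- sim_config(seed = 31, lane_factor_sd = 0.2)
  ds <- simulate_dataset(cfg)
  norm <- normalize_pipeline(ds$counts)
  # estimated technical factors track the inverse true lane factors
  r <- cor(norm$technical_factors$factor, 1 / ds$lane_factors)
  expect_gt(r, 0.95)
  # fraction flagged below noise within 3 points of the simulated 6%
  below <- mean(!norm$noise_calls$above_noise)
  expect_lt(abs(below - cfg$background_fraction), 0.03)
  # genes truly at background are the ones flagged
  flagged <- norm$noise_calls$gene[!norm$noise_calls$above_noise]
  bg_genes <- ds$truth$gene[!ds$truth$is_above_noise]
  expect_gt(mean(bg_genes %in% flagged), 0.9)

  # all-identical lanes: pipeline reduces to pure background subtraction
  m <- tiny_matrix(pos_gm = rep(100, 3), neg = 10,
                   end = matrix(c(60, 25, 8, 0), 4, 3), hk = 50)
  norm2 <- normalize_pipeline(m)
  expect_equal(unname(norm2$matrix$values["G01", ]), rep(50, 3))
  expect_equal(unname(norm2$matrix$values["G03", ]), rep(0, 3))
  expect_equal(norm2$technical_factors$factor, rep(1, 3))
  expect_equal(norm2$reference_factors$factor, rep(1, 3))
})
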