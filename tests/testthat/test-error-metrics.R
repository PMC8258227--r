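test_that("identical tracks score zero error everywhere", {
  db <- toy_track("T1", n = 6)
  gps <- db; gps$method <- "GPS"
  rec <- pair_and_score(db, gps)
  expect_equal(nrow(rec), 5)
  expect_equal(rec$distance_error, rep(0, 5))
  expect_equal(rec$bearing_error, rep(0, 5))
})

test_that("a constructed pair reproduces hand arithmetic", {
  # DB: 10 m due north; GPS: 12 m at 350 degrees
  db <- track_from_xy(c(0, 0), c(0, 10), "T1")
  gps <- track_from_xy(c(0, 12 * sin(350 * pi / 180)),
                       c(0, 12 * cos(350 * pi / 180)), "T1", method = "GPS")
  rec <- pair_and_score(db, gps)
  expect_equal(rec$distance_error, 2, tolerance = 1e-6)
  expect_equal(rec$bearing_error, 10, tolerance = 1e-6)
})

test_that("role swap flips distance error and preserves bearing error", {
  set.seed(71)
  a <- track_from_xy(cumsum(runif(6, -8, 8)), cumsum(runif(6, -8, 8)), "A")
  b <- track_from_xy(cumsum(runif(6, -8, 8)), cumsum(runif(6, -8, 8)), "B")
  ab <- pair_and_score(a, b, passive_threshold = 0)
  # swapping roles flips the activity filter too, so compare on threshold 0
  ba <- pair_and_score(b, a, passive_threshold = 0)
  expect_equal(ab$distance_error, -ba$distance_error, tolerance = 1e-9)
  expect_equal(ab$bearing_error, ba$bearing_error, tolerance = 1e-9)
})

test_that("passive and zero-length steps are excluded appropriately", {
  x <- c(0, 0.1, 5, 5, 12);  y <- c(0, 0.2, 1, 1, 3)
  db <- track_from_xy(x, y, "T1")
  gps <- track_from_xy(x + 0.5, y - 0.3, "T1", method = "GPS")
  rec <- pair_and_score(db, gps, passive_threshold = 0.5)
  # step 1 (~0.22 m) is passive, step 3 is zero-length: both dropped from
  # distance records or bearing-NA'd
  expect_false(1 %in% rec$fix_order)
  expect_false(3 %in% rec$fix_order)
  expect_true(all(!is.na(rec$bearing_error)))
  expect_error(pair_and_score(db, gps[-1, ]), "mismatch")
})

test_that("summaries match independent spreadsheet-style arithmetic", {
  set.seed(72)
  de <- round(rnorm(20, 2, 1), 3); be <- round(runif(20, 0, 90), 3)
  rec <- data.frame(track_id = rep(c("A", "B"), each = 10), fix_order = 1:20,
                    db_distance = 10, gps_distance = 10 + de,
                    distance_error = de, db_bearing = 0, gps_bearing = be,
                    bearing_error = be)
  s <- summarize_errors(rec)
  expect_equal(s$mean_distance_error, sum(de) / 20)
  expect_equal(s$sem_distance_error,
               sqrt(sum((de - mean(de))^2) / 19) / sqrt(20))
  expect_equal(s$mean_bearing_error, sum(be) / 20)
  expect_equal(s$per_track$gps_total,
               c(sum(10 + de[1:10]), sum(10 + de[11:20])))

  one <- summarize_errors(rec[1, ])
  expect_true(is.na(one$sem_distance_error))
  const <- summarize_errors(transform(rec, distance_error = 1.5))
  expect_equal(const$sem_distance_error, 0)
  expect_error(summarize_errors(rec[0, ]), "no error records")
})

test_that("coordinate correlations give Pearson r, t and n-2 df", {
  db <- toy_track("T1", n = 269)
  gps <- db
  expect_warning(coordinate_correlation(db, gps), "degenerate")  # constant lon
  gps2 <- db
  set.seed(73)
  gps2$lon <- db$lon + rnorm(269, 0, 1e-5)
  gps2$lat <- db$lat + rnorm(269, 0, 1e-5)
  cc <- coordinate_correlation(db, gps2)
  expect_equal(cc$df, c(267, 267))
  expect_equal(cc$r[2], cor(db$lat, gps2$lat))
  anti <- db; anti$lat <- -db$lat + 2 * db$lat[1]
  set.seed(74)
  db_j <- db; db_j$lon <- db$lon + rnorm(269, 0, 1e-6)
  anti$lon <- -db_j$lon
  cc2 <- coordinate_correlation(db_j, anti)
  expect_equal(cc2$r, c(-1, -1), tolerance = 1e-9)
})

test_that("the error LMM nests OLS and saturates R2 on noiseless data", {
  set.seed(75)
  d <- data.frame(g = rep(letters[1:6], each = 12), x = rnorm(72))
  d$y <- 1 + 2 * d$x + rnorm(72, 0, 0.5)   # no group effect
  res <- suppressMessages(fit_error_lmm(d, "y", "x", "g"))
  ols <- coef(lm(y ~ x, data = d))[["x"]]
  expect_equal(res$estimate, ols, tolerance = 1e-4)
  expect_true(res$chi_sq >= 0)

  d2 <- d; d2$y <- 2 * d2$x
  res2 <- suppressWarnings(suppressMessages(fit_error_lmm(d2, "y", "x", "g")))
  expect_gt(res2$marginal_R2, 0.999)  # fixed effect absorbs all variance
})

test_that("categorical predictors use a factor-level LRT df", {
  set.seed(76)
  d <- data.frame(g = rep(letters[1:6], each = 24),
                  b = rep(seq(0, 330, 30), 12))
  d$y <- rnorm(144, 10, 3)
  res <- fit_error_lmm(d, "y", "b", "g", categorical = TRUE)
  expect_equal(res$df, 11)
  expect_true(is.na(res$estimate))
})

test_that("bearing error declines with DB distance under isotropic noise", {
  set.seed(77)
  model <- gps_error_model(sigma = 3)
  recs <- lapply(1:6, function(k) {
    d <- generate_design(15, seed = 700 + k, design_id = paste0("D", k))
    db <- db_to_coords(c(19.06, 47.47), d$steps)
    dbf <- data.frame(track_id = d$design_id, order = 0:15, method = "DB",
                      lon = db$lon, lat = db$lat, active = TRUE)
    sim <- simulate_gps(dbf, model, n_repeats = 1)
    pair_and_score(dbf, sim$gps_repeats[[1]], passive_threshold = 0)
  })
  rec <- do.call(rbind, recs)
  res <- fit_error_lmm(rec, "bearing_error", "db_distance", "track_id")
  expect_lt(res$estimate, 0)
  expect_gt(mean(rec$distance_error), 0)
})

test_that("total length comparison is exact on identical tracks and conserves sums", {
  db <- rbind(toy_track("A", n = 11, step_m = 8.5),
              toy_track("B", n = 11, step_m = 6))
  more <- do.call(rbind, lapply(3:6, function(k)
    toy_track(paste0("T", k), n = 11, step_m = k)))
  db <- rbind(db, more)
  gps <- db; gps$method <- "GPS"; gps$track_id <- paste0(db$track_id, "_r1")
  res <- suppressMessages(total_length_comparison(db, gps))
  expect_equal(res$estimate, 0, tolerance = 1e-8)
  # a 10-step track with constant 8.5 m steps totals 85.0 m
  expect_equal(res$totals$total[res$totals$track_id == "A"], 85,
               tolerance = 1e-6)
})
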