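# Regression layer: speed models, AIC altitude selection, track-length and
# direction models, all on planted-truth data.

test_that("speed model recovers a planted wind-support coefficient", {
  set.seed(51)
  n <- 2000
  ids <- rep(sprintf("t%02d", 1:20), each = n / 20)
  ws <- runif(n, -8, 12)
  cw <- abs(rnorm(n, 0, 0.3)) # essentially no crosswind, jittered
  gs <- 12 + 0.8 * ws + rnorm(n, 0, 0.5)
  segs <- make_segments(ids, ws, cw, gs)
  fit <- fit_speed_model(segs, response = "ground")
  expect_gte(coef(fit)[["ws"]], 0.7)
  expect_lte(coef(fit)[["ws"]], 0.9)
  expect_true(is.finite(fit$aic))
  expect_equal(fit$n, n)
  # prediction uses the fixed effects
  expect_equal(predict(fit, data.frame(ws = 0, cw = 0)),
               coef(fit)[["(Intercept)"]], tolerance = 1e-9)
})

test_that("air-speed response with no planted dependence shows a null effect", {
  set.seed(52)
  n <- 1500
  ids <- rep(sprintf("t%02d", 1:15), each = 100)
  ws <- runif(n, -8, 12)
  cw <- abs(rnorm(n, 0, 0.3))
  air <- 11 + rnorm(n, 0, 0.8) # independent of ws by construction
  segs <- make_segments(ids, ws, cw, ground_speed = air + ws, air_speed = air)
  fit <- fit_speed_model(segs, response = "air", method = "ols")
  se <- summary(fit$model)$coefficients["ws", "Std. Error"]
  expect_lt(abs(coef(fit)[["ws"]]), 2.5 * se) # CI covers zero
})

test_that("speed model rejects degenerate inputs", {
  segs1 <- make_segments(rep("only", 50), runif(50), runif(50), rnorm(50, 12))
  expect_error(fit_speed_model(segs1), "2 tracks")
  segs2 <- make_segments(rep(c("a", "b"), 25), rep(3, 50), runif(50), rnorm(50, 12))
  expect_error(fit_speed_model(segs2), "collinear.*ws")
})

test_that("AIC selection recovers the planted active level in one world", {
  cf <- synth_config(seed = 61, n_tracks = 8, duration_h = 15,
                     decouple_levels = TRUE, ar1_sd = 3, ar1_corr_h = 8,
                     spatial_amp = 2, spatial_wavelength_km = 500,
                     active_level = "750m", air_speed_sd_step = 0.5)
  w <- gen_world(cf)
  fits <- lapply(w$grid$level_names, function(l)
    fit_speed_model(annotate_tracks(w$tracks, w$grid, l), level = l))
  segs_max <- do.call(rbind, lapply(w$tracks, annotate_track_maxws, grid = w$grid))
  class(segs_max) <- c("segments", "data.frame")
  fits <- c(fits, list(fit_speed_model(segs_max, level = "maxWs")))
  sel <- select_flight_altitude(fits)
  expect_equal(sel$level, "750m")
  expect_equal(nrow(sel$delta_aic), 7)
  expect_equal(sel$delta_aic$delta_aic[1], 0)
})

test_that("altitude selection enforces its preconditions and tie rule", {
  set.seed(63)
  n <- 200
  ids <- rep(c("a", "b", "c", "d"), each = 50)
  ws <- runif(n, -5, 10); cw <- abs(rnorm(n, 0, 1))
  gs <- 12 + 0.7 * ws + rnorm(n, 0, 0.6)
  mk <- function(lev) fit_speed_model(make_segments(ids, ws, cw, gs), level = lev,
                                      method = "ols")
  # identical data at every level: AIC ties resolve to the lowest altitude
  fits <- lapply(c("10m", "100m", "750m", "1500m", "2250m", "3000m"), mk)
  fits <- c(fits, list(mk("maxWs")))
  sel <- select_flight_altitude(fits)
  expect_equal(sel$level, "10m")
  expect_true(all(abs(sel$delta_aic$delta_aic) < 1e-9))
  # missing maxWs fit
  expect_error(select_flight_altitude(fits[1:6]), "maxWs")
  # non-identical data
  other <- fit_speed_model(make_segments(ids[1:100], ws[1:100], cw[1:100],
                                         gs[1:100]), level = "maxWs",
                           method = "ols")
  expect_error(select_flight_altitude(c(fits[1:6], list(other))), "identical")
})

test_that("track-length model recovers planted slopes and drops thin classes", {
  set.seed(55)
  mk_world <- function(slope, n) {
    ws_half <- runif(n, -5, 10)
    len <- 1300 + slope * ws_half + rnorm(n, 0, 50)
    ids <- sprintf("t%03d", seq_len(n))
    summaries <- data.frame(id = ids, track_length_km = len,
                            straightness = 1.1, final_direction = 90)
    segs <- do.call(rbind, lapply(seq_len(n), function(i)
      make_segments(rep(ids[i], 10), rep(ws_half[i], 10), rep(0, 10),
                    rep(15, 10), distance_m = len[i] * 100))) # equal-length segments
    class(segs) <- c("segments", "data.frame")
    list(su = summaries, segs = segs)
  }
  wd <- mk_world(22, 80)
  fit <- fit_track_length_model(wd$su, wd$segs)
  expect_equal(fit$slope, 22, tolerance = 0.25 * 22)
  expect_equal(fit$n, 80)

  # planted null slope: CI covers zero
  wd0 <- mk_world(0, 80)
  fit0 <- fit_track_length_model(wd0$su, wd0$segs)
  expect_lt(abs(fit0$slope), 2.5 * fit0$slope_se)

  # a class with fewer than 3 tracks is dropped with a warning
  wd2 <- mk_world(22, 40)
  wd2$su$final_direction[1:2] <- 270
  expect_warning(fit2 <- fit_track_length_model(wd2$su, wd2$segs), "directed-west")
  expect_equal(fit2$n, 38)
})

test_that("direction models detect planted wind-direction coupling", {
  set.seed(57)
  n <- 40
  ids <- sprintf("t%03d", seq_len(n))
  nights <- rep(as.Date("2012-06-01") + 0:7, each = 5)
  wdir <- (rnorm(n, 80, 40)) %% 360
  wspeed <- runif(n, 2, 12)
  init <- (wdir + rnorm(n, 0, 8)) %% 360  # initial direction tracks the wind
  fin <- (init + rnorm(n, 0, 5)) %% 360
  summaries <- data.frame(id = ids, departure_day = nights,
                          initial_direction = init, final_direction = fin)
  segs <- do.call(rbind, lapply(seq_len(n), function(i) {
    u <- wspeed[i] * sin(wdir[i] * pi / 180)
    v <- wspeed[i] * cos(wdir[i] * pi / 180)
    make_segments(rep(ids[i], 6), rep(1, 6), rep(0, 6), rep(15, 6),
                  u = rep(u, 6), v = rep(v, 6))
  }))
  class(segs) <- c("segments", "data.frame")
  fits <- fit_direction_models(summaries, segs)
  expect_gt(fits$initial_vs_wind$circ_cor, 0.7)
  expect_gt(fits$final_vs_initial$circ_cor, 0.7)
  # final ~ initial slope near identity
  expect_equal(unname(fits$final_vs_initial$coefficients["init_u"]), 1,
               tolerance = 0.15)
  # degenerate and undersized inputs
  expect_error(fit_direction_models(summaries[1:5, ], segs), "10 tracks")
  bad <- summaries; bad$initial_direction <- 90
  expect_error(fit_direction_models(bad, segs), "identical")
})

test_that("wind-independent directions show no association", {
  set.seed(58)
  n <- 40
  ids <- sprintf("t%03d", seq_len(n))
  nights <- rep(as.Date("2012-06-01") + 0:7, each = 5)
  wdir <- runif(n, 0, 360); wspeed <- runif(n, 2, 12)
  init <- runif(n, 0, 360) # unrelated to wind
  summaries <- data.frame(id = ids, departure_day = nights,
                          initial_direction = init,
                          final_direction = (init + rnorm(n, 0, 5)) %% 360)
  segs <- do.call(rbind, lapply(seq_len(n), function(i) {
    u <- wspeed[i] * sin(wdir[i] * pi / 180); v <- wspeed[i] * cos(wdir[i] * pi / 180)
    make_segments(rep(ids[i], 6), rep(1, 6), rep(0, 6), rep(15, 6),
                  u = rep(u, 6), v = rep(v, 6))
  }))
  class(segs) <- c("segments", "data.frame")
  fits <- fit_direction_models(summaries, segs)
  expect_lt(abs(fits$initial_vs_wind$circ_cor), 0.35)
})
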