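# Regression layer: ground/air-speed mixed models per altitude level with
# AIC-based flight-altitude selection, the track-length-vs-wind-support
# model, and the direction models. Mixed fits use nlme (random per-track
# intercept, MA(1) residual correlation within track, ML estimation so AICs
# are comparable across the per-level covariate sets).

#' Fit a ground- or air-speed model at one altitude level
#'
#' Linear mixed-effect model `speed ~ ws * cw` (interaction optional) with a
#' per-track random intercept and an MA(1) within-track residual
#' correlation, fitted by maximum likelihood. When the mixed fit fails to
#' converge (or `method = "ols"`), it degrades to ordinary least squares
#' with the estimator recorded in the result.
#'
#' @param segments a `segments` data.frame from [annotate_tracks()] (must
#'   span at least 2 tracks)
#' @param level level name the segments were annotated at (recorded; taken
#'   from the data if missing)
#' @param response "ground" or "air" speed
#' @param interaction include the ws:cw interaction (default TRUE)
#' @param method "lme" (mixed model, default), "ols", or "auto" (lme with
#'   OLS fallback)
#' @return object of class `speed_fit` with elements `coefficients`, `aic`,
#'   `level`, `response`, `estimator`, `n`, `tracks`, `re_sd`, `ma1`,
#'   `sigma`, `model`
#' @export
fit_speed_model <- function(segments, level = NULL,
                            response = c("ground", "air"),
                            interaction = TRUE,
                            method = c("auto", "lme", "ols")) {
  response <- match.arg(response)
  method <- match.arg(method)
  level <- level %||% unique(segments$level)
  if (length(level) != 1) stop("segments span multiple levels; fit one at a time")
  d <- data.frame(
    y = if (response == "ground") segments$ground_speed else segments$air_speed,
    ws = segments$ws, cw = segments$cw,
    track = factor(segments$track)
  )
  d <- d[is.finite(d$y), , drop = FALSE]
  if (nlevels(droplevels(d$track)) < 2) {
    stop("speed model needs segments from at least 2 tracks (random effect unidentifiable)")
  }
  if (stats::sd(d$ws) < 1e-10) stop("collinear term: wind support (ws) is constant")
  if (stats::sd(d$cw) < 1e-10 && interaction) {
    stop("collinear term: crosswind (cw) is constant; drop the interaction")
  }
  d$seg <- stats::ave(seq_len(nrow(d)), d$track, FUN = seq_along)
  form <- if (interaction) y ~ ws * cw else y ~ ws + cw
  fit <- NULL; estimator <- "lme"
  if (method != "ols") {
    fit <- tryCatch(
      nlme::lme(form, random = ~ 1 | track, data = d,
                correlation = nlme::corARMA(form = ~ seg | track, q = 1),
                method = "ML",
                control = nlme::lmeControl(opt = "optim", maxIter = 100,
                                           msMaxIter = 100, returnObject = FALSE)),
      error = function(e) NULL
    )
    if (is.null(fit) && method == "lme") stop("mixed speed model failed to converge")
  }
  if (is.null(fit)) {
    fit <- stats::lm(form, data = d)
    estimator <- "ols"
  }
  cf <- if (estimator == "lme") nlme::fixef(fit) else stats::coef(fit)
  re_sd <- if (estimator == "lme") {
    as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"])
  } else NA_real_
  ma1 <- if (estimator == "lme") {
    cs <- fit$modelStruct$corStruct
    if (!is.null(cs)) as.numeric(stats::coef(cs, unconstrained = FALSE)) else NA_real_
  } else NA_real_
  structure(
    list(coefficients = cf, aic = stats::AIC(fit), level = level,
         response = response, estimator = estimator, n = nrow(d),
         tracks = sort(unique(as.character(d$track))),
         re_sd = re_sd, ma1 = ma1,
         sigma = if (estimator == "lme") fit$sigma else summary(fit)$sigma,
         interaction = interaction, model = fit),
    class = "speed_fit"
  )
}

#' @export
print.speed_fit <- function(x, ...) {
  cat("<speed_fit>", x$response, "speed at", x$level,
      sprintf("(%s, n = %d segments, %d tracks)\n", x$estimator, x$n, length(x$tracks)))
  print(round(x$coefficients, 4))
  cat("AIC:", round(x$aic, 2), " sigma:", round(x$sigma, 3))
  if (!is.na(x$re_sd)) cat("  track-intercept sd:", round(x$re_sd, 3))
  if (!is.na(x$ma1)) cat("  MA(1):", round(x$ma1, 3))
  cat("\n")
  invisible(x)
}

#' @export
coef.speed_fit <- function(object, ...) object$coefficients

#' Predict speed from the fixed effects of a speed model
#'
#' Population-level prediction (fixed effects only): the counterfactual
#' "generic bird".
#'
#' @param object a `speed_fit`
#' @param newdata data.frame with columns `ws`, `cw`
#' @param ... unused
#' @return numeric vector of predicted speeds (m/s)
#' @export
predict.speed_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  out <- cf[["(Intercept)"]] + cf[["ws"]] * newdata$ws + cf[["cw"]] * newdata$cw
  if ("ws:cw" %in% names(cf)) out <- out + cf[["ws:cw"]] * newdata$ws * newdata$cw
  unname(out)
}

#' Select the most likely flight altitude by AIC
#'
#' Given speed-model fits at each fixed altitude plus the maxWs (hourly best
#' altitude) assignment - all on identical segment sets - returns the level
#' with the lowest AIC; ties go to the lower altitude, with maxWs ranked
#' above every fixed level.
#'
#' @param fits list of `speed_fit` objects, exactly one with level "maxWs"
#' @return list of class `altitude_selection`: `level` (winner), `delta_aic`
#'   (data.frame sorted by AIC)
#' @export
select_flight_altitude <- function(fits) {
  if (length(fits) < 3) stop("need fits for the fixed levels plus maxWs")
  levs <- vapply(fits, function(f) f$level, "")
  if (sum(levs == "maxWs") != 1) {
    stop("need exactly one fit at the 'maxWs' assignment (got ", sum(levs == "maxWs"), ")")
  }
  if (anyDuplicated(levs)) stop("duplicate level fits supplied")
  ns <- vapply(fits, function(f) f$n, 0)
  trs <- lapply(fits, function(f) f$tracks)
  if (length(unique(ns)) != 1 || !all(vapply(trs, identical, TRUE, y = trs[[1]]))) {
    stop("fits are not on identical data (different n or track sets)")
  }
  height <- suppressWarnings(as.numeric(sub("m$", "", levs)))
  height[levs == "maxWs"] <- Inf # fixed level wins an exact AIC tie
  aic <- vapply(fits, function(f) f$aic, 0)
  ord <- order(aic, height)
  tab <- data.frame(level = levs[ord], aic = aic[ord],
                    delta_aic = aic[ord] - min(aic))
  structure(list(level = tab$level[1], delta_aic = tab), class = "altitude_selection")
}

#' @export
print.altitude_selection <- function(x, ...) {
  cat("<altitude_selection> best level:", x$level, "\n")
  print(transform(x$delta_aic, aic = round(aic, 2), delta_aic = round(delta_aic, 2)),
        row.names = FALSE)
  invisible(x)
}

# Per-track mean wind support over the first `fraction` of the track length
# (segments until cumulative length reaches it; crossing segment included).
mean_ws_first_fraction <- function(segments, fraction = 0.5) {
  vapply(split(segments, segments$track), function(s) {
    cum <- cumsum(s$distance_m)
    k <- which(cum >= fraction * cum[length(cum)])[1]
    mean(s$ws[seq_len(k)])
  }, 0)
}

# Per-track mean wind support over the first `km` kilometres.
mean_ws_first_km <- function(segments, km = 50) {
  vapply(split(segments, segments$track), function(s) {
    cum <- cumsum(s$distance_m)
    k <- which(cum >= km * 1000)[1]
    if (is.na(k)) k <- nrow(s)
    mean(s$ws[seq_len(k)])
  }, 0)
}

#' Track length versus wind support
#'
#' Linear model of over-ocean track length on the mean wind support during
#' the first half of the track, controlling for flight class (east / west /
#' loop intercepts). Classes represented by fewer than `min_per_class`
#' tracks are dropped with a warning.
#'
#' @param summaries data.frame from [summarize_tracks()]; a `class` column
#'   is added via [classify_flight()] if absent
#' @param segments `segments` for the same tracks (annotated at the analysis
#'   level)
#' @param min_per_class minimum tracks per class (default 3)
#' @return object of class `tracklen_fit`: `slope` (km per m/s), `slope_se`,
#'   `intercepts`, `n`, `dropped`, `model`, `data`
#' @export
fit_track_length_model <- function(summaries, segments, min_per_class = 3) {
  s <- as.data.frame(summaries)
  if (!"class" %in% names(s)) s$class <- classify_flight(s)
  wsh <- mean_ws_first_fraction(segments, 0.5)
  s$ws_half <- wsh[match(s$id, names(wsh))]
  if (any(is.na(s$ws_half))) stop("segments missing for some summarized tracks")
  tab <- table(s$class)
  drop <- names(tab)[tab < min_per_class]
  if (length(drop)) {
    warning("dropping class(es) with < ", min_per_class, " tracks: ",
            paste(drop, collapse = ", "))
    s <- s[!s$class %in% drop, , drop = FALSE]
  }
  if (nrow(s) < min_per_class) stop("too few tracks left to fit")
  s$class <- factor(s$class)
  form <- if (nlevels(s$class) > 1) track_length_km ~ ws_half + class else
    track_length_km ~ ws_half
  m <- stats::lm(form, data = s)
  sm <- summary(m)
  structure(
    list(slope = unname(stats::coef(m)["ws_half"]),
         slope_se = sm$coefficients["ws_half", "Std. Error"],
         intercepts = stats::coef(m)[names(stats::coef(m)) != "ws_half"],
         n = nrow(s), dropped = drop, model = m, data = s),
    class = "tracklen_fit"
  )
}

#' @export
print.tracklen_fit <- function(x, ...) {
  cat("<tracklen_fit> n =", x$n, "tracks\n")
  cat(sprintf("  slope: %.2f km per m/s wind support (SE %.2f)\n", x$slope, x$slope_se))
  print(round(x$intercepts, 1))
  if (length(x$dropped)) cat("  dropped classes:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Direction models: wind vs initial direction, initial vs final
#'
#' Two mixed models with a departure-night random intercept: (1) initial
#' flight direction (mean over the first 50 km) on the interaction of mean
#' wind direction and wind speed over the same stretch; (2) final direction
#' (departure-to-arrival bearing) on initial direction. Directions are
#' angular; before linear fitting each is unwrapped onto a continuous scale
#' centred on its night's mean direction, and a circular correlation
#' coefficient is reported alongside as a scale-free diagnostic. With only
#' one night (or a singular random effect) the fits fall back to ordinary
#' least squares, recorded in `estimator`.
#'
#' @param summaries data.frame from [summarize_tracks()] (>= 10 tracks)
#' @param segments matching `segments` data.frame
#' @param initial_km stretch over which wind is averaged (default 50)
#' @return list of class `direction_fits`: `initial_vs_wind`,
#'   `final_vs_initial` (each: coefficients, circ_cor, estimator, model),
#'   `n`
#' @export
fit_direction_models <- function(summaries, segments, initial_km = 50) {
  s <- as.data.frame(summaries)
  if (nrow(s) < 10) stop("need at least 10 tracks")
  if (max(table(s$initial_direction)) == nrow(s) ||
      stats::sd(ang_diff(s$initial_direction, s$initial_direction[1])) < 1e-9) {
    stop("degenerate input: all initial directions identical")
  }
  uvm <- t(vapply(split(segments, segments$track), function(g) {
    cum <- cumsum(g$distance_m)
    k <- which(cum >= initial_km * 1000)[1]
    if (is.na(k)) k <- nrow(g)
    c(mean(g$u[seq_len(k)]), mean(g$v[seq_len(k)]))
  }, c(0, 0)))
  mi <- match(s$id, rownames(uvm))
  s$wind_speed <- sqrt(uvm[mi, 1]^2 + uvm[mi, 2]^2)
  s$wind_dir <- wrap360(rad2deg(atan2(uvm[mi, 1], uvm[mi, 2])))
  s$night <- factor(as.character(s$departure_day))
  centre <- tapply(s$initial_direction, s$night, circ_mean)
  cen <- as.numeric(centre[s$night])
  s$init_u <- unwrap_deg(s$initial_direction, cen)
  s$final_u <- unwrap_deg(s$final_direction, cen)
  s$wdir_u <- unwrap_deg(s$wind_dir, cen)

  fit_one <- function(form) {
    est <- "lme"
    m <- if (nlevels(droplevels(s$night)) >= 3) {
      tryCatch(nlme::lme(form, random = ~ 1 | night, data = s, method = "ML",
                         control = nlme::lmeControl(opt = "optim", returnObject = TRUE)),
               error = function(e) NULL)
    } else NULL
    if (is.null(m)) { m <- stats::lm(form, data = s); est <- "ols" }
    cf <- if (est == "lme") nlme::fixef(m) else stats::coef(m)
    list(coefficients = cf, estimator = est, model = m)
  }
  m1 <- fit_one(init_u ~ wdir_u * wind_speed)
  m2 <- fit_one(final_u ~ init_u)
  m1$circ_cor <- circ_cor(s$initial_direction, s$wind_dir)
  m2$circ_cor <- circ_cor(s$final_direction, s$initial_direction)
  structure(list(initial_vs_wind = m1, final_vs_initial = m2, n = nrow(s)),
            class = "direction_fits")
}

#' @export
print.direction_fits <- function(x, ...) {
  cat("<direction_fits> n =", x$n, "tracks\n")
  cat("  initial ~ wind-direction x speed (", x$initial_vs_wind$estimator, ")\n", sep = "")
  print(round(x$initial_vs_wind$coefficients, 4))
  cat("  circular cor(initial, wind):", round(x$initial_vs_wind$circ_cor, 3), "\n")
  cat("  final ~ initial (", x$final_vs_initial$estimator, ")\n", sep = "")
  print(round(x$final_vs_initial$coefficients, 4))
  cat("  circular cor(final, initial):", round(x$final_vs_initial$circ_cor, 3), "\n")
  invisible(x)
}
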