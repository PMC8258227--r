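# Per-fix DB-vs-GPS discrepancies and the error regressions.

#' Pair a DB track with a GPS track and score per-fix errors
#'
#' For each active step, computes the signed distance error (GPS minus DB, so
#' positive means the GPS-measured distance is larger) and the absolute
#' circular bearing error in `[0, 180]` degrees. Passive steps — those whose
#' DB-measured distance falls below `passive_threshold`, or whose arriving DB
#' fix carries `active = FALSE` — are excluded: measurement errors can only be
#' computed from active fixes. Bearing errors are additionally `NA` when
#' either method's step is zero-length (undefined azimuth).
#'
#' @param db_track,gps_track Fix data.frames for one track each, with equal
#'   fix counts and matching orders.
#' @param passive_threshold Passive cutoff in meters (default 0.5).
#' @return Data.frame of error records: `track_id, fix_order, db_distance,
#'   gps_distance, distance_error, db_bearing, gps_bearing, bearing_error`.
#' @export
pair_and_score <- function(db_track, gps_track, passive_threshold = 0.5) {
  db_track <- db_track[order(db_track$order), ]
  gps_track <- gps_track[order(gps_track$order), ]
  if (nrow(db_track) != nrow(gps_track))
    stop(sprintf("fix count mismatch between tracks '%s' (%d) and '%s' (%d)",
                 db_track$track_id[1], nrow(db_track),
                 gps_track$track_id[1], nrow(gps_track)))
  sdb <- coords_to_steps(db_track$lon, db_track$lat)
  sgps <- coords_to_steps(gps_track$lon, gps_track$lat)
  n <- length(sdb$step_lengths)
  if (n == 0) return(empty_error_records())
  active <- sdb$step_lengths >= passive_threshold
  if ("active" %in% names(db_track))
    active <- active & db_track$active[-1]
  rec <- data.frame(track_id = gps_track$track_id[1],
                    fix_order = seq_len(n),
                    db_distance = sdb$step_lengths,
                    gps_distance = sgps$step_lengths,
                    distance_error = sgps$step_lengths - sdb$step_lengths,
                    db_bearing = sdb$abs_azimuths,
                    gps_bearing = sgps$abs_azimuths,
                    stringsAsFactors = FALSE)
  rec$bearing_error <- ifelse(
    is.na(rec$db_bearing) | is.na(rec$gps_bearing), NA_real_,
    circular_error_deg(rec$db_bearing, rec$gps_bearing))
  rec[active, , drop = FALSE]
}

empty_error_records <- function() {
  data.frame(track_id = character(0), fix_order = integer(0),
             db_distance = numeric(0), gps_distance = numeric(0),
             distance_error = numeric(0), db_bearing = numeric(0),
             gps_bearing = numeric(0), bearing_error = numeric(0),
             stringsAsFactors = FALSE)
}

#' Summarize error records
#'
#' Headline means and standard errors of the mean (SEM = sample SD / sqrt(n))
#' for signed distance error and absolute bearing error, plus per-track total
#' lengths under each method.
#'
#' @param records Error-record data.frame from [pair_and_score()] (>= 1 row;
#'   possibly concatenated over tracks).
#' @return List with `n`, `mean_distance_error`, `sem_distance_error`,
#'   `n_bearing`, `mean_bearing_error`, `sem_bearing_error`, and `per_track`
#'   (data.frame of per-track DB and GPS totals). SEMs are `NA` when n < 2.
#' @export
summarize_errors <- function(records) {
  if (nrow(records) == 0) stop("no error records to summarize")
  sem <- function(x) if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  be <- records$bearing_error[!is.na(records$bearing_error)]
  per_track <- aggregate(cbind(db_total = db_distance,
                               gps_total = gps_distance) ~ track_id,
                         data = records, FUN = sum)
  list(n = nrow(records),
       mean_distance_error = mean(records$distance_error),
       sem_distance_error = sem(records$distance_error),
       n_bearing = length(be),
       mean_bearing_error = if (length(be)) mean(be) else NA_real_,
       sem_bearing_error = if (length(be)) sem(be) else NA_real_,
       per_track = per_track)
}

#' Pearson correlation of paired DB and GPS coordinates
#'
#' Correlates the longitude and latitude coordinate vectors of paired fixes
#' (aligned row-for-row) between the two recording methods, with the usual
#' t statistic on n - 2 degrees of freedom.
#'
#' @param db_fixes,gps_fixes Fix data.frames with equal row counts, aligned.
#' @return Data.frame with rows `lon` and `lat`: `r`, `t`, `df`, `p`.
#' @export
coordinate_correlation <- function(db_fixes, gps_fixes) {
  if (nrow(db_fixes) != nrow(gps_fixes)) stop("unequal numbers of paired fixes")
  if (nrow(db_fixes) < 3) stop("need at least 3 paired fixes")
  one <- function(a, b, label) {
    if (sd(a) == 0 || sd(b) == 0) {
      warning("degenerate (zero-variance) coordinates for ", label)
      return(data.frame(axis = label, r = NA_real_, t = NA_real_,
                        df = length(a) - 2, p = NA_real_))
    }
    ct <- cor.test(a, b, method = "pearson")
    data.frame(axis = label, r = unname(ct$estimate),
               t = unname(ct$statistic), df = unname(ct$parameter),
               p = ct$p.value)
  }
  rbind(one(db_fixes$lon, gps_fixes$lon, "lon"),
        one(db_fixes$lat, gps_fixes$lat, "lat"))
}

#' Gaussian random-intercept mixed model for a per-record error response
#'
#' Fits `response ~ predictor + (1 | group)` with lme4, the standard
#' single-argument error regression: REML for the reported variance
#' components, ML refits for the likelihood-ratio test of the fixed effect
#' against the intercept-only model. Marginal and conditional R-squared follow
#' the Nakagawa–Schielzeth variance decomposition
#' (`R2m = var_f / (var_f + var_re + var_resid)`,
#' `R2c = (var_f + var_re) / (same)`).
#'
#' @param data Data.frame holding the three columns named below.
#' @param response,predictor,group Column names (strings).
#' @param categorical If `TRUE`, the predictor enters as a factor (used for
#'   bearing-as-predictor models, where the 30-degree units form a 12-level
#'   categorical factor and the LRT has 11 df).
#' @param min_records Minimum number of complete records required
#'   (default 10; per-track summaries such as total lengths use fewer).
#' @return Object of class `mixed_model_result`: a list with `estimate`, `se`
#'   (first non-intercept coefficient; `NA` for factors), `var_intercept`,
#'   `var_residual`, `chi_sq`, `df`, `p_value`, `marginal_R2`,
#'   `conditional_R2`, `singular`, `n`, `formula`.
#' @export
fit_error_lmm <- function(data, response, predictor, group,
                          categorical = FALSE, min_records = 10) {
  data <- data[complete.cases(data[, c(response, predictor, group)]), ]
  if (length(unique(data[[group]])) < 2) stop("need >= 2 groups")
  if (nrow(data) < min_records)
    stop(sprintf("need >= %d records", min_records))
  if (categorical) data[[predictor]] <- factor(data[[predictor]])
  f_full <- as.formula(sprintf("%s ~ %s + (1 | %s)", response, predictor, group))
  f_null <- as.formula(sprintf("%s ~ 1 + (1 | %s)", response, group))
  m_reml <- lme4::lmer(f_full, data = data, REML = TRUE)
  m_full <- lme4::lmer(f_full, data = data, REML = FALSE)
  m_null <- lme4::lmer(f_null, data = data, REML = FALSE)
  lrt <- 2 * (as.numeric(logLik(m_full)) - as.numeric(logLik(m_null)))
  df <- attr(logLik(m_full), "df") - attr(logLik(m_null), "df")
  fe <- lme4::fixef(m_reml)
  se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(m_reml)))),
                 error = function(e) rep(NA_real_, length(fe)))
  r2 <- nakagawa_r2(m_reml)
  structure(list(
    estimate = if (categorical) NA_real_ else unname(fe[2]),
    se = if (categorical) NA_real_ else unname(se[2]),
    fixef = fe,
    var_intercept = r2$var_re, var_residual = r2$var_resid,
    chi_sq = max(lrt, 0), df = df,
    p_value = pchisq(max(lrt, 0), df, lower.tail = FALSE),
    marginal_R2 = r2$R2m, conditional_R2 = r2$R2c,
    singular = lme4::isSingular(m_reml), n = nrow(data),
    formula = deparse(f_full)), class = "mixed_model_result")
}

# Nakagawa & Schielzeth R2 for a Gaussian random-intercept lmer fit.
nakagawa_r2 <- function(m) {
  var_f <- var(as.vector(stats::model.matrix(m) %*% lme4::fixef(m)))
  vc <- lme4::VarCorr(m)
  var_re <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  var_resid <- attr(vc, "sc")^2
  denom <- var_f + var_re + var_resid
  list(var_f = var_f, var_re = max(var_re, 0), var_resid = var_resid,
       R2m = var_f / denom, R2c = (var_f + var_re) / denom)
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(x$formula, "\n")
  cat(sprintf("  chi^2 = %.3f, df = %d, p = %.4g | R2m = %.3f, R2c = %.3f%s\n",
              x$chi_sq, x$df, x$p_value, x$marginal_R2, x$conditional_R2,
              if (isTRUE(x$singular)) " [singular fit]" else ""))
  if (!is.na(x$estimate))
    cat(sprintf("  fixed effect: %.4f (SE %.4f)\n", x$estimate, x$se))
  invisible(x)
}

#' Compare total trajectory lengths between recording methods
#'
#' Per-track total length (sum of all step lengths) modeled with recording
#' method as the fixed effect and the underlying trajectory design as the
#' random intercept: `total ~ method + (1 | design)`.
#'
#' @param db_fixes,gps_fixes Fix data.frames (multiple tracks). If a
#'   `design_id` column is present it groups paired tracks; otherwise each
#'   GPS track id is mapped to its design by stripping a `_r<k>` repeat
#'   suffix.
#' @return A `mixed_model_result` (estimate = GPS minus DB mean difference in
#'   meters), with the per-track totals in `$totals`.
#' @export
total_length_comparison <- function(db_fixes, gps_fixes) {
  totals_of <- function(fx, method) {
    ids <- unique(fx$track_id)
    data.frame(
      track_id = ids,
      design = if ("design_id" %in% names(fx))
        fx$design_id[match(ids, fx$track_id)]
      else sub("_r[0-9]+$", "", ids),
      method = method,
      total = vapply(ids, function(id) {
        tr <- fx[fx$track_id == id, ]
        sum(coords_to_steps(tr$lon[order(tr$order)],
                            tr$lat[order(tr$order)])$step_lengths)
      }, numeric(1)), stringsAsFactors = FALSE)
  }
  totals <- rbind(totals_of(db_fixes, "DB"), totals_of(gps_fixes, "GPS"))
  totals$method <- factor(totals$method, levels = c("DB", "GPS"))
  res <- fit_error_lmm(totals, "total", "method", "design", min_records = 6)
  res$totals <- totals
  res
}
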