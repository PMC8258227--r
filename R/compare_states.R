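# Decoded movement-state composition: counts and the binomial GLMM.

#' Count decoded movement states per track
#'
#' @param decoded Either a data.frame with columns `track_id, method, state`
#'   (one row per decoded step, states 1 = random walk, 2 = directed) or a
#'   named list of integer state vectors plus a `method` string.
#' @param method Method label used when `decoded` is a list.
#' @return Data.frame `track_id, method, n_random_walk, n_directed`.
#' @export
count_states <- function(decoded, method = NULL) {
  if (is.list(decoded) && !is.data.frame(decoded)) {
    if (is.null(method)) stop("supply `method` when passing a list of decodes")
    if (is.null(names(decoded)))
      names(decoded) <- paste0("track", seq_along(decoded))
    decoded <- do.call(rbind, lapply(names(decoded), function(id)
      data.frame(track_id = id, method = method, state = decoded[[id]],
                 stringsAsFactors = FALSE)))
  }
  stopifnot(all(decoded$state %in% 1:2))
  out <- do.call(rbind, lapply(split(decoded, decoded[c("track_id", "method")],
                                     drop = TRUE), function(d)
    data.frame(track_id = d$track_id[1], method = d$method[1],
               n_random_walk = sum(d$state == 1),
               n_directed = sum(d$state == 2), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Binomial GLMM comparing state proportions between recording methods
#'
#' Models the per-track two-column outcome `[random walk, directed]` with a
#' logit link, recording method as the fixed effect and the underlying track
#' (design) as a random intercept, using the Laplace approximation. The
#' likelihood-ratio test compares against the intercept-only model. Also
#' reports the raw difference in the pooled proportion of random walk
#' (DB minus GPS) in percentage points.
#'
#' @param counts Data.frame from [count_states()]; an optional `design`
#'   column groups paired tracks, otherwise designs are derived from
#'   `track_id` by stripping a `_r<k>` suffix.
#' @return List of class `state_comparison`: `estimate` (logit-scale method
#'   coefficient, GPS vs DB), `chi_sq`, `df`, `p_value`, `marginal_R2`,
#'   `conditional_R2` (theoretical logit distribution variance pi^2/3),
#'   `prop_db`, `prop_gps`, `prop_diff_pp`, `singular`, `n_tracks`.
#' @export
compare_proportions <- function(counts) {
  if (!"design" %in% names(counts))
    counts$design <- sub("_r[0-9]+$", "", counts$track_id)
  if (any(table(counts$method) < 2)) stop("need >= 2 tracks per method")
  counts$method <- factor(counts$method, levels = c("DB", "GPS"))
  m_full <- lme4::glmer(cbind(n_random_walk, n_directed) ~ method + (1 | design),
                        data = counts, family = stats::binomial())
  m_null <- lme4::glmer(cbind(n_random_walk, n_directed) ~ 1 + (1 | design),
                        data = counts, family = stats::binomial())
  lrt <- 2 * (as.numeric(logLik(m_full)) - as.numeric(logLik(m_null)))
  df <- attr(logLik(m_full), "df") - attr(logLik(m_null), "df")
  fe <- lme4::fixef(m_full)
  var_f <- var(as.vector(stats::model.matrix(m_full) %*% fe))
  var_re <- sum(vapply(lme4::VarCorr(m_full), function(v) v[1, 1], numeric(1)))
  var_d <- pi^2 / 3  # theoretical logit-link distribution variance
  denom <- var_f + var_re + var_d
  pooled <- function(meth) {
    d <- counts[counts$method == meth, ]
    sum(d$n_random_walk) / sum(d$n_random_walk + d$n_directed)
  }
  p_db <- pooled("DB"); p_gps <- pooled("GPS")
  structure(list(estimate = unname(fe["methodGPS"]),
                 chi_sq = max(lrt, 0), df = df,
                 p_value = pchisq(max(lrt, 0), df, lower.tail = FALSE),
                 marginal_R2 = var_f / denom,
                 conditional_R2 = (var_f + var_re) / denom,
                 prop_db = p_db, prop_gps = p_gps,
                 prop_diff_pp = 100 * (p_db - p_gps),
                 singular = lme4::isSingular(m_full),
                 n_tracks = nrow(counts)),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat("Proportion of random walk ~ recording method (binomial GLMM)\n")
  cat(sprintf("  chi^2 = %.3f, df = %d, p = %.4g | R2m = %.3f, R2c = %.3f\n",
              x$chi_sq, x$df, x$p_value, x$marginal_R2, x$conditional_R2))
  cat(sprintf("  random walk: DB %.1f%%, GPS %.1f%% (DB - GPS = %.2f pp)%s\n",
              100 * x$prop_db, 100 * x$prop_gps, x$prop_diff_pp,
              if (isTRUE(x$singular)) " [singular fit]" else ""))
  invisible(x)
}
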