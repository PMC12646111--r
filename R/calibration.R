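#' Country-specific Tier 1 emission-factor calibration
#'
#' Given per-reservoir pathway fluxes predicted by the empirical model, a
#' country-specific Tier 1 table is refit by ordinary least squares on
#' climate-zone indicator variables (no global intercept).  Because the
#' indicators are disjoint, the OLS solution for each zone is exactly the
#' arithmetic mean of the fluxes of reservoirs in that zone; zones absent
#' from the data yield absent table cells.
#'
#' @param samples Calibration sample table: columns `id`, `zone`,
#'   `res_type` and one flux column per pathway
#'   (`co2_diffusive`, ..., `ch4_degassing`), gCO2e/m2/yr.
#' @param subset `"all"` keeps every reservoir; `"hp_only"` keeps
#'   hydroelectric plus multipurpose reservoirs (the predominantly
#'   hydropower subset).
#' @return A fitted [ef_table()] with per-cell `n`.
#' @export
fit_zone_efs <- function(samples, subset = c("all", "hp_only")) {
  subset <- match.arg(subset)
  samples <- calibration_subset(samples, subset)
  zones <- sort(unique(samples$zone))
  rows <- list()
  zf <- factor(samples$zone, levels = zones)
  # disjoint zone indicator design (no global intercept)
  X <- vapply(zones, function(z) as.numeric(samples$zone == z),
              numeric(nrow(samples)))
  X <- matrix(X, nrow = nrow(samples))
  for (p in emission_pathways()) {
    y <- samples[[p]]
    # OLS on the indicators; coefficients are the per-zone means.
    fit <- stats::lm.fit(X, y)
    ef <- fit$coefficients
    cnt <- as.integer(table(zf))
    rows[[p]] <- data.frame(zone = zones, pathway = p,
                            flux = pmax(unname(ef), 0),
                            n = cnt, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  ef_table(all$zone, all$pathway, all$flux, n = all$n, provenance = "fitted")
}

calibration_subset <- function(samples, subset) {
  need <- c("id", "zone", "res_type", emission_pathways())
  check_columns(samples, need, "calibration sample")
  samples$zone <- canonical_zone(samples$zone)
  if (subset == "hp_only") {
    samples <- samples[samples$res_type %in% c("hydroelectric", "multipurpose"),
                       , drop = FALSE]
  }
  if (nrow(samples) == 0L) {
    abort("no calibration samples left after subsetting", "resghg_empty_subset")
  }
  samples
}

#' Bootstrap margins of error for fitted emission factors
#'
#' Resamples reservoirs with replacement `n_boot` times, refits the
#' zone-indicator regression on each resample and reports, per (zone,
#' pathway) cell, half the width of the percentile 95% confidence interval
#' of the refitted factor.  Deterministic for a fixed seed.  Cells whose
#' zone vanishes from more than half of the resamples are flagged
#' `unreliable` (and a `resghg_degenerate_cell` warning is raised).
#'
#' @inheritParams fit_zone_efs
#' @param n_boot Number of bootstrap resamples (>= 2; 1000 by default).
#' @param seed Integer seed for the resampling.
#' @param level Confidence level (default 0.95).
#' @param method `"percentile"` (default) or `"normal"` (mean +/- z * sd)
#'   interval construction.
#' @return A fitted [ef_table()] with `margin`, `n` and a logical
#'   `unreliable` column.
#' @export
bootstrap_margins <- function(samples, n_boot = 1000, seed = 1L,
                              subset = c("all", "hp_only"), level = 0.95,
                              method = c("percentile", "normal")) {
  subset <- match.arg(subset)
  method <- match.arg(method)
  stopifnot_number(n_boot, "n_boot", min = 2)
  samples <- calibration_subset(samples, subset)
  point <- fit_zone_efs(samples, "all")  # already subset above
  zones <- sort(unique(samples$zone))
  pw <- emission_pathways()
  n <- nrow(samples)
  zf <- factor(samples$zone, levels = zones)
  ymat <- as.matrix(samples[pw])

  set.seed(as.integer(seed))
  boots <- array(NA_real_, dim = c(n_boot, length(zones), length(pw)),
                 dimnames = list(NULL, zones, pw))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    zb <- zf[idx]
    cnt <- tabulate(zb, nbins = length(zones))
    sums <- rowsum(ymat[idx, , drop = FALSE], zb, reorder = FALSE)
    # rowsum drops empty levels; align back to the full zone set
    means <- matrix(NA_real_, length(zones), length(pw),
                    dimnames = list(zones, pw))
    means[rownames(sums), ] <- sums / cnt[match(rownames(sums), zones)]
    boots[b, , ] <- means
  }

  alpha <- (1 - level) / 2
  out <- as.data.frame(point)
  out$margin <- NA_real_
  out$unreliable <- FALSE
  for (i in seq_len(nrow(out))) {
    draws <- boots[, out$zone[i], out$pathway[i]]
    present <- !is.na(draws)
    if (mean(present) < 0.5) {
      warn(sprintf("zone '%s' vanished from %.0f%% of resamples; margin unreliable",
                   out$zone[i], 100 * mean(!present)),
           "resghg_degenerate_cell")
      out$unreliable[i] <- TRUE
    }
    d <- draws[present]
    if (length(d) >= 2L) {
      if (method == "percentile") {
        ci <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE, type = 7)
      } else {
        z <- stats::qnorm(1 - alpha)
        ci <- mean(d) + c(-1, 1) * z * stats::sd(d)
      }
      out$margin[i] <- (ci[2] - ci[1]) / 2
    }
  }
  tab <- ef_table(out$zone, out$pathway, out$flux, margin = out$margin,
                  n = out$n, provenance = "fitted")
  tab$unreliable <- out$unreliable
  attr(tab, "n_boot") <- n_boot
  attr(tab, "ci") <- {
    ci_lo <- ci_hi <- numeric(nrow(out))
    for (i in seq_len(nrow(out))) {
      d <- boots[, out$zone[i], out$pathway[i]]
      d <- d[!is.na(d)]
      q <- if (length(d) >= 2L) {
        if (method == "percentile")
          stats::quantile(d, c(alpha, 1 - alpha), names = FALSE, type = 7)
        else mean(d) + c(-1, 1) * stats::qnorm(1 - alpha) * stats::sd(d)
      } else c(NA_real_, NA_real_)
      ci_lo[i] <- q[1]; ci_hi[i] <- q[2]
    }
    data.frame(zone = out$zone, pathway = out$pathway,
               lower = ci_lo, upper = ci_hi)
  }
  tab
}

#' Calibrate net-conversion parameters against model output
#'
#' Fits the bilinear net-emission relation
#' `net = (net_co2 * f_co2 + net_ch4 * f_ch4) * (1 + r)` to paired
#' per-reservoir gross fluxes and target net emissions.  Because the
#' relation is bilinear, `r_downstream` is profiled over a finite grid: for
#' each candidate `r` the two proportions are solved by least squares, and
#' the triple with the smallest residual sum of squares is returned (ties
#' broken by the smallest `r`).  Note that only the products
#' `net_co2 * (1 + r)` and `net_ch4 * (1 + r)` are identifiable from the
#' data; the tie-break therefore reports the most conservative downstream
#' ratio consistent with the fit, and the fitted relation itself (the
#' predicted net fluxes) is unique.
#'
#' @param f_co2,f_ch4 Gross areal CO2 / CH4 fluxes per reservoir.
#' @param target_net Target net areal emissions (e.g. from the empirical
#'   model), same length.
#' @param r_grid Finite candidate values for `r_downstream` (>= 0).
#' @return A [net_conversion_params()] with attributes `rss` and `fit`.
#' @section Errors: `resghg_rank_deficient` when the flux columns are
#'   collinear.
#' @export
calibrate_net_params <- function(f_co2, f_ch4, target_net, r_grid) {
  stopifnot(length(f_co2) == length(f_ch4),
            length(f_co2) == length(target_net))
  if (!length(r_grid) || any(!is.finite(r_grid)) || any(r_grid < 0)) {
    abort("r_grid must be a finite set of values >= 0", "resghg_bad_argument")
  }
  X <- cbind(f_co2, f_ch4)
  if (qr(X)$rank < 2L) {
    abort("f_co2 and f_ch4 are collinear; net proportions unidentifiable",
          "resghg_rank_deficient")
  }
  r_grid <- sort(unique(as.numeric(r_grid)))
  best <- NULL
  for (r in r_grid) {
    # net = (1+r) * (a*f_co2 + b*f_ch4): scale the design, solve for (a, b),
    # then project onto the physical box [-1, 1] before scoring
    fit <- stats::lm.fit(X * (1 + r), target_net)
    ab <- pmin(1, pmax(-1, unname(fit$coefficients)))
    rss <- sum((target_net - (1 + r) * (X %*% ab))^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(r = r, coef = ab, rss = rss)
    }
  }
  p <- net_conversion_params(best$coef[1], best$coef[2], best$r,
                             calibrated = TRUE)
  attr(p, "rss") <- best$rss
  p
}
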