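## Goodness-of-fit statistics for observed-vs-predicted trait series, the
## rRMSE accuracy bands, the missing-value weighting adjustment, and the
## image quantity x quality grid experiment.

check_series <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length")
  if (length(observed) < 2)
    stop("need at least 2 observations")
  if (any(is.na(observed)) || any(is.na(predicted)))
    stop("series must be complete; drop missing pairs first and count them as 'mv'")
  invisible(TRUE)
}

#' Coefficient of determination
#'
#' The default `"standard"` mode returns `1 - SS_res / SS_tot`, so a perfect
#' fit scores 1. The `"literal"` mode returns the bare ratio
#' `sum((O - P)^2) / sum((O - mean(O))^2)` as sometimes printed, where a
#' perfect fit scores 0; the two modes sum to 1 on every series.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 2).
#' @param mode `"standard"` (default) or `"literal"`.
#' @return dimensionless statistic.
#' @export
r_squared <- function(observed, predicted, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  check_series(observed, predicted)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0)
    stop("undefined variance: the observed series is constant")
  ratio <- sum((observed - predicted)^2) / ss_tot
  if (mode == "literal") ratio else 1 - ratio
}

#' Relative root mean squared error
#'
#' `rRMSE = sqrt(mean((P - O)^2)) / mean(O) * 100`, in percent; invariant
#' under joint positive rescaling of both series.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 2).
#' @return rRMSE in percent.
#' @export
rrmse <- function(observed, predicted) {
  check_series(observed, predicted)
  ob <- mean(observed)
  if (abs(ob) < .Machine$double.eps)
    stop("division error: the observed mean is zero")
  sqrt(mean((predicted - observed)^2)) / ob * 100
}

#' Akaike information criterion for an observed-vs-predicted series
#'
#' `AIC = 2k - 2 ln(L)` with the Gaussian residual likelihood at its
#' maximum-likelihood variance: `-2 ln(L) = n ln(2 pi sigma2) + n`,
#' `sigma2 = sum((P - O)^2) / n`. The default `k = 1` counts the residual
#' variance as the single estimated parameter.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 2).
#' @param k number of estimated parameters.
#' @return AIC value; a zero-residual (perfect-fit) series returns the
#'   sentinel `-Inf` with a warning rather than a silent finite number.
#' @export
aic <- function(observed, predicted, k = 1L) {
  check_series(observed, predicted)
  n <- length(observed)
  ss <- sum((predicted - observed)^2)
  if (ss <= 0) {
    warning("perfect fit: zero residual sum of squares, AIC is -Inf")
    return(-Inf)
  }
  2 * k + n * log(2 * pi * ss / n) + n
}

#' Missing-value weighting adjustment
#'
#' `Sw = S * (1 - mv / n)`: down-weights a statistic by the fraction of
#' missing values among the `n` observations, penalising incomplete
#' reconstructions.
#'
#' @param S statistic value.
#' @param mv number of missing values (0 <= mv <= n).
#' @param n number of observations (> 0).
#' @return the weighted statistic.
#' @export
weight_adjust <- function(S, mv, n) {
  if (n <= 0) stop("'n' must be positive")
  if (mv < 0 || mv > n) stop("domain error: need 0 <= mv <= n")
  S * (1 - mv / n)
}

#' rRMSE accuracy band
#'
#' Model accuracy is banded as excellent when rRMSE <= 10%, good when
#' 10% < rRMSE <= 20%, fair when 20% < rRMSE <= 30% and poor above 30%
#' (boundaries closed exactly as stated).
#'
#' @param rrmse_pct rRMSE in percent (>= 0); vectorised.
#' @return factor with levels excellent, good, fair, poor.
#' @export
accuracy_band <- function(rrmse_pct) {
  if (any(rrmse_pct < 0)) stop("domain error: rRMSE must be >= 0")
  cut(rrmse_pct, breaks = c(-Inf, 10, 20, 30, Inf),
      labels = c("excellent", "good", "fair", "poor"), right = TRUE)
}

#' Evaluate predicted against observed trait tables
#'
#' Joins long-format trait tables (columns `plant_id`, `trait`,
#' `organ_index`, `value`) on `(plant_id, trait, organ_index)`; for each
#' trait the complete pairs feed [r_squared()], [rrmse()] and [aic()],
#' observations whose prediction is missing are counted as `mv`, each index
#' is weighted with [weight_adjust()], and the accuracy band is attached
#' from the weighted rRMSE. The weighting is applied to all three indexes
#' by default; `weight_aic = FALSE` exempts AIC (whose orientation is
#' lower-is-better).
#'
#' @param observed,predicted long-format trait data.frames (e.g. from
#'   [as.data.frame.trait_record()]).
#' @param k AIC parameter count.
#' @param merge_diameters if `TRUE`, BD/HD/AD are pooled as one trait `"D"`.
#' @param weight_aic apply the Sw weighting to AIC as well (default `TRUE`).
#' @return data.frame with one row per trait: `trait`, `n`, `n_pairs`,
#'   `mv`, `r2`, `r2_literal`, `rrmse`, `aic`, `r2_sw`, `rrmse_sw`,
#'   `aic_sw`, `band` (from `rrmse_sw`).
#' @export
evaluate_traits <- function(observed, predicted, k = 1L,
                            merge_diameters = FALSE, weight_aic = TRUE) {
  need <- c("plant_id", "trait", "organ_index", "value")
  stopifnot(all(need %in% names(observed)), all(need %in% names(predicted)))
  obs <- observed[, need]
  prd <- predicted[, need]
  if (merge_diameters) {
    relab <- function(d) {
      sel <- d$trait %in% c("BD", "HD", "AD")
      d$organ_index[sel] <- match(d$trait[sel], c("BD", "HD", "AD"))
      d$trait[sel] <- "D"
      d
    }
    obs <- relab(obs); prd <- relab(prd)
  }
  m <- merge(obs, prd, by = c("plant_id", "trait", "organ_index"),
             suffixes = c("_obs", "_prd"))
  m <- m[!is.na(m$value_obs), , drop = FALSE]
  if (nrow(m) == 0) stop("join error: no overlapping (plant_id, trait, organ_index) keys")
  out <- lapply(split(m, m$trait), function(d) {
    n <- nrow(d)
    cc <- !is.na(d$value_prd)
    mv <- sum(!cc)
    if (sum(cc) < 2)
      return(data.frame(trait = d$trait[1], n = n, n_pairs = sum(cc), mv = mv,
                        r2 = NA_real_, r2_literal = NA_real_,
                        rrmse = NA_real_, aic = NA_real_, r2_sw = NA_real_,
                        rrmse_sw = NA_real_, aic_sw = NA_real_,
                        band = NA_character_))
    o <- d$value_obs[cc]; p <- d$value_prd[cc]
    r2 <- r_squared(o, p)
    rr <- rrmse(o, p)
    a <- suppressWarnings(aic(o, p, k = k))
    rr_sw <- weight_adjust(rr, mv, n)
    data.frame(trait = d$trait[1], n = n, n_pairs = sum(cc), mv = mv,
               r2 = r2, r2_literal = 1 - r2, rrmse = rr, aic = a,
               r2_sw = weight_adjust(r2, mv, n), rrmse_sw = rr_sw,
               aic_sw = if (weight_aic) weight_adjust(a, mv, n) else a,
               band = as.character(accuracy_band(rr_sw)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "k") <- k
  attr(res, "weight_aic") <- weight_aic
  res
}

#' Image quantity x quality grid experiment
#'
#' The synthetic analogue of the platform's response-surface analysis: for
#' each (quantity, quality) cell, `reps` plants of the chosen archetype are
#' generated, degraded with the cell's presets, run through
#' [extract_traits()], and scored against their ground truth with
#' [evaluate_traits()] (diameters merged as `D`). The quality preset sets
#' the base sampling density and noise; the view count `v` culls azimuthal
#' visibility and additionally scales density by `sqrt(v / 90)` (fewer
#' azimuths, fewer multi-view feature matches) and noise by `sqrt(90 / v)`
#' (fewer rays per point, poorer depth precision). Generation happens once
#' per replicate at `gen_density` and the same plants are degraded for
#' every cell, so cell comparisons are paired. Deterministic given `seed`.
#'
#' @param archetype passed to [synthetic_plant_spec()].
#' @param quantities integer vector of view counts (e.g. `c(30, 45, 90)`).
#' @param qualities character vector of [quality_preset()] names.
#' @param reps plants per cell (>= 2).
#' @param k AIC parameter count.
#' @param seed base seed; replicate and degradation seeds derive from it.
#' @param gen_density generation density, points/cm^2 (must cover the
#'   densest quality preset).
#' @param config an [extract_config()].
#' @return data.frame with columns `quantity`, `quality`, `trait`, `n`,
#'   `n_pairs`, `mv`, `r2`, `r2_literal`, `rrmse`, `aic`, `r2_sw`,
#'   `rrmse_sw`, `aic_sw`, `band`.
#' @export
evaluate_grid <- function(archetype, quantities = c(30, 45, 90),
                          qualities = c("L", "M", "H"), reps = 5, k = 1L,
                          seed = 1L, gen_density = 200,
                          config = extract_config()) {
  if (reps < 2) stop("'reps' must be >= 2")
  quantities <- as.integer(quantities)
  if (any(is.na(quantities)) || any(quantities < 1))
    stop("configuration error: invalid quantity levels")
  if (!all(qualities %in% c("H", "M", "L")))
    stop("configuration error: unknown quality level(s): ",
         paste(setdiff(qualities, c("H", "M", "L")), collapse = ", "))
  gens <- lapply(seq_len(reps), function(r)
    generate_plant(synthetic_plant_spec(archetype,
                                        seed = derive_seed(seed, 500L, r)),
                   density = gen_density))
  obs <- do.call(rbind, lapply(seq_len(reps), function(r) {
    d <- as.data.frame(gens[[r]]$truth)
    d$plant_id <- sprintf("rep%02d", r)
    d
  }))
  cells <- expand.grid(quality = qualities, quantity = quantities,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    qual <- quality_preset(cells$quality[ci])
    v <- cells$quantity[ci]
    ## image quantity acts through three channels: azimuthal visibility
    ## culling (n_views), the density of multi-view feature matches
    ## (~ sqrt(v / 90)), and per-point depth precision (~ sqrt(90 / v))
    cell_density <- qual$density * sqrt(min(v, 90) / 90)
    cell_sigma <- qual$noise_sigma * sqrt(90 / min(v, 90))
    prd <- do.call(rbind, lapply(seq_len(reps), function(r) {
      deg <- degrade(gens[[r]]$plant,
                     degradation(density = cell_density,
                                 n_views = v,
                                 noise_sigma = cell_sigma,
                                 seed = derive_seed(seed, 600L, r,
                                                    match(cells$quality[ci],
                                                          c("H", "M", "L")),
                                                    v)))
      d <- as.data.frame(extract_traits(deg, config = config))
      d$plant_id <- sprintf("rep%02d", r)
      d
    }))
    stats <- evaluate_traits(obs, prd, k = k, merge_diameters = TRUE)
    cbind(quantity = cells$quantity[ci], quality = cells$quality[ci], stats)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
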