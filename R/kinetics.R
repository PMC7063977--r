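#' Construct a kinetic dataset
#'
#' A rate table for one enzyme: substrate concentrations in mM against
#' specific activities in U/mg, where 1 U releases 1 umol p-nitrophenol per
#' minute.
#'
#' @param enzyme_id label for the enzyme.
#' @param substrate_mM strictly positive substrate concentrations (mM).
#' @param rate_U_per_mg matching specific activities (U/mg).
#' @return an object of class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(enzyme_id, substrate_mM, rate_U_per_mg) {
  if (length(substrate_mM) != length(rate_U_per_mg))
    stop("substrate and rate vectors must have equal length", call. = FALSE)
  if (length(substrate_mM) < 3L || length(unique(substrate_mM)) < 3L)
    stop("need at least 3 distinct substrate concentrations", call. = FALSE)
  if (any(substrate_mM <= 0))
    stop("substrate concentrations must be positive", call. = FALSE)
  structure(list(enzyme_id = enzyme_id,
                 substrate_mM = as.numeric(substrate_mM),
                 rate_U_per_mg = as.numeric(rate_U_per_mg)),
            class = "kinetic_dataset")
}

#' Fit Michaelis-Menten kinetics
#'
#' The default method is the classical double-reciprocal (Lineweaver-Burk)
#' linearization: ordinary least squares of `1/v` on `1/[S]`, with
#' `Vmax = 1/intercept` and `Km = slope/intercept`. The reciprocal
#' transform amplifies noise at low substrate concentrations, so a direct
#' nonlinear least-squares fit of `v = Vmax*[S]/(Km+[S])`, initialized from
#' the Lineweaver-Burk estimate, is provided as the recommended cross-check
#' (`method = "nonlinear"`).
#'
#' The turnover number kcat cannot always be derived from Vmax without
#' knowing the convention used (mass basis, active-site titration), so a
#' measured `kcat_per_s` may be supplied and is then used as-is. When
#' absent and a molar mass is given, kcat is derived as
#' `Vmax * M / 60` (M in mg/umol, numerically the mass in kDa) and labeled
#' `"derived"`.
#'
#' @param dataset a `kinetic_dataset`.
#' @param method `"lineweaver-burk"` (default) or `"nonlinear"`.
#' @param kcat_per_s optional measured turnover number (/s).
#' @param molar_mass_kDa optional enzyme molar mass used to derive kcat
#'   when `kcat_per_s` is not supplied.
#' @return an object of class `kinetic_fit`: `vmax_U_per_mg`, `km_mM`,
#'   `kcat_per_s` (possibly `NA`), `kcat_source` (`"supplied"`,
#'   `"derived"`, or `"none"`), `efficiency_per_s_per_mM`, `r2`, `method`.
#' @export
#' @examples
#' s <- 10 / 2^(0:7)
#' v <- 714.29 * s / (0.36 + s)
#' fit_michaelis_menten(kinetic_dataset("wt", s, v))
fit_michaelis_menten <- function(dataset,
                                 method = c("lineweaver-burk", "nonlinear"),
                                 kcat_per_s = NULL, molar_mass_kDa = NULL) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  method <- match.arg(method)
  s <- dataset$substrate_mM
  v <- dataset$rate_U_per_mg
  if (any(v == 0)) stop("reciprocal undefined: zero rate in dataset",
                        call. = FALSE)

  lb <- stats::lm(I(1 / v) ~ I(1 / s))
  intercept <- unname(stats::coef(lb)[1L])
  slope <- unname(stats::coef(lb)[2L])
  if (intercept <= 0) stop("fit not hyperbolic: non-positive 1/v intercept",
                           call. = FALSE)
  vmax <- 1 / intercept
  km <- slope / intercept
  r2 <- summary(lb)$r.squared

  if (method == "nonlinear") {
    ## Levenberg-Marquardt: robust to the zero-residual case exact data
    ## produces, where Gauss-Newton stalls
    nl <- minpack.lm::nlsLM(v ~ Vmax * s / (Km + s),
                            start = list(Vmax = vmax, Km = max(km, 1e-6)))
    cf <- stats::coef(nl)
    vmax <- unname(cf["Vmax"])
    km <- unname(cf["Km"])
    r2 <- 1 - sum(stats::residuals(nl)^2) / sum((v - mean(v))^2)
  }
  if (km <= 0) stop("fit not hyperbolic: non-positive Km estimate",
                    call. = FALSE)

  if (!is.null(kcat_per_s)) {
    kcat <- kcat_per_s
    kcat_source <- "supplied"
  } else if (!is.null(molar_mass_kDa)) {
    ## U/mg = umol/min/mg; * mg/umol enzyme = /min; /60 = /s
    kcat <- vmax * molar_mass_kDa / 60
    kcat_source <- "derived"
  } else {
    kcat <- NA_real_
    kcat_source <- "none"
  }

  structure(list(enzyme_id = dataset$enzyme_id,
                 vmax_U_per_mg = vmax, km_mM = km,
                 kcat_per_s = kcat, kcat_source = kcat_source,
                 efficiency_per_s_per_mM =
                   if (is.na(kcat)) NA_real_ else kcat / km,
                 r2 = r2, method = method),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Michaelis-Menten fit (", x$method, ") for ", x$enzyme_id, "\n", sep = "")
  cat(sprintf("  Vmax = %.2f U/mg, Km = %.3f mM, R^2 = %.4f\n",
              x$vmax_U_per_mg, x$km_mM, x$r2))
  if (!is.na(x$kcat_per_s))
    cat(sprintf("  kcat = %.2f /s (%s), kcat/Km = %.2f /s/mM\n",
                x$kcat_per_s, x$kcat_source, x$efficiency_per_s_per_mM))
  invisible(x)
}

#' Catalytic efficiency kcat/Km
#'
#' @param kcat_per_s turnover number (/s).
#' @param km_mM Michaelis constant (mM), positive.
#' @return efficiency in /s/mM.
#' @export
#' @examples
#' catalytic_efficiency(188.10, 0.36)  # 522.5
catalytic_efficiency <- function(kcat_per_s, km_mM) {
  if (any(km_mM <= 0)) stop("invalid Km: must be positive", call. = FALSE)
  kcat_per_s / km_mM
}

#' Mutant-over-wild-type fold change
#'
#' @param value_mutant,value_wt quantities on the same scale; `value_wt`
#'   must be nonzero.
#' @return the ratio `value_mutant / value_wt` (full precision; reports
#'   conventionally round to 2 decimals).
#' @export
fold_change <- function(value_mutant, value_wt) {
  if (any(value_wt == 0)) stop("undefined ratio: zero denominator",
                               call. = FALSE)
  value_mutant / value_wt
}

#' Construct a thermal-inactivation time course
#'
#' Residual activity (% of the untreated enzyme) after incubation at a
#' fixed temperature for increasing times.
#'
#' @param enzyme_id label.
#' @param temperature_C incubation temperature.
#' @param time_min strictly increasing sampling times (min), starting at or
#'   after 0.
#' @param residual_pct residual activities in `[0, 110]`; a time-0 point,
#'   if present, is expected to be ~100. Values above 100 are kept with a
#'   warning, never truncated.
#' @return an object of class `inactivation_series`.
#' @export
inactivation_series <- function(enzyme_id, temperature_C, time_min,
                                residual_pct) {
  if (length(time_min) != length(residual_pct))
    stop("time and residual vectors must have equal length", call. = FALSE)
  if (length(time_min) == 0L) stop("empty series", call. = FALSE)
  if (any(diff(time_min) <= 0) || time_min[1L] < 0)
    stop("times must be strictly increasing and start at >= 0", call. = FALSE)
  if (any(residual_pct < 0) || any(residual_pct > 110))
    stop("residual activities must lie in [0, 110]", call. = FALSE)
  if (any(residual_pct > 100))
    warning("residual activity above 100% retained as-is", call. = FALSE)
  if (time_min[1L] == 0 && abs(residual_pct[1L] - 100) > 5)
    warning("time-0 residual differs from 100%", call. = FALSE)
  structure(list(enzyme_id = enzyme_id, temperature_C = temperature_C,
                 time_min = as.numeric(time_min),
                 residual_pct = as.numeric(residual_pct)),
            class = "inactivation_series")
}

#' Estimate a thermal-inactivation half-life
#'
#' Two estimators are provided. The default fits first-order decay by
#' ordinary least squares of `ln(residual)` on time over the points with
#' positive residual activity, giving the decay constant `k` and
#' `t1/2 = ln(2)/k`. The `"nearest-timepoint"` method instead reads the
#' half-life off the sampling grid as the time whose residual activity is
#' closest to 50% (ties resolved toward the earlier time) — the way
#' half-lives are commonly quoted directly from an assay time course.
#'
#' @param series an `inactivation_series`.
#' @param method `"first-order-fit"` (default) or `"nearest-timepoint"`.
#' @return an object of class `half_life_estimate`: `t_half_min`,
#'   `method`, `k_per_min` (`NA` for the read-off method).
#' @export
#' @examples
#' tt <- c(5, 10, 20, 40, 60)
#' s <- inactivation_series("wt", 60, tt, 100 * exp(-log(2) / 30 * tt))
#' estimate_half_life(s)  # 30 min
estimate_half_life <- function(series,
                               method = c("first-order-fit",
                                          "nearest-timepoint")) {
  stopifnot(inherits(series, "inactivation_series"))
  method <- match.arg(method)
  if (method == "first-order-fit") {
    keep <- series$residual_pct > 0
    if (sum(keep) < 3L)
      stop("invalid series: need >= 3 points with positive residual activity",
           call. = FALSE)
    tt <- series$time_min[keep]
    fit <- stats::lm(log(series$residual_pct[keep]) ~ tt)
    k <- -unname(stats::coef(fit)[2L])
    if (k <= 0) stop("no decay detected", call. = FALSE)
    t_half <- log(2) / k
  } else {
    if (all(series$residual_pct <= 0)) stop("invalid series", call. = FALSE)
    i <- which.min(abs(series$residual_pct - 50))  # first min = earlier time
    t_half <- series$time_min[i]
    k <- NA_real_
  }
  structure(list(enzyme_id = series$enzyme_id,
                 temperature_C = series$temperature_C,
                 t_half_min = t_half, k_per_min = k, method = method),
            class = "half_life_estimate")
}

#' @export
print.half_life_estimate <- function(x, ...) {
  cat(sprintf("t1/2 = %.2f min at %g C (%s) for %s\n", x$t_half_min,
              x$temperature_C, x$method, x$enzyme_id))
  invisible(x)
}

#' Residual-activity gain of a mutant over wild type
#'
#' Difference in residual activity, in percentage points, between two
#' inactivation series at a common sampled time.
#'
#' @param series_mut,series_wt `inactivation_series` objects sampled at `t`.
#' @param t time (min) present in both series.
#' @return `residual_mut(t) - residual_wt(t)` in percentage points.
#' @export
residual_activity_gain <- function(series_mut, series_wt, t) {
  stopifnot(inherits(series_mut, "inactivation_series"),
            inherits(series_wt, "inactivation_series"))
  im <- which(abs(series_mut$time_min - t) < 1e-9)
  iw <- which(abs(series_wt$time_min - t) < 1e-9)
  if (length(im) == 0L || length(iw) == 0L)
    stop("time not sampled: t = ", t, " min", call. = FALSE)
  series_mut$residual_pct[im[1L]] - series_wt$residual_pct[iw[1L]]
}

#' Read kinetics / inactivation tables from CSV
#'
#' `read_kinetics_csv()` expects columns `enzyme_id,substrate_mM,rate_U_per_mg`
#' and returns one [kinetic_dataset()] per enzyme. `read_inactivation_csv()`
#' expects `enzyme_id,temperature_C,time_min,residual_pct` and returns one
#' [inactivation_series()] per enzyme x temperature.
#'
#' @param file CSV path.
#' @return a named list of datasets / series.
#' @export
read_kinetics_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  lapply(split(df, df$enzyme_id), function(d)
    kinetic_dataset(d$enzyme_id[1L], d$substrate_mM, d$rate_U_per_mg))
}

#' @rdname read_kinetics_csv
#' @export
read_inactivation_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  key <- paste(df$enzyme_id, df$temperature_C, sep = "@")
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    inactivation_series(d$enzyme_id[1L], d$temperature_C[1L],
                        d$time_min, d$residual_pct)
  })
}
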