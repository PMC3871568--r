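# Exponential growth kinetics of longitudinal tumor volumes:
# V(t) = V0 * exp(r t); doubling time VDT = ln 2 / r; growth index
# GI = 100 (e^(30.44 r) - 1) percent per month (30.44 = mean days/month).

DAYS_PER_MONTH <- 30.44

check_series <- function(data, min_n = 3L) {
  req <- c("t_days", "volume_mm3")
  if (!all(req %in% names(data)))
    stop_murinod("value", paste("Growth data needs columns:",
                                paste(req, collapse = ", ")))
  data <- dplyr::arrange(as_tibble(data), .data$t_days)
  if (nrow(data) < min_n)
    stop_murinod("insufficient_data", sprintf(
      "At least %d observations are required (a tumor must be visible on %d or more sequential scans); got %d.",
      min_n, min_n, nrow(data)))
  if (any(data$t_days < 0) || is.unsorted(data$t_days, strictly = TRUE))
    stop_murinod("value", "`t_days` must be non-negative and strictly increasing.")
  if (any(data$volume_mm3 <= 0))
    stop_murinod("domain", "All volumes must be > 0.")
  data
}

#' Fit an exponential growth curve
#'
#' Unweighted nonlinear least squares of `V(t) = V0 * exp(r t)` on the
#' natural volume scale, initialised from the log-linear fit.  At least
#' three observations are required.
#'
#' @param data Data frame with columns `t_days` (days since the first
#'   scan) and `volume_mm3`.
#' @return An object of class `exp_fit` with elements `V0`, `r`, `V0_se`,
#'   `r_se`, `R2` (on the natural scale), `n`, `data`.
#' @examples
#' d <- tibble::tibble(t_days = c(0, 30, 60, 90),
#'                     volume_mm3 = 0.05 * exp(0.02 * c(0, 30, 60, 90)))
#' tidy(fit_exponential(d))
#' @export
fit_exponential <- function(data) {
  data <- check_series(data)
  ll <- loglinear_fit(data)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      volume_mm3 ~ V0 * exp(r * t_days), data = data,
      start = list(V0 = exp(ll$intercept), r = ll$slope),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop_murinod("fit", paste(
      "Exponential fit did not converge:", conditionMessage(e)))
  )
  est <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((data$volume_mm3 - mean(data$volume_mm3))^2)
  structure(list(
    V0 = unname(est["V0"]), r = unname(est["r"]),
    V0_se = unname(se["V0"]), r_se = unname(se["r"]),
    R2 = r2, n = nrow(data), data = data, nls = fit
  ), class = "exp_fit")
}

#' Log-linear growth fit
#'
#' Ordinary least squares of `ln V` on time — the representation used to
#' compare growth slopes between measurement methods.
#'
#' @inheritParams fit_exponential
#' @return An object of class `loglinear_fit` with `slope`, `intercept`,
#'   `slope_se`, `R2`, `n`, plus the residual sum of squares and time
#'   sum-of-squares needed for slope comparison.
#' @export
loglinear_fit <- function(data) {
  data <- check_series(data)
  lf <- lm(log(volume_mm3) ~ t_days, data = data)
  sm <- suppressWarnings(summary(lf))  # noiseless series fit perfectly
  structure(list(
    slope = unname(coef(lf)["t_days"]),
    intercept = unname(coef(lf)["(Intercept)"]),
    slope_se = unname(sm$coefficients["t_days", "Std. Error"]),
    R2 = sm$r.squared,
    n = nrow(data),
    sse = sum(stats::resid(lf)^2),
    sxx = sum((data$t_days - mean(data$t_days))^2),
    data = data, lm = lf
  ), class = "loglinear_fit")
}

#' Volume doubling time from a growth rate
#'
#' `VDT = ln 2 / r` days; defined only for growing tumors (r > 0).
#'
#' @param r Growth rate(s), per day.
#' @return Doubling time(s) in days.
#' @examples
#' vdt_from_rate(0.0057)  # 121.6 days
#' @export
vdt_from_rate <- function(r) {
  if (any(!is.finite(r)))
    stop_murinod("value", "`r` must be finite.")
  if (any(r <= 0))
    stop_murinod("non_growing",
                 "VDT is undefined for non-growing tumors (r <= 0).")
  log(2) / r
}

#' Growth index from a growth rate
#'
#' Percent volume increase per month: `GI = 100 (e^(30.44 r) - 1)`, with
#' 30.44 the average number of days per month.
#'
#' @param r Growth rate(s), per day.
#' @return Growth index in percent per month.
#' @examples
#' gi_from_rate(0.0182)  # 74.0 % per month
#' @export
gi_from_rate <- function(r) {
  if (any(!is.finite(r)))
    stop_murinod("value", "`r` must be finite.")
  100 * (exp(DAYS_PER_MONTH * r) - 1)
}

#' Growth index from a doubling time
#'
#' `GI = 100 (2^(30.44 / VDT) - 1)`; one doubling per month is GI 100.
#'
#' @param vdt Doubling time(s) in days (> 0).
#' @return Growth index in percent per month.
#' @examples
#' gi_from_vdt(30.44)  # 100
#' @export
gi_from_vdt <- function(vdt) {
  if (any(!is.finite(vdt)) || any(vdt <= 0))
    stop_murinod("value", "`vdt` must be > 0.")
  100 * (2^(DAYS_PER_MONTH / vdt) - 1)
}

#' Compare two growth slopes
#'
#' Two-sided Student's t test of log-linear slope equality with pooled
#' residual variance and `n1 + n2 - 4` degrees of freedom (equivalent to
#' the interaction term of a dummy-coded combined regression).
#'
#' @param fit_a,fit_b Objects from [loglinear_fit()].
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "loglinear_fit"), inherits(fit_b, "loglinear_fit"))
  df <- fit_a$n + fit_b$n - 4L
  if (df <= 0)
    stop_murinod("insufficient_data", "No residual degrees of freedom.")
  sp2 <- (fit_a$sse + fit_b$sse) / df
  se <- sqrt(sp2 * (1 / fit_a$sxx + 1 / fit_b$sxx))
  t <- (fit_a$slope - fit_b$slope) / se
  tibble(statistic = t, df = df, p.value = 2 * pt(-abs(t), df))
}

#' Cohort kinetic summary
#'
#' Arithmetic mean of the doubling times and mean/median of the growth
#' indices across tumors, as reported for a cohort.
#'
#' @param kinetics Data frame with columns `vdt_days` and `gi_pct`.
#' @return A one-row tibble: `mean_vdt_days`, `mean_gi_pct`,
#'   `median_gi_pct`, `n`.
#' @export
cohort_summary <- function(kinetics) {
  if (is.null(kinetics) || nrow(kinetics) == 0L)
    stop_murinod("empty_input", "No kinetic summaries supplied.")
  if (!all(c("vdt_days", "gi_pct") %in% names(kinetics)))
    stop_murinod("value", "`kinetics` needs columns vdt_days and gi_pct.")
  tibble(
    mean_vdt_days = mean(kinetics$vdt_days),
    mean_gi_pct = mean(kinetics$gi_pct),
    median_gi_pct = median(kinetics$gi_pct),
    n = nrow(kinetics)
  )
}

#' Fit growth kinetics for every tumor in a longitudinal table
#'
#' Groups a longitudinal volume table by `tumor_id`, fits the log-linear
#' and exponential models per tumor, and derives VDT and GI from the
#' exponential rate.  Tumors with fewer than three observations are
#' returned flagged (`fitted = FALSE`) with NA kinetics rather than
#' dropped.
#'
#' @param data Data frame with columns `tumor_id`, `t_days`, `volume_mm3`.
#' @return A tibble with one row per tumor: `tumor_id`, `n`, `fitted`,
#'   `v0_mm3`, `r_per_day`, `r_se`, `slope`, `slope_se`, `r2`,
#'   `vdt_days`, `gi_pct`.
#' @examples
#' d <- simulate_growth_series(n_series = 2, seed = 1)
#' fit_growth_cohort(d)
#' @export
fit_growth_cohort <- function(data) {
  if (!all(c("tumor_id", "t_days", "volume_mm3") %in% names(data)))
    stop_murinod("value", "Need columns tumor_id, t_days, volume_mm3.")
  purrr::map_dfr(split(as_tibble(data), data$tumor_id), function(d) {
    base <- tibble(tumor_id = d$tumor_id[1], n = nrow(d))
    if (nrow(d) < 3L) {
      return(dplyr::mutate(base, fitted = FALSE, v0_mm3 = NA_real_,
                           r_per_day = NA_real_, r_se = NA_real_,
                           slope = NA_real_, slope_se = NA_real_,
                           r2 = NA_real_, vdt_days = NA_real_,
                           gi_pct = NA_real_))
    }
    ef <- fit_exponential(d)
    ll <- loglinear_fit(d)
    dplyr::mutate(base, fitted = TRUE, v0_mm3 = ef$V0, r_per_day = ef$r,
                  r_se = ef$r_se, slope = ll$slope, slope_se = ll$slope_se,
                  r2 = ll$R2,
                  vdt_days = if (ef$r > 0) vdt_from_rate(ef$r) else NA_real_,
                  gi_pct = gi_from_rate(ef$r))
  })
}

#' Simulate longitudinal tumor-volume series
#'
#' Generates exponential growth observations with multiplicative
#' log-normal measurement noise — the study design of a longitudinal
#' micro-CT experiment (several scans per tumor, weeks apart).
#'
#' @param n_series Number of tumors.
#' @param v0 True initial volume (mm^3).
#' @param r True growth rate (per day).
#' @param times Scan times in days since the first scan (default four
#'   scans three weeks apart).
#' @param sigma_log SD of the log-normal measurement noise.
#' @param seed RNG seed.
#' @return A tibble with columns `tumor_id`, `t_days`, `volume_mm3`.
#' @export
simulate_growth_series <- function(n_series = 1, v0 = 0.05, r = 0.02,
                                   times = c(0, 21, 42, 63),
                                   sigma_log = 0.1, seed = NULL) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  purrr::map_dfr(seq_len(n_series), function(i) {
    tibble(
      tumor_id = sprintf("sim_%03d", i),
      t_days = times,
      volume_mm3 = v0 * exp(r * times) * exp(rnorm(length(times), 0, sigma_log))
    )
  })
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> V(t) = %.4g * exp(%.4g t), n = %d, R2 = %.4f\n",
    x$V0, x$r, x$n, x$R2))
  if (x$r > 0)
    cat(sprintf("  VDT %.2f days, GI %.2f %%/month\n",
                vdt_from_rate(x$r), gi_from_rate(x$r)))
  invisible(x)
}

#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(
    term = c("V0", "r"),
    estimate = c(x$V0, x$r),
    std.error = c(x$V0_se, x$r_se)
  )
}

#' @export
glance.exp_fit <- function(x, ...) {
  tibble(
    r.squared = x$R2, n = x$n,
    vdt_days = if (x$r > 0) vdt_from_rate(x$r) else NA_real_,
    gi_pct = gi_from_rate(x$r)
  )
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat(sprintf(
    "<loglinear_fit> ln V = %.4g + %.4g t, n = %d, R2 = %.4f\n",
    x$intercept, x$slope, x$n, x$R2))
  invisible(x)
}

#' @export
tidy.loglinear_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "t_days"),
    estimate = c(x$intercept, x$slope),
    std.error = c(unname(suppressWarnings(summary(x$lm))$coefficients["(Intercept)", "Std. Error"]),
                  x$slope_se)
  )
}

#' @export
glance.loglinear_fit <- function(x, ...) {
  tibble(r.squared = x$R2, n = x$n, slope = x$slope, slope_se = x$slope_se)
}

#' @export
autoplot.exp_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(t_days = seq(min(d$t_days), max(d$t_days), length.out = 100))
  grid$volume_mm3 <- object$V0 * exp(object$r * grid$t_days)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_days, y = .data$volume_mm3)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time from first scan (days)",
                  y = expression(Volume ~ (mm^3))) +
    ggplot2::theme_minimal()
}

#' Plot a longitudinal cohort on the log scale
#'
#' @param data Data frame with `tumor_id`, `t_days`, `volume_mm3`.
#' @return A ggplot of ln-volume against time with per-tumor least-squares
#'   lines.
#' @export
plot_growth_series <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$t_days, y = log(.data$volume_mm3),
                                     colour = .data$tumor_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "Time from first scan (days)",
                  y = expression(ln ~ volume ~ (mm^3)), colour = "tumor") +
    ggplot2::theme_minimal()
}
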