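#' Bleach-correct and normalize a FRAP trace
#'
#' Double normalization: background is subtracted from the bleach and
#' reference ROIs, the bleach ROI is divided by the reference ROI frame by
#' frame (cancelling acquisition photobleaching, which affects both alike),
#' and the result is scaled so the mean over the pre-bleach frames is 1:
#' \deqn{F(t) = \frac{B(t)-bg(t)}{R(t)-bg(t)} \cdot
#'       \frac{\langle R-bg\rangle_{pre}}{\langle B-bg\rangle_{pre}}}
#'
#' @param trace a [frap_trace].
#' @return list `(times, values, n_prebleach)`; pre-bleach mean of
#'   `values` is 1 by construction.
#' @export
correct_and_normalize <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  ref <- trace$reference_roi - trace$background_roi
  if (any(ref <= 0))
    stop("invalid reference: reference - background must be positive at every frame")
  ble <- trace$bleach_roi - trace$background_roi
  pre <- seq_len(trace$n_prebleach)
  f <- (ble / ref) * (mean(ref[pre]) / mean(ble[pre]))
  list(times = trace$times, values = f, n_prebleach = trace$n_prebleach)
}

#' Fit a single-exponential recovery and extract the mobile fraction
#'
#' Least-squares fit of
#' \deqn{F(t) = f_0 + (f_\infty - f_0)(1 - e^{-(t - t_b)/\tau})}
#' over the post-bleach frames of a normalized curve, with the bleach time
#' \eqn{t_b} taken as the time of the first post-bleach frame. With the
#' pre-bleach level normalized to 1, the mobile fraction is
#' \eqn{100\,(f_\infty - f_0)/(1 - f_0)} percent: the share of the bleached
#' pool that exchanges. Initialization is data-driven: `f0` from the first
#' post-bleach value, `f_inf` from the mean of the last 10% of frames, `tau`
#' from the time to reach halfway between them.
#'
#' @param curve normalized curve from [correct_and_normalize()] (or a list
#'   with `times` and `values`).
#' @param n_prebleach pre-bleach frame count (defaults to
#'   `curve$n_prebleach`).
#' @param mode `"full_bleach"` or `"half_bleach"`; annotation only, the
#'   model is identical.
#' @return object of class `frap_result`: `mobile_fraction` (percent,
#'   clamped to `[0, 100]` with a warning if the fit exceeds bounds), `tau`
#'   (s), `half_time` (`tau * ln 2`), `f0`, `f_inf`, `fit_rss`, `n_frames`,
#'   `mode`, `model` (`"single_exponential"`).
#' @export
fit_recovery <- function(curve, n_prebleach = curve$n_prebleach,
                         mode = c("full_bleach", "half_bleach")) {
  mode <- match.arg(mode)
  times <- curve$times
  values <- curve$values
  n <- length(values)
  stopifnot(length(times) == n, n_prebleach >= 1L)
  post <- (n_prebleach + 1L):n
  if (length(post) < 10L) stop("need >= 10 post-bleach frames")
  pre_level <- mean(values[seq_len(n_prebleach)])
  if (values[post[1]] >= pre_level)
    stop("first post-bleach value is not below the pre-bleach level")
  t_b <- times[post[1]]
  tt <- times[post] - t_b
  vv <- values[post]
  f0_init <- vv[1]
  f_inf_init <- mean(vv[max(1L, length(vv) - ceiling(length(vv) / 10) + 1L):
                        length(vv)])
  if (f_inf_init - f0_init < 0.01) {
    # essentially no recovery: the exponential time constant is
    # unidentifiable, report the plateau-based mobile fraction directly
    mf <- 100 * max(f_inf_init - f0_init, 0) / (1 - f0_init)
    return(structure(list(
      mobile_fraction = mf, tau = NA_real_, half_time = NA_real_,
      f0 = f0_init, f_inf = f_inf_init,
      fit_rss = sum((vv - mean(vv))^2), n_frames = n, mode = mode,
      model = "flat_no_recovery"), class = "frap_result"))
  }
  halfway <- (f0_init + f_inf_init) / 2
  i_half <- which(vv >= halfway)[1]
  tau_init <- max(if (is.na(i_half)) max(tt) / 3 else tt[i_half],
                  diff(range(tt)) / 200, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      vv ~ f0 + (f_inf - f0) * (1 - exp(-tt / tau)),
      start = list(f0 = f0_init, f_inf = f_inf_init, tau = tau_init),
      lower = c(f0 = -Inf, f_inf = -Inf, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf(
      "FRAP fit did not converge (init f0=%.3g, f_inf=%.3g, tau=%.3g; %d frames): %s",
      f0_init, f_inf_init, tau_init, length(vv), conditionMessage(e))))
  cf <- stats::coef(fit)
  mf <- 100 * (cf[["f_inf"]] - cf[["f0"]]) / (1 - cf[["f0"]])
  if (mf < 0 || mf > 100) {
    warning(sprintf("mobile fraction %.1f%% outside [0, 100], clamped", mf))
    mf <- min(max(mf, 0), 100)
  }
  structure(list(
    mobile_fraction = mf, tau = cf[["tau"]],
    half_time = cf[["tau"]] * log(2),
    f0 = cf[["f0"]], f_inf = cf[["f_inf"]],
    fit_rss = sum(stats::resid(fit)^2), n_frames = n, mode = mode,
    model = "single_exponential"), class = "frap_result")
}

#' @export
print.frap_result <- function(x, ...) {
  cat(sprintf(
    "frap_result (%s, %s): mobile fraction %.1f%% | tau %.3g s (t1/2 %.3g s) | f0 %.3f -> plateau %.3f\n",
    x$mode, x$model, x$mobile_fraction, x$tau, x$half_time, x$f0, x$f_inf))
  invisible(x)
}

#' Analyze a batch of FRAP traces
#'
#' Corrects, normalizes and fits each trace; per-trace failures are recorded
#' in the output, not fatal.
#'
#' @param traces list of [frap_trace] (optionally named; names become the
#'   `trace` column).
#' @param mode passed to [fit_recovery()].
#' @return list with `results` (data.frame: trace, mobile_fraction, tau,
#'   half_time, f0, f_inf, fit_rss, n_frames, mode, error), and `summary`
#'   (group mean, sd and N of the mobile fraction over successful fits;
#'   sd is `NA` for N = 1).
#' @export
batch_frap <- function(traces, mode = c("full_bleach", "half_bleach")) {
  mode <- match.arg(mode)
  stopifnot(length(traces) >= 1L)
  ids <- names(traces)
  if (is.null(ids)) ids <- sprintf("trace_%02d", seq_along(traces))
  rows <- lapply(seq_along(traces), function(i) {
    res <- tryCatch(
      fit_recovery(correct_and_normalize(traces[[i]]), mode = mode),
      error = function(e) e)
    if (inherits(res, "error"))
      data.frame(trace = ids[i], mobile_fraction = NA_real_, tau = NA_real_,
                 half_time = NA_real_, f0 = NA_real_, f_inf = NA_real_,
                 fit_rss = NA_real_, n_frames = NA_integer_, mode = mode,
                 error = conditionMessage(res))
    else
      data.frame(trace = ids[i], mobile_fraction = res$mobile_fraction,
                 tau = res$tau, half_time = res$half_time, f0 = res$f0,
                 f_inf = res$f_inf, fit_rss = res$fit_rss,
                 n_frames = res$n_frames, mode = mode, error = "")
  })
  results <- do.call(rbind, rows)
  ok <- results$mobile_fraction[!is.na(results$mobile_fraction)]
  summary <- data.frame(
    mode = mode, n = length(ok),
    mobile_fraction_mean = if (length(ok)) mean(ok) else NA_real_,
    mobile_fraction_sd = if (length(ok) > 1L) stats::sd(ok) else NA_real_)
  list(results = results, summary = summary)
}
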