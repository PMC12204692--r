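#' Default spectral-parameteriser settings
#'
#' Peak width limits of 1-12 Hz are interpreted as bounds on the full
#' bandwidth (2 standard deviations), so the Gaussian sd is bounded in
#' `[0.5, 6]` Hz. Heights and thresholds are in log10-power units.
#'
#' @param peak_width_limits full-bandwidth limits in Hz.
#' @param max_peaks cap on the number of peaks (default unlimited).
#' @param min_peak_height absolute minimum peak amplitude.
#' @param peak_threshold relative threshold in residual standard deviations.
#' @param fit_range frequency range fitted.
#' @param robust_tail upper tail fraction of residuals dropped in the robust
#'   aperiodic refit.
#' @return Named list of settings.
#' @export
spectral_settings <- function(peak_width_limits = c(1, 12),
                              max_peaks = Inf,
                              min_peak_height = 0.05,
                              peak_threshold = 2.0,
                              fit_range = c(1.5, 30),
                              robust_tail = 0.025) {
  list(peak_width_limits = peak_width_limits, max_peaks = max_peaks,
       min_peak_height = min_peak_height, peak_threshold = peak_threshold,
       fit_range = fit_range, robust_tail = robust_tail,
       sd_limits = peak_width_limits / 2)
}

#' Fit the aperiodic 1/f component: offset - exponent * log10(f)
#' @keywords internal
fit_aperiodic <- function(f, y, robust_tail = 0.025) {
  lf <- log10(f)
  fit <- lm(y ~ lf)
  co <- coef(fit)
  # robust refit: drop points in the upper residual tail (oscillatory peaks
  # sit above the background, so only positive residuals are suspect)
  res <- y - (co[1] + co[2] * lf)
  thr <- quantile(res, 1 - robust_tail, names = FALSE)
  keep <- res <= thr
  fit2 <- lm(y[keep] ~ lf[keep])
  co2 <- coef(fit2)
  c(offset = unname(co2[1]), exponent = unname(-co2[2]))
}

#' Parameterise a power spectrum into aperiodic and periodic components
#'
#' Separates a log10-power spectrum into an aperiodic background
#' `offset - exponent * log10(f)` and a sum of Gaussian oscillatory peaks.
#' The procedure: (i) robust aperiodic fit (least squares, then refit after
#' dropping the upper residual tail so peaks do not drag the background up);
#' (ii) iterative peak extraction from the aperiodic-subtracted residual --
#' the tallest residual point seeds a Gaussian whose sd is guessed from the
#' half-height span (clipped to the width bounds), which is subtracted, until
#' the tallest point falls below `max(min_peak_height, peak_threshold *
#' sd(residual))`; (iii) joint bounded least-squares refinement of all
#' Gaussians on the aperiodic-subtracted curve; (iv) aperiodic refit on the
#' peak-subtracted curve; (v) goodness of fit `r_squared = 1 - SSE/SST` of
#' the full model against the input.
#'
#' @param curve log10-power values on `grid`.
#' @param grid positive frequency grid (Hz) covering `settings$fit_range`.
#' @param settings list from [spectral_settings].
#' @return Object of class `spectral_fit`: `offset`, `exponent`, `peaks`
#'   (data frame: center, amplitude, sd), `fit_range`, `r_squared`,
#'   `peak_curve` (periodic component on the fitted grid), `grid` (the
#'   fitted sub-grid), `aperiodic_curve`.
#' @export
#' @examples
#' f <- default_psd_grid()
#' y <- simulate_raw_psd(f, 1, 1, rbind(c(10, .5, 1.5)))
#' fit <- fit_spectral_model(y, f)
#' fit$peaks
fit_spectral_model <- function(curve, grid, settings = spectral_settings()) {
  validate_grid(grid)
  fr <- settings$fit_range
  if (fr[1] < min(grid) - 1e-9 || fr[2] > max(grid) + 1e-9)
    stop("fit_range [", fr[1], ", ", fr[2], "] is outside the grid range",
         call. = FALSE)
  sel <- grid >= fr[1] & grid <= fr[2]
  f <- grid[sel]
  y <- curve[sel]
  sd_lo <- settings$sd_limits[1]; sd_hi <- settings$sd_limits[2]

  ap <- fit_aperiodic(f, y, settings$robust_tail)
  aperiodic <- ap["offset"] - ap["exponent"] * log10(f)
  resid <- y - aperiodic

  # (ii) iterative peak extraction
  peaks <- NULL
  work <- resid
  hard_cap <- length(f)  # cannot meaningfully fit more peaks than points
  while ((is.null(peaks) || nrow(peaks) < min(settings$max_peaks, hard_cap))) {
    i_max <- which.max(work)
    height <- work[i_max]
    stop_h <- max(settings$min_peak_height,
                  settings$peak_threshold * sd(work))
    if (height <= stop_h) break
    center <- f[i_max]
    # guess sd from the span where the residual exceeds half the height
    half <- height / 2
    lo <- i_max; while (lo > 1L && work[lo - 1L] > half) lo <- lo - 1L
    hi <- i_max; while (hi < length(f) && work[hi + 1L] > half) hi <- hi + 1L
    fwhm <- f[hi] - f[lo]
    guess_sd <- if (fwhm > 0) fwhm / 2.355 else sd_lo
    guess_sd <- min(max(guess_sd, sd_lo), sd_hi)
    # refine this Gaussian alone before subtracting, so the working
    # residual carries no subtraction artifacts that would seed spurious
    # further peaks
    one <- tryCatch({
      nl <- minpack.lm::nls.lm(
        par = c(center, height, guess_sd),
        fn = function(p) work - gaussian_bump(f, p[1], p[2], p[3]),
        lower = c(max(fr[1], center - 1.5 * guess_sd), 0, sd_lo),
        upper = c(min(fr[2], center + 1.5 * guess_sd), Inf, sd_hi),
        control = minpack.lm::nls.lm.control(maxiter = 100))
      nl$par
    }, error = function(e) c(center, height, guess_sd))
    peaks <- rbind(peaks, one)
    work <- work - gaussian_bump(f, one[1], one[2], one[3])
  }

  # (iii) joint bounded least-squares refinement of all Gaussians, alternated
  # with (iv) an aperiodic refit on the peak-subtracted curve. One extra
  # alternation corrects the bias the initial background fit absorbs from
  # tall peaks.
  refine_peaks <- function(target, peaks, guesses) {
    n_pk <- nrow(peaks)
    par0 <- as.numeric(t(peaks))
    # each center is confined near its seed guess so overlapping Gaussians
    # cannot wander or split one true peak into several
    c_lo <- pmax(fr[1], guesses[, 1] - 1.5 * guesses[, 3])
    c_hi <- pmin(fr[2], guesses[, 1] + 1.5 * guesses[, 3])
    lower <- as.numeric(rbind(c_lo, 0, sd_lo))
    upper <- as.numeric(rbind(c_hi, Inf, sd_hi))
    model_fn <- function(par) {
      m <- matrix(par, ncol = 3, byrow = TRUE)
      out <- numeric(length(f))
      for (r in seq_len(nrow(m)))
        out <- out + gaussian_bump(f, m[r, 1], m[r, 2], m[r, 3])
      out
    }
    tryCatch({
      nl <- minpack.lm::nls.lm(par = par0,
                               fn = function(p) target - model_fn(p),
                               lower = lower, upper = upper,
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      matrix(nl$par, ncol = 3, byrow = TRUE)
    }, error = function(e) {
      warning("joint peak refinement failed (", conditionMessage(e),
              "); keeping unrefined peaks", call. = FALSE)
      peaks
    })
  }
  aperiodic_ls <- function(target) {
    lf <- log10(f)
    co <- coef(lm(target ~ lf))
    c(offset = unname(co[1]), exponent = unname(-co[2]))
  }
  ap2 <- ap
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    guesses <- peaks
    target <- resid
    for (pass in 1:3) {
      peaks <- refine_peaks(target, peaks, guesses)
      pk_now <- numeric(length(f))
      for (r in seq_len(nrow(peaks)))
        pk_now <- pk_now + gaussian_bump(f, peaks[r, 1], peaks[r, 2], peaks[r, 3])
      ap2 <- aperiodic_ls(y - pk_now)
      target <- y - (ap2["offset"] - ap2["exponent"] * log10(f))
    }
    # enforce declared constraints; sub-threshold peaks are dropped
    keep <- peaks[, 2] >= settings$min_peak_height &
      peaks[, 3] >= sd_lo - 1e-9 & peaks[, 3] <= sd_hi + 1e-9 &
      peaks[, 1] >= fr[1] & peaks[, 1] <= fr[2]
    peaks <- peaks[keep, , drop = FALSE]
    if (nrow(peaks) > 0L) peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  }
  if (is.null(peaks)) peaks <- matrix(numeric(0), 0, 3)
  peaks_df <- data.frame(center = peaks[, 1], amplitude = peaks[, 2],
                         sd = peaks[, 3])

  # final aperiodic component on the peak-subtracted curve
  pk_curve <- peak_curve(peaks_df, f)
  ap2 <- aperiodic_ls(y - pk_curve)
  aperiodic2 <- ap2["offset"] - ap2["exponent"] * log10(f)

  fitted <- aperiodic2 + pk_curve
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1

  structure(list(offset = unname(ap2["offset"]),
                 exponent = unname(ap2["exponent"]),
                 peaks = peaks_df, fit_range = fr,
                 r_squared = r2, peak_curve = pk_curve,
                 aperiodic_curve = as.numeric(aperiodic2),
                 grid = f),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat("<spectral_fit> offset ", format(x$offset, digits = 4),
      ", exponent ", format(x$exponent, digits = 4), ", ",
      nrow(x$peaks), " peak(s), R^2 = ", format(x$r_squared, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Periodic (peak-only) component of a spectral fit
#'
#' Pointwise sum of the fitted Gaussian peaks on a grid; the all-zero curve
#' when there are no peaks. Linear in the peak list, so two fits superpose.
#'
#' @param fit a `spectral_fit`, or a data frame/matrix with columns
#'   (center, amplitude, sd).
#' @param grid evaluation grid.
#' @return Numeric vector on `grid`.
#' @export
peak_curve <- function(fit, grid) {
  pk <- if (inherits(fit, "spectral_fit")) fit$peaks else as.data.frame(fit)
  out <- numeric(length(grid))
  if (NROW(pk) == 0L) return(out)
  for (r in seq_len(nrow(pk)))
    out <- out + gaussian_bump(grid, pk[r, 1][[1]], pk[r, 2][[1]], pk[r, 3][[1]])
  out
}

#' Parameterise a batch of spectra and return peak curves plus a fit report
#'
#' @param curves n x G matrix of log10-power spectra on `grid`.
#' @param grid frequency grid.
#' @param settings [spectral_settings].
#' @return List: `peak_curves` (n x G' matrix on the fitted sub-grid),
#'   `grid` (fitted sub-grid), `report` (data frame: offset, exponent,
#'   n_peaks, r_squared), `fits` (list of `spectral_fit`).
#' @export
fit_spectral_batch <- function(curves, grid, settings = spectral_settings()) {
  curves <- rbind(curves)
  fits <- lapply(seq_len(nrow(curves)),
                 function(i) fit_spectral_model(curves[i, ], grid, settings))
  pk <- do.call(rbind, lapply(fits, `[[`, "peak_curve"))
  report <- data.frame(
    offset = vapply(fits, `[[`, 0, "offset"),
    exponent = vapply(fits, `[[`, 0, "exponent"),
    n_peaks = vapply(fits, function(f) nrow(f$peaks), 0L),
    r_squared = vapply(fits, `[[`, 0, "r_squared"))
  list(peak_curves = pk, grid = fits[[1]]$grid, report = report, fits = fits)
}
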