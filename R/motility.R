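## Calcium dose-response of in vitro motility: sliding velocity versus pCa
## (-log10 molar free calcium) fitted with a Hill function. pCa50 is the
## calcium concentration at half-maximal velocity; n_H the Hill coefficient.

#' Hill dose-response curve
#'
#' `v(x) = v_min + (v_max - v_min) / (1 + 10^(n_H * (x - pCa50)))`.
#' At `x = pCa50` the velocity is `(v_max + v_min)/2`; as calcium rises
#' (pCa decreases) velocity approaches `v_max`.
#'
#' @param v_min,v_max Low/high-calcium plateau velocities (nm/s).
#' @param pCa50 pCa at half-maximal velocity.
#' @param n_H Hill coefficient (> 0 for a decreasing curve in pCa).
#' @param x pCa values.
#' @return Velocities.
#' @export
hill_velocity <- function(v_min, v_max, pCa50, n_H, x) {
  v_min + (v_max - v_min) / (1 + 10^(n_H * (x - pCa50)))
}

#' Parse compact pCa labels
#'
#' Labels of the form `"pca68"` mean pCa 6.8 (decimal point implied after
#' the first digit); `"pca9"` is 9.0.
#'
#' @param x Character vector of labels (case-insensitive) or numerics.
#' @return Numeric pCa values.
#' @export
parse_pca_label <- function(x) {
  if (is.numeric(x)) return(x)
  d <- sub("^pca", "", tolower(trimws(x)))
  if (any(!grepl("^[0-9]+(\\.[0-9]+)?$", d)))
    stop("unparseable pCa label: ", x[!grepl("^[0-9]+", d)][1],
         call. = FALSE)
  vapply(d, function(s) {
    if (grepl(".", s, fixed = TRUE)) as.numeric(s)
    else if (nchar(s) == 1L) as.numeric(s)
    else as.numeric(paste0(substr(s, 1, 1), ".", substr(s, 2, nchar(s))))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Fit a Hill curve to velocity-vs-pCa data
#'
#' Aggregates raw measurements to per-pCa means (the reported mean +/- SEM
#' representation) and fits [hill_velocity()] by weighted nonlinear least
#' squares (weights = replicate counts) with a multistart over
#' `n_H in {1, 2, 4}` and `pCa50` over the observed range. `v_min` is a
#' free non-negative parameter unless `fix_vmin` is given. Set
#' `on_means = FALSE` to fit the raw points instead.
#'
#' @param data Data frame with columns `pCa` (numeric or `"pca68"`-style
#'   labels) and `velocity` (nm/s).
#' @param fix_vmin Optional fixed value for `v_min` (e.g. 0).
#' @param on_means Fit per-pCa means (default) or raw points.
#' @return List of class `dose_response_fit`: `v_max`, `v_min`, `pCa50`,
#'   `n_H`, `r_squared` (on the fitted points), `curve` (table of per-pCa
#'   n, mean, sd, sem, fitted), `converged`, `low_plateau_observed`.
#' @export
fit_hill <- function(data, fix_vmin = NULL, on_means = TRUE) {
  x <- parse_pca_label(data$pCa)
  v <- as.numeric(data$velocity)
  if (any(is.na(x)) || any(is.na(v))) stop("NA in motility data",
                                           call. = FALSE)
  agg <- do.call(rbind, lapply(split(v, x), function(vv)
    data.frame(n = length(vv), mean = mean(vv), sd = stats::sd(vv))))
  agg$pCa <- as.numeric(rownames(agg))
  agg$sem <- agg$sd / sqrt(agg$n)
  agg <- agg[order(agg$pCa), c("pCa", "n", "mean", "sd", "sem")]
  rownames(agg) <- NULL
  if (nrow(agg) < 4L)
    stop("need >= 4 distinct pCa values spanning both plateaus",
         call. = FALSE)

  if (on_means) { xf <- agg$pCa; yf <- agg$mean; wf <- agg$n }
  else { xf <- x; yf <- v; wf <- rep(1, length(v)) }

  rng <- range(xf)
  span <- diff(rng)
  starts <- expand.grid(n_H = c(1, 2, 4),
                        pCa50 = rng[1] + span * c(0.25, 0.5, 0.75))
  vmax0 <- max(yf); vmin0 <- max(0, min(yf))
  fits <- list()
  for (i in seq_len(nrow(starts))) {
    st <- list(v_max = vmax0, pCa50 = starts$pCa50[i], n_H = starts$n_H[i])
    if (is.null(fix_vmin)) {
      st$v_min <- vmin0
      form <- yf ~ v_min + (v_max - v_min) / (1 + 10^(n_H * (xf - pCa50)))
      lower <- c(v_max = 0, pCa50 = rng[1], n_H = 0.05, v_min = 0)
      upper <- c(v_max = Inf, pCa50 = rng[2], n_H = 20, v_min = Inf)
    } else {
      vmin_fixed <- fix_vmin
      form <- yf ~ vmin_fixed +
        (v_max - vmin_fixed) / (1 + 10^(n_H * (xf - pCa50)))
      lower <- c(v_max = 0, pCa50 = rng[1], n_H = 0.05)
      upper <- c(v_max = Inf, pCa50 = rng[2], n_H = 20)
    }
    f <- tryCatch(
      stats::nls(form, start = st, weights = wf, algorithm = "port",
                 lower = lower, upper = upper,
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(f))
      fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L)
    stop("Hill fit did not converge from any start; residual ranges: ",
         paste(signif(range(yf), 4), collapse = " .. "), call. = FALSE)
  ss <- vapply(fits, function(f) sum(wf * stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(ss)]]
  cf <- as.list(stats::coef(best))
  if (!is.null(fix_vmin)) cf$v_min <- fix_vmin
  pred <- hill_velocity(cf$v_min, cf$v_max, cf$pCa50, cf$n_H, xf)
  r2 <- 1 - sum((yf - pred)^2) / sum((yf - mean(yf))^2)
  agg$fitted <- hill_velocity(cf$v_min, cf$v_max, cf$pCa50, cf$n_H, agg$pCa)
  ## a low-velocity plateau needs data well above pCa50
  low_plateau <- max(agg$pCa) > cf$pCa50 + 1 / max(cf$n_H, 0.05)
  if (!low_plateau)
    warning("no low-velocity plateau observed; v_min poorly identified")
  structure(list(v_max = cf$v_max, v_min = cf$v_min, pCa50 = cf$pCa50,
                 n_H = cf$n_H, r_squared = r2, curve = agg,
                 converged = TRUE, low_plateau_observed = low_plateau),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("<dose_response_fit> v_max = %.1f nm/s, v_min = %.1f",
                     " nm/s, pCa50 = %.2f, n_H = %.2f, R^2 = %.3f\n"),
              x$v_max, x$v_min, x$pCa50, x$n_H, x$r_squared))
  invisible(x)
}
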