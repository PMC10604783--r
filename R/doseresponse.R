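#' Fit the variable-slope four-parameter logistic inhibition model
#'
#' Least-squares fit of
#' \deqn{y = bottom + \frac{top - bottom}{1 + 10^{\,hill\,(\log_{10} x - \log_{10} IC_{50})}}}
#' to a dose series on the log10-dose axis, with multi-start initialization:
#' bottom/top from the response extremes, log10 IC50 from the dose bracketing
#' the half-range crossing, hill started at 0.5, 1 and 2; the best residual
#' sum of squares wins. Parameters are bounded (IC50 within
#' \[min dose/100, max dose x 100\], hill in (0, 10\]). The primary engine is
#' Levenberg-Marquardt ([minpack.lm::nlsLM]); bounded Nelder-Mead/L-BFGS-B is
#' the fallback when it fails to converge from a start.
#'
#' @param doses strictly positive dose vector, micromolar; at least 5
#'   distinct values (dose 0 never enters the fit - vehicle defines the
#'   normalization instead). Replicate doses are allowed and fitted as
#'   individual points.
#' @param responses response values, one per dose.
#' @return A [DoseResponseFit-class]; `extrapolated` is TRUE when the fitted
#'   IC50 falls outside the tested dose span.
#' @export
#' @examples
#' d <- 10^seq(log10(0.02), log10(50), length.out = 8)
#' y <- 0 + (1 - 0) / (1 + 10^(1 * (log10(d) - log10(1))))
#' fit4PL(d, y)   # recovers IC50 = 1
fit4PL <- function(doses, responses) {
  .stopIfNot(length(doses) == length(responses),
             "doses and responses must have equal length")
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  .stopIfNot(all(doses > 0), "doses must be strictly positive")
  if (length(unique(doses)) < 5)
    stop("design error: need >= 5 distinct positive doses")
  if (stats::sd(responses) == 0)
    stop("degenerate fit: all responses are equal")
  lx <- log10(doses)
  lo <- c(bottom = min(responses) - diff(range(responses)),
          top = min(responses) - diff(range(responses)),
          lic50 = log10(min(doses) / 100), hill = 1e-3)
  hi <- c(bottom = max(responses) + diff(range(responses)),
          top = max(responses) + diff(range(responses)),
          lic50 = log10(max(doses) * 100), hill = 10)
  model <- function(p, x) p[1] + (p[2] - p[1]) / (1 + 10^(p[4] * (x - p[3])))
  rss <- function(p) sum((responses - model(p, lx))^2)
  # half-range crossing for the IC50 start
  mid <- (max(responses) + min(responses)) / 2
  ord <- order(lx)
  below <- which(responses[ord] <= mid)
  licStart <- if (length(below)) lx[ord][below[1L]] else stats::median(lx)
  starts <- lapply(c(0.5, 1, 2), function(h)
    c(bottom = min(responses), top = max(responses),
      lic50 = licStart, hill = h))
  starts <- c(starts, list(c(bottom = min(responses), top = max(responses),
                             lic50 = stats::median(lx), hill = 1)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch({
      f <- minpack.lm::nlsLM(
        responses ~ bottom + (top - bottom) /
          (1 + 10^(hill * (lx - lic50))),
        start = as.list(st), lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200))
      p <- stats::coef(f)[c("bottom", "top", "lic50", "hill")]
      list(par = p, value = rss(p), conv = TRUE)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      o <- stats::optim(st, rss, method = "L-BFGS-B",
                        lower = lo, upper = hi,
                        control = list(maxit = 500))
      fit <- list(par = o$par, value = o$value, conv = o$convergence == 0)
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- best$par
  new("DoseResponseFit",
      bottom = unname(p[1]), top = unname(p[2]),
      ic50 = unname(10^p[3]), hill = unname(p[4]),
      rss = best$value, converged = best$conv,
      extrapolated = unname(10^p[3] > max(doses) | 10^p[3] < min(doses)))
}

#' Predict from a 4PL fit
#'
#' @param object a [DoseResponseFit-class].
#' @param doses positive dose vector.
#' @return Fitted response values; at `doses == ic50` this equals
#'   `(top + bottom) / 2`.
#' @export
predict4PL <- function(object, doses) {
  object@bottom + (object@top - object@bottom) /
    (1 + 10^(object@hill * (log10(doses) - log10(object@ic50))))
}

#' IC50 per marker from vehicle-normalized dose-response tables
#'
#' Fits [fit4PL()] to each marker's relative expression across the dose
#' grid and reports the fitted IC50s; when a fit fails (e.g. a flat,
#' uninhibited marker) or the IC50 lands beyond the top tested dose, the
#' sentinel `"> <max dose>"` is reported instead of a number, mirroring how
#' potency tables report markers that are not inhibited within the tested
#' range.
#'
#' @param exprByDose `data.frame` with columns `marker`, `dose`
#'   (micromolar > 0) and `response` (relative expression, vehicle = 1).
#' @return `data.frame` with columns `marker`, `ic50` (NA when sentinel),
#'   `ic50_label` (number as text, or `"> <max>"`), `hill`, `bottom`, `top`,
#'   `converged`, `extrapolated`. Fit objects are attached as attribute
#'   `"fits"`.
#' @export
ic50FromMarkers <- function(exprByDose) {
  need <- c("marker", "dose", "response")
  .stopIfNot(all(need %in% colnames(exprByDose)),
             "need columns marker, dose, response")
  markers <- unique(exprByDose$marker)
  fits <- list()
  rows <- lapply(markers, function(m) {
    tab <- exprByDose[exprByDose$marker == m, ]
    maxDose <- max(tab$dose)
    fit <- tryCatch(fit4PL(tab$dose, tab$response), error = function(e) NULL)
    fits[[m]] <<- fit
    flat <- !is.null(fit) &&
      abs(fit@top - fit@bottom) <
        2 * sqrt(fit@rss / max(1, nrow(tab) - 4))  # span within noise
    if (is.null(fit) || fit@extrapolated || flat) {
      data.frame(marker = m, ic50 = NA_real_,
                 ic50_label = paste0("> ", format(maxDose)),
                 hill = if (is.null(fit)) NA_real_ else fit@hill,
                 bottom = if (is.null(fit)) NA_real_ else fit@bottom,
                 top = if (is.null(fit)) NA_real_ else fit@top,
                 converged = !is.null(fit) && fit@converged,
                 extrapolated = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(marker = m, ic50 = fit@ic50,
                 ic50_label = format(fit@ic50, digits = 3),
                 hill = fit@hill, bottom = fit@bottom, top = fit@top,
                 converged = fit@converged, extrapolated = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
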