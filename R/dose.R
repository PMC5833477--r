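#' Fit a four-parameter logistic dose-response curve
#'
#' Bounded least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)` with the IC50
#' optimised on the log10-dose scale (Levenberg-Marquardt,
#' \pkg{minpack.lm}). Multistart initialization: IC50 starts at the dose
#' quartiles, the Hill slope at +1 and -1; the best (lowest-RSS)
#' converged start wins. Bounds: `bottom` in \[-20, 50\], `top` in
#' \[50, 150\] percent, `log10(ic50)` within two decades of the dose
#' range, `hill` in \[-10, 10\]. A response with no variation, or a
#' fitted slope indistinguishable from flat, is non-identifiable and
#' returns `converged = FALSE` rather than a forced fit.
#'
#' @param doses positive doses, uM (>= 4 distinct values required).
#' @param effects responses on the percent scale.
#' @return A [DoseResponseFit-class].
#' @examples
#' d <- genDoseResponse(10^seq(-2, 1.5, length.out = 8))
#' ic50(fitFourParameterLogistic(d$data$dose, d$data$effect))
#' @export
fitFourParameterLogistic <- function(doses, effects) {
  if (length(doses) != length(effects))
    stop("doses and effects must have the same length")
  ok <- is.finite(doses) & is.finite(effects)
  doses <- doses[ok]; effects <- effects[ok]
  if (any(doses <= 0)) stop("doses must be > 0")
  if (length(unique(doses)) < 4)
    stop("fit refused: fewer than 4 distinct doses")
  n <- length(doses)
  failed <- new("DoseResponseFit",
    top = NA_real_, bottom = NA_real_, ic50 = NA_real_, hill = NA_real_,
    rss = NA_real_, converged = FALSE, nPoints = as.integer(n)
  )
  if (stats::sd(effects) < 1e-9) return(failed)  # flat curve: non-identifiable
  lr <- range(log10(doses))
  lower <- c(top = 50, bottom = -20, lic = lr[1] - 2, hill = -10)
  upper <- c(top = 150, bottom = 50, lic = lr[2] + 2, hill = 10)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  top0 <- clamp(max(effects), 50, 150)
  bot0 <- clamp(min(effects), -20, 50)
  residFun <- function(p) {
    effects - (p[2] + (p[1] - p[2]) / (1 + (doses / 10^p[3])^p[4]))
  }
  starts <- expand.grid(
    lic = log10(unname(stats::quantile(doses, c(0.25, 0.5, 0.75)))),
    hill = c(1, -1)
  )
  best <- NULL
  bestRss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- suppressWarnings(tryCatch(
      minpack.lm::nls.lm(
        par = c(top = top0, bottom = bot0,
                lic = starts$lic[i], hill = starts$hill[i]),
        lower = lower, upper = upper, fn = residFun,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    ))
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    rss <- sum(fit$fvec^2)
    if (is.finite(rss) && rss < bestRss) { best <- fit; bestRss <- rss }
  }
  if (is.null(best)) return(failed)
  p <- best$par
  if (abs(p[["hill"]]) < 0.05) return(failed)  # flat slope: IC50 unidentifiable
  new("DoseResponseFit",
    top = p[["top"]], bottom = p[["bottom"]],
    ic50 = unname(10^p[["lic"]]), hill = p[["hill"]],
    rss = bestRss, converged = TRUE, nPoints = as.integer(n)
  )
}
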