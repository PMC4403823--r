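#' Five-parameter logistic in pH
#'
#' The empirical model used for pH--oxygen-saturation curves at constant
#' PO2: `S(pH) = c + (d - c) / (1 + exp(b * (e - pH)))^f`, increasing in pH
#' (b > 0), with lower asymptote `c`, upper asymptote `d`, inflection-region
#' anchor `e` and asymmetry exponent `f` (f = 1 gives a symmetric logistic
#' with inflection at `e`).
#'
#' @param b Slope parameter, per pH unit (> 0).
#' @param c Lower asymptote (fraction).
#' @param d Upper asymptote (fraction), `c < d`.
#' @param e Inflection-region pH anchor.
#' @param f Asymmetry exponent (> 0).
#' @return An object of class `fivepl`.
#' @export
fivepl <- function(b, c, d, e, f) {
  for (nm in c("b", "c", "d", "e", "f")) {
    stop_if_not_scalar(get(nm), nm)
  }
  if (b <= 0) stop("b must be > 0 (curves increase with pH)")
  if (f <= 0) stop("f must be > 0")
  if (c >= d) stop("lower asymptote c must be below upper asymptote d")
  structure(list(b = b, c = c, d = d, e = e, f = f), class = "fivepl")
}

#' Evaluate a five-parameter logistic
#'
#' @param p A [fivepl()] (or `ph_o2_curve`, whose parameters are used).
#' @param ph pH values.
#' @return Saturation fractions.
#' @export
fivepl_eval <- function(p, ph) {
  p <- as_fivepl(p)
  p$c + (p$d - p$c) / (1 + exp(p$b * (p$e - ph)))^p$f
}

#' Analytic slope dS/dpH of a five-parameter logistic
#'
#' @inheritParams fivepl_eval
#' @return Slopes (saturation per pH unit), non-negative for b > 0.
#' @export
fivepl_slope <- function(p, ph) {
  p <- as_fivepl(p)
  z <- exp(p$b * (p$e - ph))
  (p$d - p$c) * p$f * p$b * z * (1 + z)^(-p$f - 1)
}

as_fivepl <- function(x) {
  if (inherits(x, "fivepl")) return(x)
  if (inherits(x, "ph_o2_curve")) return(x$params)
  if (is.list(x) && all(c("b", "c", "d", "e", "f") %in% names(x))) {
    return(structure(x[c("b", "c", "d", "e", "f")], class = "fivepl"))
  }
  stop("cannot interpret object as a five-parameter logistic")
}

# Deterministic multi-start list derived from the data quantiles.
fivepl_starts <- function(ph, sat) {
  rng <- range(ph)
  c0 <- min(max(0, min(sat)), 0.45)
  d0 <- max(min(1.05, max(sat)), 0.55)
  mid <- (c0 + d0) / 2
  if (min(sat) > mid) {
    e_base <- rng[1] - 0.2          # transition below the observed window
  } else if (max(sat) < mid) {
    e_base <- rng[2] + 0.2          # transition above the observed window
  } else {
    e_base <- ph[which.min(abs(sat - mid))]
  }
  offs <- c(-0.3, -0.1, 0, 0.1, 0.3)
  b0 <- c(6, 8, 6, 4, 6)
  f0 <- c(1, 0.8, 1, 1.3, 1)
  lapply(seq_along(offs), function(i) {
    list(bb = b0[i], cc = c0, dd = d0, ee = e_base + offs[i], ff = f0[i])
  })
}

fivepl_bounds <- function(ph) {
  rng <- range(ph)
  list(lower = c(bb = 0.5, cc = 0, dd = 0.5, ee = rng[1] - 2, ff = 0.1),
       upper = c(bb = 60, cc = 0.6, dd = 1.05, ee = rng[2] + 2, ff = 10))
}

fivepl_nls <- function(df, start, bounds) {
  suppressWarnings(
    minpack.lm::nlsLM(
      sat ~ cc + (dd - cc) / (1 + exp(bb * (ee - ph)))^ff,
      data = df, start = start,
      lower = bounds$lower, upper = bounds$upper,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-15, ptol = 1e-15)
    )
  )
}

#' Fit a five-parameter logistic pH--oxygen-saturation curve
#'
#' Nonlinear least squares (Levenberg--Marquardt with box bounds) over five
#' deterministic starts derived from the data quantiles; the best converged
#' fit by residual sum of squares is kept. Parameter 95 percent confidence
#' intervals come from residual-resampling bootstrap.
#'
#' @param series A `saturation_series` (columns `ph_free`, `saturation`),
#'   with at least 6 distinct pH points.
#' @param n_boot Number of bootstrap replicates (0 disables the bootstrap).
#' @param seed Integer seed for the bootstrap; the fit is deterministic
#'   given the seed.
#' @return An object of class `ph_o2_curve`: the fitted [fivepl()]
#'   parameters, `po2` (kPa), `temperature` (degC), `n_points`, the
#'   bootstrap draws (`boot`, one row per replicate) and percentile
#'   intervals (`boot_ci`), and the seed.
#' @export
fit_5pl <- function(series, n_boot = 1000, seed = 1L) {
  ph <- series$ph_free
  sat <- series$saturation
  keep <- is.finite(ph) & is.finite(sat)
  ph <- ph[keep]; sat <- sat[keep]
  if (length(unique(round(ph, 8))) < 6) {
    stop("fit_5pl requires at least 6 distinct pH points")
  }
  df <- data.frame(ph = ph, sat = sat)
  bounds <- fivepl_bounds(ph)
  starts <- fivepl_starts(ph, sat)
  fits <- lapply(starts, function(st) {
    fit <- tryCatch(fivepl_nls(df, st, bounds), error = function(e) NULL)
    if (is.null(fit)) {
      # a singular gradient at the start is broken by a small deterministic
      # nudge of the start values
      st2 <- list(bb = st$bb * 1.15, cc = st$cc, dd = st$dd,
                  ee = st$ee + 0.05, ff = st$ff * 1.1)
      fit <- tryCatch(fivepl_nls(df, st2, bounds), error = function(e) NULL)
    }
    fit
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    msg <- paste(vapply(starts, function(st)
      sprintf("(b=%g,c=%g,d=%g,e=%g,f=%g)",
              st$bb, st$cc, st$dd, st$ee, st$ff), character(1)),
      collapse = ", ")
    stop("5PL fit failed to converge from all starts: ", msg)
  }
  best <- fits[ok][[which.min(vapply(fits[ok], deviance, numeric(1)))]]
  cf <- coef(best)
  if (cf["dd"] - cf["cc"] < 0.05) {
    stop("degenerate 5PL fit (upper and lower asymptotes nearly equal)")
  }
  params <- fivepl(b = unname(cf["bb"]), c = unname(cf["cc"]),
                   d = unname(cf["dd"]), e = unname(cf["ee"]),
                   f = unname(cf["ff"]))
  fit_vals <- fitted(best)
  res <- resid(best)

  boot <- NULL
  boot_ci <- NULL
  if (n_boot > 0) {
    draws <- withr::with_seed(seed, {
      lapply(seq_len(n_boot), function(i) {
        yb <- fit_vals + sample(res, replace = TRUE)
        fb <- tryCatch(
          fivepl_nls(data.frame(ph = ph, sat = yb),
                     as.list(setNames(cf, c("bb", "cc", "dd", "ee", "ff"))),
                     bounds),
          error = function(e) NULL)
        if (is.null(fb)) NULL else coef(fb)
      })
    })
    draws <- draws[!vapply(draws, is.null, logical(1))]
    if (length(draws) >= max(10, 0.5 * n_boot)) {
      boot <- do.call(rbind, draws)
      colnames(boot) <- c("b", "c", "d", "e", "f")
      boot_ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975),
                       names = FALSE)
      rownames(boot_ci) <- c("lo", "hi")
      # percentile intervals are widened, if needed, to bracket the point
      # estimate (they can narrowly miss it for parameters at a bound)
      pt <- unlist(params)
      boot_ci["lo", ] <- pmin(boot_ci["lo", ], pt)
      boot_ci["hi", ] <- pmax(boot_ci["hi", ], pt)
    } else {
      warning("bootstrap unstable: fewer than half of the replicates ",
              "converged; no confidence intervals returned")
    }
  }
  structure(
    list(params = params,
         po2 = attr(series, "po2") %||% series$po2_kpa[1],
         temperature = attr(series, "temperature") %||% series$temp_c[1],
         n_points = length(ph),
         boot = boot, boot_ci = boot_ci,
         seed = as.integer(seed),
         data = df),
    class = "ph_o2_curve"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ph_o2_curve <- function(x, ...) {
  p <- x$params
  cat(sprintf("pH-O2 saturation curve at PO2 %g kPa, %g degC (n = %d)\n",
              x$po2, x$temperature, x$n_points))
  cat(sprintf("  5PL: b=%.3f c=%.3f d=%.3f e=%.3f f=%.3f\n",
              p$b, p$c, p$d, p$e, p$f))
  p50 <- tryCatch(ph50(x), error = function(e) NA_real_)
  if (is.finite(p50)) cat(sprintf("  pH50 = %.4f\n", p50))
  else cat("  pH50 undefined (curve does not cross 50% saturation)\n")
  invisible(x)
}

#' pH at half saturation of a fitted curve
#'
#' Unique root of `S(pH) = 0.5`, located by a bracketing root-finder to a
#' tolerance of 1e-8 pH. Undefined (an error) when the lower asymptote is at
#' or above 0.5 or the upper asymptote at or below 0.5, as for cold curves
#' with high residual saturation.
#'
#' @param curve A `ph_o2_curve` or [fivepl()].
#' @param tol Root tolerance, pH units.
#' @return The pH of half saturation.
#' @export
ph50 <- function(curve, tol = 1e-8) {
  p <- as_fivepl(curve)
  if (p$c >= 0.5 || p$d <= 0.5) {
    stop("pH50 undefined: the curve does not cross 50% saturation ",
         sprintf("(c = %.3f, d = %.3f)", p$c, p$d))
  }
  g <- function(ph) fivepl_eval(p, ph) - 0.5
  w <- 1 / p$b
  lo <- p$e - w; hi <- p$e + w
  it <- 0
  while (g(lo) >= 0 && it < 60) { w <- 2 * w; lo <- p$e - w; it <- it + 1 }
  it <- 0
  while (g(hi) <= 0 && it < 60) { w <- 2 * w; hi <- p$e + w; it <- it + 1 }
  if (g(lo) >= 0 || g(hi) <= 0) stop("failed to bracket the half-saturation pH")
  uniroot(g, c(lo, hi), tol = tol / 10)$root
}
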