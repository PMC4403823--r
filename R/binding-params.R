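# Derived pigment parameters: P50 at a stated pH, Bohr coefficient,
# cooperativity of oxygenation-linked proton binding, and the temperature
# sensitivity of P50.

ph50_pairs <- function(curves) {
  po2 <- vapply(curves, function(cv) cv$po2, numeric(1))
  p50 <- vapply(curves, function(cv) {
    tryCatch(ph50(cv), error = function(e) NA_real_)
  }, numeric(1))
  data.frame(po2 = po2, ph50 = p50)
}

bohr_line <- function(curves) {
  pairs <- ph50_pairs(curves)
  pairs <- pairs[is.finite(pairs$ph50), , drop = FALSE]
  if (nrow(pairs) == 0) stop("pH50 undefined for all curves")
  if (nrow(pairs) < 2) stop("need at least 2 curves with a defined pH50")
  if (max(pairs$ph50) - min(pairs$ph50) < 1e-10) {
    stop("degenerate Bohr line: all pH50 values identical")
  }
  list(fit = lm(log10(po2) ~ ph50, data = pairs), pairs = pairs)
}

#' P50 at a stated pH from curves at several PO2 levels
#'
#' Each fixed-PO2 curve contributes the pair (pH50, log10 PO2); because the
#' curve is half-saturated at its pH50, that PO2 is the P50 at that pH. A
#' least-squares line of log10(PO2) on pH50 (the Bohr line) is evaluated at
#' `target_ph` and exponentiated. Evaluation beyond the observed pH50 range
#' is flagged with a warning and in the `"extrapolated"` attribute.
#'
#' @param curves List of `ph_o2_curve` objects at one temperature; at least
#'   two must have a defined pH50.
#' @param target_ph pH at which to report P50.
#' @return P50 in kPa, with attribute `extrapolated` (logical).
#' @export
p50_at_ph <- function(curves, target_ph) {
  bl <- bohr_line(curves)
  extrap <- target_ph < min(bl$pairs$ph50) || target_ph > max(bl$pairs$ph50)
  if (extrap) {
    warning(sprintf(
      "target pH %.3f outside the fitted pH50 range [%.3f, %.3f]",
      target_ph, min(bl$pairs$ph50), max(bl$pairs$ph50)))
  }
  p50 <- 10^unname(predict(bl$fit,
                           newdata = data.frame(ph50 = target_ph)))
  attr(p50, "extrapolated") <- extrap
  p50
}

#' Bohr coefficient from curves at several PO2 levels
#'
#' Slope of the regression of log10(PO2) on pH50 across fixed-PO2 curves,
#' i.e. d log10(P50) / d pH. Curves from different temperatures may be
#' pooled (unweighted).
#'
#' @param curves List of `ph_o2_curve` objects, at least two with a defined
#'   pH50.
#' @return The Bohr coefficient (dimensionless).
#' @export
bohr_coefficient <- function(curves) {
  bl <- bohr_line(curves)
  unname(coef(bl$fit)["ph50"])
}

#' Cooperativity of oxygenation-linked proton binding
#'
#' `capacity` times the maximum slope of the fitted pH oxygen-saturation
#' curve, in mmol O2 L-1 per pH unit. The maximum of the analytic slope is
#' located numerically.
#'
#' @param curve A `ph_o2_curve` or [fivepl()].
#' @param capacity Oxygen carrying capacity, mmol O2 L-1 (>= 0).
#' @return Cooperativity, with attribute `ph_max` (the pH of maximum slope).
#' @export
cooperativity <- function(curve, capacity) {
  if (capacity < 0) stop("capacity must be >= 0")
  p <- as_fivepl(curve)
  # the slope maximum sits at e + log(f)/b; search well beyond it
  half_width <- (abs(log(p$f)) + 30) / p$b
  opt <- optimize(function(ph) fivepl_slope(p, ph),
                  interval = c(p$e - half_width, p$e + half_width),
                  maximum = TRUE, tol = 1e-10)
  out <- capacity * opt$objective
  attr(out, "ph_max") <- opt$maximum
  out
}

#' Temperature sensitivity of P50
#'
#' `(p50_high - p50_low) / (t_high - t_low)` in kPa per degC, with each P50
#' evaluated at the alpha-stat venous pH of its own temperature (the caller
#' supplies P50 values already referred to those pHs).
#'
#' @param p50_low,p50_high P50 (kPa) at the lower/higher temperature.
#' @param t_low,t_high Temperatures, degC; must differ.
#' @return kPa per degC.
#' @export
delta_p50_per_degC <- function(p50_low, p50_high, t_low, t_high) {
  if (!is.finite(p50_low) || !is.finite(p50_high)) {
    stop("P50 undefined at one of the temperatures")
  }
  if (t_high == t_low) stop("temperatures must differ")
  (p50_high - p50_low) / (t_high - t_low)
}

#' Derived binding parameters at one temperature
#'
#' Convenience bundle mirroring a one-temperature row of a binding-parameter
#' table: pH50 per PO2 level, P50 at the stated (alpha-stat venous) pH, the
#' Bohr coefficient over these curves, and the mean cooperativity. When the
#' curves carry bootstrap draws, joint percentile intervals for P50 and the
#' Bohr coefficient are computed by recomputing both quantities on each
#' bootstrap replicate.
#'
#' @param curves List of `ph_o2_curve` objects at one temperature.
#' @param capacity Oxygen carrying capacity, mmol O2 L-1.
#' @param venous_ph pH at which P50 is reported.
#' @param species Optional species tag.
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(curves, capacity, venous_ph, species = "") {
  pairs <- ph50_pairs(curves)
  p50 <- tryCatch(suppressWarnings(p50_at_ph(curves, venous_ph)),
                  error = function(e) NA_real_)
  bohr <- tryCatch(bohr_coefficient(curves), error = function(e) NA_real_)
  coop <- vapply(curves, function(cv)
    as.numeric(cooperativity(cv, capacity)), numeric(1))
  ci <- binding_boot_ci(curves, capacity, venous_ph)
  structure(
    list(species = species,
         temperature = curves[[1]]$temperature,
         ph50_by_po2 = setNames(pairs$ph50, sprintf("po2_%g", pairs$po2)),
         venous_ph = venous_ph,
         p50 = as.numeric(p50),
         p50_ci = ci$p50,
         bohr = bohr,
         bohr_ci = ci$bohr,
         cooperativity = mean(coop),
         cooperativity_ci = ci$cooperativity,
         cooperativity_by_po2 = setNames(coop, sprintf("po2_%g", pairs$po2)),
         capacity = capacity),
    class = "binding_params"
  )
}

# Joint bootstrap intervals for P50-at-pH, Bohr coefficient and mean
# cooperativity, using the per-curve bootstrap parameter draws replicate by
# replicate. Returns NA intervals when any curve lacks draws.
binding_boot_ci <- function(curves, capacity, venous_ph) {
  na_ci <- c(lo = NA_real_, hi = NA_real_)
  out <- list(p50 = na_ci, bohr = na_ci, cooperativity = na_ci)
  boots <- lapply(curves, function(cv) cv$boot)
  if (any(vapply(boots, is.null, logical(1)))) return(out)
  n <- min(vapply(boots, nrow, integer(1)))
  if (n < 10) return(out)
  po2 <- vapply(curves, function(cv) cv$po2, numeric(1))
  reps <- vapply(seq_len(n), function(i) {
    p50s <- vapply(seq_along(curves), function(j) {
      p <- boots[[j]][i, ]
      tryCatch(
        ph50(fivepl(p["b"], p["c"], p["d"], p["e"], p["f"])),
        error = function(e) NA_real_)
    }, numeric(1))
    coopv <- vapply(seq_along(curves), function(j) {
      p <- boots[[j]][i, ]
      as.numeric(cooperativity(
        fivepl(p["b"], p["c"], p["d"], p["e"], p["f"]), capacity))
    }, numeric(1))
    keep <- is.finite(p50s)
    if (sum(keep) >= 2 && max(p50s[keep]) - min(p50s[keep]) > 1e-10) {
      fit <- lm(y ~ x, data = data.frame(x = p50s[keep],
                                         y = log10(po2[keep])))
      c(10^unname(predict(fit, newdata = data.frame(x = venous_ph))),
        unname(coef(fit)[2]), mean(coopv))
    } else {
      c(NA_real_, NA_real_, mean(coopv))
    }
  }, numeric(3))
  qs <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 10) return(na_ci)
    setNames(quantile(v, c(0.025, 0.975), names = FALSE), c("lo", "hi"))
  }
  list(p50 = qs(reps[1, ]), bohr = qs(reps[2, ]),
       cooperativity = qs(reps[3, ]))
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("Binding parameters%s at %g degC\n",
              if (nzchar(x$species)) paste0(" [", x$species, "]") else "",
              x$temperature))
  cat(sprintf("  P50 at pH %.3f : %s kPa\n", x$venous_ph,
              ifelse(is.finite(x$p50), sprintf("%.3f", x$p50), "undefined")))
  cat(sprintf("  Bohr coefficient: %s\n",
              ifelse(is.finite(x$bohr), sprintf("%.3f", x$bohr), "undefined")))
  cat(sprintf("  Cooperativity   : %.3f mmol O2 L-1 pH-1\n", x$cooperativity))
  invisible(x)
}
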