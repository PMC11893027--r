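#' Polynomial growth-curve fit against gestational age
#'
#' Ordinary least squares on the polynomial basis `{1, ga, ..., ga^degree}`.
#' The gestational-age association p-value is the joint F-test of all GA
#' terms; per-coefficient t-test p-values are also reported. A constant
#' outcome yields zero GA coefficients, an undefined p-value and R-squared
#' zero.
#'
#' @param ga Gestational ages in decimal weeks.
#' @param y Outcome values (e.g., regional mean T2* in ms, or volume in mL).
#' @param degree Polynomial degree (>= 1, default 2).
#' @return A `growth_model`: list with `degree`, `coefficients` (intercept
#'   first), `p_value` (joint F), `term_p_values`, `r_squared`, `n`.
#' @export
#' @examples
#' ga <- seq(20, 40, length.out = 30)
#' fit_growth_curve(ga, 400 - 3 * ga - 0.1 * ga^2)
fit_growth_curve <- function(ga, y, degree = 2) {
  if (degree < 1) stop("degree must be >= 1")
  if (length(ga) != length(y)) stop("ga and y must have the same length")
  n <- length(ga)
  if (n < degree + 2) {
    stop("need at least degree + 2 observations, got ", n)
  }
  if (var(y) == 0) {
    coefs <- c(y[1], rep(0, degree))
    names(coefs) <- c("(Intercept)", paste0("ga^", seq_len(degree)))
    return(structure(list(degree = degree, coefficients = coefs,
                          p_value = NA_real_,
                          term_p_values = rep(NA_real_, degree),
                          r_squared = 0, n = n), class = "growth_model"))
  }
  df <- data.frame(ga = ga, y = y)
  fit <- lm(y ~ poly(ga, degree, raw = TRUE), data = df)
  sm <- summary(fit)
  fs <- sm$fstatistic
  p <- if (is.null(fs)) NA_real_ else
    unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  coefs <- coef(fit)
  names(coefs) <- c("(Intercept)", paste0("ga^", seq_len(degree)))
  tp <- sm$coefficients[-1, "Pr(>|t|)"]
  structure(list(degree = degree, coefficients = coefs, p_value = p,
                 term_p_values = unname(tp), r_squared = sm$r.squared,
                 n = n, fit = fit),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("growth_model (degree %d, n = %d): R2 = %.3f, joint GA p = %s\n",
              x$degree, x$n, x$r_squared, format.pval(x$p_value)))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Predict from a growth model
#' @param object A `growth_model`.
#' @param ga Gestational ages at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.growth_model <- function(object, ga, ...) {
  X <- outer(ga, 0:object$degree, `^`)
  as.numeric(X %*% object$coefficients)
}

#' Fit growth curves for every region of a cohort table
#'
#' @param records Data frame with columns `region`, `ga` and the outcome
#'   column named by `outcome`.
#' @param outcome Column to model (default `"mean_t2star_ms"`).
#' @param degree Polynomial degree.
#' @return Named list of `growth_model` objects, one per region present.
#' @export
fit_region_growth <- function(records, outcome = "mean_t2star_ms",
                              degree = 2) {
  regions <- unique(records$region)
  setNames(lapply(regions, function(rg) {
    sub <- records[records$region == rg, ]
    fit_growth_curve(sub$ga, sub[[outcome]], degree = degree)
  }), regions)
}

# half-open 2-week bins [a, a+2), last bin closed at the upper edge
ga_bin_index <- function(ga, edges) {
  idx <- findInterval(ga, edges, rightmost.closed = TRUE)
  idx[ga < edges[1] | ga > edges[length(edges)]] <- NA_integer_
  idx
}

#' Normative percentile table over 2-week gestational-age bins
#'
#' Per (region, bin): scan count, arithmetic mean and empirical
#' 5th/50th/95th percentiles (linear-interpolation quantiles, type 7 --
#' stated explicitly because small-bin percentiles are sensitive to the
#' convention). Bins are half-open `[a, a+2)`, the last closed. Empty bins
#' are emitted with `n = 0` and undefined statistics.
#'
#' @param records Data frame with columns `region`, `ga` and the outcome
#'   column named by `outcome`; all `ga` must lie in the binned range.
#' @param outcome Outcome column (default `"mean_t2star_ms"`).
#' @param edges Bin edges in weeks (default `seq(20, 40, 2)`).
#' @return A `percentile_table` data frame with columns `region`,
#'   `bin_start`, `bin_end`, `n`, `mean`, `p5`, `p50`, `p95`; the raw
#'   per-cell values are attached as the `"bin_values"` attribute for
#'   centile lookups.
#' @export
make_percentile_table <- function(records, outcome = "mean_t2star_ms",
                                  edges = seq(20, 40, by = 2)) {
  if (any(records$ga < edges[1] | records$ga > edges[length(edges)])) {
    stop("all gestational ages must lie within the binned range")
  }
  regions <- unique(records$region)
  nb <- length(edges) - 1
  rows <- list()
  bin_values <- list()
  for (rg in regions) {
    sub <- records[records$region == rg, ]
    bi <- ga_bin_index(sub$ga, edges)
    for (b in seq_len(nb)) {
      vals <- sub[[outcome]][which(bi == b)]
      vals <- vals[is.finite(vals)]
      key <- paste(rg, b, sep = "|")
      bin_values[[key]] <- sort(vals)
      if (length(vals) == 0) {
        rows[[key]] <- data.frame(region = rg, bin_start = edges[b],
                                  bin_end = edges[b + 1], n = 0L,
                                  mean = NA_real_, p5 = NA_real_,
                                  p50 = NA_real_, p95 = NA_real_,
                                  stringsAsFactors = FALSE)
      } else {
        q <- quantile(vals, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
        rows[[key]] <- data.frame(region = rg, bin_start = edges[b],
                                  bin_end = edges[b + 1],
                                  n = length(vals), mean = mean(vals),
                                  p5 = q[1], p50 = q[2], p95 = q[3],
                                  stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bin_values") <- bin_values
  attr(out, "edges") <- edges
  attr(out, "quantile_type") <- 7L
  class(out) <- c("percentile_table", "data.frame")
  out
}

#' Centile position of a value within its gestational-age bin
#'
#' Returns the fraction of the bin's control values lying below `value`,
#' by linear interpolation of the empirical distribution (the inverse of
#' the type-7 quantile). Values below the bin minimum return 0, above the
#' maximum 1. An empty bin returns `NA` with a warning.
#'
#' @param table A `percentile_table`.
#' @param region Region name.
#' @param ga Gestational age in weeks (within the binned range).
#' @param value Measurement to place (same units as the table outcome).
#' @return A fraction in `[0, 1]`, or `NA` for an empty bin.
#' @export
evaluate_centile <- function(table, region, ga, value) {
  edges <- attr(table, "edges")
  if (ga < edges[1] || ga > edges[length(edges)]) {
    stop("gestational age outside the binned range")
  }
  b <- ga_bin_index(ga, edges)
  vals <- attr(table, "bin_values")[[paste(region, b, sep = "|")]]
  if (is.null(vals) || length(vals) == 0) {
    warning("empty bin: centile undefined")
    return(NA_real_)
  }
  if (value <= vals[1]) return(0)
  n <- length(vals)
  if (value >= vals[n]) return(1)
  if (n == 1) return(0.5)
  approx(vals, (seq_len(n) - 1) / (n - 1), xout = value,
         ties = mean)$y
}
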