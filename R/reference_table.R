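#' Region names of the seven-category fetal brain parcellation
#'
#' The merged parcellation used throughout the package: external
#' cerebrospinal fluid, cortical gray matter, white matter, deep gray matter
#' (thalami and basal ganglia), ventricles, cerebellum (including the
#' vermis), and brainstem. Integer labels 1..7 in this order; 0 is
#' background.
#'
#' @return Character vector of length 7, named by label id.
#' @export
region_names <- function() {
  c(`1` = "eCSF", `2` = "gray_matter", `3` = "white_matter",
    `4` = "deep_gray_matter", `5` = "ventricles", `6` = "cerebellum",
    `7` = "brainstem")
}

# Normative regional T2* (ms) of the fetal brain at 0.55 T in healthy
# controls, per 2-week gestational-age bin: per-bin scan count, mean and
# empirical 5th/50th/95th percentiles. Bins are half-open [a, a+2) weeks,
# the last bin closed at 40; `midpoint` is the bin centre used for
# interpolation.
.t2star_reference_build <- function() {
  bin_start <- seq(20, 38, by = 2)
  n <- c(8, 10, 11, 9, 9, 8, 11, 8, 7, 11)
  vals <- list(
    eCSF = list(
      mean = c(357.7, 362.8, 365.9, 370.4, 358.9, 357.5, 331.4, 307.7, 266.4, 228.9),
      p5   = c(328.3, 337.0, 336.4, 341.9, 309.3, 328.9, 298.8, 276.6, 217.3, 198.7),
      p50  = c(354.1, 356.1, 371.8, 374.2, 352.5, 357.1, 333.5, 302.0, 280.9, 230.7),
      p95  = c(394.3, 392.4, 386.7, 399.1, 413.2, 383.4, 358.5, 339.6, 299.3, 264.0)),
    gray_matter = list(
      mean = c(294.4, 272.9, 266.9, 258.2, 259.0, 254.1, 233.6, 225.0, 201.3, 178.1),
      p5   = c(266.8, 250.1, 242.1, 232.4, 225.9, 228.1, 214.9, 200.4, 180.3, 157.7),
      p50  = c(290.3, 264.5, 261.0, 261.7, 260.1, 246.0, 235.7, 226.9, 196.4, 179.4),
      p95  = c(328.7, 316.6, 289.0, 286.5, 295.1, 288.1, 250.6, 243.0, 231.0, 201.7)),
    white_matter = list(
      mean = c(311.7, 320.5, 321.6, 331.6, 321.0, 316.9, 289.7, 281.3, 253.0, 221.7),
      p5   = c(293.3, 292.9, 290.0, 308.9, 286.8, 280.6, 264.3, 249.0, 228.9, 203.7),
      p50  = c(317.7, 320.4, 329.5, 341.7, 333.1, 311.5, 294.1, 286.0, 249.6, 219.0),
      p95  = c(323.6, 346.1, 340.2, 343.6, 346.7, 359.1, 315.0, 301.8, 290.1, 243.3)),
    ventricles = list(
      mean = c(409.0, 402.6, 395.9, 420.6, 391.1, 385.1, 378.5, 369.0, 364.4, 332.9),
      p5   = c(371.8, 379.4, 324.0, 372.8, 364.3, 343.6, 325.8, 347.2, 340.2, 275.8),
      p50  = c(412.3, 398.5, 415.3, 427.5, 390.8, 387.4, 380.5, 358.1, 358.0, 336.9),
      p95  = c(438.3, 429.7, 436.5, 453.2, 412.1, 418.1, 416.3, 402.7, 397.7, 372.1)),
    brainstem = list(
      mean = c(243.0, 236.7, 225.6, 222.3, 210.0, 199.6, 189.2, 177.6, 168.7, 149.6),
      p5   = c(227.2, 221.7, 217.9, 211.7, 175.5, 187.7, 176.3, 163.9, 145.4, 135.6),
      p50  = c(241.2, 236.1, 223.3, 222.0, 215.0, 196.8, 184.3, 177.7, 165.1, 148.3),
      p95  = c(267.8, 252.2, 238.7, 237.2, 229.3, 220.1, 205.5, 188.9, 202.4, 160.0)),
    cerebellum = list(
      mean = c(315.8, 337.4, 325.4, 315.9, 297.6, 288.0, 253.7, 243.8, 214.5, 178.2),
      p5   = c(289.7, 297.9, 309.6, 290.1, 259.7, 264.6, 223.2, 219.7, 172.4, 151.2),
      p50  = c(319.7, 344.3, 319.9, 321.9, 297.7, 286.1, 254.7, 244.5, 210.4, 181.8),
      p95  = c(335.6, 371.9, 346.1, 332.2, 322.5, 312.3, 281.0, 266.0, 249.0, 194.4)),
    deep_gray_matter = list(
      mean = c(223.2, 251.2, 242.3, 243.4, 230.9, 221.6, 211.0, 198.4, 184.8, 167.9),
      p5   = c(150.4, 223.6, 221.9, 232.2, 213.5, 198.4, 196.7, 188.4, 172.7, 154.0),
      p50  = c(242.4, 249.7, 247.0, 246.9, 234.3, 225.1, 213.9, 199.2, 176.1, 165.7),
      p95  = c(262.1, 275.3, 256.0, 248.8, 245.1, 247.3, 225.1, 208.5, 208.7, 185.9))
  )
  rows <- lapply(names(vals), function(rg) {
    data.frame(region = rg, bin_start = bin_start, bin_end = bin_start + 2,
               midpoint = bin_start + 1, n = n,
               mean = vals[[rg]]$mean, p5 = vals[[rg]]$p5,
               p50 = vals[[rg]]$p50, p95 = vals[[rg]]$p95,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.t2star_reference <- .t2star_reference_build()

#' Normative regional T2* reference table
#'
#' Per-region, per-2-week-bin normative T2* values (ms) in healthy control
#' fetuses at 0.55 T: scan count, mean, and 5th/50th/95th percentiles for
#' gestational ages 20--40 weeks. Bins are half-open `[a, a+2)` weeks with
#' the last bin closed at 40; `midpoint` marks the bin centre.
#'
#' @return A data frame with columns `region`, `bin_start`, `bin_end`,
#'   `midpoint`, `n`, `mean`, `p5`, `p50`, `p95` (70 rows: 7 regions x 10
#'   bins).
#' @export
#' @examples
#' head(reference_t2star_table())
reference_t2star_table <- function() .t2star_reference

#' Look up the normative mean T2* of a brain region at a gestational age
#'
#' Piecewise-linear interpolation of the per-bin normative means placed at
#' the bin midpoints (21, 23, ..., 39 weeks), with constant extrapolation
#' beyond the outermost midpoints. Values in ms.
#'
#' @param region One of the seven region names (see [region_names()]).
#' @param ga Gestational age(s) in decimal weeks, within `[20, 40]`.
#' @return Numeric vector of T2* values (ms), same length as `ga`.
#' @export
#' @examples
#' lookup_reference_t2star("white_matter", 27)
#' lookup_reference_t2star("cerebellum", c(21, 22, 23))
lookup_reference_t2star <- function(region, ga) {
  region <- match.arg(region, unname(region_names()))
  if (any(!is.finite(ga)) || any(ga < 20) || any(ga > 40)) {
    stop("gestational age must lie in [20, 40] weeks")
  }
  ref <- .t2star_reference[.t2star_reference$region == region, ]
  approx(ref$midpoint, ref$mean, xout = ga, rule = 2)$y
}

#' Synthetic normative regional volume model
#'
#' A smooth per-region volume growth model (mL) used by the synthetic cohort
#' generator. The published reference table for this parcellation reports
#' T2* percentiles; region volumes here follow a cubic-in-linear-scale
#' growth convention anchored so cortical gray matter reaches about 51 mL at
#' 31 weeks, consistent with volumetry of the same age range. This is a
#' package convention for simulation, not a measured normative table.
#'
#' @param region One of the seven region names.
#' @param ga Gestational age(s) in decimal weeks, within `[20, 40]`.
#' @return Volume(s) in mL.
#' @export
reference_volume <- function(region, ga) {
  region <- match.arg(region, unname(region_names()))
  if (any(ga < 20) || any(ga > 40)) {
    stop("gestational age must lie in [20, 40] weeks")
  }
  # linear spatial scale factor shared with the phantom geometry
  v40 <- c(eCSF = 120, gray_matter = 95, white_matter = 180,
           deep_gray_matter = 30, ventricles = 10, cerebellum = 25,
           brainstem = 8)
  s <- 0.60 + 0.40 * (ga - 20) / 20
  unname(v40[region]) * s^3
}
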