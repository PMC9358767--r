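## Specimen-level statistics across an ontogenetic series: PCA carapace
## dimensions, log-log scaling regressions with 95% confidence intervals, a
## Poisson count model for scute number, and series summaries.

#' Carapace length, height and width from scute centers
#'
#' Principal component analysis of the N x 3 scute center coordinates; the
#' dimension along PC k is the range (max - min) of the scores. For a
#' carapace, PC1 is the anteroposterior axis (length), PC2 the dorsoventral
#' axis (height) and PC3 the laterolateral axis (width).
#'
#' @param centers N x 3 matrix of scute centers (mm), N >= 4, not collinear.
#' @return named numeric `c(length_mm, height_mm, width_mm)`.
#' @export
carapace_dimensions <- function(centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 4L) stop("need at least 4 scute centers")
  p <- prcomp(centers, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  if (ev[3] <= .Machine$double.eps * ev[1])
    stop("scute centers are (near) collinear or coplanar")
  if (any(ev[-3] / ev[-1] < 1.01))
    warning("axis identity ambiguous: near-equal PCA eigenvalues (ratio < 1.01)")
  dims <- apply(p$x, 2, function(s) diff(range(s)))
  c(length_mm = dims[[1]], height_mm = dims[[2]], width_mm = dims[[3]])
}

new_allometry_fit <- function(slope, intercept, ci, model, ref, n) {
  structure(list(slope = slope, intercept = intercept,
                 ci_low = ci[1], ci_high = ci[2], model = model,
                 isometry_reference = ref, n = n),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("<allometry_fit %s> slope %.4g [%.4g; %.4g] (n = %d%s)\n",
              x$model, x$slope, x$ci_low, x$ci_high, x$n,
              if (is.na(x$isometry_reference)) "" else
                sprintf(", isometry ref %.2g", x$isometry_reference)))
  invisible(x)
}

#' Log-log scaling regression
#'
#' Ordinary least squares of ln(y) on ln(x) with the t-based 95% confidence
#' interval of the slope. The slope is the allometric scaling exponent; for
#' regressions on surface area, isometry corresponds to 0.5 for linear
#' dimensions, 1.0 for areas and 1.5 for volumes.
#'
#' @param x positive predictor values (typically surface areas).
#' @param y positive response values.
#' @param isometry_reference optional reference exponent stored with the fit.
#' @return an `allometry_fit`: `slope`, `intercept`, `ci_low`, `ci_high`,
#'   `model = "loglog_ols"`, `isometry_reference`, `n`.
#' @export
fit_loglog <- function(x, y, isometry_reference = NA_real_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("log-log regression requires positive finite x and y")
  fit <- lm(log(y) ~ log(x))
  # suppress the "essentially perfect fit" warning: exact power laws are a
  # legitimate input here (noiseless ground-truth tables)
  ci <- suppressWarnings(confint(fit, "log(x)", level = 0.95))
  new_allometry_fit(unname(coef(fit)[2]), unname(coef(fit)[1]),
                    as.numeric(ci), "loglog_ols", isometry_reference,
                    length(x))
}

#' Poisson regression of scute counts on surface area
#'
#' Generalized linear model with Poisson family and log link,
#' `count ~ SA` with SA untransformed (in the configured unit; cm^2 by
#' convention for carapace-scale areas, recorded in the result). The
#' reported slope is the exponentiated coefficient exp(beta1) — the
#' multiplicative change in expected count per unit SA — with the
#' exponentiated Wald 95% confidence interval.
#'
#' @param counts positive integer scute counts.
#' @param sa surface areas (same length).
#' @param sa_unit unit label recorded in the fit metadata (default "cm2").
#' @return an `allometry_fit` with `model = "poisson_glm"`; `slope` is
#'   exp(beta1).
#' @export
fit_scute_count <- function(counts, sa, sa_unit = "cm2") {
  if (length(counts) != length(sa)) stop("counts and sa lengths differ")
  if (length(counts) < 3L) stop("need at least 3 points")
  if (any(counts != round(counts)) || any(counts <= 0))
    stop("counts must be positive integers")
  fit <- glm(counts ~ sa, family = poisson(link = "log"))
  b1 <- unname(coef(fit)[2])
  se <- sqrt(diag(vcov(fit)))[2]
  ci <- exp(b1 + c(-1, 1) * qnorm(0.975) * se)
  out <- new_allometry_fit(exp(b1), unname(coef(fit)[1]), ci, "poisson_glm",
                           1.0, length(counts))
  out$sa_unit <- sa_unit
  out
}

#' Five-number summary with interpolated quartiles
#'
#' min, lower quartile, median, upper quartile, max; quartiles by linear
#' interpolation of order statistics (quantile type 7). The median of an
#' even count is the mean of the two central order statistics.
#'
#' @param x numeric vector (NAs dropped).
#' @return named numeric of length 5.
#' @export
five_number <- function(x) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Summarize an ontogenetic series and fit all scaling models
#'
#' Builds the per-specimen series table (surface area, PCA carapace
#' dimensions, scute count, per-scute medians with PBA sentinels excluded),
#' fits the log-log scaling model for every dimension variable against SA,
#' the Poisson model for scute count, and collects five-number summaries of
#' every normalized variable per specimen.
#'
#' @param stats_list list of `scute_stats` data frames, one per specimen
#'   (see [compute_scute_stats()]), ordered by specimen.
#' @param sa_mm2 numeric vector of carapace surface areas (mm^2).
#' @param sa_unit_glm unit for the Poisson covariate: `"cm2"` (default) or
#'   `"mm2"`.
#' @return list of class `series_summary` with `table` (per-specimen rows),
#'   `fits` (named list of `allometry_fit`: length, height, width,
#'   med_volume, med_pba, med_thickness, med_width, n_scutes) and
#'   `box_summaries` (long data frame of five-number summaries of the
#'   normalized variables per specimen, ordered by SA).
#' @export
summarize_series <- function(stats_list, sa_mm2, sa_unit_glm = c("cm2", "mm2")) {
  sa_unit_glm <- match.arg(sa_unit_glm)
  n <- length(stats_list)
  if (n < 3L) stop("need at least 3 specimens")
  if (length(sa_mm2) != n) stop("one SA per specimen required")

  med_or_na <- function(x) if (length(x) == 0L) NA_real_ else median(x)
  rows <- lapply(seq_len(n), function(i) {
    st <- stats_list[[i]]
    dims <- carapace_dimensions(as.matrix(st[, c("cx", "cy", "cz")]))
    pba_ok <- st$pba_mm2[st$pba_mm2 != PBA_SENTINEL]
    data.frame(specimen = i, sa_mm2 = sa_mm2[i],
               length_mm = dims[["length_mm"]],
               height_mm = dims[["height_mm"]],
               width_mm = dims[["width_mm"]],
               n_scutes = nrow(st),
               med_volume_mm3 = median(st$volume_mm3),
               med_pba_mm2 = med_or_na(pba_ok),
               med_thickness_mm = median(st$thickness_mm),
               med_width_mm = median(st$width_mm))
  })
  tab <- do.call(rbind, rows)
  fits <- fit_series_table(tab, sa_unit_glm)

  box <- do.call(rbind, lapply(order(sa_mm2), function(i) {
    st <- normalize_stats(stats_list[[i]], sa_mm2[i])
    vars <- c("norm_volume", "norm_pba", "norm_thickness", "norm_width",
              "norm_gaussK", "norm_meanH")
    do.call(rbind, lapply(vars, function(v) {
      fn <- five_number(st[[v]])
      data.frame(specimen = i, sa_mm2 = sa_mm2[i], variable = v,
                 min = fn[["min"]], q1 = fn[["q1"]], median = fn[["median"]],
                 q3 = fn[["q3"]], max = fn[["max"]])
    }))
  }))
  structure(list(table = tab, fits = fits, box_summaries = box),
            class = "series_summary")
}

#' Fit all scaling models to a per-specimen series table
#'
#' Works directly on a `scute_series` table (ground truth or table-only
#' series) or on the table from [summarize_series()].
#'
#' @param tab data frame with columns `sa_mm2`, `length_mm`, `height_mm`,
#'   `width_mm`, `n_scutes`, `med_volume_mm3`, `med_pba_mm2`,
#'   `med_thickness_mm`, `med_width_mm`.
#' @param sa_unit_glm `"cm2"` (default) or `"mm2"` for the Poisson covariate.
#' @return named list of `allometry_fit` objects.
#' @export
fit_series_table <- function(tab, sa_unit_glm = c("cm2", "mm2")) {
  sa_unit_glm <- match.arg(sa_unit_glm)
  sa <- tab$sa_mm2
  spec <- list(length = c("length_mm", 0.5),
               height = c("height_mm", 0.5),
               width = c("width_mm", 0.5),
               med_volume = c("med_volume_mm3", 1.5),
               med_pba = c("med_pba_mm2", 1.0),
               med_thickness = c("med_thickness_mm", 0.5),
               med_width = c("med_width_mm", 0.5))
  fits <- list()
  for (nm in names(spec)) {
    col <- spec[[nm]][1]
    ref <- as.numeric(spec[[nm]][2])
    y <- tab[[col]]
    ok <- is.finite(y) & y > 0
    if (sum(ok) < length(y))
      warning(sum(!ok), " specimen(s) dropped from the ", nm,
              " fit (no valid median)")
    if (sum(ok) >= 3L)
      fits[[nm]] <- fit_loglog(sa[ok], y[ok], isometry_reference = ref)
  }
  sa_glm <- if (sa_unit_glm == "cm2") sa / 100 else sa
  fits$n_scutes <- fit_scute_count(tab$n_scutes, sa_glm, sa_unit = sa_unit_glm)
  fits
}

#' Write fitted scaling models as JSON
#' @param fits named list of `allometry_fit` (e.g., from
#'   [fit_series_table()]).
#' @param path output JSON path.
#' @export
write_fits <- function(fits, path) {
  out <- lapply(fits, function(f)
    list(slope = f$slope, intercept = f$intercept,
         ci = c(f$ci_low, f$ci_high), model = f$model,
         isometry_reference = f$isometry_reference, n = f$n))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# classification used in reports: does the CI sit below/above/around the
# isometry reference?
allometry_class <- function(fit) {
  ref <- fit$isometry_reference
  if (is.na(ref)) return("unclassified")
  if (fit$ci_low > ref) "positive allometry"
  else if (fit$ci_high < ref) "negative allometry"
  else "isometric"
}
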