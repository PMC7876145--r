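#' Average CEST profiles over a symmetric offset pair
#'
#' Saturation profiles of broad bound states are symmetric in the offset, so
#' the per-residue ratio at +x and -x kHz is averaged to halve the noise.
#'
#' @param profiles a [cest_profile_set()]
#' @param offset_magnitude positive offset x (kHz); both +x and -x must be
#'   present in the profile set
#' @return named numeric vector, one averaged ratio per residue
#' @export
average_cest_offsets <- function(profiles, offset_magnitude) {
  stopifnot(inherits(profiles, "cest_profile_set"), offset_magnitude > 0)
  ip <- which(abs(profiles$offsets - offset_magnitude) < 1e-9)
  im <- which(abs(profiles$offsets + offset_magnitude) < 1e-9)
  if (length(ip) == 0)
    stop(sprintf("offset +%g kHz not present in profile set", offset_magnitude))
  if (length(im) == 0)
    stop(sprintf("offset -%g kHz not present in profile set", offset_magnitude))
  avg <- (profiles$ratios[, ip[1]] + profiles$ratios[, im[1]]) / 2
  names(avg) <- profiles$residues
  avg
}

#' Estimate the detached-conformation population of a region
#'
#' Ratio estimator for the fraction of conformations in which a region is
#' detached from the membrane: the region's mean offset-averaged CEST ratio
#' divided by that of a reference region assumed fully detached (default
#' the C-terminal residues 120-140, which show no membrane affinity). A
#' fully detached region retains the reference's saturation level (ratio 1);
#' a fully bound region is completely saturated (ratio 0). The estimate is
#' clipped to \[0, 1\].
#'
#' @param profiles a [cest_profile_set()]
#' @param region a [region_definition()] for the region of interest
#' @param reference_free_region reference [region_definition()] assumed
#'   fully detached; default residues 120-140
#' @param offset_magnitude offset pair used (kHz), default 1.5
#' @return object of class `detached_population_estimate` with
#'   `fraction_detached` in \[0,1\]
#' @export
estimate_detached_population <- function(profiles, region,
                                         reference_free_region = region_definition(120, 140, "C-terminal"),
                                         offset_magnitude = 1.5) {
  stopifnot(inherits(region, "region_definition"),
            inherits(reference_free_region, "region_definition"))
  avg <- average_cest_offsets(profiles, offset_magnitude)
  res <- profiles$residues
  in_region <- res >= region$start & res <= region$end
  in_ref <- res >= reference_free_region$start & res <= reference_free_region$end
  if (!any(in_region)) stop("no residues in target region")
  if (!any(in_ref)) stop("no residues in reference region")
  m_ref <- mean(avg[in_ref])
  if (m_ref <= 0.1)
    stop("reference region is saturated (mean ratio <= 0.1); estimator invalid")
  frac <- min(max(mean(avg[in_region]) / m_ref, 0), 1)
  structure(list(region = region, reference_region = reference_free_region,
                 fraction_detached = frac, offset_used = offset_magnitude),
            class = "detached_population_estimate")
}

#' @export
print.detached_population_estimate <- function(x, ...) {
  cat(sprintf("Detached population of region %s: %.1f%% (reference %s, offsets +/-%g kHz)\n",
              x$region$name, 100 * x$fraction_detached,
              x$reference_region$name, x$offset_used))
  invisible(x)
}

#' Fit single-exponential T2 decays per residue
#'
#' Least-squares fit of `A * exp(-delay / t2)` to each residue's relaxation
#' decay. Residues whose decay cannot be fit with a positive finite T2
#' (e.g. constant intensities) are flagged invalid rather than erroring.
#'
#' @param series a [relaxation_series()] with at least 3 delays
#' @return object of class `t2_result`: data frame with `residue`, `t2`
#'   (ms), `t2_se`, `amplitude`, `valid`
#' @export
fit_t2 <- function(series) {
  stopifnot(inherits(series, "relaxation_series"))
  d <- series$delays
  if (length(d) < 3) stop("need at least 3 relaxation delays")
  fit_one <- function(y) {
    # log-linear start from positive intensities
    pos <- y > 0
    out <- c(t2 = NA_real_, se = NA_real_, A = NA_real_)
    if (sum(pos) < 2) return(out)
    lf <- stats::lm(log(y[pos]) ~ d[pos])
    rate0 <- -unname(stats::coef(lf)[2])
    if (!is.finite(rate0) || rate0 <= 1e-12) rate0 <- 1 / (max(d) + 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-d / t2),
                        data = data.frame(d = d, y = y),
                        start = list(A = max(y), t2 = 1 / rate0),
                        lower = c(A = 0, t2 = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(out)
    co <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients["t2", "Std. Error"],
                   error = function(e) NA_real_)
    c(t2 = unname(co["t2"]), se = se, A = unname(co["A"]))
  }
  res <- t(apply(series$intensities, 1, fit_one))
  # a fit pinned at huge t2 with enormous SE means "no measurable decay"
  valid <- is.finite(res[, "t2"]) & res[, "t2"] > 0 &
    is.finite(res[, "se"]) & res[, "se"] < res[, "t2"] * 100 &
    res[, "t2"] < 100 * max(d)
  structure(data.frame(residue = series$residues,
                       t2 = res[, "t2"], t2_se = res[, "se"],
                       amplitude = res[, "A"], valid = valid,
                       row.names = NULL),
            class = c("t2_result", "data.frame"))
}
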