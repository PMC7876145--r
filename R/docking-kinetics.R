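#' Analysis window over a frame sequence
#'
#' Frames are 0-based and bounds inclusive. The standard protocol analyses
#' the last 3500 of 7500 frames so that the initial photobleaching step has
#' reached steady state; [last_frames_window()] builds that window.
#'
#' @param first_frame,last_frame 0-based inclusive bounds
#' @return object of class `analysis_window`
#' @export
analysis_window <- function(first_frame, last_frame) {
  stopifnot(first_frame >= 0, last_frame >= first_frame)
  structure(list(first_frame = as.integer(first_frame),
                 last_frame = as.integer(last_frame)),
            class = "analysis_window")
}

#' @param frame_count total frames available
#' @param n number of trailing frames to keep (default 3500)
#' @rdname analysis_window
#' @export
last_frames_window <- function(frame_count, n = 3500) {
  n <- min(n, frame_count)
  analysis_window(frame_count - n, frame_count - 1L)
}

# presence intervals (runs of consecutive frames) per track, clipped to window
.track_intervals <- function(tracks, window) {
  pts <- tracks$points
  pts <- pts[pts$frame >= window$first_frame & pts$frame <= window$last_frame, ]
  if (nrow(pts) == 0)
    return(data.frame(track_id = integer(), start = integer(), end = integer()))
  pts <- pts[order(pts$track_id, pts$frame), ]
  new_run <- c(TRUE, diff(pts$frame) != 1L | diff(pts$track_id) != 0L)
  start_idx <- which(new_run)
  end_idx <- c(start_idx[-1] - 1L, nrow(pts))
  data.frame(track_id = pts$track_id[start_idx],
             start = pts$frame[start_idx],
             end = pts$frame[end_idx])
}

#' Count docked vesicles per frame
#'
#' The per-frame count is the number of tracks present (observed or
#' bridged) at each frame of the window.
#'
#' @param tracks a [track_set()]
#' @param window an [analysis_window()]; default the last 3500 frames
#' @return object of class `docking_counts`: `per_frame` (integer vector,
#'   one entry per window frame), `mean`, `sd`
#' @export
count_docked <- function(tracks, window = last_frames_window(tracks$frame_count)) {
  stopifnot(inherits(tracks, "track_set"), inherits(window, "analysis_window"))
  if (window$last_frame >= tracks$frame_count)
    stop("window extends beyond the track set's frames")
  w0 <- window$first_frame; w1 <- window$last_frame
  Tn <- w1 - w0 + 1L
  if (Tn < 1) stop("empty analysis window")
  fr <- tracks$points$frame
  fr <- fr[fr >= w0 & fr <= w1]
  per_frame <- tabulate(fr - w0 + 1L, nbins = Tn)
  structure(list(per_frame = per_frame, mean = mean(per_frame),
                 sd = stats::sd(per_frame), window = window),
            class = "docking_counts")
}

#' @export
print.docking_counts <- function(x, ...) {
  cat(sprintf("Docked vesicles: %.2f +/- %.2f per frame (frames %d-%d)\n",
              x$mean, x$sd, x$window$first_frame, x$window$last_frame))
  invisible(x)
}

#' Particle-persistence autocorrelation of a track set
#'
#' For each lag tau (in frames) computes
#' \deqn{P(\tau) = \sum_{t} \frac{1}{N_t} \sum_{i=1}^{N_t}
#'   \delta[w_i(t), w_i(t+\tau)]}
#' where the sum runs over window frames t = 0 ... T-1-tau (T - tau terms),
#' N_t is the number of particles present at frame t, and the delta is 1
#' when particle i is present (observed or gap-bridged) at both t and
#' t + tau — identity taken from the track id. Frames with N_t = 0
#' contribute 0. The curve is also returned normalised by P(0).
#'
#' @param tracks a [track_set()]
#' @param tau_max maximum lag (frames); default `min(100, window length / 4)`
#' @param window an [analysis_window()]; default the last 3500 frames
#' @return object of class `acf_curve`: `taus` (frames, starting at 0),
#'   `values` (raw P), `values_norm` (P / P(0)), `frame_period` (ms)
#' @export
compute_acf <- function(tracks, tau_max = NULL,
                        window = last_frames_window(tracks$frame_count)) {
  stopifnot(inherits(tracks, "track_set"), inherits(window, "analysis_window"))
  w0 <- window$first_frame; w1 <- window$last_frame
  Tn <- w1 - w0 + 1L
  if (is.null(tau_max)) tau_max <- min(100L, Tn %/% 4L)
  if (tau_max >= Tn) stop("tau_max must be smaller than the window length")
  iv <- .track_intervals(tracks, window)
  taus <- 0:tau_max
  if (nrow(iv) == 0) {
    return(structure(list(taus = taus, values = numeric(length(taus)),
                          values_norm = numeric(length(taus)),
                          frame_period = tracks$frame_period, window = window),
                     class = "acf_curve"))
  }
  # N_t over the window: +1 at interval start, -1 just after its end
  delta <- tabulate(iv$start - w0 + 1L, nbins = Tn + 1L) -
    tabulate(iv$end - w0 + 2L, nbins = Tn + 1L)
  n_t <- cumsum(delta)[seq_len(Tn)]
  inv_n <- ifelse(n_t > 0, 1 / n_t, 0)
  # ordered same-track interval pairs (a, b) with b not earlier than a
  o <- order(iv$track_id, iv$start)
  iv <- iv[o, ]
  grp <- split(seq_len(nrow(iv)), iv$track_id)
  pa <- pb <- integer(0)
  for (g in grp) {
    k <- length(g)
    if (k == 1L) { pa <- c(pa, g); pb <- c(pb, g) }
    else {
      idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
      pa <- c(pa, g[idx[, 1]]); pb <- c(pb, g[idx[, 2]])
    }
  }
  A1 <- iv$start[pa]; A2 <- iv$end[pa]
  B1 <- iv$start[pb]; B2 <- iv$end[pb]
  values <- numeric(length(taus))
  for (j in seq_along(taus)) {
    tau <- taus[j]
    lo <- pmax(A1, B1 - tau); hi <- pmin(A2, B2 - tau)
    ok <- hi >= lo
    if (!any(ok)) next
    d <- tabulate(lo[ok] - w0 + 1L, nbins = Tn + 1L) -
      tabulate(hi[ok] - w0 + 2L, nbins = Tn + 1L)
    cnt <- cumsum(d)[seq_len(Tn)]
    values[j] <- sum(cnt * inv_n)
  }
  values_norm <- if (values[1] > 0) values / values[1] else values
  structure(list(taus = taus, values = values, values_norm = values_norm,
                 frame_period = tracks$frame_period, window = window),
            class = "acf_curve")
}

#' @export
print.acf_curve <- function(x, ...) {
  cat(sprintf("Persistence ACF: lags 0-%d frames (%g ms/frame), P(0) = %.4g\n",
              max(x$taus), x$frame_period, x$values[1]))
  invisible(x)
}

# Levenberg-Marquardt with box bounds via nls.lm (nlsLM's post-fit model
# construction fails when a parameter converges onto a degenerate bound,
# e.g. a vanishing fast component, so the raw optimiser is used here).
.lm_fit <- function(par, lower, fn) {
  res <- tryCatch(
    minpack.lm::nls.lm(par = par, lower = lower, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500,
                                                            ftol = 1e-15,
                                                            ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(res) || !res$info %in% 1:4) return(NULL)
  se <- tryCatch(summary(res)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, length(par)), names(par)))
  list(par = stats::setNames(res$par, names(par)), se = se,
       rss = res$deviance)
}

.fit_single_exp <- function(tau_ms, y) {
  th <- tau_ms[which(y <= y[1] / exp(1))[1]]
  if (is.na(th) || th <= 0) th <- max(tau_ms) / 2
  best <- NULL
  for (f in c(0.3, 1, 3)) {
    r <- .lm_fit(c(a = max(y) - min(y), t2 = f * th, c0 = max(min(y), 0)),
                 lower = c(0, 1e-9, 0),
                 function(p) y - (p[1] * exp(-tau_ms / p[2]) + p[3]))
    if (!is.null(r) && (is.null(best) || r$rss < best$rss)) best <- r
  }
  best
}

#' Residence time from a persistence ACF
#'
#' Fits the normalised ACF with a double exponential
#' \deqn{P(\tau) = a_1 e^{-\tau/t_1} + a_2 e^{-\tau/t_2} + c_0}
#' under the constraints a1, a2, c0 >= 0 and t1 <= t2 (label-swap symmetry
#' broken by ordering). The fast constant t1 absorbs stochastic
#' detection-intensity loss; the slow constant t2 is the residence time of
#' docked vesicles, reported in ms. If the two-component model is
#' unidentifiable (relative standard error of t2 above 100%, or a2 below
#' 1e-3), a single exponential is refit and its constant reported as t2
#' with `degenerate = TRUE`.
#'
#' @param acf an `acf_curve` from [compute_acf()] (at least 8 lag points)
#' @return object of class `residence_fit`: amplitudes `a1`, `a2`, `c0`,
#'   time constants `t1`, `t2` (ms), standard errors, `degenerate`,
#'   `converged`
#' @export
fit_residence <- function(acf) {
  stopifnot(inherits(acf, "acf_curve"))
  if (length(acf$taus) < 8) stop("need at least 8 lag points")
  tau_ms <- acf$taus * acf$frame_period
  y <- acf$values_norm
  fail <- function(msg) structure(list(
    a1 = NA_real_, t1 = NA_real_, a2 = NA_real_, t2 = NA_real_,
    c0 = NA_real_, t2_se = NA_real_, t1_se = NA_real_,
    degenerate = NA, converged = FALSE, message = msg,
    frame_period = acf$frame_period), class = "residence_fit")
  if (all(y <= 0)) return(fail("empty ACF"))
  # decay-scale guess from the 1/e crossing
  th <- tau_ms[which(y <= y[1] / exp(1))[1]]
  if (is.na(th) || th <= 0) th <- max(tau_ms) / 2
  fac <- c(0.1, 0.3, 1, 3, 10)
  combos <- expand.grid(f1 = fac, f2 = fac)
  combos <- combos[combos$f1 < combos$f2, ]
  best <- NULL
  for (i in seq_len(nrow(combos))) {
    st <- c(a1 = 0.4 * y[1], t1 = combos$f1[i] * th,
            a2 = 0.5 * y[1], t2 = combos$f2[i] * th,
            c0 = max(min(y), 0))
    r <- .lm_fit(st, lower = c(0, 1e-9, 0, 1e-9, 0),
                 function(p) y - (p[1] * exp(-tau_ms / p[2]) +
                                    p[3] * exp(-tau_ms / p[4]) + p[5]))
    if (!is.null(r) && (is.null(best) || r$rss < best$rss - 1e-15)) best <- r
  }
  if (is.null(best)) return(fail("no start converged"))
  co <- best$par
  se <- best$se
  # order the components: t1 <= t2
  if (co["t1"] > co["t2"]) {
    co[c("a1", "t1", "a2", "t2")] <- co[c("a2", "t2", "a1", "t1")]
    se[c("a1", "t1", "a2", "t2")] <- se[c("a2", "t2", "a1", "t1")]
  }
  rel_se_t2 <- se["t2"] / co["t2"]
  # unidentifiable second component: huge uncertainty, vanishing amplitude,
  # or both constants collapsing onto each other
  degenerate <- !is.finite(rel_se_t2) || rel_se_t2 > 1 || co["a2"] < 1e-3 ||
    co["a1"] < 1e-3 || co["t1"] > 0.8 * co["t2"]
  if (degenerate) {
    sf <- .fit_single_exp(tau_ms, y)
    if (!is.null(sf)) {
      return(structure(list(
        a1 = 0, t1 = NA_real_, a2 = unname(sf$par["a"]),
        t2 = unname(sf$par["t2"]), c0 = unname(sf$par["c0"]),
        t2_se = unname(sf$se["t2"]), t1_se = NA_real_,
        degenerate = TRUE, converged = TRUE, message = "single-exponential",
        frame_period = acf$frame_period), class = "residence_fit"))
    }
  }
  structure(list(
    a1 = unname(co["a1"]), t1 = unname(co["t1"]),
    a2 = unname(co["a2"]), t2 = unname(co["t2"]), c0 = unname(co["c0"]),
    t2_se = unname(se["t2"]), t1_se = unname(se["t1"]),
    degenerate = FALSE, converged = TRUE, message = "ok",
    frame_period = acf$frame_period), class = "residence_fit")
}

#' @export
print.residence_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Residence fit: NOT converged (", x$message, ")\n", sep = "")
  } else if (x$degenerate) {
    cat(sprintf("Residence fit (single-exponential, degenerate two-component model):\n  t2 = %.1f ms (se %.2g)\n",
                x$t2, x$t2_se))
  } else {
    cat(sprintf("Residence fit: t2 = %.1f ms (se %.2g), t1 = %.1f ms, a1 = %.3f, a2 = %.3f, c0 = %.3f\n",
                x$t2, x$t2_se, x$t1, x$a1, x$a2, x$c0))
  }
  invisible(x)
}
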