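#' Configuration for a synthetic TIRF movie
#'
#' Emulates single-vesicle TIRF acquisition of docking events: vesicles
#' arrive on the membrane as a Poisson process, reside for a geometrically
#' distributed number of frames (the discrete analogue of an exponential
#' residence time), and render as 2-D Gaussian spots with per-spot
#' photobleaching. Out-of-focus vesicles in the bulk are modelled as broad,
#' dim, mobile Gaussians. Pixel values are Poisson(signal + background)
#' plus Gaussian read noise.
#'
#' Defaults mirror the acquisition analysed throughout: 7500 frames at
#' 40 ms exposure on a 4x4-binned field, ~5-pixel spot diameter.
#'
#' @param frame_count number of frames
#' @param frame_period frame period (ms), > 0
#' @param image_size side length of the square field (pixels)
#' @param psf_sigma Gaussian PSF width (pixels)
#' @param arrival_rate expected new docking events per frame
#' @param mean_residence mean residence time (ms), > 0
#' @param spot_amplitude peak spot intensity above background (counts)
#' @param background_level uniform background (counts)
#' @param bleach_rate per-frame fractional intensity decay of a docked spot
#' @param dropout_prob per-frame probability a docked spot is not rendered
#'   (detector-level loss); in \[0, 1)
#' @param n_diffuse number of out-of-focus background walkers
#' @param diffuse_sigma_scale width multiplier (>= 2) for out-of-focus spots
#' @param diffuse_amplitude peak intensity of out-of-focus spots (counts);
#'   must be <= 0.25 * spot_amplitude
#' @param diffuse_step per-frame random-walk displacement SD (pixels)
#' @param read_noise_sd Gaussian read-noise SD (counts)
#' @param shot_noise logical; apply Poisson shot noise (disable for exact
#'   noiseless fixtures)
#' @param seed integer RNG seed
#' @return object of class `tirf_sim_config`
#' @export
tirf_sim_config <- function(frame_count = 7500, frame_period = 40,
                            image_size = 128, psf_sigma = 1.7,
                            arrival_rate = 26.8 / 22.5, mean_residence = 900,
                            spot_amplitude = 150, background_level = 100,
                            bleach_rate = 0.001, dropout_prob = 0,
                            n_diffuse = 30, diffuse_sigma_scale = 4,
                            diffuse_amplitude = 0.25 * spot_amplitude,
                            diffuse_step = 1.5,
                            read_noise_sd = 2, shot_noise = TRUE,
                            seed = 1L) {
  stopifnot(frame_count >= 1, frame_period > 0, mean_residence > 0,
            arrival_rate >= 0, dropout_prob >= 0, dropout_prob < 1,
            diffuse_sigma_scale >= 2, bleach_rate >= 0, read_noise_sd >= 0,
            diffuse_amplitude <= 0.25 * spot_amplitude)
  if (image_size < ceiling(6 * psf_sigma) + 1)
    stop("image_size too small to hold one PSF")
  structure(as.list(environment()), class = "tirf_sim_config")
}

# Poisson arrivals + geometric residence -> event table.
# Durations are geometric on {1, 2, ...} with mean mean_residence/frame_period
# frames, so frame-level ground truth is exact.
.draw_events <- function(frame_count, arrival_rate, mean_residence_frames,
                         image_size, margin = 0) {
  n_new <- stats::rpois(frame_count, arrival_rate)
  n <- sum(n_new)
  if (n == 0)
    return(data.frame(event_id = integer(), x = numeric(), y = numeric(),
                      start_frame = integer(), end_frame = integer()))
  start <- rep(seq_len(frame_count) - 1L, n_new)
  dur <- stats::rgeom(n, prob = 1 / mean_residence_frames) + 1L
  lo <- margin
  hi <- image_size - 1 - margin
  data.frame(event_id = seq_len(n),
             x = stats::runif(n, lo, hi), y = stats::runif(n, lo, hi),
             start_frame = start,
             end_frame = pmin(start + dur - 1L, frame_count - 1L))
}

.per_frame_count <- function(events, frame_count) {
  delta <- numeric(frame_count + 1)
  if (nrow(events)) {
    add <- tabulate(events$start_frame + 1L, nbins = frame_count)
    rem <- tabulate(events$end_frame + 2L, nbins = frame_count + 1L)
    delta <- c(add, 0) - rem
  }
  cumsum(delta)[seq_len(frame_count)]
}

# Observation model on one event: iid per-frame dropout, then gap closing.
# Returns frames present (0-based) and observed flags; dropout runs longer
# than max_gap leave the track absent but do not change its identity.
.observe_event <- function(start, end, dropout_prob, max_gap) {
  frames <- start:end
  obs <- stats::runif(length(frames)) >= dropout_prob
  if (!any(obs)) return(NULL)
  fobs <- frames[obs]
  keep_frames <- fobs
  observed <- rep(TRUE, length(fobs))
  if (length(fobs) > 1 && max_gap > 0) {
    gaps <- diff(fobs) - 1L
    bridge <- which(gaps > 0 & gaps <= max_gap)
    if (length(bridge)) {
      extra <- unlist(lapply(bridge, function(i) (fobs[i] + 1L):(fobs[i + 1L] - 1L)))
      keep_frames <- c(fobs, extra)
      observed <- c(observed, rep(FALSE, length(extra)))
      o <- order(keep_frames)
      keep_frames <- keep_frames[o]
      observed <- observed[o]
    }
  }
  list(frames = keep_frames, observed = observed)
}

#' Track set container
#'
#' A set of linked particle trajectories: one row per (track, frame) with
#' continuous pixel coordinates and an observed flag (FALSE for frames
#' bridged by gap closing). Frames and coordinates are 0-based with pixel
#' centers at integer positions.
#'
#' @param points data.frame with columns `track_id`, `frame`, `x`, `y`,
#'   `observed` (frames strictly increasing within a track)
#' @param frame_count total number of frames in the movie
#' @param frame_period frame period (ms)
#' @return object of class `track_set`
#' @export
track_set <- function(points, frame_count, frame_period = 40) {
  stopifnot(all(c("track_id", "frame", "x", "y", "observed") %in% names(points)),
            frame_count >= 1, frame_period > 0)
  points <- points[order(points$track_id, points$frame), , drop = FALSE]
  if (nrow(points) && any(unlist(tapply(points$frame, points$track_id, duplicated))))
    stop("duplicate frames within a track")
  structure(list(points = points, frame_count = as.integer(frame_count),
                 frame_period = frame_period),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("Track set: %d tracks, %d points, %d frames at %g ms\n",
              length(unique(x$points$track_id)), nrow(x$points),
              x$frame_count, x$frame_period))
  invisible(x)
}

#' Simulate a docked-vesicle track set with known ground truth
#'
#' Generates the docking-event process (Poisson arrivals, geometric
#' residence) and returns it directly as a [track_set()], bypassing image
#' rendering. Each event is one track whose identity persists for the whole
#' residence; per-frame detection dropout removes frames, single gaps up to
#' `max_gap` are bridged (marked unobserved), and longer dropout runs leave
#' the track temporarily absent — emulating the output of tracking a
#' stationary docked vesicle with gap closing. Events entirely lost to
#' dropout are dropped.
#'
#' @param frame_count number of frames
#' @param arrival_rate expected new events per frame
#' @param mean_residence mean residence time (ms)
#' @param frame_period frame period (ms)
#' @param dropout_prob per-frame detection dropout probability
#' @param max_gap gap-closing span (frames)
#' @param image_size field side (pixels), for event positions
#' @param seed integer RNG seed
#' @return list with `tracks` (a [track_set()]) and `truth` (`event_log`,
#'   `per_frame_docked_count`, generator parameters)
#' @export
simulate_track_set <- function(frame_count, arrival_rate, mean_residence,
                               frame_period = 40, dropout_prob = 0,
                               max_gap = 1, image_size = 128, seed = 1L) {
  stopifnot(frame_count >= 1, mean_residence > 0, frame_period > 0,
            dropout_prob >= 0, dropout_prob < 1, max_gap >= 0)
  set.seed(seed)
  m_frames <- mean_residence / frame_period
  events <- .draw_events(frame_count, arrival_rate, m_frames, image_size)
  pts <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ob <- .observe_event(events$start_frame[i], events$end_frame[i],
                         dropout_prob, max_gap)
    if (is.null(ob)) next
    pts[[i]] <- data.frame(track_id = events$event_id[i], frame = ob$frames,
                           x = events$x[i], y = events$y[i],
                           observed = ob$observed)
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts))
    pts <- data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric(), observed = logical())
  list(tracks = track_set(pts, frame_count, frame_period),
       truth = list(event_log = events,
                    per_frame_docked_count = .per_frame_count(events, frame_count),
                    arrival_rate = arrival_rate,
                    mean_residence = mean_residence,
                    frame_period = frame_period, dropout_prob = dropout_prob,
                    max_gap = max_gap, seed = seed))
}

#' Image stack container
#'
#' @param frames list of equally sized non-negative numeric matrices
#' @param frame_period frame period (ms)
#' @param pixel_binning label, e.g. "4x4"
#' @return object of class `image_stack`
#' @export
image_stack <- function(frames, frame_period = 40, pixel_binning = "4x4") {
  stopifnot(length(frames) >= 1, frame_period > 0)
  dm <- dim(frames[[1]])
  for (f in frames) if (!identical(dim(f), dm)) stop("frames differ in shape")
  structure(list(frames = frames, frame_period = frame_period,
                 pixel_binning = pixel_binning),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("Image stack: %d frames of %d x %d px, %g ms/frame\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$frame_period))
  invisible(x)
}

# add A * exp(-r^2 / 2 sigma^2) centred at (x, y) (0-based, col/row) to `img`
.add_gaussian_patch <- function(img, x, y, sigma, amp, half = ceiling(4 * sigma)) {
  nr <- nrow(img); nc <- ncol(img)
  c0 <- max(0L, floor(x) - half); c1 <- min(nc - 1L, ceiling(x) + half)
  r0 <- max(0L, floor(y) - half); r1 <- min(nr - 1L, ceiling(y) + half)
  if (c0 > c1 || r0 > r1) return(img)
  dx2 <- ((c0:c1) - x)^2
  dy2 <- ((r0:r1) - y)^2
  patch <- amp * exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  img[(r0:r1) + 1L, (c0:c1) + 1L] <- img[(r0:r1) + 1L, (c0:c1) + 1L] + patch
  img
}

#' Simulate a TIRF movie of vesicle docking
#'
#' Renders the docking-event process of [simulate_track_set()] as an image
#' sequence: in-focus docked vesicles appear as sharp Gaussian spots that
#' photobleach with time docked; out-of-focus bulk vesicles as broad, dim,
#' mobile Gaussians; pixel values carry Poisson shot noise and Gaussian read
#' noise and are clamped non-negative and rounded to integer counts.
#'
#' @param config a [tirf_sim_config()]
#' @param events optional scripted event table (`x`, `y`, `start_frame`,
#'   `end_frame`) overriding the stochastic arrival process
#' @return list with `stack` (an [image_stack()]) and `truth` (`event_log`,
#'   `per_frame_docked_count`, generator parameters)
#' @export
generate_tirf_movie <- function(config, events = NULL) {
  stopifnot(inherits(config, "tirf_sim_config"))
  set.seed(config$seed)
  n <- config$image_size
  Tn <- config$frame_count
  if (is.null(events)) {
    events <- .draw_events(Tn, config$arrival_rate,
                           config$mean_residence / config$frame_period, n)
  } else {
    events <- data.frame(event_id = seq_len(nrow(events)),
                         x = events$x, y = events$y,
                         start_frame = as.integer(events$start_frame),
                         end_frame = pmin(as.integer(events$end_frame), Tn - 1L))
  }
  # per-frame active event ids
  active <- vector("list", Tn)
  if (nrow(events)) {
    fr <- unlist(mapply(seq.int, events$start_frame, events$end_frame,
                        SIMPLIFY = FALSE))
    ids <- rep(events$event_id, events$end_frame - events$start_frame + 1L)
    keep <- if (config$dropout_prob > 0)
      stats::runif(length(ids)) >= config$dropout_prob else TRUE
    sp <- split(ids[keep], fr[keep])
    active[as.integer(names(sp)) + 1L] <- sp
  }
  # out-of-focus walkers: precomputed pixel-centred template, integer shifts
  nd <- config$n_diffuse
  if (nd > 0) {
    dsig <- config$diffuse_sigma_scale * config$psf_sigma
    dh <- ceiling(2.5 * dsig)
    dxs <- (-dh):dh
    tmpl <- config$diffuse_amplitude *
      exp(-outer(dxs^2, dxs^2, "+") / (2 * dsig^2))
    wx <- stats::runif(nd, 0, n - 1)
    wy <- stats::runif(nd, 0, n - 1)
  }
  frames <- vector("list", Tn)
  for (t in seq_len(Tn) - 1L) {
    img <- matrix(config$background_level, n, n)
    for (id in active[[t + 1L]]) {
      age <- t - events$start_frame[id]
      amp <- config$spot_amplitude * exp(-config$bleach_rate * age)
      img <- .add_gaussian_patch(img, events$x[id], events$y[id],
                                 config$psf_sigma, amp)
    }
    if (nd > 0) {
      wx <- (wx + stats::rnorm(nd, sd = config$diffuse_step)) %% (n - 1)
      wy <- (wy + stats::rnorm(nd, sd = config$diffuse_step)) %% (n - 1)
      for (k in seq_len(nd)) {
        cx <- round(wx[k]); cy <- round(wy[k])
        c0 <- max(0L, cx - dh); c1 <- min(n - 1L, cx + dh)
        r0 <- max(0L, cy - dh); r1 <- min(n - 1L, cy + dh)
        img[(r0:r1) + 1L, (c0:c1) + 1L] <-
          img[(r0:r1) + 1L, (c0:c1) + 1L] +
          tmpl[(r0 - cy + dh + 1L):(r1 - cy + dh + 1L),
               (c0 - cx + dh + 1L):(c1 - cx + dh + 1L)]
      }
    }
    if (config$shot_noise)
      img[] <- stats::rpois(length(img), lambda = img)
    if (config$read_noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = config$read_noise_sd)
    img[img < 0] <- 0
    storage.mode(img) <- "integer"
    frames[[t + 1L]] <- img
  }
  list(stack = image_stack(frames, config$frame_period),
       truth = list(event_log = events,
                    per_frame_docked_count = .per_frame_count(events, Tn),
                    config = config))
}
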