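# shift a matrix by (dr, dc) with replicated edges
.shift_replicate <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  img[ri, ci, drop = FALSE]
}

# ball structuring element: offsets within `radius` and their heights
.ball_se <- function(radius) {
  h <- floor(radius)
  off <- expand.grid(dr = -h:h, dc = -h:h)
  d2 <- off$dr^2 + off$dc^2
  keep <- d2 <= radius^2
  list(dr = off$dr[keep], dc = off$dc[keep],
       height = sqrt(radius^2 - d2[keep]))
}

# grayscale erosion/dilation with a (non-flat) ball SE, vectorised over shifts
.ball_opening <- function(img, se) {
  ero <- NULL
  for (k in seq_along(se$dr)) {
    s <- .shift_replicate(img, se$dr[k], se$dc[k]) - se$height[k]
    ero <- if (is.null(ero)) s else pmin(ero, s)
  }
  dil <- NULL
  for (k in seq_along(se$dr)) {
    s <- .shift_replicate(ero, -se$dr[k], -se$dc[k]) + se$height[k]
    dil <- if (is.null(dil)) s else pmax(dil, s)
  }
  dil
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of each frame as the grayscale
#' morphological opening with a ball-shaped structuring element (the
#' classical rolling-ball equivalence: the ball profile, in intensity
#' units, is the sphere of the given radius) and subtracts it, clipping at
#' zero. Structures narrower than the ball — in-focus docked-vesicle spots —
#' survive the subtraction, while broad out-of-focus blobs and slowly
#' varying background are removed. Radii between 1 and 2 pixels suit
#' ~5-pixel spots.
#'
#' @param x an [image_stack()] or a single numeric matrix
#' @param radius ball radius (pixels), >= 1 and at most half the image side
#' @return same type as `x`, background-subtracted
#' @export
subtract_background <- function(x, radius = 2) {
  if (radius < 1) stop("radius must be >= 1")
  one <- function(img) {
    if (radius > min(dim(img)) / 2)
      stop("radius larger than half the image")
    out <- img - .ball_opening(img, se)
    out[out < 0] <- 0
    out
  }
  se <- .ball_se(radius)
  if (inherits(x, "image_stack")) {
    x$frames <- lapply(x$frames, one)
    x
  } else one(as.matrix(x))
}

# replicate-padded 1-D convolution as a banded matrix (built per size)
.conv_band <- function(n, kernel) {
  h <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in -h:h) {
    j <- pmin(pmax(seq_len(n) + o, 1L), n)
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + kernel[o + h + 1L]
  }
  K
}

# scale-normalised Laplacian-of-Gaussian response, negated so bright blobs
# score positive; separable: -sigma^2 (Gxx*Gy + Gx*Gyy)
.log_response <- function(img, sigma) {
  h <- max(3L, ceiling(3 * sigma))
  u <- (-h):h
  g <- exp(-u^2 / (2 * sigma^2)); g <- g / sum(g)
  g2 <- g * (u^2 - sigma^2) / sigma^4
  Kr_g <- .conv_band(nrow(img), g); Kr_g2 <- .conv_band(nrow(img), g2)
  Kc_g <- .conv_band(ncol(img), g); Kc_g2 <- .conv_band(ncol(img), g2)
  lap <- Kr_g2 %*% img %*% t(Kc_g) + Kr_g %*% img %*% t(Kc_g2)
  -sigma^2 * lap
}

#' Detect diffraction-limited spots with a Laplacian-of-Gaussian filter
#'
#' Computes the scale-normalised LoG response at the blob scale
#' `sigma = diameter / (2 sqrt(2))`, takes local maxima of the negated
#' response above `quality_threshold` (non-maximum suppression within half
#' the spot diameter), and refines each maximum to sub-pixel precision by
#' 1-D quadratic interpolation. Coordinates are 0-based with pixel centers
#' at integers.
#'
#' @param frame 2-D numeric matrix (background-subtracted)
#' @param diameter nominal spot diameter (pixels), >= 3
#' @param quality_threshold minimum LoG response (same units as intensity
#'   counts) for a detection
#' @return data.frame with columns `x`, `y` (continuous, 0-based) and
#'   `quality` (LoG response at the maximum)
#' @export
detect_spots <- function(frame, diameter = 5, quality_threshold = 10) {
  if (diameter < 3) stop("diameter must be >= 3")
  frame <- as.matrix(frame)
  sigma <- diameter / (2 * sqrt(2))
  R <- .log_response(frame, sigma)
  nr <- floor(diameter / 2)
  # neighbourhood maximum over the square window of radius nr
  nbmax <- matrix(-Inf, nrow(R), ncol(R))
  for (dr in -nr:nr) for (dc in -nr:nr) {
    if (dr == 0 && dc == 0) next
    nbmax <- pmax(nbmax, .shift_replicate(R, dr, dc))
  }
  cand <- which(R > quality_threshold & R >= nbmax, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(), y = numeric(), quality = numeric()))
  q <- R[cand]
  o <- order(-q)
  cand <- cand[o, , drop = FALSE]; q <- q[o]
  # greedy suppression of plateau ties within the window
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      close <- abs(cand[later, 1] - cand[i, 1]) <= nr &
        abs(cand[later, 2] - cand[i, 2]) <= nr
      keep[later][close] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]; q <- q[keep]
  # sub-pixel quadratic refinement along each axis
  refine <- function(r0, c0) {
    dy <- dx <- 0
    if (r0 > 1 && r0 < nrow(R)) {
      a <- R[r0 - 1, c0]; b <- R[r0, c0]; cc <- R[r0 + 1, c0]
      den <- a - 2 * b + cc
      if (den < 0) dy <- min(max(0.5 * (a - cc) / den, -0.5), 0.5)
    }
    if (c0 > 1 && c0 < ncol(R)) {
      a <- R[r0, c0 - 1]; b <- R[r0, c0]; cc <- R[r0, c0 + 1]
      den <- a - 2 * b + cc
      if (den < 0) dx <- min(max(0.5 * (a - cc) / den, -0.5), 0.5)
    }
    c(dx, dy)
  }
  adj <- t(mapply(refine, cand[, 1], cand[, 2]))
  data.frame(x = cand[, 2] - 1 + adj[, 1],
             y = cand[, 1] - 1 + adj[, 2],
             quality = q)
}

#' Detect spots in every frame of a stack
#'
#' Convenience wrapper running [subtract_background()] (optional) and
#' [detect_spots()] frame by frame.
#'
#' @param stack an [image_stack()]
#' @param radius rolling-ball radius; `NULL` skips background subtraction
#' @param diameter,quality_threshold passed to [detect_spots()]
#' @param frames 0-based frame indices to process (default all)
#' @return data.frame with columns `frame` (0-based), `x`, `y`, `quality`
#' @export
detect_stack <- function(stack, radius = 2, diameter = 5,
                         quality_threshold = 10,
                         frames = seq_along(stack$frames) - 1L) {
  stopifnot(inherits(stack, "image_stack"))
  se_sub <- !is.null(radius)
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- stack$frames[[frames[i] + 1L]]
    if (se_sub) f <- subtract_background(f, radius)
    d <- detect_spots(f, diameter, quality_threshold)
    if (nrow(d)) d$frame <- frames[i]
    out[[i]] <- d
  }
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(out))
    out <- data.frame(x = numeric(), y = numeric(), quality = numeric(),
                      frame = integer())
  out[, c("frame", "x", "y", "quality")]
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate
#' (track, detection) pairs within `max_displacement` are linked closest
#' first, each detection used at most once. A track missing from up to
#' `max_gap` consecutive frames can be re-linked; the bridged frames are
#' filled by linear interpolation and marked unobserved. Docked vesicles
#' are near-stationary, so this simple linker resolves them without global
#' assignment.
#'
#' @param detections data.frame with columns `frame` (0-based), `x`, `y`
#'   (and optionally `quality`)
#' @param max_displacement maximum link distance (pixels), > 0
#' @param max_gap maximum number of missing frames bridged, >= 0
#' @param frame_count total frames in the movie (default: max frame + 1)
#' @param frame_period frame period (ms)
#' @return a [track_set()]
#' @export
link_particles <- function(detections, max_displacement = 2, max_gap = 1,
                           frame_count = max(detections$frame) + 1L,
                           frame_period = 40) {
  stopifnot(max_displacement > 0, max_gap >= 0)
  if (nrow(detections) == 0)
    return(track_set(data.frame(track_id = integer(), frame = integer(),
                                x = numeric(), y = numeric(),
                                observed = logical()),
                     max(frame_count, 1L), frame_period))
  detections <- detections[order(detections$frame), , drop = FALSE]
  # active track state
  tid <- integer(0); tx <- ty <- numeric(0); tlast <- integer(0)
  next_id <- 1L
  frames_u <- unique(detections$frame)
  chunks <- vector("list", length(frames_u))
  for (fi in seq_along(frames_u)) {
    fr <- frames_u[fi]
    di <- which(detections$frame == fr)
    dx <- detections$x[di]; dy <- detections$y[di]
    nd <- length(di)
    loc <- matrix(0, 0, 5)
    push <- function(id, frame, x, y, obs)
      loc <<- rbind(loc, c(id, frame, x, y, obs))
    # retire tracks beyond bridging reach
    alive <- tlast >= fr - 1L - max_gap
    tid <- tid[alive]; tx <- tx[alive]; ty <- ty[alive]; tlast <- tlast[alive]
    assigned_d <- rep(FALSE, nd)
    if (length(tid) && nd) {
      dist <- sqrt(outer(tx, dx, "-")^2 + outer(ty, dy, "-")^2)
      dist[dist > max_displacement] <- NA
      ord <- order(dist, na.last = NA)
      used_t <- rep(FALSE, length(tid))
      for (k in ord) {
        ti <- (k - 1L) %% length(tid) + 1L
        dj <- (k - 1L) %/% length(tid) + 1L
        if (used_t[ti] || assigned_d[dj]) next
        used_t[ti] <- TRUE; assigned_d[dj] <- TRUE
        gap <- fr - tlast[ti] - 1L
        if (gap > 0) {
          for (g in seq_len(gap)) {
            w <- g / (gap + 1)
            push(tid[ti], tlast[ti] + g,
                 tx[ti] + w * (dx[dj] - tx[ti]),
                 ty[ti] + w * (dy[dj] - ty[ti]), 0)
          }
        }
        push(tid[ti], fr, dx[dj], dy[dj], 1)
        tx[ti] <- dx[dj]; ty[ti] <- dy[dj]; tlast[ti] <- fr
      }
    }
    if (any(!assigned_d)) {
      for (dj in which(!assigned_d)) {
        push(next_id, fr, dx[dj], dy[dj], 1)
        tid <- c(tid, next_id); tx <- c(tx, dx[dj]); ty <- c(ty, dy[dj])
        tlast <- c(tlast, fr)
        next_id <- next_id + 1L
      }
    }
    chunks[[fi]] <- loc
  }
  m <- do.call(rbind, chunks)
  track_set(data.frame(track_id = as.integer(m[, 1]),
                       frame = as.integer(m[, 2]),
                       x = m[, 3], y = m[, 4],
                       observed = m[, 5] > 0),
            frame_count, frame_period)
}
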