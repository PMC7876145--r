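# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route (root-finding, exhaustive enumeration,
# double loops) so the package code is checked against something it does
# not share.

# bound fraction by numeric root-finding of the mass-action equilibrium:
# complex C solves (P - C)(S/L - C) = KD * C on [0, min(P, S/L)]
chi_oracle <- function(P, S, KD, L) {
  sites <- S / L
  hi <- min(P, sites)
  if (hi == 0) return(0)
  f <- function(C) (P - C) * (sites - C) - KD * C
  stats::uniroot(f, c(0, hi), tol = 1e-15)$root / P
}

# persistence ACF by exhaustive triple loop over (t, tau, particle)
brute_acf <- function(tracks, tau_max, w0, w1) {
  pts <- tracks$points
  pts <- pts[pts$frame >= w0 & pts$frame <= w1, ]
  ids <- unique(pts$track_id)
  pres <- lapply(ids, function(id) pts$frame[pts$track_id == id])
  vapply(0:tau_max, function(tau) {
    tot <- 0
    for (t in w0:(w1 - tau)) {
      at_t <- vapply(pres, function(f) t %in% f, TRUE)
      Nt <- sum(at_t)
      if (Nt == 0) next
      both <- vapply(pres, function(f) (t %in% f) && ((t + tau) %in% f), TRUE)
      tot <- tot + sum(both) / Nt
    }
    tot
  }, 0)
}

# grayscale opening with a ball structuring element, double-loop reference
brute_ball_opening <- function(img, radius) {
  h <- floor(radius)
  nr <- nrow(img); nc <- ncol(img)
  clamp <- function(v, n) pmin(pmax(v, 1L), n)
  offs <- subset(expand.grid(dr = -h:h, dc = -h:h),
                 dr^2 + dc^2 <= radius^2)
  offs$height <- sqrt(radius^2 - (offs$dr^2 + offs$dc^2))
  ero <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    ero[r, c] <- min(img[cbind(clamp(r + offs$dr, nr),
                               clamp(c + offs$dc, nc))] - offs$height)
  }
  dil <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    dil[r, c] <- max(ero[cbind(clamp(r - offs$dr, nr),
                               clamp(c - offs$dc, nc))] + offs$height)
  }
  dil
}

# small helper: build a track_set from a list of frame vectors
tracks_from_frames <- function(frame_list, frame_count, frame_period = 40) {
  pts <- do.call(rbind, lapply(seq_along(frame_list), function(i) {
    if (length(frame_list[[i]]) == 0) return(NULL)
    data.frame(track_id = i, frame = frame_list[[i]],
               x = i, y = i, observed = TRUE)
  }))
  track_set(pts, frame_count, frame_period)
}

# render one noiseless Gaussian-spot frame
gaussian_frame <- function(size, xs, ys, amp, sigma, background = 0) {
  img <- matrix(background, size, size)
  for (k in seq_along(xs)) {
    for (r in 1:size) for (c in 1:size) {
      img[r, c] <- img[r, c] +
        amp[k] * exp(-(((c - 1) - xs[k])^2 + ((r - 1) - ys[k])^2) /
                       (2 * sigma^2))
    }
  }
  img
}
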