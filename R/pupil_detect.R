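# Pupil and corneal-reflection extraction from grayscale eye frames.
# Bright CRs are localized with a circular Hough transform, masked out to
# avoid false pupil edges, and the pupil is found with the Starburst
# strategy: rays cast from a seed point, the strongest dark-to-light
# gradient along each ray taken as a candidate edge, and a consensus
# (RANSAC) ellipse fitted to the candidates. Images are height x width
# matrices in [0, 1]; pixel (1, 1) is the top-left pixel center, x = column,
# y = row.

# darkest point of a box-smoothed image: a robust pupil seed
.darkest_point <- function(img, box = 9) {
  k <- rep(1 / box, box)
  sm <- apply(img, 2, function(col) stats::filter(col, k, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, k, sides = 2)))
  sm[is.na(sm)] <- Inf
  p <- which(sm == min(sm), arr.ind = TRUE)[1, ]
  c(p[2], p[1])  # (x, y)
}

# bilinear image sampling at fractional (x, y); clamps to the border
.interp_image <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 1), w); y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)];     i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]; i11 <- img[cbind(y0 + 1, x0 + 1)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

#' Corneal-reflection localization by circular Hough transform
#'
#' Thresholds bright pixels, takes the boundary pixels of the bright
#' regions as edge points and accumulates circle-center votes over a range
#' of radii. Peaks are returned sorted by score and refined to sub-pixel
#' precision by an intensity-weighted centroid. The reference CR — the
#' reflection of the own camera's LED — is the detected center nearest the
#' image center; reflections of the opposite camera's LED land elsewhere
#' and are thereby ignored.
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param threshold Bright-pixel threshold. Default 0.75.
#' @param radius_range Circle radii to accumulate (px). Default `c(2, 6)`.
#' @param max_centers Maximum number of peaks returned. Default 4.
#' @param min_score_frac Peaks below this fraction of the best score are
#'   dropped. Default 0.4.
#' @return A `cr_detection`: `centers_px` (n x 2), `radii_px`, `scores`,
#'   `reference_index` (0 when nothing was detected; frame to be flagged).
#' @export
detect_crs <- function(image, threshold = 0.75, radius_range = c(2, 6),
                       max_centers = 4, min_score_frac = 0.4) {
  h <- nrow(image); w <- ncol(image)
  bright <- image > threshold
  empty <- structure(list(centers_px = matrix(numeric(0), ncol = 2),
                          radii_px = numeric(0), scores = numeric(0),
                          reference_index = 0L),
                     class = "cr_detection")
  if (!any(bright)) return(empty)
  # boundary pixels of the bright regions
  pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- bright
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  edge <- which(bright & !interior, arr.ind = TRUE)
  if (nrow(edge) == 0L) edge <- which(bright, arr.ind = TRUE)

  acc <- matrix(0L, h, w)
  angles <- seq(0, 2 * pi, length.out = 25)[-25]
  for (r in seq(radius_range[1], radius_range[2], by = 1)) {
    for (a in angles) {
      cx <- round(edge[, "col"] + r * cos(a))
      cy <- round(edge[, "row"] + r * sin(a))
      ok <- cx >= 1 & cx <= w & cy >= 1 & cy <= h
      idx <- cbind(cy[ok], cx[ok])
      tab <- table(idx[, 1] + (idx[, 2] - 1L) * h)
      ii <- as.integer(names(tab))
      acc[ii] <- acc[ii] + as.integer(tab)
    }
  }
  centers <- NULL; scores <- numeric(0); radii <- numeric(0)
  rmax <- radius_range[2]
  acc_work <- acc
  for (k in seq_len(max_centers)) {
    s <- max(acc_work)
    if (s <= 0 || (length(scores) > 0 && s < min_score_frac * scores[1])) break
    p <- which(acc_work == s, arr.ind = TRUE)[1, ]
    # sub-pixel refinement: brightness-weighted centroid in a local disc
    win <- rmax + 2
    ys <- max(1, p[1] - win):min(h, p[1] + win)
    xs <- max(1, p[2] - win):min(w, p[2] + win)
    sub <- image[ys, xs, drop = FALSE]
    # weight only supra-threshold pixels: symmetric about the glint center
    # even when the dark pupil edge runs through the window
    wts <- pmax(sub - threshold, 0)
    if (sum(wts) > 0) {
      cy <- sum(row(sub) * wts) / sum(wts) + ys[1] - 1
      cx <- sum(col(sub) * wts) / sum(wts) + xs[1] - 1
    } else { cy <- p[1]; cx <- p[2] }
    rr <- sqrt(sum(wts * ((row(sub) + ys[1] - 1 - cy)^2 +
                            (col(sub) + xs[1] - 1 - cx)^2)) / max(sum(wts), 1))
    centers <- rbind(centers, c(cx, cy))
    scores <- c(scores, s); radii <- c(radii, max(rr, radius_range[1]))
    # suppress this peak's neighbourhood
    acc_work[max(1, p[1] - 2 * rmax):min(h, p[1] + 2 * rmax),
             max(1, p[2] - 2 * rmax):min(w, p[2] + 2 * rmax)] <- 0L
  }
  if (is.null(centers)) return(empty)
  colnames(centers) <- c("x", "y")
  dc <- sqrt((centers[, 1] - (w + 1) / 2)^2 + (centers[, 2] - (h + 1) / 2)^2)
  structure(
    list(centers_px = centers, radii_px = radii, scores = scores,
         reference_index = which.min(dc)),
    class = "cr_detection"
  )
}

#' Mask detected corneal reflections
#'
#' Replaces the pixels inside each detected CR disc (radius times a safety
#' factor) by the median of an annular neighbourhood just outside it, so
#' the bright glints cannot masquerade as pupil edges. A frame with no
#' detections is returned unchanged.
#'
#' @param image Grayscale matrix.
#' @param crs A `cr_detection` from [detect_crs()].
#' @param safety_factor Disc radius multiplier. Default 1.5.
#' @param annulus_px Annulus width outside the disc (px). Default 3.
#' @return The masked image.
#' @export
mask_crs <- function(image, crs, safety_factor = 1.5, annulus_px = 3) {
  if (nrow(crs$centers_px) == 0L) return(image)
  h <- nrow(image); w <- ncol(image)
  for (k in seq_len(nrow(crs$centers_px))) {
    cx <- crs$centers_px[k, 1]; cy <- crs$centers_px[k, 2]
    r <- crs$radii_px[k] * safety_factor
    win <- ceiling(r + annulus_px)
    ys <- max(1, floor(cy - win)):min(h, ceiling(cy + win))
    xs <- max(1, floor(cx - win)):min(w, ceiling(cx + win))
    dd <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
    disc <- dd <= r
    ann <- dd > r & dd <= r + annulus_px
    if (any(disc) && any(ann)) {
      image[ys, xs][disc] <- stats::median(image[ys, xs][ann])
    }
  }
  image
}

# direct least-squares conic fit constrained to an ellipse (generalized
# eigenvalue formulation), on centered/scaled coordinates for stability
.fit_ellipse_lsq <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  s <- mean(c(stats::sd(x), stats::sd(y)))
  if (!is.finite(s) || s == 0) return(NULL)
  xs <- (x - mx) / s; ys <- (y - my) / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(NULL)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) return(NULL)
  a1 <- evec[, ok[1]]
  a <- c(a1, as.numeric(T1 %*% a1))
  # un-normalize: conic in original coordinates
  A <- a[1] / s^2; B <- a[2] / s^2; C <- a[3] / s^2
  D <- a[4] / s - 2 * A * mx - B * my
  E <- a[5] / s - 2 * C * my - B * mx
  F0 <- a[6] + A * mx^2 + B * mx * my + C * my^2 - a[4] * mx / s - a[5] * my / s
  .conic_to_ellipse(c(A, B, C, D, E, F0))
}

.conic_to_ellipse <- function(co) {
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F0 <- co[6]
  den <- 4 * A * C - B^2
  if (den <= 0) return(NULL)
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  num <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F0
  # eigen-decomposition of the quadratic part gives axes/orientation
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values
  if (any(lam <= 0) && any(lam >= 0) && !(all(lam > 0) || all(lam < 0))) return(NULL)
  ax <- sqrt(abs(-num / lam))
  if (any(!is.finite(ax)) || any(ax <= 0)) return(NULL)
  ord <- order(ax, decreasing = TRUE)
  v <- eg$vectors[, ord[1]]
  list(center = c(cx, cy), semi_axes = ax[ord],
       orientation_deg = (atan2(v[2], v[1]) * 180 / pi) %% 180)
}

.ellipse_distance <- function(ell, x, y) {
  th <- ell$orientation_deg * pi / 180
  dx <- x - ell$center[1]; dy <- y - ell$center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  rho <- sqrt((u / ell$semi_axes[1])^2 + (v / ell$semi_axes[2])^2)
  abs(rho - 1) * mean(ell$semi_axes)
}

#' Starburst pupil detection with consensus ellipse fitting
#'
#' Casts `n_rays` rays outward from a seed point, takes the strongest
#' dark-to-light intensity gradient along each ray (sub-pixel, by parabolic
#' interpolation) as a candidate pupil edge, re-seeds at the candidate
#' centroid and iterates to convergence, then fits an ellipse to the
#' candidates by random-sample consensus followed by a least-squares refit
#' on the inliers. CRs must be masked first ([mask_crs()]).
#'
#' @param image Grayscale matrix (CRs masked).
#' @param seed_point_px `c(x, y)` starting point, inside or near the pupil.
#' @param n_rays Number of rays. Default 36.
#' @param max_ray_px Maximum ray length (px). Default 80.
#' @param gradient_min Minimum outward gradient (intensity per px) for an
#'   edge candidate. Default 0.05.
#' @param max_iter Seed-recentering iterations. Default 10.
#' @param ransac_iter Consensus draws. Default 60.
#' @param inlier_tol_px Inlier distance tolerance (px). Default 1.5.
#' @param min_edge_points Minimum candidate edges for a fit. Default 8.
#' @param seed RNG seed for the consensus draws (reproducibility of the
#'   stochastic fit). Default 42.
#' @return An `ellipse_fit`: `center_px`, `semi_axes_px`,
#'   `orientation_deg`, `inlier_fraction`, `converged`, `edge_points`.
#'   A failed detection returns `converged = FALSE` (flagged frame), not an
#'   error.
#' @export
detect_pupil <- function(image, seed_point_px, n_rays = 36, max_ray_px = 80,
                         gradient_min = 0.05, max_iter = 10,
                         ransac_iter = 60, inlier_tol_px = 1.5,
                         min_edge_points = 8, seed = 42) {
  failed <- structure(list(center_px = c(NA_real_, NA_real_),
                           semi_axes_px = c(NA_real_, NA_real_),
                           orientation_deg = NA_real_,
                           inlier_fraction = 0, converged = FALSE,
                           edge_points = NULL),
                      class = "ellipse_fit")
  pt <- as.numeric(seed_point_px)
  step <- 0.5
  rr <- seq(1, max_ray_px, by = step)
  ang <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  edges <- NULL
  for (it in seq_len(max_iter)) {
    ex <- outer(rr, cos(ang)); ey <- outer(rr, sin(ang))
    xi <- pt[1] + ex; yi <- pt[2] + ey
    vals <- matrix(.interp_image(image, as.numeric(xi), as.numeric(yi)),
                   nrow = length(rr))
    g <- (vals[-1, , drop = FALSE] - vals[-nrow(vals), , drop = FALSE]) / step
    pts <- NULL
    for (k in seq_len(n_rays)) {
      gk <- g[, k]
      j <- which.max(gk)
      if (!is.finite(gk[j]) || gk[j] < gradient_min) next
      # parabolic sub-sample interpolation of the gradient peak
      off <- 0
      if (j > 1 && j < length(gk)) {
        d2 <- gk[j - 1] - 2 * gk[j] + gk[j + 1]
        if (d2 < 0) off <- 0.5 * (gk[j - 1] - gk[j + 1]) / d2
      }
      r_edge <- rr[j] + step / 2 + off * step
      pts <- rbind(pts, c(pt[1] + r_edge * cos(ang[k]),
                          pt[2] + r_edge * sin(ang[k])))
    }
    if (is.null(pts) || nrow(pts) < min_edge_points) return(failed)
    new_pt <- colMeans(pts)
    edges <- pts
    if (sqrt(sum((new_pt - pt)^2)) < 0.5) { pt <- new_pt; break }
    pt <- new_pt
  }
  x <- edges[, 1]; y <- edges[, 2]
  n <- length(x)
  best <- NULL; best_in <- -1L
  draw <- function() {
    for (i in seq_len(ransac_iter)) {
      s6 <- sample.int(n, min(6L, n))
      ell <- .fit_ellipse_lsq(x[s6], y[s6])
      if (is.null(ell)) next
      inl <- .ellipse_distance(ell, x, y) < inlier_tol_px
      if (sum(inl) > best_in) { best_in <<- sum(inl); best <<- inl }
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (is.null(best) || best_in < min_edge_points) return(failed)
  ell <- .fit_ellipse_lsq(x[best], y[best])
  if (is.null(ell)) return(failed)
  structure(
    list(center_px = ell$center, semi_axes_px = ell$semi_axes,
         orientation_deg = ell$orientation_deg,
         inlier_fraction = best_in / n, converged = TRUE,
         edge_points = edges),
    class = "ellipse_fit"
  )
}

#' @export
print.ellipse_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<ellipse_fit> not converged (flagged frame)\n")
  } else {
    cat(sprintf(paste0("<ellipse_fit> center (%.2f, %.2f) px, semi-axes ",
                       "(%.2f, %.2f) px, %.1f deg, %d%% inliers\n"),
                x$center_px[1], x$center_px[2], x$semi_axes_px[1],
                x$semi_axes_px[2], x$orientation_deg,
                round(100 * x$inlier_fraction)))
  }
  invisible(x)
}

#' LED sync-flash onsets in a frame-intensity series
#'
#' Flags frames whose mean intensity exceeds the series median plus
#' `k_mad` robust SDs (MAD), and merges consecutive supra-threshold frames
#' into single onsets (a 30 ms flash spans at most 2 frames at 30 fps; the
#' onset is the first supra-threshold frame).
#'
#' @param intensity Per-frame mean intensity.
#' @param k_mad Threshold in MADs above the median. Default 6.
#' @return Integer vector of onset frame indices (1-based); empty, with a
#'   warning, when no flash is found.
#' @export
detect_sync_flash <- function(intensity, k_mad = 6) {
  med <- stats::median(intensity)
  mad <- stats::mad(intensity)
  thr <- med + k_mad * max(mad, 1e-12)
  hot <- intensity > thr
  if (!any(hot)) {
    warning("no sync flashes found in the intensity series", call. = FALSE)
    return(integer(0))
  }
  onsets <- which(hot & !c(FALSE, hot[-length(hot)]))
  onsets
}

#' Landmarks for a series of rendered frame pairs
#'
#' Convenience wrapper running [detect_crs()], [mask_crs()] and
#' [detect_pupil()] on every frame of both cameras and assembling the
#' landmark table of the dual-angle geometry.
#'
#' @param rendered Output of [render_eye_frames()].
#' @param rig A [camera_rig()].
#' @param seed_point_px Initial pupil seed `c(x, y)`; `NULL` (default)
#'   seeds every frame at the darkest point of the box-smoothed masked
#'   image.
#' @param ... Passed to [detect_pupil()].
#' @return A [pupil_frames()] data.frame.
#' @export
detect_landmarks <- function(rendered, rig = camera_rig(),
                             seed_point_px = NULL, ...) {
  rows <- list()
  for (cam in 1:2) {
    imgs <- rendered[[paste0("cam", cam)]]
    for (i in seq_along(imgs)) {
      crs <- detect_crs(imgs[[i]])
      img <- mask_crs(imgs[[i]], crs)
      sp <- seed_point_px %||% .darkest_point(img)
      fit <- detect_pupil(img, sp, ...)
      ok <- fit$converged && crs$reference_index > 0L
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = rendered$time_s[i], cam = cam,
        pupil_x_px = if (ok) fit$center_px[1] else NA_real_,
        pupil_y_px = if (ok) fit$center_px[2] else NA_real_,
        cr_x_px = if (ok) crs$centers_px[crs$reference_index, 1] else NA_real_,
        cr_y_px = if (ok) crs$centers_px[crs$reference_index, 2] else NA_real_,
        valid = ok)
    }
  }
  df <- do.call(rbind, rows)
  pupil_frames(df, rig)
}
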