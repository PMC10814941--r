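# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (double loops, direct
# convolution, explicit moment sums) and must stay independent of the
# package implementations they check.

# exhaustive GLCM pair counting by double loop over every ROI pixel
brute_glcm <- function(img, roi, angle_deg, distance_px, levels = 256L) {
  sub <- img[roi$row:(roi$row + roi$height - 1),
             roi$col:(roi$col + roi$width - 1), drop = FALSE]
  off <- switch(as.character(angle_deg),
                "0" = c(0, distance_px), "45" = c(-distance_px, distance_px),
                "90" = c(-distance_px, 0), "135" = c(-distance_px, -distance_px))
  m <- matrix(0, levels, levels)
  for (r in seq_len(nrow(sub))) {
    for (cc in seq_len(ncol(sub))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(sub) && c2 >= 1 && c2 <= ncol(sub)) {
        a <- sub[r, cc]; b <- sub[r2, c2]
        if (a > 0 && b > 0) {
          ia <- floor(a * levels / 256) + 1; ib <- floor(b * levels / 256) + 1
          m[ia, ib] <- m[ia, ib] + 1
        }
      }
    }
  }
  m <- m + t(m)
  m / sum(m)
}

# direct 3x3 minimum filter with replicated borders (EBImage convention)
brute_min_filter <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      rs <- max(1, r - 1):min(nr, r + 1)
      cs <- max(1, cc - 1):min(nc, cc + 1)
      out[r, cc] <- min(img[rs, cs])
    }
  }
  out
}

# direct 2-D Gaussian convolution; returns NA on the border where the kernel
# does not fit, so comparisons are interior-only
brute_gaussian <- function(img, sigma, radius) {
  k1 <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k2 <- outer(k1, k1); k2 <- k2 / sum(k2)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (r in (radius + 1):(nr - radius)) {
    for (cc in (radius + 1):(nc - radius)) {
      out[r, cc] <- sum(img[(r - radius):(r + radius),
                            (cc - radius):(cc + radius)] * k2)
    }
  }
  out
}

# population moments of a vector, written out longhand
brute_population_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  list(mean = m, sd = sqrt(v),
       skewness = (sum((x - m)^3) / n) / sqrt(v)^3,
       kurtosis = (sum((x - m)^4) / n) / v^2)
}

# second central moment matrix of foreground pixel centers (pixel coords)
brute_moment_matrix <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  x <- pts[, 2]; y <- pts[, 1]
  rbind(c(mean((x - mean(x))^2), mean((x - mean(x)) * (y - mean(y)))),
        c(mean((x - mean(x)) * (y - mean(y))), mean((y - mean(y))^2)))
}

# normal-equation OLS slope/intercept and RMS residual
brute_ols <- function(x, y) {
  xtx <- rbind(c(length(x), sum(x)), c(sum(x), sum(x^2)))
  beta <- solve(xtx, c(sum(y), sum(x * y)))
  res <- y - beta[1] - beta[2] * x
  list(slope = beta[2], rms = sqrt(mean(res^2)))
}

# a spectrum tibble from a reflectance function of wavelength
make_spectrum <- function(f, wl = seq(450, 950, by = 2)) {
  tibble::tibble(wavelength_nm = wl, reflectance = f(wl))
}

# small deterministic bscan wrapper with generous pitch so ROI extent checks
# pass on tiny test images
tiny_bscan <- function(px) bscan(px, axial_pitch_um = 50, lateral_pitch_um = 50)

# fused toy table: k tumors per class over nclass classes, nobs rows each,
# with class-separated features plus noise
toy_fused <- function(n_tumor = 6, nobs = 4, seed = 1) {
  withr::with_seed(seed, {
    labs <- rep(diagnosis_levels(), length.out = n_tumor)
    rows <- lapply(seq_len(n_tumor), function(k) {
      mu <- match(labs[k], diagnosis_levels())
      tibble::tibble(
        tumor_id = sprintf("X%02d", k),
        label = labs[k], obs_idx = seq_len(nobs),
        f1 = mu + stats::rnorm(nobs, 0, 0.05),
        f2 = -mu + stats::rnorm(nobs, 0, 0.05),
        f3 = stats::rnorm(nobs))
    })
    out <- dplyr::bind_rows(rows)
    out$label <- factor(out$label, levels = diagnosis_levels())
    out
  })
}
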