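# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force voxel-centre distance (mm) from each foreground voxel of
# `from` to the nearest foreground voxel of `to`.
brute_min_distance <- function(from, to, spacing) {
  a <- sweep(arrayInd(which(from != 0), dim(from)) - 1, 2, spacing, "*")
  b <- sweep(arrayInd(which(to != 0), dim(to)) - 1, 2, spacing, "*")
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(0, apply(d2, 1, min)))
}

# ICC(A,1) by an independent route: two-way ANOVA mean squares via aov().
icc_a1_oracle <- function(ratings) {
  long <- data.frame(
    y = as.vector(ratings),
    target = factor(rep(seq_len(nrow(ratings)), ncol(ratings))),
    rater = factor(rep(seq_len(ncol(ratings)), each = nrow(ratings))))
  ms <- summary(aov(y ~ target + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(ratings); k <- ncol(ratings)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Extended-Tofts enhancement by fine-grid trapezoidal convolution of the
# AIF with the exponential residue (numerical, independent of the
# closed-form path).
tofts_numeric_oracle <- function(t, ktrans, kep, vp, aif, dt_fine = 0.05) {
  vapply(t, function(ti) {
    if (ti <= attr(aif, "params")$t0) return(vp * aif(ti))
    tau <- seq(0, ti, length.out = max(2, ceiling(ti / dt_fine)) + 1)
    dt <- tau[2] - tau[1]
    integrand <- aif(tau) * exp(-kep * (ti - tau) / 60)
    integral <- sum((integrand[-1] + integrand[-length(integrand)]) / 2) *
      dt / 60   # minutes
    vp * aif(ti) + ktrans * integral
  }, numeric(1))
}

# Small non-overlapping lesion spec generator: ellipsoids on a jittered
# grid either side of the central slab of the default 64 x 32 x 32 scene.
random_lesion_specs <- function(n_per_side = 4) {
  base <- expand.grid(cx = c(0, 0), cy = c(9, 23), cz = c(9, 23))[seq_len(n_per_side * 2), ]
  base <- rbind(
    data.frame(cx = 8, cy = rep(c(9, 23), 2), cz = rep(c(9, 23), each = 2)),
    data.frame(cx = 52, cy = rep(c(9, 23), 2), cz = rep(c(9, 23), each = 2)))
  base$cx <- base$cx + runif(8, -3.5, 3.5)
  base$ax <- runif(8, 2, 3.5)
  base$ay <- runif(8, 2, 3.5)
  base$az <- runif(8, 2, 3.5)
  base
}

# Lesion specs with controlled surface gaps to the ventricular slab of the
# default 64 x 32 x 32 scene (faces at x = 27 and 36 mm): gaps are sampled
# away from the 8-mm rule with at least `margin` mm to spare.
lesion_specs_with_gaps <- function(margin = 1.2) {
  gaps <- ifelse(runif(8) < 0.5,
                 runif(8, 0.5, 8 - margin),
                 runif(8, 8 + margin, 15))
  ax <- runif(8, 2, 3)
  data.frame(
    cx = c(27 - gaps[1:4] - ax[1:4], 36 + gaps[5:8] + ax[5:8]),
    cy = rep(c(9, 23), 4),
    cz = rep(c(9, 23), each = 2),
    ax = ax, ay = runif(8, 2, 3.2), az = runif(8, 2, 3.2))
}
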