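# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own computational paths: superposition is done with
# base-R SVD, GDT by exhaustive subset enumeration, distances by brute
# force.

# Base-R Kabsch, independent of the compiled kernel.
oracle_superpose <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cy - as.numeric(cx %*% R)
  fit <- sweep(X %*% R, 2, -t, "-")
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((fit - Y)^2))))
}

# Exhaustive GDT oracle: max over ALL residue subsets of size >= 3 of the
# fraction of residues within t after superposing on the subset, for each
# threshold in one pass over the subsets.  Feasible for m <= 12.
oracle_gdt_ts <- function(X, Y, thresholds = c(1, 2, 4, 8)) {
  m <- nrow(X)
  best <- integer(length(thresholds))
  for (size in 3:m) {
    subs <- utils::combn(m, size)
    for (c in seq_len(ncol(subs))) {
      S <- subs[, c]
      fit <- oracle_superpose(X[S, , drop = FALSE], Y[S, , drop = FALSE])
      Xf <- sweep(X %*% fit$rotation, 2, -fit$translation, "-")
      d <- sqrt(rowSums((Xf - Y)^2))
      for (k in seq_along(thresholds)) {
        cnt <- sum(d <= thresholds[k])
        if (cnt > best[k]) best[k] <- cnt
      }
    }
  }
  mean(100 * best / m)
}

# Quaternion-grid search oracle for the optimal superposition of small
# point sets: scans rotations from a deterministic quaternion grid and
# polishes with optim.  Slow but independent of any closed form.
oracle_grid_superpose_rmsd <- function(X, Y, n_grid = 2000) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  quat_to_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  rss <- function(q) {
    R <- quat_to_rot(q)
    sum((Xc %*% t(R) - Yc)^2)
  }
  set.seed(42)
  qs <- matrix(rnorm(4 * n_grid), n_grid, 4)
  vals <- apply(qs, 1, rss)
  q0 <- qs[which.min(vals), ]
  opt <- stats::optim(q0, rss, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  sqrt(opt$value / nrow(X))
}

# Toy fixtures shared across test files.
toy_hairpin <- function(noise = 0, seed = 1) {
  generate_toy_structure(toy_spec("helix_hairpin", noise = noise,
                                  seed = seed))
}

# The reference hairpin re-expressed as a scored model (idealized bodies
# superposed onto the reference, zero relaxation steps).
hairpin_native_record <- function(restraints = NULL) {
  ref <- toy_hairpin()
  relax_from_reference(ref, attr(ref, "pool"),
                       mcm_config(models_to_sample = 1,
                                  steps_per_stage = 0,
                                  restraints = restraints))[[1]]
}
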