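random_instance <- function(n, noise_sd, n_outliers = 0) {
  # reference: a self-avoiding-ish 3.8 A random walk
  ref <- matrix(0, n, 3)
  for (i in 2:n) {
    step <- rnorm(3)
    ref[i, ] <- ref[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
  }
  mod <- ref + matrix(rnorm(3 * n, 0, noise_sd), n, 3)
  if (n_outliers > 0) {
    out <- sample.int(n, n_outliers)
    mod[out, ] <- mod[out, ] + matrix(rnorm(3 * n_outliers, 0, 15),
                                      n_outliers, 3)
  }
  R <- ssefold:::rotation_about_axis(rnorm(3), runif(1, 0, 180))
  list(ref = ref, mod = ssefold:::apply_transform(mod, R, rnorm(3, 0, 20)))
}

test_that("superposition is exact for congruent sets and matches oracles", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(X, X)$rmsd, 0, tolerance = 1e-12)
  R <- ssefold:::rotation_about_axis(c(1, -2, 0.5), 67)
  Y <- ssefold:::apply_transform(X, R, c(4, 5, 6))
  fit <- superpose(X, Y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(ssefold:::apply_transform(X, t(fit$rotation),
                                         as.numeric(fit$translation)),
               Y, tolerance = 1e-9)
  # 4-point asymmetric case vs the base-R and quaternion-grid oracles
  X4 <- matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 0, 1, 1, 2), 4, 3, byrow = TRUE)
  Y4 <- X4 + matrix(c(0.3, -0.2, 0.1, 0, 0.25, -0.1, 0.2, 0, 0.15,
                      -0.1, 0.1, 0), 4, 3, byrow = TRUE)
  got <- superpose(X4, Y4)$rmsd
  expect_equal(got, oracle_superpose(X4, Y4)$rmsd, tolerance = 1e-9)
  expect_equal(got, oracle_grid_superpose_rmsd(X4, Y4), tolerance = 1e-6)
  expect_error(superpose(X4[1:2, ], Y4[1:2, ]), "m >= 3")
})

test_that("superposition agrees with an established reference implementation", {
  set.seed(6)
  X <- matrix(rnorm(45, sd = 4), 15, 3)
  Y <- X + matrix(rnorm(45, sd = 1), 15, 3)
  got <- superpose(X, Y)$rmsd
  ref_fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(Y)), mobile = as.numeric(t(X))))
  want <- bio3d::rmsd(as.numeric(t(Y)), ref_fit)
  expect_equal(got, want, tolerance = 1e-3)  # bio3d rounds its RMSD
})

test_that("RMSD100 normalization has the documented fixed point and slope", {
  expect_equal(rmsd100(3, 100), 3)
  expect_equal(rmsd100(0, 150), 0)
  expect_equal(rmsd100(3, 200), 3 / (1 + log(sqrt(2))), tolerance = 1e-12)
  # strictly decreasing in n for fixed rmsd
  vals <- vapply(seq(20, 400, by = 20), function(n) rmsd100(3, n),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(rmsd100(3, 10), "n >= 20")
})

test_that("GDT_TS is 100 for self, 0 for scatter, 90 for one displaced residue", {
  set.seed(3)
  inst <- random_instance(10, 0)
  expect_equal(gdt_ts(inst$mod, inst$ref,
                      thresholds = c(1, 2, 4, 8)) , 100)
  # one residue displaced far away, the rest exact: 9/10 at every
  # threshold (verified against the exhaustive oracle at this size)
  ref <- inst$ref
  mod <- ref
  mod[4, ] <- mod[4, ] + c(100, 0, 0)
  rownames(mod) <- rownames(ref) <- 1:10
  expect_equal(gdt_ts(mod, ref), 90)
  expect_equal(oracle_gdt_ts(mod, ref), 90)
  # pathological scatter: nothing superposable within 8 A
  far <- matrix(rnorm(30, sd = 200), 10, 3)
  rownames(far) <- 1:10
  expect_lt(gdt_ts(far, ref), 30)
})

test_that("GDT_TS equals the exhaustive-subset oracle on small instances", {
  set.seed(41)
  n_cases <- 20  # the acceptance suite runs the full 200-instance sweep
  for (case in seq_len(n_cases)) {
    n <- sample(6:12, 1)
    inst <- random_instance(n, runif(1, 0.3, 3),
                            n_outliers = sample(0:2, 1))
    rownames(inst$mod) <- rownames(inst$ref) <- seq_len(n)
    got <- gdt_ts(inst$mod, inst$ref)
    want <- oracle_gdt_ts(inst$mod, inst$ref)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("GDT_TS is rigid-motion invariant and degrades with noise", {
  set.seed(17)
  ref <- toy_hairpin()
  rec <- hairpin_native_record()
  g0 <- gdt_ts(rec, ref)
  m2 <- rec
  R <- ssefold:::rotation_about_axis(c(0, 1, 1), 133)
  m2$ca <- ssefold:::apply_transform(rec$ca, R, c(10, -3, 2))
  rownames(m2$ca) <- rownames(rec$ca)
  expect_equal(gdt_ts(m2, ref), g0, tolerance = 1e-9)
  # monotone (stochastically) under growing per-residue noise
  gs <- vapply(c(0.3, 1.5, 4, 10), function(sd) {
    mean(vapply(1:5, function(i) {
      mm <- rec
      mm$ca <- rec$ca + matrix(rnorm(length(rec$ca), 0, sd),
                               nrow(rec$ca), 3)
      rownames(mm$ca) <- rownames(rec$ca)
      gdt_ts(mm, ref)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gs) < 0))
})

test_that("contact order counts sequence separation of spatial contacts", {
  # two-residue contact at separation 30 only
  n <- 31
  CB <- matrix(seq(0, 3000, by = 100), n, 3)
  CB[31, ] <- CB[1, ] + c(5, 0, 0)
  mats <- list(N = CB, CA = CB, C = CB, O = CB, CB = CB)
  s <- protein_structure(sequence_info(strrep("A", n)), mats$N, mats$CA,
                         mats$C, mats$O, CB)
  expect_equal(contact_order(s), 30)
  # no contacts -> 0 with a warning
  CB2 <- matrix(seq(0, 3000, by = 100), n, 3)
  s2 <- protein_structure(sequence_info(strrep("A", n)), CB2, CB2, CB2,
                          CB2, CB2)
  expect_warning(co <- contact_order(s2), "no contacts")
  expect_equal(co, 0)
  # an ideal 30-residue helix has only local contacts
  seq30 <- sequence_info(strrep("A", 30))
  b <- build_idealized_sse(sse_definition(1, 30, "helix"), seq30)
  m <- protein_model(seq30, setNames(list(b), 1))
  co_helix <- contact_order(m)
  expect_gt(co_helix, 3)
  expect_lt(co_helix, 4.5)
  # invariance under rigid motion
  m2 <- m
  m2$bodies[[1]] <- transform_sse(
    b, ssefold:::rotation_about_axis(c(1, 0, 2), 71), c(9, 9, 9))
  expect_equal(contact_order(m2), co_helix, tolerance = 1e-9)
})

test_that("ensemble metrics aggregate best, mu10 and enrichment", {
  ref <- toy_hairpin()
  rec <- hairpin_native_record()
  # ten identical perfect models
  perfect <- lapply(1:10, function(i) {
    r <- rec
    r$id <- sprintf("p%02d", i)
    r
  })
  em <- ensemble_metrics(perfect, ref)
  expect_equal(em$best_gdt_ts, 100)
  expect_equal(em$mu10, 100)
  # constructed set with a known top-10 mean
  d <- generate_decoy_set(ref, 25, accuracy = c(0.5, 6), rho = 0.5,
                          seed = 12)
  em2 <- ensemble_metrics(d, ref)
  g <- sort(vapply(em2$records, function(r) r$metrics$gdt_ts,
                   numeric(1)), decreasing = TRUE)
  expect_equal(em2$mu10, mean(g[1:10]), tolerance = 1e-12)
  expect_gte(em2$best_gdt_ts, em2$mu10)
  expect_error(ensemble_metrics(d[1:9], ref), "at least 10")
})
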