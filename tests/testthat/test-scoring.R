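two_sse_model <- function(gap_x = 12, seq_len = 40) {
  s <- sequence_info(strrep("L", seq_len))
  pool <- list(sse_definition(1, 10, "helix"),
               sse_definition(15, 24, "helix"))
  b1 <- build_idealized_sse(pool[[1]], s)
  b2 <- transform_sse(build_idealized_sse(pool[[2]], s), diag(3),
                      c(gap_x, 0, 0))
  protein_model(s, setNames(list(b1, b2), 1:2), pool)
}

test_that("inverse Boltzmann energies follow the closed form", {
  # identical observed/background -> zero energy in populated bins
  x <- rep(c(1, 2, 3), c(10, 20, 10))
  p <- derive_potential(x, x, edges = c(0.5, 1.5, 2.5, 3.5))
  expect_equal(p$energy, rep(0, 3))
  expect_equal(sum(p$p_obs), 1, tolerance = 1e-12)
  expect_equal(sum(p$p_back), 1, tolerance = 1e-12)
  # a bin observed at twice its background probability scores -ln 2
  p2 <- potential_table(c(0, 1, 2), p_obs = c(0.4, 0.6),
                        p_back = c(0.2, 0.8))
  expect_equal(p2$energy[1], -log(2), tolerance = 1e-12)
  # never-observed bins get the finite ceiling, not Inf
  p3 <- derive_potential(c(1, 1), c(1, 3), edges = c(0.5, 1.5, 2.5, 3.5))
  expect_equal(p3$energy[3], 5)
  expect_true(all(is.finite(p3$energy)))
  expect_error(derive_potential(numeric(0), 1:3, 0:4), "non-empty")
})

test_that("inverse Boltzmann is antisymmetric under swapping samples", {
  set.seed(31)
  a <- rnorm(500, 3, 1)
  b <- runif(500, 0, 6)
  edges <- seq(-1, 7, by = 0.5)
  pab <- derive_potential(a, b, edges)
  pba <- derive_potential(b, a, edges)
  both <- pab$p_obs > 0 & pab$p_back > 0
  expect_equal(pab$energy[both], -pba$energy[both], tolerance = 1e-12)
})

test_that("bimodal mixture recovery locates planted minima", {
  set.seed(7)
  obs <- c(rnorm(4000, 2, 0.3), rnorm(4000, 7, 0.3))
  back <- runif(8000, 0, 10)
  edges <- seq(0, 10, by = 0.5)
  pot <- derive_potential(obs, back, edges)
  ctr <- edges[-1] - 0.25
  left <- ctr < 5
  expect_lt(abs(ctr[left][which.min(pot$energy[left])] - 2), 0.5)
  expect_lt(abs(ctr[!left][which.min(pot$energy[!left])] - 7), 0.5)
})

test_that("potential tables round-trip through TSV", {
  pot <- derive_potential(rnorm(200, 5, 1), runif(200, 0, 10),
                          seq(0, 10, 0.5))
  p <- tempfile(fileext = ".tsv")
  write_potential_table(pot, p)
  back <- read_potential_table(p)
  expect_equal(back$energy, pot$energy, tolerance = 1e-9)
  expect_equal(back$edges, pot$edges)
})

test_that("neighbor count uses the cosine switching function", {
  cs <- score_constants()
  m <- two_sse_model(gap_x = 100)  # far apart: only intra-SSE neighbors
  nc_far <- neighbor_count(m, 1, cs)
  expect_gte(nc_far, 0)
  # two residues midway between the bounds contribute 0.5 each way
  mid <- (cs$nc_lower + cs$nc_upper) / 2
  s <- sequence_info("AA")
  b <- build_idealized_sse(sse_definition(1, 2, "helix"), s)
  # direct check of the switching form via the kernel
  cb <- rbind(c(0, 0, 0), c(mid, 0, 0))
  pt <- ssefold:::.pair_terms_cpp(cb, c(1L, 2L), cs$nc_lower, cs$nc_upper,
                                  cs$clash_radius, numeric(0), numeric(0))
  expect_equal(as.numeric(pt$neighbor_counts), c(0.5, 0.5),
               tolerance = 1e-12)
  cb2 <- rbind(c(0, 0, 0), c(cs$nc_lower - 0.5, 0, 0))
  pt2 <- ssefold:::.pair_terms_cpp(cb2, c(1L, 2L), cs$nc_lower,
                                   cs$nc_upper, cs$clash_radius,
                                   numeric(0), numeric(0))
  expect_equal(as.numeric(pt2$neighbor_counts), c(1, 1))
  expect_error(neighbor_count(m, 39), "not part of a placed SSE")
})

test_that("loop closure penalizes only infeasible gaps, quadratically", {
  cs <- score_constants()
  # single SSE: no loops
  s <- sequence_info(strrep("A", 20))
  one <- protein_model(s, setNames(list(build_idealized_sse(
    sse_definition(1, 8, "helix"), s)), 1))
  expect_equal(score_loop_closure(one), 0)
  # the toy hairpin has a feasible loop by construction
  m0 <- hairpin_native_record()$model
  expect_equal(score_loop_closure(m0, cs), 0)
  # move the second SSE along the gap direction until the gap exceeds
  # the feasibility bound by exactly 2 A
  fl <- ssefold:::model_flat(m0)
  n1 <- nrow(fl$bodies[[1]]$coords$C)
  v <- fl$bodies[[2]]$coords$N[1, ] - fl$bodies[[1]]$coords$C[n1, ]
  gap0 <- sqrt(sum(v^2))
  L <- fl$bodies[[2]]$definition$first_res -
    fl$bodies[[1]]$definition$last_res - 1L
  bound <- L * cs$loop_d_per_res + cs$loop_d_offset
  shift <- (bound + 2) - gap0
  m2 <- m0
  m2$bodies[[2]] <- transform_sse(m0$bodies[[2]], diag(3),
                                  shift * v / gap0)
  expect_equal(score_loop_closure(m2, cs), 4, tolerance = 1e-6)
})

test_that("radius of gyration is scored against the expected globule size", {
  cs <- score_constants()
  m <- two_sse_model(gap_x = 11)
  fl <- ssefold:::model_flat(m)
  ctr <- colMeans(fl$ca)
  rg <- sqrt(mean(rowSums(sweep(fl$ca, 2, ctr)^2)))
  expected <- cs$rg_a * fl$m^(1 / 3) + cs$rg_b
  expect_equal(score_radius_of_gyration(m, cs), (rg - expected)^2,
               tolerance = 1e-9)
})

test_that("clash terms detect superposed SSEs and scale linearly", {
  m_far <- two_sse_model(gap_x = 30)
  expect_equal(unname(score_clashes(m_far)), c(0, 0))
  # exactly superposed SSEs clash in both terms
  s <- sequence_info(strrep("L", 40))
  pool <- list(sse_definition(1, 10, "helix"),
               sse_definition(15, 24, "helix"))
  b1 <- build_idealized_sse(pool[[1]], s)
  b2 <- build_idealized_sse(pool[[2]], s)
  m_sup <- protein_model(s, setNames(list(b1, b2), 1:2), pool)
  cl <- score_clashes(m_sup)
  expect_gt(cl["residue"], 0)
  expect_gt(cl["sse"], 0)
  # two isolated CB at clash_radius - 1 -> penalty 1 (unit slope)
  cs <- score_constants()
  cb <- rbind(c(0, 0, 0), c(cs$clash_radius - 1, 0, 0))
  pt <- ssefold:::.pair_terms_cpp(cb, c(1L, 2L), cs$nc_lower, cs$nc_upper,
                                  cs$clash_radius, numeric(0), numeric(0))
  expect_equal(pt$clash, 1, tolerance = 1e-12)
})

test_that("SSE packing evaluates the distance/angle table with a cutoff", {
  s <- sequence_info(strrep("A", 40))
  pool <- list(sse_definition(1, 10, "helix"),
               sse_definition(15, 24, "helix"))
  b1 <- build_idealized_sse(pool[[1]], s)
  b2 <- build_idealized_sse(pool[[2]], s)
  # parallel helices 20 A apart: beyond the 12 A cutoff
  expect_equal(score_sse_packing(b1, transform_sse(b2, diag(3),
                                                   c(20, 0, 0))), 0)
  # synthetic potential with a known minimum at (10 A, 20 deg)
  de <- seq(0, 12, 1); ae <- seq(0, 90, 15)
  E <- matrix(0, 12, 6); E[11, 2] <- -3  # bin (10,11] x (15,30]
  pot <- ssefold:::packing_potential(de, ae, E)
  b2r <- transform_sse(b2, ssefold:::rotation_about_axis(c(1, 0, 0), 20),
                       c(10.5, 0, 0))
  expect_equal(score_sse_packing(b1, b2r, pot), -3)
})

test_that("restraint scoring is flat-bottomed, capped and confidence-scaled", {
  m <- two_sse_model(gap_x = 12)
  empty <- restraint_set(data.frame())
  expect_equal(score_restraints(m, empty), 0)
  fl <- ssefold:::model_flat(m)
  d <- sqrt(sum((fl$cb[match(1, fl$resno), ] -
                 fl$cb[match(15, fl$resno), ])^2))
  sat <- restraint_set(data.frame(res_i = 1, res_j = 15, atom = "CB",
                                  lower = 0, upper = ceiling(d) + 1,
                                  kind = "contact", confidence = 1))
  expect_equal(score_restraints(m, sat), 0)
  # violation of 3 A with unit confidence scores 9 (below the cap of 10)
  viol <- restraint_set(data.frame(res_i = 1, res_j = 15, atom = "CB",
                                   lower = 0, upper = d - 3,
                                   kind = "contact", confidence = 1))
  expect_equal(score_restraints(m, viol), 9, tolerance = 1e-9)
  half <- restraint_set(data.frame(res_i = 1, res_j = 15, atom = "CB",
                                   lower = 0, upper = d - 3,
                                   kind = "contact", confidence = 0.5))
  expect_equal(score_restraints(m, half), 4.5, tolerance = 1e-9)
  # gross violation is capped
  far <- restraint_set(data.frame(res_i = 1, res_j = 15, atom = "CB",
                                  lower = 0, upper = 1,
                                  kind = "contact", confidence = 1))
  expect_equal(score_restraints(m, far), 10)
  # unplaced endpoint contributes the neutral value
  un <- restraint_set(data.frame(res_i = 1, res_j = 30, atom = "CB",
                                 lower = 0, upper = 8,
                                 kind = "contact", confidence = 1))
  expect_equal(score_restraints(m, un), score_constants()$restraint_neutral)
})

test_that("restraint score improves monotonically toward the bounds", {
  cs <- score_constants()
  s <- sequence_info(strrep("A", 40))
  pool <- list(sse_definition(1, 10, "helix"),
               sse_definition(15, 24, "helix"))
  rs <- restraint_set(data.frame(res_i = 5, res_j = 19, atom = "CB",
                                 lower = 0, upper = 8, kind = "contact",
                                 confidence = 1))
  pens <- vapply(seq(30, 9, by = -3), function(gap) {
    b1 <- build_idealized_sse(pool[[1]], s)
    b2 <- transform_sse(build_idealized_sse(pool[[2]], s), diag(3),
                        c(gap, 0, 0))
    score_restraints(protein_model(s, setNames(list(b1, b2), 1:2), pool),
                     rs, cs)
  }, numeric(1))
  expect_true(all(diff(pens) <= 1e-9))
})

test_that("total score is the weighted sum with stage-scheduled clash weights", {
  m <- two_sse_model(gap_x = 6)
  w <- score_weights()
  for (stage in c(1, 3, 6)) {
    sr <- total_score(m, w, stage)
    expect_equal(sr$total, sum(sr$raw * sr$weights), tolerance = 1e-9)
  }
  # all weights zero -> total zero regardless of geometry
  w0 <- score_weights(0, 0, 0, 0, 0, 0, 0, 0, clash_schedule = rep(0, 5))
  expect_equal(total_score(m, w0, 3)$total, 0)
  expect_error(total_score(m, w, 0), "stage")
  expect_error(total_score(m, w, 7), "stage")
  # stage 1 zeroes the clash contribution even for clashing geometry
  s <- sequence_info(strrep("L", 40))
  pool <- list(sse_definition(1, 10, "helix"),
               sse_definition(15, 24, "helix"))
  clash_model <- protein_model(
    s, setNames(lapply(pool, build_idealized_sse, sequence = s), 1:2),
    pool)
  sr1 <- total_score(clash_model, w, 1)
  expect_equal(unname(sr1$weights[c("clash_residue", "clash_sse")]),
               c(0, 0))
})

test_that("every score term is invariant under global rigid motion", {
  m <- two_sse_model(gap_x = 8)
  R <- ssefold:::rotation_about_axis(c(2, -1, 1), 117)
  tr <- c(12, -4, 9)
  m2 <- m
  m2$bodies <- lapply(m$bodies, transform_sse, rotation = R,
                      translation = tr)
  rs <- restraint_set(data.frame(res_i = 3, res_j = 17, atom = "CB",
                                 lower = 0, upper = 6, kind = "contact",
                                 confidence = 1))
  s1 <- total_score(m, stage = 4, restraints = rs)
  s2 <- total_score(m2, stage = 4, restraints = rs)
  expect_equal(s1$raw, s2$raw, tolerance = 1e-9)
})
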