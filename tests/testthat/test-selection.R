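# Synthetic score/completeness records (no coordinates) for the filter
# and split operations.
fake_records <- function(completeness, total = seq_along(completeness),
                         ids = sprintf("f%04d", seq_along(completeness))) {
  lapply(seq_along(completeness), function(i)
    structure(list(id = ids[i], total = total[i],
                   completeness = completeness[i], metrics = list()),
              class = "model_record"))
}

test_that("completeness filter removes the stated fraction", {
  set.seed(8)
  recs <- fake_records(runif(20000), total = rnorm(20000))
  kept <- filter_by_completeness(recs, 0.25)
  expect_length(kept, 15000)
  kept2 <- filter_by_completeness(fake_records(runif(10)), 0.5)
  expect_length(kept2, 5)
  # idempotent at fraction 0
  expect_identical(filter_by_completeness(recs[1:50], 0), recs[1:50])
  # removed models are exactly the lowest-completeness ones
  comp <- vapply(kept, `[[`, numeric(1), "completeness")
  all_comp <- vapply(recs, `[[`, numeric(1), "completeness")
  expect_equal(sort(comp), sort(all_comp)[5001:20000], tolerance = 1e-12)
})

test_that("completeness ties are broken by keeping better scores", {
  recs <- fake_records(rep(0.5, 4), total = c(10, -5, 3, 0),
                       ids = c("a", "b", "c", "d"))
  kept <- filter_by_completeness(recs, 0.5)
  expect_setequal(vapply(kept, `[[`, character(1), "id"), c("b", "d"))
  # the filter-fraction rule follows the maximum completeness reached
  expect_equal(choose_filter_fraction(fake_records(c(0.2, 0.96))), 0.5)
  expect_equal(choose_filter_fraction(fake_records(c(0.2, 0.9))), 0.25)
})

test_that("score split takes floor(20%) as the low stratum", {
  recs <- fake_records(runif(10), total = c(5, 1, 9, 3, 7, 2, 8, 4, 6, 0))
  st <- split_by_score(recs)
  expect_length(st$low, 2)
  expect_length(st$high, 8)
  expect_setequal(vapply(st$low, `[[`, numeric(1), "total"), c(0, 1))
  st5 <- split_by_score(recs[1:5])
  expect_length(st5$low, 1)
  # all-equal scores: deterministic tie-break by id
  eq <- fake_records(runif(10), total = rep(1, 10))
  st_eq <- split_by_score(eq)
  expect_equal(vapply(st_eq$low, `[[`, character(1), "id"),
               c("f0001", "f0002"))
})

test_that("pairwise model distance is a superposition-invariant metric", {
  ref <- toy_hairpin()
  d1 <- generate_decoy_set(ref, 2, accuracy = c(1, 3), seed = 2)
  expect_equal(pairwise_model_distance(d1[[1]], d1[[1]]), 0,
               tolerance = 1e-9)
  # a rigidly rotated copy is at distance zero
  rot <- d1[[1]]
  R <- ssefold:::rotation_about_axis(c(1, 2, -1), 49)
  rot$ca <- ssefold:::apply_transform(d1[[1]]$ca, R, c(3, 4, 5))
  rownames(rot$ca) <- rownames(d1[[1]]$ca)
  expect_equal(pairwise_model_distance(d1[[1]], rot), 0, tolerance = 1e-9)
  expect_equal(pairwise_model_distance(d1[[1]], d1[[2]]),
               pairwise_model_distance(d1[[2]], d1[[1]]),
               tolerance = 1e-12)
})

test_that("pairwise distance matches a brute-force superposition oracle", {
  set.seed(13)
  # hand-built > 20-residue case so the RMSD100 normalization applies
  n <- 24
  ca_a <- matrix(rnorm(3 * n, sd = 5), n, 3,
                 dimnames = list(1:n, NULL))
  ca_b <- ca_a + matrix(rnorm(3 * n, sd = 1.5), n, 3)
  rec_a <- structure(list(id = "a", ca = ca_a, metrics = list()),
                     class = "model_record")
  rec_b <- structure(list(id = "b", ca = ca_b, metrics = list()),
                     class = "model_record")
  got <- pairwise_model_distance(rec_a, rec_b)
  want <- rmsd100(oracle_grid_superpose_rmsd(ca_a, ca_b), n)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("planted clusters are recovered with correct medoids", {
  ref1 <- toy_hairpin()
  ref2 <- generate_toy_structure(toy_spec("helix_hairpin", noise = 6,
                                          seed = 77))
  ref3 <- generate_toy_structure(toy_spec("helix_hairpin", noise = 6,
                                          seed = 170))
  blobs <- list(ref1, ref2, ref3)
  recs <- list()
  for (k in 1:3) {
    d <- generate_decoy_set(blobs[[k]], 50, accuracy = c(0.05, 0.3),
                            seed = 100 + k)
    for (i in seq_along(d)) d[[i]]$id <- sprintf("b%d_%02d", k, i)
    recs <- c(recs, d)
  }
  for (i in seq_along(recs)) recs[[i]]$total <- i  # irrelevant here
  sol <- cluster_models(recs, max_radius = 5, min_pop = 0.005,
                        k_range = 1:6, split = FALSE)
  expect_equal(sol$k, 3)
  expect_true(sol$feasible)
  # one medoid per planted blob
  blobs_of_medoids <- substr(sol$medoids, 1, 2)
  expect_setequal(blobs_of_medoids, c("b1", "b2", "b3"))
  # assignment purity: every member shares its medoid's blob
  ids <- vapply(recs, `[[`, character(1), "id")
  for (c in seq_along(sol$medoids)) {
    members <- ids[sol$assignment == sol$assignment[match(sol$medoids[c],
                                                          ids)]]
    expect_true(all(substr(members, 1, 2) == substr(sol$medoids[c], 1, 2)))
  }
})

test_that("cluster solutions respect the radius and population rules", {
  ref <- toy_hairpin()
  d <- generate_decoy_set(ref, 40, accuracy = c(0.05, 0.5), seed = 31)
  # an outlier far from everything, population 1/41 = 2.4% > 0.5%: kept;
  # then check the radius bookkeeping
  sol <- cluster_models(d, max_radius = 5, min_pop = 0.005, k_range = 1:4,
                        split = FALSE)
  expect_true(all(sol$radii <= 5))
  D <- model_distance_matrix(d)
  ids <- vapply(d, `[[`, character(1), "id")
  for (c in seq_along(sol$medoids)) {
    mi <- match(sol$medoids[c], ids)
    members <- which(sol$assignment == sol$assignment[mi])
    expect_true(all(D[members, mi] <= sol$radii[c] + 1e-9))
  }
  # all models identical -> one cluster of radius 0
  same <- rep(d[1], 12)
  for (i in seq_along(same)) same[[i]]$id <- sprintf("s%02d", i)
  sol1 <- cluster_models(same, k_range = 1:3, split = FALSE)
  expect_equal(sol1$k, 1)
  expect_equal(max(sol1$radii), 0)
})

test_that("tiny clusters are dropped by the population cutoff", {
  ref <- toy_hairpin()
  main <- generate_decoy_set(ref, 999, accuracy = c(0.05, 0.4), seed = 5)
  # a single far-away model: population 1/1000 = 0.1% < 0.5%
  far <- generate_decoy_set(generate_toy_structure(
    toy_spec("helix_hairpin", noise = 9, seed = 55)), 1,
    accuracy = c(0.05, 0.1), seed = 6)
  far[[1]]$id <- "lone"
  recs <- c(main, far)
  sol <- cluster_models(recs, max_radius = 5, min_pop = 0.005,
                        k_range = 2, split = FALSE)
  expect_false("lone" %in% sol$medoids)
  expect_equal(sol$dropped, 1)
})

test_that("enrichment spans 0 to 10 with the formula's extremes", {
  ref <- toy_hairpin()
  # perfectly correlated scores: the 10% best-scoring are the 10% most
  # accurate
  d <- generate_decoy_set(ref, 200, rho = 1, seed = 3)
  expect_equal(compute_enrichment(d), 10)
  # perfectly anti-correlated: none of them
  d2 <- generate_decoy_set(ref, 200, rho = -1, seed = 3)
  expect_equal(compute_enrichment(d2), 0)
  expect_error(compute_enrichment(d[1:5]), "at least 10")
  d3 <- d
  d3[[1]]$metrics$rmsd100 <- NULL
  expect_error(compute_enrichment(d3), "metric")
})

test_that("enrichment is invariant under monotone transforms", {
  ref <- toy_hairpin()
  d <- generate_decoy_set(ref, 150, rho = 0.6, seed = 9)
  e0 <- compute_enrichment(d)
  d_t <- lapply(d, function(r) {
    r$total <- exp(r$total / 3) + 5
    r$metrics$rmsd100 <- r$metrics$rmsd100^3
    r
  })
  expect_equal(compute_enrichment(d_t), e0)
})
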