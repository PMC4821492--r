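#' Score term weights and the staged clash-weight schedule
#'
#' The total score is the weighted sum of all scoring terms.  The clash
#' terms are special: over the five large-perturbation assembly stages
#' their weight ramps up through the schedule (0, 125, 250, 375, 500); the
#' final small-perturbation stage keeps the last value.  The per-term
#' clash weights below act as multipliers on that schedule.
#'
#' @param loop_closure,radius_of_gyration,burial,pairing,sse_packing
#'   non-negative weights of the knowledge-based terms.
#' @param clash_residue,clash_sse multipliers applied on top of the staged
#'   clash schedule.
#' @param restraints weight of the distance-restraint term.
#' @param clash_schedule length-5 non-negative vector, one clash weight
#'   per large-perturbation stage.
#' @return object of class \code{score_weights}.
#' @export
score_weights <- function(loop_closure = 1, radius_of_gyration = 1,
                          burial = 1, pairing = 1, sse_packing = 1,
                          clash_residue = 1, clash_sse = 1, restraints = 1,
                          clash_schedule = c(0, 125, 250, 375, 500)) {
  w <- c(loop_closure = loop_closure,
         radius_of_gyration = radius_of_gyration, burial = burial,
         pairing = pairing, sse_packing = sse_packing,
         clash_residue = clash_residue, clash_sse = clash_sse,
         restraints = restraints)
  if (any(w < 0) || any(clash_schedule < 0))
    stop("weights must be non-negative")
  if (length(clash_schedule) != 5)
    stop("clash_schedule must have one entry per large-perturbation stage (5)")
  structure(list(terms = w, clash_schedule = as.numeric(clash_schedule)),
            class = "score_weights")
}

# Flat per-residue view of a model's placed coordinates, plus per-SSE
# geometry, as consumed by the scoring kernels.
model_flat <- function(model) {
  bodies <- model$bodies
  if (length(bodies) == 0)
    return(list(m = 0L, bodies = bodies))
  ord <- order(vapply(bodies, function(b) b$definition$first_res, integer(1)))
  bodies <- bodies[ord]
  ca <- do.call(rbind, lapply(bodies, function(b) b$coords$CA))
  cb <- do.call(rbind, lapply(bodies, function(b) b$coords$CB))
  resno <- unlist(lapply(bodies, `[[`, "residues"), use.names = FALSE)
  aa <- unlist(lapply(bodies, `[[`, "aa"), use.names = FALSE)
  sse_id <- rep(seq_along(bodies),
                vapply(bodies, function(b) length(b$residues), integer(1)))
  axes <- lapply(bodies, sse_axis)
  list(m = nrow(ca), bodies = bodies, ca = ca, cb = cb, resno = resno,
       aa = aa, sse_id = as.integer(sse_id), axes = axes,
       types = vapply(bodies, function(b) b$definition$ss_type,
                      character(1)))
}

# Pre-resolved potential tables for the inner scoring loop: the burial
# tables as one energy matrix (bin x amino acid), the pairing table as
# bare vectors.
prep_potentials <- function(potentials) {
  bedges <- potentials$burial[[1]]$edges
  list(bedges = bedges,
       nbin = length(bedges) - 1L,
       burial_mat = vapply(potentials$burial, `[[`,
                           numeric(length(bedges) - 1L), "energy"),
       pair_edges = potentials$pairing$edges,
       pair_energy = potentials$pairing$energy,
       packing = potentials$packing)
}

#' Neighbor count of a placed residue
#'
#' Degree of burial of residue \code{resno}: the sum over all other placed
#' residues of a switching function of the Cbeta-Cbeta distance -- 1 below
#' \code{nc_lower}, 0 above \code{nc_upper}, cosine-interpolated between.
#'
#' @param model a [protein_model()].
#' @param resno 1-based residue index; must lie in a placed SSE.
#' @param constants a [score_constants()].
#' @return non-negative real.
#' @export
neighbor_count <- function(model, resno, constants = score_constants()) {
  fl <- model_flat(model)
  if (fl$m == 0 || !(resno %in% fl$resno))
    stop("residue ", resno, " is not part of a placed SSE")
  nc <- .pair_terms_cpp(fl$cb, fl$sse_id, constants$nc_lower,
                        constants$nc_upper, constants$clash_radius,
                        numeric(0), numeric(0))$neighbor_counts
  nc[match(resno, fl$resno)]
}

#' Burial score of a model
#'
#' Sum over placed residues of the residue-type burial potential
#' evaluated at the residue's neighbor count.
#'
#' @inheritParams neighbor_count
#' @param potentials as returned by [default_potentials()].
#' @return real score (0 for an empty model).
#' @export
score_burial <- function(model, potentials = default_potentials(),
                         constants = score_constants()) {
  fl <- model_flat(model)
  if (fl$m == 0) return(0)
  score_terms_flat(fl, potentials, constants)[["burial"]]
}

#' Loop-closure feasibility score
#'
#' For each pair of sequence-adjacent placed SSEs with a loop of L
#' residues between them, the Euclidean gap from the C atom of the first
#' SSE's last residue to the N atom of the next SSE's first residue is
#' compared with the feasibility bound \code{L * loop_d_per_res +
#' loop_d_offset}; any excess is penalized quadratically (unit slope).
#'
#' @inheritParams neighbor_count
#' @return non-negative penalty; 0 with fewer than two placed SSEs.
#' @export
score_loop_closure <- function(model, constants = score_constants()) {
  fl <- model_flat(model)
  loop_closure_flat(fl, constants)
}

loop_closure_flat <- function(fl, constants) {
  bodies <- fl$bodies
  if (length(bodies) < 2) return(0)
  pen <- 0
  for (k in seq_len(length(bodies) - 1)) {
    a <- bodies[[k]]; b <- bodies[[k + 1]]
    L <- b$definition$first_res - a$definition$last_res - 1L
    gap <- vnorm(b$coords$N[1, ] - a$coords$C[nrow(a$coords$C), ])
    bound <- L * constants$loop_d_per_res + constants$loop_d_offset
    if (gap > bound) pen <- pen + (gap - bound)^2
  }
  pen
}

#' Radius-of-gyration score
#'
#' The radius of gyration of the placed Calpha set is compared with the
#' expected value for a globule of as many residues,
#' \code{rg_a * m^(1/3) + rg_b}; the deviation is penalized
#' quadratically.  The term can be disabled by zeroing its weight.
#'
#' @inheritParams neighbor_count
#' @return non-negative penalty; 0 for an empty model.
#' @export
score_radius_of_gyration <- function(model, constants = score_constants()) {
  fl <- model_flat(model)
  rg_flat(fl, constants)
}

rg_flat <- function(fl, constants) {
  if (fl$m == 0) return(0)
  ctr <- colMeans(fl$ca)
  rg <- sqrt(mean(rowSums(sweep(fl$ca, 2, ctr)^2)))
  expected <- constants$rg_a * fl$m^(1 / 3) + constants$rg_b
  (rg - expected)^2
}

#' SSE-SSE packing score for one pair of bodies
#'
#' The shortest distance between the two SSE axis segments and the acute
#' crossing angle between the axes are evaluated against a distance x
#' angle potential; pairs beyond \code{packing_cutoff} contribute 0.
#'
#' @param a,b \code{sse_body} objects.
#' @param potential a packing potential (see [default_potentials()]).
#' @param constants a [score_constants()].
#' @return real score.
#' @export
score_sse_packing <- function(a, b,
                              potential = default_potentials()$packing,
                              constants = score_constants()) {
  packing_pair(sse_axis(a), sse_axis(b), potential, constants)
}

packing_pair <- function(ax_a, ax_b, potential, constants) {
  d <- .segment_distance_cpp(ax_a[1, ], ax_a[2, ], ax_b[1, ], ax_b[2, ])
  if (d > constants$packing_cutoff) return(0)
  u <- unit(ax_a[2, ] - ax_a[1, ])
  v <- unit(ax_b[2, ] - ax_b[1, ])
  ang <- rad2deg(acos(min(1, abs(sum(u * v)))))
  evaluate_packing(potential, d, ang)
}

#' Residue and SSE clash scores
#'
#' The residue term sums, over Cbeta pairs from different SSEs closer
#' than \code{clash_radius}, a penalty linear in the overlap.  The SSE
#' term penalizes overlap of the SSE bounding cylinders (axis-axis
#' distance below the sum of the per-type cylinder radii), again linear
#' in the overlap.
#'
#' @inheritParams neighbor_count
#' @return named numeric vector \code{c(residue = ..., sse = ...)}, both
#'   non-negative.
#' @export
score_clashes <- function(model, constants = score_constants()) {
  fl <- model_flat(model)
  if (fl$m == 0) return(c(residue = 0, sse = 0))
  pt <- .pair_terms_cpp(fl$cb, fl$sse_id, constants$nc_lower,
                        constants$nc_upper, constants$clash_radius,
                        numeric(0), numeric(0))
  c(residue = pt$clash, sse = sse_clash_flat(fl, constants))
}

sse_clash_flat <- function(fl, constants) {
  nb <- length(fl$bodies)
  if (nb < 2) return(0)
  rad <- ifelse(fl$types == "helix", constants$sse_radius_helix,
                constants$sse_radius_strand)
  pen <- 0
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    d <- .segment_distance_cpp(fl$axes[[i]][1, ], fl$axes[[i]][2, ],
                               fl$axes[[j]][1, ], fl$axes[[j]][2, ])
    ov <- rad[[i]] + rad[[j]] - d
    if (ov > 0) pen <- pen + ov
  }
  as.numeric(pen)
}

#' Distance-restraint score
#'
#' Flat-bottom potential per restraint: zero when the anchor-atom distance
#' lies inside [lower, upper], quadratic in the violation outside, capped
#' at \code{restraint_cap}, and scaled by the restraint confidence.
#' Restraints with an unplaced endpoint contribute the configurable
#' neutral value.
#'
#' @inheritParams neighbor_count
#' @param restraints a [restraint_set()].
#' @return non-negative penalty; 0 for an empty restraint set.
#' @export
score_restraints <- function(model, restraints,
                             constants = score_constants()) {
  fl <- model_flat(model)
  restraints_flat(fl, restraints, constants)
}

restraints_flat <- function(fl, restraints, constants) {
  df <- restraints$table
  if (is.null(df) || nrow(df) == 0) return(0)
  if (fl$m == 0) return(constants$restraint_neutral * nrow(df))
  pos <- match(df$res_i, fl$resno)
  pos2 <- match(df$res_j, fl$resno)
  pen <- 0
  for (k in seq_len(nrow(df))) {
    if (is.na(pos[k]) || is.na(pos2[k])) {
      pen <- pen + constants$restraint_neutral
      next
    }
    M <- if (df$atom[k] == "CA") fl$ca else fl$cb
    d <- vnorm(M[pos[k], ] - M[pos2[k], ])
    viol <- max(0, d - df$upper[k], df$lower[k] - d)
    pen <- pen + df$confidence[k] * min(viol^2, constants$restraint_cap)
  }
  pen
}

# All raw score terms from a flat view, in fixed order.  `prep` is the
# pre-resolved potential set (prep_potentials); passing it avoids
# re-deriving lookup tables in the sampling inner loop.
score_terms_flat <- function(fl, potentials, constants,
                             restraints = NULL, prep = NULL) {
  if (is.null(prep)) prep <- prep_potentials(potentials)
  terms <- c(loop_closure = 0, radius_of_gyration = 0, burial = 0,
             pairing = 0, sse_packing = 0, clash_residue = 0,
             clash_sse = 0, restraints = 0)
  if (fl$m > 0) {
    pt <- .pair_terms_cpp(fl$cb, fl$sse_id, constants$nc_lower,
                          constants$nc_upper, constants$clash_radius,
                          prep$pair_edges, prep$pair_energy)
    # burial: per-residue table lookup on neighbor count
    idx <- findInterval(pt$neighbor_counts, prep$bedges,
                        rightmost.closed = TRUE)
    ok <- idx >= 1 & idx <= prep$nbin
    bur <- sum(prep$burial_mat[cbind(idx[ok],
                                     match(fl$aa[ok], AA1))])
    pack <- 0
    nb <- length(fl$bodies)
    if (nb >= 2) {
      for (i in seq_len(nb - 1)) for (j in (i + 1):nb)
        pack <- pack + packing_pair(fl$axes[[i]], fl$axes[[j]],
                                    prep$packing, constants)
    }
    terms["loop_closure"] <- loop_closure_flat(fl, constants)
    terms["radius_of_gyration"] <- rg_flat(fl, constants)
    terms["burial"] <- bur
    terms["pairing"] <- pt$pairing
    terms["sse_packing"] <- pack
    terms["clash_residue"] <- pt$clash
    terms["clash_sse"] <- sse_clash_flat(fl, constants)
  }
  if (!is.null(restraints))
    terms["restraints"] <- restraints_flat(fl, restraints, constants)
  terms
}

effective_weights <- function(weights, stage) {
  if (!is.numeric(stage) || length(stage) != 1 || stage < 1 || stage > 6)
    stop("stage must be an integer in [1, 6]")
  w <- weights$terms
  cw <- weights$clash_schedule[min(stage, 5L)]
  c(loop_closure = unname(w["loop_closure"]),
    radius_of_gyration = unname(w["radius_of_gyration"]),
    burial = unname(w["burial"]),
    pairing = unname(w["pairing"]),
    sse_packing = unname(w["sse_packing"]),
    clash_residue = cw * unname(w["clash_residue"]),
    clash_sse = cw * unname(w["clash_sse"]),
    restraints = unname(w["restraints"]))
}

#' Total model score: weighted sum of all scoring terms
#'
#' Evaluates every low-resolution scoring term on the model and returns
#' the weighted sum, with the clash weights taken from the stage schedule
#' (stage 1 scores clashes with weight 0; stages 2-5 ramp up through the
#' schedule; stage 6 keeps the final value).
#'
#' @inheritParams neighbor_count
#' @param weights a [score_weights()].
#' @param stage integer assembly stage in [1, 6].
#' @param restraints optional [restraint_set()].
#' @param potentials as returned by [default_potentials()].
#' @return object of class \code{score_result}: \code{raw} per-term
#'   values, \code{weights} (effective, stage-resolved), \code{weighted}
#'   products, and \code{total} (their sum).
#' @export
total_score <- function(model, weights = score_weights(), stage = 1L,
                        restraints = NULL,
                        potentials = default_potentials(),
                        constants = score_constants()) {
  fl <- model_flat(model)
  ew <- effective_weights(weights, stage)
  raw <- score_terms_flat(fl, potentials, constants, restraints)
  weighted <- raw * ew
  structure(list(raw = raw, weights = ew, weighted = weighted,
                 total = sum(weighted), stage = as.integer(stage)),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> stage %d, total %.3f\n", x$stage, x$total))
  df <- data.frame(raw = x$raw, weight = x$weights, weighted = x$weighted)
  print(round(df, 4))
  invisible(x)
}
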