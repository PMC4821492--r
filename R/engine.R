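# Internal sampling engine.  The Monte Carlo loop operates on a flat
# state -- preallocated coordinate matrices over the pool's residues with
# a placed mask -- so a move touches one SSE's rows and a score
# evaluation is a handful of vectorized kernel calls.  The public
# protein_model API wraps this state at trajectory boundaries.

# Static (per-run) description of the pool geometry.
engine_init <- function(sequence, pool, canon) {
  npool <- length(pool)
  n_i <- vapply(canon, function(b) length(b$residues), integer(1))
  ends <- cumsum(n_i)
  starts <- ends - n_i + 1L
  # scoring-relevant canonical stack per body:
  # [CA rows; CB rows; N(first); C(last); axis lo; axis hi]
  cstack <- lapply(canon, function(b) {
    zr <- range(b$canonical$CA[, 3])
    rbind(b$canonical$CA, b$canonical$CB,
          b$canonical$N[1, ], b$canonical$C[nrow(b$canonical$C), ],
          c(0, 0, zr[1]), c(0, 0, zr[2]))
  })
  resno <- unlist(lapply(canon, `[[`, "residues"), use.names = FALSE)
  aa <- unlist(lapply(canon, `[[`, "aa"), use.names = FALSE)
  types <- vapply(pool, `[[`, character(1), "ss_type")
  list(sequence = sequence, pool = pool, canon = canon, npool = npool,
       n_i = n_i, starts = starts, ends = ends, M = sum(n_i),
       cstack = cstack, resno = resno, aa_idx = match(aa, AA1),
       sse_id = rep(seq_len(npool), n_i), types = types,
       loop_L = if (npool > 1) vapply(seq_len(npool - 1), function(k)
         pool[[k + 1]]$first_res - pool[[k]]$last_res - 1L,
         integer(1)) else integer(0))
}

engine_state <- function(eng) {
  list(placed = rep(FALSE, eng$npool),
       R = vector("list", eng$npool), t = vector("list", eng$npool),
       CA = matrix(0, eng$M, 3), CB = matrix(0, eng$M, 3),
       NF = matrix(0, eng$npool, 3), CL = matrix(0, eng$npool, 3),
       AX0 = matrix(0, eng$npool, 3), AX1 = matrix(0, eng$npool, 3))
}

state_place <- function(st, eng, i, R, t) {
  tb <- apply_transform(eng$cstack[[i]], R, t)
  n <- eng$n_i[i]
  rows <- eng$starts[i]:eng$ends[i]
  st$CA[rows, ] <- tb[seq_len(n), ]
  st$CB[rows, ] <- tb[n + seq_len(n), ]
  st$NF[i, ] <- tb[2L * n + 1L, ]
  st$CL[i, ] <- tb[2L * n + 2L, ]
  st$AX0[i, ] <- tb[2L * n + 3L, ]
  st$AX1[i, ] <- tb[2L * n + 4L, ]
  st$R[[i]] <- R
  st$t[[i]] <- t
  st$placed[i] <- TRUE
  st
}

state_center <- function(st, eng) {
  if (!any(st$placed)) return(c(0, 0, 0))
  mask <- rep(st$placed, eng$n_i)
  colMeans(st$CA[mask, , drop = FALSE])
}

state_body_center <- function(st, eng, i) {
  colMeans(st$CA[eng$starts[i]:eng$ends[i], , drop = FALSE])
}

state_completeness <- function(st, eng) sum(eng$n_i[st$placed]) / eng$M

# Restraints resolved against the pool layout once per run.
prep_restraints <- function(restraints, eng) {
  df <- restraints$table
  if (is.null(df) || nrow(df) == 0) return(NULL)
  list(pi = match(df$res_i, eng$resno), pj = match(df$res_j, eng$resno),
       is_ca = df$atom == "CA", lower = df$lower, upper = df$upper,
       conf = df$confidence)
}

state_restraint_score <- function(st, eng, pr, constants) {
  if (is.null(pr)) return(0)
  mask <- rep(st$placed, eng$n_i)
  ok <- !is.na(pr$pi) & !is.na(pr$pj) & mask[pmax(pr$pi, 1L)] &
    mask[pmax(pr$pj, 1L)]
  pen <- constants$restraint_neutral * sum(!ok)
  if (any(ok)) {
    A <- ifelse(pr$is_ca[ok], 1, 0)
    P1 <- st$CB[pr$pi[ok], , drop = FALSE]
    P2 <- st$CB[pr$pj[ok], , drop = FALSE]
    ca_sel <- pr$is_ca[ok]
    if (any(ca_sel)) {
      P1[ca_sel, ] <- st$CA[pr$pi[ok][ca_sel], , drop = FALSE]
      P2[ca_sel, ] <- st$CA[pr$pj[ok][ca_sel], , drop = FALSE]
    }
    d <- sqrt(rowSums((P1 - P2)^2))
    viol <- pmax(0, d - pr$upper[ok], pr$lower[ok] - d)
    pen <- pen + sum(pr$conf[ok] * pmin(viol^2, constants$restraint_cap))
  }
  pen
}

# All raw score terms from the flat engine state.
state_score <- function(st, eng, prep, constants, pr = NULL) {
  terms <- c(loop_closure = 0, radius_of_gyration = 0, burial = 0,
             pairing = 0, sse_packing = 0, clash_residue = 0,
             clash_sse = 0, restraints = 0)
  placed <- which(st$placed)
  if (length(placed) > 0) {
    mask <- rep(st$placed, eng$n_i)
    cb <- st$CB[mask, , drop = FALSE]
    ca <- st$CA[mask, , drop = FALSE]
    m <- nrow(ca)
    pt <- .pair_terms_cpp(cb, eng$sse_id[mask], constants$nc_lower,
                          constants$nc_upper, constants$clash_radius,
                          prep$pair_edges, prep$pair_energy)
    idx <- findInterval(pt$neighbor_counts, prep$bedges,
                        rightmost.closed = TRUE)
    ok <- idx >= 1 & idx <= prep$nbin
    terms["burial"] <- sum(prep$burial_mat[cbind(idx[ok],
                                                 eng$aa_idx[mask][ok])])
    terms["pairing"] <- pt$pairing
    terms["clash_residue"] <- pt$clash
    # radius of gyration (closed form)
    ctr <- colMeans(ca)
    rg <- sqrt(max(0, sum(ca * ca) / m - sum(ctr * ctr)))
    terms["radius_of_gyration"] <-
      (rg - (constants$rg_a * m^(1 / 3) + constants$rg_b))^2
    # loop closure over sequence-adjacent placed SSEs
    if (length(placed) > 1) {
      lp <- 0
      for (k in seq_len(length(placed) - 1)) {
        a <- placed[k]; b <- placed[k + 1]
        L <- eng$pool[[b]]$first_res - eng$pool[[a]]$last_res - 1L
        gap <- sqrt(sum((st$NF[b, ] - st$CL[a, ])^2))
        bound <- L * constants$loop_d_per_res + constants$loop_d_offset
        if (gap > bound) lp <- lp + (gap - bound)^2
      }
      terms["loop_closure"] <- lp
      # SSE packing and cylinder clash
      pack <- 0; scl <- 0
      rad <- ifelse(eng$types == "helix", constants$sse_radius_helix,
                    constants$sse_radius_strand)
      for (ii in seq_len(length(placed) - 1)) {
        for (jj in (ii + 1):length(placed)) {
          a <- placed[ii]; b <- placed[jj]
          d <- .segment_distance_cpp(st$AX0[a, ], st$AX1[a, ],
                                     st$AX0[b, ], st$AX1[b, ])
          ov <- rad[a] + rad[b] - d
          if (ov > 0) scl <- scl + ov
          if (d <= constants$packing_cutoff) {
            u <- st$AX1[a, ] - st$AX0[a, ]
            v <- st$AX1[b, ] - st$AX0[b, ]
            cosang <- abs(sum(u * v)) /
              sqrt(sum(u * u) * sum(v * v))
            ang <- rad2deg(acos(min(1, cosang)))
            pack <- pack + evaluate_packing(prep$packing, d, ang)
          }
        }
      }
      terms["sse_packing"] <- pack
      terms["clash_sse"] <- scl
    }
  }
  if (!is.null(pr))
    terms["restraints"] <- state_restraint_score(st, eng, pr, constants)
  terms
}

# One proposed move on the engine state; mirrors the documented move set.
propose_state <- function(st, eng, stage, moves) {
  placed_ids <- which(st$placed)
  np <- length(placed_ids)
  legal <- c(add_sse = np < eng$npool, remove_sse = np >= 1,
             translate_large = np >= 1, rotate_large = np >= 1,
             flip_sse = np >= 1, swap_sses = np >= 2,
             move_domain = np >= 1, translate_small = np >= 1,
             rotate_small = np >= 1)
  p <- moves$mix[, stage]
  p[!legal] <- 0
  if (sum(p) == 0) { p <- as.numeric(legal); names(p) <- names(legal) }
  kind <- sample(names(p), 1, prob = p)

  if (kind == "add_sse") {
    i <- resample(which(!st$placed), 1)
    tgt <- state_center(st, eng) + runif_ball(moves$translate_large)
    st <- state_place(st, eng, i, random_rotation(), tgt)
  } else if (kind == "remove_sse") {
    i <- resample(placed_ids, 1)
    st$placed[i] <- FALSE
  } else if (kind == "translate_large") {
    i <- resample(placed_ids, 1)
    st <- state_place(st, eng, i, st$R[[i]],
                      st$t[[i]] + runif_ball(moves$translate_large))
  } else if (kind == "rotate_large") {
    i <- resample(placed_ids, 1)
    R <- rotation_about_axis(rnorm(3), runif(1, 0, moves$rotate_large))
    ctr <- state_body_center(st, eng, i)
    st <- state_place(st, eng, i, R %*% st$R[[i]],
                      as.numeric(R %*% (st$t[[i]] - ctr)) + ctr)
  } else if (kind == "flip_sse") {
    i <- resample(placed_ids, 1)
    ax <- as.numeric(st$R[[i]] %*% diag(3)[, resample(1:2, 1)])
    R <- rotation_about_axis(ax, 180)
    ctr <- state_body_center(st, eng, i)
    st <- state_place(st, eng, i, R %*% st$R[[i]],
                      as.numeric(R %*% (st$t[[i]] - ctr)) + ctr)
  } else if (kind == "swap_sses") {
    ij <- resample(placed_ids, 2)
    Ra <- st$R[[ij[1]]]; ta <- st$t[[ij[1]]]
    st <- state_place(st, eng, ij[1], st$R[[ij[2]]], st$t[[ij[2]]])
    st <- state_place(st, eng, ij[2], Ra, ta)
  } else if (kind == "move_domain") {
    ord <- placed_ids  # pool (hence sequence) order
    start <- resample(seq_len(np), 1)
    len <- resample(seq_len(np - start + 1), 1)
    sel <- ord[start:(start + len - 1)]
    ctr <- colMeans(do.call(rbind, lapply(sel, function(i)
      state_body_center(st, eng, i))))
    R <- rotation_about_axis(rnorm(3), runif(1, 0, moves$rotate_large))
    tr <- runif_ball(moves$domain_translate)
    for (i in sel)
      st <- state_place(st, eng, i, R %*% st$R[[i]],
                        as.numeric(R %*% (st$t[[i]] - ctr)) + ctr + tr)
  } else if (kind == "translate_small") {
    i <- resample(placed_ids, 1)
    st <- state_place(st, eng, i, st$R[[i]],
                      st$t[[i]] + runif_ball(moves$translate_small))
  } else if (kind == "rotate_small") {
    i <- resample(placed_ids, 1)
    R <- rotation_about_axis(rnorm(3), runif(1, 0, moves$rotate_small))
    ctr <- state_body_center(st, eng, i)
    st <- state_place(st, eng, i, R %*% st$R[[i]],
                      as.numeric(R %*% (st$t[[i]] - ctr)) + ctr)
  }
  list(state = st, kind = kind)
}

# Metropolis stage loop on the engine state.
engine_trajectory <- function(st, eng, config, stages, prep, pr) {
  cs <- config$constants
  for (stage in stages) {
    ew <- effective_weights(config$weights, stage)
    temp <- config$temperatures[stage]
    cur <- sum(state_score(st, eng, prep, cs, pr) * ew)
    for (step in seq_len(config$steps_per_stage)) {
      prop <- propose_state(st, eng, stage, config$moves)
      new_total <- sum(state_score(prop$state, eng, prep, cs, pr) * ew)
      if (new_total - cur <= 0 ||
          runif(1) < exp(-(new_total - cur) / temp)) {
        st <- prop$state
        cur <- new_total
      }
    }
  }
  st
}

# Engine state -> public protein_model (bodies rebuilt from transforms).
state_to_model <- function(st, eng) {
  bodies <- list()
  for (i in which(st$placed))
    bodies[[as.character(i)]] <-
      set_transform(eng$canon[[i]], st$R[[i]], st$t[[i]])
  m <- structure(list(sequence = eng$sequence, bodies = bodies,
                      pool = eng$pool), class = "protein_model")
  m$completeness <- state_completeness(st, eng)
  m
}

model_to_state <- function(model, eng) {
  st <- engine_state(eng)
  for (nm in names(model$bodies)) {
    i <- as.integer(nm)
    b <- model$bodies[[nm]]
    st <- state_place(st, eng, i, b$rotation, b$translation)
  }
  st
}
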