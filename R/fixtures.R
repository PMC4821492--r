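# Seed-deterministic synthetic fixtures: toy structures of named
# topologies, decoy ensembles with controlled score-accuracy correlation,
# and restraint sets with a controlled error fraction.  These emulate the
# shapes of real data (SSE-only models, CASP-style restraint files) so
# every other module is testable without downloads.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Toy-structure specification
#'
#' @param topology one of \code{"helix_hairpin"},
#'   \code{"three_helix_bundle"}, \code{"beta_hairpin"},
#'   \code{"ferredoxin_like"} (two helices and four strands packed
#'   against a sheet).
#' @param lengths optional per-SSE residue counts (topology defaults
#'   used when NULL).
#' @param loops optional per-loop residue counts.
#' @param noise Gaussian coordinate noise amplitude (Angstrom, per
#'   coordinate).
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return object of class \code{toy_spec}.
#' @export
toy_spec <- function(topology = c("helix_hairpin", "three_helix_bundle",
                                  "beta_hairpin", "ferredoxin_like"),
                     lengths = NULL, loops = NULL, noise = 0, seed = 1L) {
  topology <- match.arg(topology)
  def <- switch(topology,
    helix_hairpin = list(types = c("helix", "helix"),
                         lengths = c(12L, 12L), loops = 4L),
    three_helix_bundle = list(types = rep("helix", 3),
                              lengths = rep(10L, 3), loops = c(3L, 3L)),
    beta_hairpin = list(types = c("strand", "strand"),
                        lengths = c(6L, 6L), loops = 2L),
    ferredoxin_like = list(
      types = c("strand", "helix", "strand", "strand", "helix",
                "strand"),
      lengths = c(5L, 10L, 5L, 5L, 10L, 5L), loops = rep(4L, 5)))
  if (!is.null(lengths)) def$lengths <- as.integer(lengths)
  if (!is.null(loops)) def$loops <- as.integer(loops)
  stopifnot(length(def$loops) == length(def$lengths) - 1)
  structure(list(topology = topology, types = def$types,
                 lengths = def$lengths, loops = def$loops,
                 noise = noise, seed = as.integer(seed)),
            class = "toy_spec")
}

# Repeating residue patterns give SSE-appropriate sequences without RNG.
toy_sequence <- function(spec) {
  pat <- list(helix = strsplit("AELKKLFEAL", "")[[1]],
              strand = strsplit("VTIVEV", "")[[1]],
              loop = strsplit("GSGS", "")[[1]])
  res <- character(0)
  for (k in seq_along(spec$lengths)) {
    p <- pat[[spec$types[k]]]
    res <- c(res, rep_len(p, spec$lengths[k]))
    if (k < length(spec$lengths))
      res <- c(res, rep_len(pat$loop, spec$loops[k]))
  }
  sequence_info(res, id = spec$topology)
}

# Per-topology rigid placements: position of the SSE axis center (x, y),
# whether the SSE points down (flipped 180 about x), and a spin about its
# own axis.
toy_layout <- function(topology) {
  switch(topology,
    helix_hairpin = data.frame(
      x = c(0, 9.8), y = c(0, 0), flip = c(FALSE, TRUE),
      spin = c(150, 210)),
    three_helix_bundle = data.frame(
      x = c(0, 8.6, 4.3), y = c(0, 0, 7.4),
      flip = c(FALSE, TRUE, FALSE), spin = c(0, 90, 0)),
    beta_hairpin = data.frame(
      x = c(0, 5.2), y = c(0, 0), flip = c(FALSE, TRUE),
      spin = c(0, 180)),
    ferredoxin_like = data.frame(
      x = c(5, 2.5, 0, 10, 12.5, 15),
      y = c(0, 10, 0, 0, 10, 0),
      flip = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
      spin = c(0, 0, 0, 0, 0, 0)))
}

#' Generate a toy reference structure
#'
#' Builds idealized SSEs and places them in the named topology with
#' physically plausible loop gaps (Euclidean gap at most 3 Angstrom per
#' loop residue).  Optional Gaussian noise perturbs every coordinate.
#' The SSE pool and the generating spec are attached as attributes.
#'
#' @param spec a [toy_spec()].
#' @return a [protein_structure()] (loop residues carry no coordinates)
#'   with attributes \code{pool} and \code{spec}.
#' @export
generate_toy_structure <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  sequence <- toy_sequence(spec)
  pool <- list()
  first <- 1L
  for (k in seq_along(spec$lengths)) {
    pool[[k]] <- sse_definition(first, first + spec$lengths[k] - 1L,
                                spec$types[k])
    first <- first + spec$lengths[k] +
      if (k < length(spec$lengths)) spec$loops[k] else 0L
  }
  lay <- toy_layout(spec$topology)
  bodies <- list()
  for (k in seq_along(pool)) {
    b <- build_idealized_sse(pool[[k]], sequence)
    R <- rotation_about_axis(c(0, 0, 1), lay$spin[k])
    if (lay$flip[k])
      R <- rotation_about_axis(c(1, 0, 0), 180) %*% R
    bodies[[as.character(k)]] <-
      set_transform(b, R, c(lay$x[k], lay$y[k], 0))
  }
  model <- empty_model(sequence, pool)
  model$bodies <- bodies
  model <- refresh_completeness(model, pool_residue_count(pool))
  s <- model_to_structure(model)
  if (spec$noise > 0) {
    s <- with_seed(spec$seed, {
      for (nm in c("N", "CA", "C", "O", "CB")) {
        ok <- !is.na(s[[nm]][, 1])
        s[[nm]][ok, ] <- s[[nm]][ok, ] +
          rnorm(3 * sum(ok), 0, spec$noise)
      }
      s
    })
  }
  s$id <- spec$topology
  attr(s, "pool") <- pool
  attr(s, "spec") <- spec
  s
}

#' Generate a decoy ensemble with controlled score-accuracy correlation
#'
#' Perturbed copies of the reference whose RMSD100 values follow the
#' requested accuracy range, with synthetic scores whose rank correlation
#' with RMSD100 is approximately \code{rho} (exactly 1 or 0 at the
#' extremes: at \code{rho = 1} the score rank equals the accuracy rank).
#'
#' @param reference a [protein_structure()].
#' @param n number of decoys.
#' @param accuracy length-2 range of target RMSD100 values (Angstrom).
#' @param rho target rank correlation between score and RMSD100.
#' @param seed RNG seed.
#' @return list of [model_record()] (coordinates and measured
#'   \code{rmsd100} metric attached; no full model objects).
#' @export
generate_decoy_set <- function(reference, n, accuracy = c(0.5, 8),
                               rho = 0, seed = 1L) {
  stopifnot(inherits(reference, "protein_structure"), n >= 1,
            rho >= -1, rho <= 1)
  idx <- structure_placed(reference)
  ref_ca <- reference$CA[idx, , drop = FALSE]
  rownames(ref_ca) <- idx
  m <- nrow(ref_ca)
  denom <- if (m >= 20) 1 + log(sqrt(m / 100)) else 1
  with_seed(seed, {
    targets <- runif(n, accuracy[1], accuracy[2])
    recs <- vector("list", n)
    r100 <- numeric(n)
    for (i in seq_len(n)) {
      sigma <- targets[i] * denom / sqrt(3)
      ca <- ref_ca + matrix(rnorm(3 * m, 0, sigma), m, 3)
      rownames(ca) <- rownames(ref_ca)
      r <- .kabsch_cpp(ca, ref_ca)$rmsd
      r100[i] <- if (m >= 20) rmsd100(r, m) else r
      recs[[i]] <- structure(list(
        id = sprintf("d%05d", i), model = NULL, scores = NULL,
        total = NA_real_, completeness = 1, ca = ca,
        resno = as.integer(rownames(ca)),
        metrics = list(rmsd = r, rmsd100 = r100[i])),
        class = "model_record")
    }
    z <- qnorm(rank(r100, ties.method = "first") / (n + 1))
    latent <- if (abs(rho) == 1) sign(rho) * z else
      rho * z + sqrt(1 - rho^2) * rnorm(n)
    for (i in seq_len(n)) recs[[i]]$total <- latent[i]
    recs
  })
}

#' Generate distance restraints from a reference with a controlled
#' error fraction
#'
#' Samples \code{count} restraints from the reference's true contacting
#' pairs and replaces a fraction of them with decoys drawn from clearly
#' non-contacting pairs (which the reference therefore violates).
#'
#' @param reference a [protein_structure()].
#' @param count number of restraints.
#' @param error_fraction fraction in [0, 1] replaced by incorrect
#'   restraints.
#' @param kind \code{"contact"} (Cbeta, upper 8), \code{"NOE"} (Cbeta,
#'   bounds 1.8-5.5) or \code{"XL"} (Calpha, upper 30).
#' @param seed RNG seed.
#' @param min_sep minimum sequence separation of restrained pairs.
#' @return a [restraint_set()].
#' @export
generate_restraints <- function(reference, count, error_fraction = 0,
                                kind = c("contact", "NOE", "XL"),
                                seed = 1L, min_sep = 6L) {
  kind <- match.arg(kind)
  stopifnot(inherits(reference, "protein_structure"),
            error_fraction >= 0, error_fraction <= 1)
  par <- switch(kind,
    contact = list(atom = "CB", lower = 0, upper = 8),
    NOE = list(atom = "CB", lower = 1.8, upper = 5.5),
    XL = list(atom = "CA", lower = 0, upper = 30))
  idx <- structure_placed(reference)
  M <- if (par$atom == "CB") reference$CB else reference$CA
  M <- M[idx, , drop = FALSE]
  D <- as.matrix(stats::dist(M))
  sep <- abs(outer(idx, idx, "-"))
  ut <- upper.tri(D)
  true_pairs <- which(ut & D <= par$upper & D >= par$lower &
                        sep >= min_sep, arr.ind = TRUE)
  bad_pairs <- which(ut & D > par$upper + 4 & sep >= min_sep,
                     arr.ind = TRUE)
  n_err <- round(error_fraction * count)
  n_true <- count - n_err
  if (nrow(true_pairs) < n_true)
    stop("reference has only ", nrow(true_pairs),
         " true contacting pairs (need ", n_true, ")")
  if (nrow(bad_pairs) < n_err)
    stop("reference has only ", nrow(bad_pairs),
         " non-contacting pairs (need ", n_err, ")")
  with_seed(seed, {
    pick_t <- true_pairs[resample(seq_len(nrow(true_pairs)), n_true), ,
                         drop = FALSE]
    pick_b <- bad_pairs[resample(seq_len(nrow(bad_pairs)), n_err), ,
                        drop = FALSE]
    pick <- rbind(pick_t, pick_b)
    restraint_set(data.frame(
      res_i = idx[pick[, 1]], res_j = idx[pick[, 2]],
      atom = par$atom, lower = par$lower, upper = par$upper,
      kind = kind, confidence = 1), reference$sequence)
  })
}

# ss2-style prediction synthesized from a pool (for fixtures and CLI
# worked examples).
make_ss_prediction <- function(sequence, pool, p = 0.9) {
  n <- sequence$n
  prob <- matrix(rep(c(1, 0, 0), each = n), n, 3,
                 dimnames = list(NULL, c("C", "H", "E")))
  for (d in pool) {
    col <- if (d$ss_type == "helix") 2L else 3L
    for (r in d$first_res:d$last_res) {
      prob[r, ] <- (1 - p) / 2
      prob[r, col] <- p
    }
  }
  structure(list(prob = prob, aa = sequence$residues,
                 method = "synthetic"), class = "ss_prediction")
}

write_ss_prediction <- function(pred, path) {
  state <- c("C", "H", "E")[max.col(pred$prob, ties.method = "first")]
  lines <- c("# PSIPRED VFORMAT (synthetic)", "")
  for (i in seq_len(nrow(pred$prob)))
    lines <- c(lines, sprintf("%4d %s %s  %6.3f %6.3f %6.3f", i,
                              pred$aa[i], state[i], pred$prob[i, "C"],
                              pred$prob[i, "H"], pred$prob[i, "E"]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete worked-example fixture directory
#'
#' Emits sequence (FASTA), synthetic secondary-structure prediction
#' (ss2), SSE pool (TSV), reference structure (PDB) and contact
#' restraint files at error fractions 0, 0.3 and 1.0 (CASP RR format)
#' for a toy topology.
#'
#' @param dir output directory (created if needed).
#' @param spec a [toy_spec()].
#' @param n_restraints restraints per file.
#' @return the directory path, invisibly.
#' @export
fixture_directory <- function(dir, spec = toy_spec("helix_hairpin"),
                              n_restraints = 10L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_toy_structure(spec)
  pool <- attr(ref, "pool")
  write_fasta(ref$sequence, file.path(dir, "sequence.fasta"))
  write_ss_prediction(make_ss_prediction(ref$sequence, pool),
                      file.path(dir, "prediction.ss2"))
  write_sse_pool(pool, file.path(dir, "pool.tsv"))
  write_pdb(ref, file.path(dir, "reference.pdb"))
  for (ef in c(0, 0.3, 1.0)) {
    rs <- generate_restraints(ref, n_restraints, ef, "contact",
                              seed = spec$seed)
    df <- rs$table
    lines <- c("PFRMAT RR", paste("TARGET", spec$topology),
               sprintf("%d %d %g %g %.2f", df$res_i, df$res_j,
                       df$lower, df$upper, df$confidence), "END")
    writeLines(lines, file.path(dir,
                                sprintf("contacts_err%02d.rr", ef * 10)))
  }
  invisible(dir)
}
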