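# Knowledge-based potentials via the inverse Boltzmann relation
# E = -rt * ln(p_obs / p_back).

inverse_boltzmann <- function(p_obs, p_back, rt = 1, ceiling = 5 * rt) {
  e <- rep(0, length(p_obs))
  both <- p_obs > 0 & p_back > 0
  e[both] <- -rt * log(p_obs[both] / p_back[both])
  e[p_obs == 0 & p_back > 0] <- ceiling
  e[p_obs > 0 & p_back == 0] <- -ceiling  # flagged by the caller
  e
}

#' Construct a binned potential table directly
#'
#' Low-level constructor used both by [derive_potential()] and for
#' synthetic tables with analytically specified bin probabilities.
#'
#' @param edges strictly increasing bin edges.
#' @param p_obs,p_back per-bin probabilities (each summing to 1).
#' @param rt energy scale (dimensionless score units).
#' @param ceiling energy assigned to bins with \code{p_obs = 0}.
#' @param feature label.
#' @return object of class \code{potential_table} with per-bin
#'   \code{energy} and a \code{flagged} logical marking bins observed but
#'   absent from the background.
#' @export
potential_table <- function(edges, p_obs, p_back, rt = 1,
                            ceiling = 5 * rt, feature = "feature") {
  stopifnot(all(diff(edges) > 0),
            length(p_obs) == length(edges) - 1,
            length(p_back) == length(edges) - 1)
  p_obs <- p_obs / sum(p_obs)
  p_back <- p_back / sum(p_back)
  structure(list(
    feature = feature, edges = edges, p_obs = p_obs, p_back = p_back,
    energy = inverse_boltzmann(p_obs, p_back, rt, ceiling),
    flagged = p_obs > 0 & p_back == 0, rt = rt), class = "potential_table")
}

#' Derive a knowledge-based potential from observed and background samples
#'
#' Histograms both sample sets on common bins, normalizes to
#' probabilities, and applies the inverse Boltzmann relation
#' \eqn{E = -rt \ln(P_{obs}/P_{back})}.  Bins never observed get a finite
#' ceiling energy (so downstream Metropolis sampling never sees
#' non-finite scores); bins observed but absent from the background are
#' flagged.
#'
#' @param observed,background non-empty numeric sample vectors.
#' @param edges strictly increasing bin edges covering both sample ranges.
#' @param rt energy scale.
#' @param ceiling ceiling energy for unobserved bins.
#' @param feature label.
#' @return a [potential_table()].
#' @export
derive_potential <- function(observed, background, edges, rt = 1,
                             ceiling = 5 * rt, feature = "feature") {
  if (length(observed) == 0 || length(background) == 0)
    stop("observed and background sample sets must be non-empty")
  if (min(observed, background) < edges[1] ||
      max(observed, background) > edges[length(edges)])
    stop("bin edges do not cover the sample range")
  h_obs <- hist(observed, breaks = edges, plot = FALSE)$counts
  h_back <- hist(background, breaks = edges, plot = FALSE)$counts
  potential_table(edges, h_obs / sum(h_obs), h_back / sum(h_back),
                  rt = rt, ceiling = ceiling, feature = feature)
}

#' Evaluate a potential table at given feature values
#'
#' Values outside the binned range contribute zero energy.
#'
#' @param pot a [potential_table()].
#' @param x numeric vector of feature values.
#' @return energies, same length as \code{x}.
#' @export
evaluate_potential <- function(pot, x) {
  idx <- findInterval(x, pot$edges, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx <= length(pot$energy)
  out <- numeric(length(x))
  out[ok] <- pot$energy[idx[ok]]
  out
}

#' @export
print.potential_table <- function(x, ...) {
  cat(sprintf("<potential_table> %s: %d bins on [%g, %g], rt = %g\n",
              x$feature, length(x$energy), x$edges[1],
              x$edges[length(x$edges)], x$rt))
  invisible(x)
}

#' Write / read a potential table as TSV
#'
#' Columns: \code{lower}, \code{upper}, \code{p_obs}, \code{p_back},
#' \code{energy}.
#'
#' @param pot a [potential_table()].
#' @param path file path.
#' @return \code{read_potential_table} returns a [potential_table()]
#'   (energies recomputed from the stored probabilities).
#' @export
write_potential_table <- function(pot, path) {
  nb <- length(pot$energy)
  df <- data.frame(lower = pot$edges[-(nb + 1)], upper = pot$edges[-1],
                   p_obs = pot$p_obs, p_back = pot$p_back,
                   energy = pot$energy)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_potential_table
#' @export
read_potential_table <- function(path, rt = 1, feature = basename(path)) {
  df <- read.table(path, sep = "\t", header = TRUE)
  potential_table(c(df$lower, df$upper[nrow(df)]), df$p_obs, df$p_back,
                  rt = rt, feature = feature)
}

# 2-D (distance x angle) packing potential for SSE pairs.
packing_potential <- function(dist_edges, angle_edges, energy,
                              feature = "sse_packing") {
  stopifnot(nrow(energy) == length(dist_edges) - 1,
            ncol(energy) == length(angle_edges) - 1)
  structure(list(feature = feature, dist_edges = dist_edges,
                 angle_edges = angle_edges, energy = energy),
            class = "packing_potential")
}

evaluate_packing <- function(pot, d, ang) {
  i <- findInterval(d, pot$dist_edges, rightmost.closed = TRUE)
  j <- findInterval(ang, pot$angle_edges, rightmost.closed = TRUE)
  if (i < 1 || i > nrow(pot$energy) || j < 1 || j > ncol(pot$energy))
    return(0)
  pot$energy[i, j]
}

.potential_cache <- new.env(parent = emptyenv())

#' Default scoring potentials
#'
#' Synthetic knowledge-based tables built from analytic priors via the
#' package's own inverse-Boltzmann machinery: a per-amino-acid burial
#' potential in which hydrophobic residues (Kyte-Doolittle scale) prefer
#' higher neighbor counts, a generic residue-pairing distance potential
#' with its minimum in the Cbeta contact band, and a distance x angle SSE
#' packing potential favoring side-chain-mediated packing distances and
#' moderate crossing angles.  These are synthetic stand-ins shaped like
#' the statistics-derived tables the method normally uses; they are not
#' derived from structures in the PDB.
#'
#' @param rt energy scale.
#' @return list with elements \code{burial} (named list of
#'   [potential_table()] per amino-acid code), \code{pairing}
#'   (a [potential_table()]) and \code{packing} (distance x angle table).
#' @export
default_potentials <- function(rt = 1) {
  key <- paste0("rt", rt)
  if (!is.null(.potential_cache[[key]])) return(.potential_cache[[key]])

  # Each table is built as background x enhancement so that the preferred
  # band of the feature is a negative-energy basin and everything else
  # stays near zero: favorable states score negative, as the inverse
  # Boltzmann normalization intends.

  # burial: neighbor-count bins 0..30
  edges <- 0:30
  ctr <- edges[-1] - 0.5
  back <- dnorm(ctr, 8, 5.5)
  back <- back / sum(back)
  burial <- lapply(AA1, function(aa) {
    pref <- 8 + 1.2 * KD_HYDROPATHY[[aa]]
    enh <- 1 + 1.5 * exp(-0.5 * ((ctr - pref) / 4)^2)
    potential_table(edges, back * enh, back, rt = rt,
                    feature = paste0("burial_", aa))
  })
  names(burial) <- AA1

  # generic residue pairing: Cbeta distance bins on the 0..8 A
  # interaction support (no information beyond it); background grows with
  # the spherical shell area, observed enhanced in the contact band and
  # depleted at steric range
  pe <- seq(0, 8, by = 0.5)
  pc <- pe[-1] - 0.25
  p_back <- pc^2 / sum(pc^2)
  enh <- 0.05 + 2.5 * exp(-0.5 * ((pc - 5.5) / 1.2)^2)
  pairing <- potential_table(pe, p_back * enh, p_back, rt = rt,
                             feature = "residue_pairing")

  # SSE packing: axis distance 0..12 A x acute crossing angle 0..90 deg,
  # enhanced at side-chain-mediated packing distance / moderate crossing
  de <- seq(0, 12, by = 1)
  ae <- seq(0, 90, by = 15)
  dc <- de[-1] - 0.5
  ac <- ae[-1] - 7.5
  pback2 <- matrix(dc^2, length(dc), length(ac))
  pback2 <- pback2 / sum(pback2)
  enh2 <- outer(exp(-0.5 * ((dc - 9.5) / 1.5)^2),
                exp(-0.5 * ((ac - 30) / 25)^2))
  pobs2 <- pback2 * (1 + 2 * enh2)
  pobs2 <- pobs2 / sum(pobs2)
  packing <- packing_potential(
    de, ae, matrix(inverse_boltzmann(as.vector(pobs2), as.vector(pback2),
                                     rt = rt),
                   length(dc), length(ac)))

  out <- list(burial = burial, pairing = pairing, packing = packing)
  .potential_cache[[key]] <- out
  out
}
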