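#' Protein sequence container
#'
#' @param residues character vector of one-letter amino-acid codes (the 20
#'   standard residues or \code{X}), or a single string.
#' @param id identifier.
#' @return object of class \code{sequence_info} with fields \code{id},
#'   \code{residues} and \code{n}.
#' @export
sequence_info <- function(residues, id = "seq") {
  if (length(residues) == 1 && nchar(residues) > 1)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(as.character(residues))
  if (length(residues) < 1) stop("sequence must contain at least 1 residue")
  bad <- setdiff(unique(residues), AA1)
  if (length(bad))
    stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  structure(list(id = id, residues = residues, n = length(residues)),
            class = "sequence_info")
}

#' @export
print.sequence_info <- function(x, ...) {
  cat("<sequence_info>", x$id, "-", x$n, "residues\n")
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' Secondary structure element definition
#'
#' A predicted SSE as a residue range on the sequence, before any 3-D
#' placement.
#'
#' @param first_res,last_res 1-based inclusive residue indices.
#' @param ss_type \code{"helix"} or \code{"strand"}.
#' @param confidence real in [0, 1].
#' @return object of class \code{sse_definition}.
#' @export
sse_definition <- function(first_res, last_res, ss_type,
                           confidence = 1.0) {
  ss_type <- match.arg(ss_type, c("helix", "strand"))
  stopifnot(first_res >= 1, last_res >= first_res,
            confidence >= 0, confidence <= 1)
  structure(list(first_res = as.integer(first_res),
                 last_res = as.integer(last_res),
                 ss_type = ss_type, confidence = confidence),
            class = "sse_definition")
}

#' @export
print.sse_definition <- function(x, ...) {
  cat(sprintf("<sse_definition> %s %d-%d (conf %.2f)\n",
              x$ss_type, x$first_res, x$last_res, x$confidence))
  invisible(x)
}

sse_length <- function(def) def$last_res - def$first_res + 1L

#' Build an idealized SSE body from canonical dihedral angles
#'
#' Constructs backbone (N, Calpha, C, O) plus a Cbeta "superatom" per
#' residue from the ideal dihedrals of the SSE type -- (-60, -40) degrees
#' for alpha-helices, (-135, 135) for beta-strands -- with standard bond
#' lengths and angles and omega fixed trans.  Glycine receives a virtual
#' Cbeta so every residue has a uniform side-chain interaction center.
#' The body is returned in a canonical frame (Calpha centroid at the
#' origin, principal axis along z) with an identity rigid transform.
#'
#' @param definition an [sse_definition()].
#' @param sequence a [sequence_info()] covering the definition's range.
#' @return object of class \code{sse_body}: the definition, per-atom
#'   coordinate matrices (length x 3) for N, CA, C, O, CB in the current
#'   frame, the canonical-frame copies, and the rigid transform
#'   (\code{rotation}, \code{translation}) taking canonical to current.
#' @export
build_idealized_sse <- function(definition, sequence) {
  stopifnot(inherits(definition, "sse_definition"),
            inherits(sequence, "sequence_info"))
  if (definition$last_res > sequence$n)
    stop("SSE range ", definition$first_res, "-", definition$last_res,
         " out of bounds for sequence of length ", sequence$n)
  len <- sse_length(definition)
  if (len < 2) stop("degenerate SSE of length ", len, " (minimum 2)")

  ideal <- IDEAL_DIHEDRALS[[definition$ss_type]]
  g <- BACKBONE_GEOM
  phi <- rep(ideal["phi"], len)
  psi <- rep(ideal["psi"], len)

  N <- CA <- C <- O <- CB <- matrix(NA_real_, len, 3)
  # Seed residue 1 in an arbitrary frame.
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- deg2rad(g$a_n_ca_c)
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(len - 1)) {
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                             g$b_c_n, g$a_ca_c_n, psi[i])
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ],
                              g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ],
                             g$b_ca_c, g$a_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(len)) {
    # Carbonyl O antiperiplanar to the next N (psi + 180).
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi[i] + 180)
    CB[i, ] <- place_cbeta(N[i, ], CA[i, ], C[i, ])
  }

  # Canonical frame: CA centroid at origin, principal axis of the CA set
  # along +z (oriented N-term -> C-term).
  ctr <- colMeans(CA)
  ax <- principal_axis(sweep(CA, 2, ctr))
  if (sum(ax * (CA[len, ] - CA[1, ])) < 0) ax <- -ax
  Rc <- rotation_to_z(ax)
  canon <- lapply(list(N = N, CA = CA, C = C, O = O, CB = CB),
                  function(M) sweep(M, 2, ctr) %*% t(Rc))

  res <- definition$first_res:definition$last_res
  body <- structure(list(
    definition = definition,
    residues = res,
    aa = sequence$residues[res],
    canonical = canon,
    rotation = diag(3),
    translation = c(0, 0, 0),
    coords = canon), class = "sse_body")
  body
}

# Virtual/real Cbeta from backbone, standard L-amino-acid geometry.
place_cbeta <- function(N, CA, C) {
  b <- CA - N
  c <- C - CA
  a <- cross3(b, c)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * c + CA
}

principal_axis <- function(Xc) {
  e <- eigen(crossprod(Xc), symmetric = TRUE)
  e$vectors[, 1]
}

# Rotation carrying unit vector ax onto +z.
rotation_to_z <- function(ax) {
  z <- c(0, 0, 1)
  v <- cross3(ax, z)
  s <- vnorm(v)
  if (s < 1e-12) {
    if (sum(ax * z) > 0) return(diag(3))
    return(rotation_about_axis(c(1, 0, 0), 180))
  }
  rotation_about_axis(v, rad2deg(atan2(s, sum(ax * z))))
}

#' Rigidly transform an SSE body
#'
#' @param body an \code{sse_body}.
#' @param rotation 3 x 3 orthonormal matrix (tolerance 1e-8).
#' @param translation length-3 vector, Angstrom.
#' @return the transformed body; internal geometry is unchanged.
#' @export
transform_sse <- function(body, rotation, translation = c(0, 0, 0)) {
  stopifnot(inherits(body, "sse_body"))
  if (!is_orthonormal(rotation))
    stop("rotation matrix is not orthonormal within 1e-8")
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  body$rotation <- rotation %*% body$rotation
  body$translation <- as.numeric(rotation %*% body$translation) + translation
  body$coords <- lapply(body$canonical, apply_transform,
                        R = body$rotation, t = body$translation)
  body
}

# Axis endpoints of the body in the current frame: canonical z-axis spans
# the CA extent.
sse_axis <- function(body) {
  zr <- range(body$canonical$CA[, 3])
  ends <- rbind(c(0, 0, zr[1]), c(0, 0, zr[2]))
  apply_transform(ends, body$rotation, body$translation)
}

#' Measure backbone dihedrals of an SSE body
#'
#' @param body an \code{sse_body}.
#' @return data frame with columns \code{resno}, \code{phi}, \code{psi}
#'   (degrees; NA at chain termini where undefined).
#' @export
measure_dihedrals <- function(body) {
  N <- body$coords$N; CA <- body$coords$CA; C <- body$coords$C
  len <- nrow(CA)
  phi <- psi <- rep(NA_real_, len)
  for (i in seq_len(len)) {
    if (i > 1)
      phi[i] <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < len)
      psi[i] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
  }
  data.frame(resno = body$residues, phi = phi, psi = psi)
}

#' Assemble a protein model from placed SSE bodies
#'
#' A model is a possibly incomplete set of rigidly placed SSEs over a
#' sequence; loop regions carry no coordinates.  Completeness is the
#' fraction of pool-SSE residues covered by the placed SSEs.
#'
#' @param sequence a [sequence_info()].
#' @param bodies list of \code{sse_body} with mutually disjoint residue
#'   ranges.
#' @param pool list of [sse_definition()] the model draws from; defaults to
#'   the placed bodies' own definitions.
#' @return object of class \code{protein_model}.
#' @export
protein_model <- function(sequence, bodies = list(), pool = NULL) {
  stopifnot(inherits(sequence, "sequence_info"))
  if (is.null(pool)) pool <- lapply(bodies, `[[`, "definition")
  res <- unlist(lapply(bodies, `[[`, "residues"))
  if (anyDuplicated(res))
    stop("placed SSEs share residue indices: ",
         paste(unique(res[duplicated(res)]), collapse = ", "))
  m <- structure(list(sequence = sequence, bodies = bodies, pool = pool),
                 class = "protein_model")
  m$completeness <- model_completeness(m, pool)
  m
}

#' Completeness of a model against an SSE pool
#'
#' @param model a [protein_model()].
#' @param pool non-empty list of [sse_definition()].
#' @return fraction in [0, 1] of residues covered by the pool's SSEs that
#'   are covered by the model's placed SSEs.
#' @export
model_completeness <- function(model, pool = model$pool) {
  if (length(pool) == 0) stop("SSE pool is empty")
  pool_res <- unique(unlist(lapply(pool, function(d) d$first_res:d$last_res)))
  placed_res <- unlist(lapply(model$bodies, `[[`, "residues"))
  length(intersect(placed_res, pool_res)) / length(pool_res)
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> %s: %d/%d SSEs placed, completeness %.2f\n",
              x$sequence$id, length(x$bodies), length(x$pool),
              x$completeness))
  for (b in x$bodies)
    cat(sprintf("  %s %d-%d\n", b$definition$ss_type,
                b$definition$first_res, b$definition$last_res))
  invisible(x)
}

# Matrix of placed CA coordinates with resno rownames, ordered by resno.
model_ca <- function(model) {
  if (length(model$bodies) == 0)
    return(matrix(numeric(0), 0, 3))
  ca <- do.call(rbind, lapply(model$bodies, function(b) b$coords$CA))
  resno <- unlist(lapply(model$bodies, `[[`, "residues"))
  o <- order(resno)
  ca <- ca[o, , drop = FALSE]
  rownames(ca) <- resno[o]
  ca
}
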