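# File formats: FASTA (via seqinr), PDB (via bio3d), restraint files,
# record tables.

#' Reduced-representation protein structure
#'
#' Per-residue backbone (N, CA, C, O) and Cbeta-superatom coordinates for
#' a single chain.  Residues without coordinates (e.g. loop regions of
#' SSE-only models) carry NA rows.
#'
#' @param sequence a [sequence_info()].
#' @param N,CA,C,O,CB n x 3 coordinate matrices (Angstrom); NA rows allowed.
#' @param cb_virtual logical vector flagging reconstructed Cbeta atoms.
#' @param id identifier.
#' @return object of class \code{protein_structure}.
#' @export
protein_structure <- function(sequence, N, CA, C, O, CB,
                              cb_virtual = rep(FALSE, sequence$n),
                              id = sequence$id) {
  n <- sequence$n
  for (M in list(N, CA, C, O, CB))
    stopifnot(is.matrix(M), nrow(M) == n, ncol(M) == 3)
  structure(list(id = id, sequence = sequence, N = N, CA = CA, C = C,
                 O = O, CB = CB, cb_virtual = cb_virtual),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  placed <- sum(!is.na(x$CA[, 1]))
  cat(sprintf("<protein_structure> %s: %d residues (%d with coordinates)\n",
              x$id, x$sequence$n, placed))
  invisible(x)
}

# Residue indices that actually carry coordinates.
structure_placed <- function(s) which(!is.na(s$CA[, 1]))

#' Read a sequence from a FASTA file
#'
#' @param path file path; the first record is used.
#' @return a [sequence_info()].
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE)
  if (length(recs) == 0) stop("no FASTA records in ", path)
  sequence_info(toupper(as.character(recs[[1]])),
                id = attr(recs[[1]], "name"))
}

#' Write a sequence to a FASTA file
#'
#' @param sequence a [sequence_info()].
#' @param path file path.
#' @export
write_fasta <- function(sequence, path) {
  seqinr::write.fasta(list(sequence$residues), names = sequence$id,
                      file.out = path)
  invisible(path)
}

#' Read a protein structure from a PDB file
#'
#' First model, one chain (the first unless \code{chain} is given),
#' altloc blank or 'A'.  Insertion codes are collapsed by sequential
#' renumbering (the original numbering is kept as an attribute);
#' non-monotone residue numbering triggers a warning and renumbering.
#' Missing Cbeta atoms (glycine) are reconstructed geometrically and
#' flagged.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier.
#' @return a [protein_structure()].
#' @export
read_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  ins <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$resno, ins, sep = "_")
  ukey <- unique(key)
  resmap <- setNames(seq_along(ukey), ukey)
  newres <- resmap[key]
  if (is.unsorted(at$resno[!duplicated(key)]))
    warning("non-monotone residue numbering in ", path, "; renumbered")
  n <- length(ukey)
  aa <- character(n)
  mats <- list(N = NULL, CA = NULL, C = NULL, O = NULL, CB = NULL)
  for (nm in names(mats)) mats[[nm]] <- matrix(NA_real_, n, 3)
  for (i in seq_len(nrow(at))) {
    r <- newres[i]
    nm <- at$elety[i]
    if (nm %in% names(mats) && is.na(mats[[nm]][r, 1]))
      mats[[nm]][r, ] <- c(at$x[i], at$y[i], at$z[i])
    if (aa[r] == "") aa[r] <- bio3d::aa321(at$resid[i])
  }
  aa[aa == "" | is.na(aa)] <- "X"
  cb_virtual <- rep(FALSE, n)
  for (r in seq_len(n)) {
    if (is.na(mats$CB[r, 1]) && !anyNA(c(mats$N[r, ], mats$CA[r, ],
                                         mats$C[r, ]))) {
      mats$CB[r, ] <- place_cbeta(mats$N[r, ], mats$CA[r, ], mats$C[r, ])
      cb_virtual[r] <- TRUE
    }
  }
  s <- protein_structure(sequence_info(aa, id = basename(path)),
                         mats$N, mats$CA, mats$C, mats$O, mats$CB,
                         cb_virtual = cb_virtual)
  attr(s, "residue_map") <- data.frame(original = ukey,
                                       renumbered = seq_len(n))
  s
}

#' Write a protein structure (or model) to a PDB file
#'
#' Residues without coordinates are skipped; virtual Cbeta atoms are
#' written like real ones (the reduced representation treats them
#' identically).
#'
#' @param x a [protein_structure()] or [protein_model()].
#' @param path output path.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "protein_model")) x <- model_to_structure(x)
  stopifnot(inherits(x, "protein_structure"))
  rows <- list()
  aa3 <- bio3d::aa123(x$sequence$residues)
  for (r in structure_placed(x)) {
    for (nm in c("N", "CA", "C", "O", "CB")) {
      xyz <- x[[nm]][r, ]
      if (anyNA(xyz)) next
      if (nm == "CB" && x$sequence$residues[r] == "G" &&
          !is.null(x$cb_virtual) && x$cb_virtual[r]) next
      rows[[length(rows) + 1L]] <- list(elety = nm, resno = r,
                                        resid = aa3[r], xyz = xyz)
    }
  }
  if (length(rows) == 0) stop("structure has no coordinates to write")
  xyz <- as.numeric(vapply(rows, `[[`, numeric(3), "xyz"))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = vapply(rows, `[[`, numeric(1), "resno"),
    resid = vapply(rows, `[[`, character(1), "resid"),
    elety = vapply(rows, `[[`, character(1), "elety"),
    chain = rep("A", length(rows)))
  invisible(path)
}

# SSE-only model -> structure with NA loops.
model_to_structure <- function(model) {
  n <- model$sequence$n
  mats <- lapply(1:5, function(i) matrix(NA_real_, n, 3))
  names(mats) <- c("N", "CA", "C", "O", "CB")
  for (b in model$bodies) {
    for (nm in names(mats))
      mats[[nm]][b$residues, ] <- b$coords[[nm]]
  }
  protein_structure(model$sequence, mats$N, mats$CA, mats$C, mats$O,
                    mats$CB, cb_virtual = model$sequence$residues == "G",
                    id = model$sequence$id)
}

#' Distance restraint set
#'
#' @param table data frame with columns \code{res_i}, \code{res_j}
#'   (1-based residue indices, distinct), \code{atom} ("CA" or "CB"),
#'   \code{lower}, \code{upper} (Angstrom, lower <= upper), \code{kind}
#'   ("contact", "NOE" or "XL") and \code{confidence} in [0, 1].
#' @param sequence optional [sequence_info()] for index validation.
#' @return object of class \code{restraint_set}.
#' @export
restraint_set <- function(table, sequence = NULL) {
  need <- c("res_i", "res_j", "atom", "lower", "upper", "kind",
            "confidence")
  if (nrow(table) == 0) {
    table <- data.frame(res_i = integer(0), res_j = integer(0),
                        atom = character(0), lower = numeric(0),
                        upper = numeric(0), kind = character(0),
                        confidence = numeric(0))
  }
  stopifnot(all(need %in% names(table)))
  if (any(table$res_i == table$res_j))
    stop("restraint endpoints must be distinct residues")
  if (any(table$lower > table$upper))
    stop("restraint lower bound exceeds upper bound")
  if (any(table$confidence < 0 | table$confidence > 1))
    stop("restraint confidence must lie in [0, 1]")
  if (!all(table$atom %in% c("CA", "CB")))
    stop("restraint anchor atom must be CA or CB")
  if (!is.null(sequence) &&
      any(c(table$res_i, table$res_j) > sequence$n |
          c(table$res_i, table$res_j) < 1))
    stop("restraint residue index outside the sequence")
  structure(list(table = table), class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("<restraint_set>", nrow(x$table), "restraints\n")
  if (nrow(x$table)) print(table(x$table$kind))
  invisible(x)
}

#' @export
length.restraint_set <- function(x) nrow(x$table)

#' Read residue-residue contacts in CASP RR exchange format
#'
#' Data lines are \code{i j d_lower d_upper confidence}; header lines
#' (PFRMAT, TARGET, MODEL, sequence blocks, END) are skipped.  Contacts
#' anchor on Cbeta.
#'
#' @param path file path.
#' @param sequence optional [sequence_info()] for validation.
#' @return a [restraint_set()] of kind \code{"contact"}.
#' @export
read_casp_rr <- function(path, sequence = NULL) {
  lines <- trimws(readLines(path))
  rows <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\\s+")[[1]]
    if (length(f) != 5) next
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) next
    if (v[5] < 0 || v[5] > 1)
      stop("confidence out of [0, 1] at line ", k, " of ", path)
    rows[[length(rows) + 1L]] <-
      data.frame(res_i = as.integer(v[1]), res_j = as.integer(v[2]),
                 atom = "CB", lower = v[3], upper = v[4],
                 kind = "contact", confidence = v[5])
  }
  restraint_set(if (length(rows)) do.call(rbind, rows)
                else data.frame(), sequence)
}

#' Read a tabular NOE or cross-link restraint file
#'
#' Tab-separated with a header: columns \code{res_i}, \code{res_j},
#' \code{atom}, \code{lower}, \code{upper} and optional
#' \code{confidence} (default 1).  For cross-links (\code{kind = "XL"}) a
#' column \code{linker} may replace \code{lower}/\code{upper}: the upper
#' bound becomes linker length + \code{xl_tolerance} on the Calpha
#' anchor, the lower bound 0.
#'
#' @param path file path.
#' @param kind \code{"NOE"} or \code{"XL"}.
#' @param sequence optional [sequence_info()] for validation.
#' @param constants a [score_constants()] (provides \code{xl_tolerance}).
#' @return a [restraint_set()].
#' @export
read_restraint_table <- function(path, kind = c("NOE", "XL"),
                                 sequence = NULL,
                                 constants = score_constants()) {
  kind <- match.arg(kind)
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (!"confidence" %in% names(df)) df$confidence <- 1
  if (kind == "XL" && "linker" %in% names(df)) {
    df$lower <- 0
    df$upper <- df$linker + constants$xl_tolerance
    if (!"atom" %in% names(df)) df$atom <- "CA"
  }
  if (!"atom" %in% names(df))
    df$atom <- if (kind == "XL") "CA" else "CB"
  df$kind <- kind
  restraint_set(df[c("res_i", "res_j", "atom", "lower", "upper", "kind",
                     "confidence")], sequence)
}

#' Write a restraint set as TSV
#'
#' @param restraints a [restraint_set()].
#' @param path output path.
#' @export
write_restraint_table <- function(restraints, path) {
  write.table(restraints$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
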