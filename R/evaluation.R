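# Accuracy metrics against a reference structure.

#' Optimal rigid superposition of two matched point sets
#'
#' Closed-form least-squares (Kabsch/SVD) superposition of \code{X} onto
#' \code{Y}.
#'
#' @param X,Y m x 3 matrices of matched coordinates, m >= 3.
#' @return list with \code{rotation} (3 x 3, applied on the right of
#'   row-coordinates), \code{translation} (length 3) and \code{rmsd}
#'   (Angstrom).
#' @export
superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 3 || nrow(X) != nrow(Y) || ncol(X) != 3 || ncol(Y) != 3)
    stop("superpose needs two equal-length m x 3 coordinate sets, m >= 3")
  .kabsch_cpp(X, Y)
}

#' Length-normalized RMSD (RMSD100)
#'
#' Normalizes a Calpha RMSD to the value expected for a 100-residue
#' protein: \code{RMSD / (1 + ln(sqrt(n / 100)))}.  (The frequently
#' printed short form RMSD / ln(n / 100) is degenerate at n = 100 and
#' negative below it; this is the standard form of the cited metric,
#' which equals the plain RMSD at n = 100.)
#'
#' @param rmsd Calpha RMSD in Angstrom.
#' @param n number of residues, at least 20 (the normalization is
#'   meaningless for shorter chains).
#' @return RMSD100 in Angstrom.
#' @export
rmsd100 <- function(rmsd, n) {
  if (any(n < 20)) stop("RMSD100 requires n >= 20")
  rmsd / (1 + log(sqrt(n / 100)))
}

#' Global distance test total score (GDT_TS)
#'
#' For each distance threshold t in {1, 2, 4, 8} Angstrom, P_t is the
#' largest percentage of matched Calpha atoms that can be superposed
#' within t of the reference; GDT_TS = (P_1 + P_2 + P_4 + P_8) / 4.
#' Matched sets of at most 12 residues are scored exactly by
#' enumerating every residue subset of size >= 3; larger sets use an
#' LGA-style search seeded from sliding sequence windows (lengths 3-8)
#' and iteratively extended over the residues currently within the
#' threshold.
#'
#' @param model a [protein_model()], [model_record()],
#'   [protein_structure()] or an m x 3 Calpha matrix with residue-number
#'   rownames.
#' @param reference a [protein_structure()] or Calpha matrix with
#'   residue-number rownames.
#' @param thresholds distance thresholds in Angstrom.
#' @return GDT_TS in percent, over the residues present in both inputs
#'   (>= 4 required).
#' @export
gdt_ts <- function(model, reference, thresholds = c(1, 2, 4, 8)) {
  mod_ca <- ca_with_resno(model)
  ref_ca <- ca_with_resno(reference)
  shared <- intersect(rownames(mod_ca), rownames(ref_ca))
  if (length(shared) < 4)
    stop("GDT_TS needs at least 4 matched residues")
  X <- mod_ca[shared, , drop = FALSE]
  Y <- ref_ca[shared, , drop = FALSE]
  counts <- .gdt_counts_cpp(X, Y, thresholds)
  mean(100 * counts / nrow(X))
}

ca_with_resno <- function(x) {
  if (inherits(x, "protein_structure")) {
    idx <- structure_placed(x)
    ca <- x$CA[idx, , drop = FALSE]
    rownames(ca) <- idx
    return(ca)
  }
  ca <- if (is.matrix(x)) x else record_ca(x)
  if (is.null(rownames(ca)))
    rownames(ca) <- seq_len(nrow(ca))
  ca
}

#' Contact order of a structure
#'
#' Absolute contact order: the mean sequence separation |i - j| over
#' residue pairs whose Cbeta atoms lie within \code{cutoff} and whose
#' separation is at least \code{min_sep}.
#'
#' @param structure a [protein_structure()] or [protein_model()].
#' @param cutoff Cbeta-Cbeta contact distance, Angstrom.
#' @param min_sep minimum sequence separation counted.
#' @return mean separation (0, with a warning, if there are no contacts).
#' @export
contact_order <- function(structure, cutoff = 8, min_sep = 3) {
  if (inherits(structure, "protein_model"))
    structure <- model_to_structure(structure)
  idx <- which(!is.na(structure$CB[, 1]))
  cb <- structure$CB[idx, , drop = FALSE]
  n <- length(idx)
  seps <- integer(0)
  if (n >= 2) {
    D <- as.matrix(stats::dist(cb))
    sep <- abs(outer(idx, idx, "-"))
    hit <- D < cutoff & sep >= min_sep & upper.tri(D)
    seps <- sep[hit]
  }
  if (length(seps) == 0) {
    warning("no contacts found; contact order is 0")
    return(0)
  }
  mean(seps)
}

#' Accuracy metrics of one model against a reference
#'
#' @param x a [model_record()] or [protein_model()].
#' @param reference a [protein_structure()].
#' @return the record (or a wrapped model) with \code{metrics} filled:
#'   \code{rmsd}, \code{rmsd100}, \code{gdt_ts}, \code{contact_order}.
#' @export
model_metrics <- function(x, reference) {
  rec <- if (inherits(x, "model_record")) x else
    model_record("model", x, structure(list(total = NA_real_),
                                       class = "score_result"))
  mod_ca <- ca_with_resno(rec)
  ref_ca <- ca_with_resno(reference)
  shared <- intersect(rownames(mod_ca), rownames(ref_ca))
  if (length(shared) < 3)
    stop("model and reference share fewer than 3 residues")
  fit <- .kabsch_cpp(mod_ca[shared, , drop = FALSE],
                     ref_ca[shared, , drop = FALSE])
  n <- length(shared)
  rec$metrics$rmsd <- fit$rmsd
  rec$metrics$rmsd100 <- if (n >= 20) rmsd100(fit$rmsd, n) else fit$rmsd
  rec$metrics$gdt_ts <- gdt_ts(rec, reference)
  rec$metrics$contact_order <-
    if (inherits(rec$model, "protein_model") &&
        length(rec$model$bodies)) {
      suppressWarnings(contact_order(rec$model))
    } else NA_real_
  rec
}

#' Ensemble accuracy summary
#'
#' Computes per-model accuracy metrics against the reference and the
#' ensemble summaries: the best GDT_TS, mu10 (the mean GDT_TS of the ten
#' most accurate models), and the enrichment.
#'
#' @param records list of at least 10 [model_record()].
#' @param reference a [protein_structure()].
#' @return object of class \code{ensemble_metrics}: fields
#'   \code{best_gdt_ts}, \code{mu10}, \code{enrichment}, \code{table}
#'   (per-model metrics) and \code{records} (with metrics attached).
#' @export
ensemble_metrics <- function(records, reference) {
  if (length(records) < 10)
    stop("ensemble metrics need at least 10 records")
  records <- lapply(records, model_metrics, reference = reference)
  gdt <- record_metric(records, "gdt_ts")
  top10 <- sort(gdt, decreasing = TRUE)[1:10]
  e <- tryCatch(compute_enrichment(records), error = function(e) NA_real_)
  structure(list(best_gdt_ts = max(gdt), mu10 = mean(top10),
                 enrichment = e, table = records_table(records),
                 records = records), class = "ensemble_metrics")
}

#' @export
print.ensemble_metrics <- function(x, ...) {
  cat(sprintf(paste0("<ensemble_metrics> %d models: best GDT_TS %.1f%%,",
                     " mu10 %.1f%%, enrichment %s\n"),
              nrow(x$table), x$best_gdt_ts, x$mu10,
              if (is.na(x$enrichment)) "NA" else
                sprintf("%.2f", x$enrichment)))
  invisible(x)
}
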