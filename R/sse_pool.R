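#' Read a three-state secondary-structure prediction (PSIPRED ss2 layout)
#'
#' Expects the PSIPRED VFORMAT column layout -- residue index, amino acid,
#' winning state, then the coil/helix/strand probabilities (pC pH pE) --
#' or an equivalent whitespace-separated table.  Comment lines starting
#' with \code{#} and blank lines are ignored.  Rows whose probabilities sum
#' to within [0.99, 1.01] are renormalized to 1; anything further off is
#' rejected.
#'
#' @param path file path.
#' @param sequence optional [sequence_info()]; if given, the row count must
#'   match the sequence length.
#' @param method label stored with the prediction.
#' @return object of class \code{ss_prediction}: matrix \code{prob} with
#'   columns \code{C}, \code{H}, \code{E} (one row per residue), residue
#'   letters \code{aa}, and \code{method}.
#' @export
read_ss_prediction <- function(path, sequence = NULL, method = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  n <- length(lines)
  if (n == 0) stop("no data rows in ", path)
  prob <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("C", "H", "E")))
  aa <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 6 || anyNA(suppressWarnings(as.numeric(f[4:6]))))
      stop("malformed ss2 row at line ", lineno[i], " of ", path)
    aa[i] <- toupper(f[2])
    p <- as.numeric(f[4:6])
    s <- sum(p)
    if (s < 0.99 || s > 1.01)
      stop("probabilities at line ", lineno[i], " sum to ",
           format(s), " (must be within [0.99, 1.01])")
    prob[i, ] <- p / s
  }
  if (!is.null(sequence) && n != sequence$n)
    stop("prediction has ", n, " rows but sequence has ", sequence$n,
         " residues")
  structure(list(prob = prob, aa = aa, method = method),
            class = "ss_prediction")
}

#' @export
print.ss_prediction <- function(x, ...) {
  cat("<ss_prediction>", x$method, "-", nrow(x$prob), "residues\n")
  invisible(x)
}

#' Consensus of several secondary-structure predictions
#'
#' Per-residue probability averaging over 1-3 prediction objects.
#'
#' @param preds list of \code{ss_prediction} of equal length.
#' @return an \code{ss_prediction} labelled \code{"consensus"}.
#' @export
consensus_prediction <- function(preds) {
  if (inherits(preds, "ss_prediction")) preds <- list(preds)
  stopifnot(length(preds) >= 1)
  nr <- vapply(preds, function(p) nrow(p$prob), integer(1))
  if (length(unique(nr)) != 1)
    stop("predictions disagree on residue count: ",
         paste(nr, collapse = ", "))
  prob <- Reduce(`+`, lapply(preds, `[[`, "prob")) / length(preds)
  prob <- prob / rowSums(prob)
  structure(list(prob = prob, aa = preds[[1]]$aa, method = "consensus"),
            class = "ss_prediction")
}

#' Build the candidate SSE pool from a secondary-structure prediction
#'
#' Maximal runs of residues whose winning state has probability at or above
#' \code{threshold} and is not coil become candidate SSEs; runs are split
#' at state changes and discarded if shorter than the per-type minimum
#' length.  Confidence of each SSE is the mean winning probability over its
#' run.
#'
#' @param pred an \code{ss_prediction} (use [consensus_prediction()] to
#'   merge several).
#' @param min_helix,min_strand minimum SSE lengths (residues).
#' @param threshold winning-probability threshold in (0, 1).
#' @return list of [sse_definition()], non-overlapping, sorted by
#'   \code{first_res}.
#' @export
build_sse_pool <- function(pred, min_helix = 5L, min_strand = 3L,
                           threshold = 0.5) {
  stopifnot(inherits(pred, "ss_prediction"),
            threshold > 0, threshold < 1)
  prob <- pred$prob
  win <- max.col(prob, ties.method = "first")  # 1=C, 2=H, 3=E
  pwin <- prob[cbind(seq_len(nrow(prob)), win)]
  state <- ifelse(pwin < threshold, 1L, win)   # below threshold -> coil
  pool <- list()
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    st <- r$values[k]
    if (st == 1L) next
    type <- if (st == 2L) "helix" else "strand"
    min_len <- if (st == 2L) min_helix else min_strand
    if (r$lengths[k] < min_len) next
    idx <- starts[k]:ends[k]
    pool[[length(pool) + 1L]] <-
      sse_definition(starts[k], ends[k], type, mean(pwin[idx]))
  }
  pool
}

#' Write / read an SSE pool as TSV
#'
#' Columns: \code{first_res}, \code{last_res}, \code{type},
#' \code{confidence}, tab-separated with a header row.
#'
#' @param pool list of [sse_definition()].
#' @param path file path.
#' @return \code{read_sse_pool} returns a list of [sse_definition()].
#' @export
write_sse_pool <- function(pool, path) {
  df <- data.frame(
    first_res = vapply(pool, `[[`, integer(1), "first_res"),
    last_res = vapply(pool, `[[`, integer(1), "last_res"),
    type = vapply(pool, `[[`, character(1), "ss_type"),
    confidence = vapply(pool, `[[`, numeric(1), "confidence"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sse_pool
#' @export
read_sse_pool <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    sse_definition(df$first_res[i], df$last_res[i], df$type[i],
                   df$confidence[i]))
}
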