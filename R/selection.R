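# Inter-stage model selection: completeness filter, score-stratified
# k-medoids clustering on the RMSD100 model distance, enrichment.

records_field <- function(records, field, default = NA_real_) {
  vapply(records, function(r) {
    v <- r[[field]]
    if (is.null(v)) default else as.numeric(v)
  }, numeric(1))
}

record_metric <- function(records, name) {
  vapply(records, function(r) {
    v <- r$metrics[[name]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
}

record_ids <- function(records) {
  vapply(records, function(r) as.character(r$id), character(1))
}

#' Summary table of an ensemble of model records
#'
#' @param records list of [model_record()].
#' @return data frame with one row per record: id, total score,
#'   completeness and any accuracy metrics attached.
#' @export
records_table <- function(records) {
  data.frame(id = record_ids(records),
             total = records_field(records, "total"),
             completeness = records_field(records, "completeness"),
             rmsd = record_metric(records, "rmsd"),
             rmsd100 = record_metric(records, "rmsd100"),
             gdt_ts = record_metric(records, "gdt_ts"),
             stringsAsFactors = FALSE)
}

#' Filter out the lowest-completeness models
#'
#' Removes the fraction of the models with the lowest completeness (ties
#' broken so that models with the better total score are retained first).
#' The production pipeline uses fractions between 0.25 and 0.5 depending
#' on the maximum completeness reached; see [choose_filter_fraction()].
#'
#' @param records list of [model_record()].
#' @param fraction fraction in [0, 0.5] to remove.
#' @return the retained records, original order preserved.
#' @export
filter_by_completeness <- function(records, fraction = 0.25) {
  stopifnot(fraction >= 0, fraction <= 0.5)
  n <- length(records)
  k <- floor(fraction * n)
  if (k == 0) return(records)
  comp <- records_field(records, "completeness")
  total <- records_field(records, "total")
  # removal order: lowest completeness first; among ties, worst (highest)
  # score removed first
  drop_idx <- order(comp, -total)[seq_len(k)]
  records[-drop_idx]
}

#' Completeness-filter fraction rule
#'
#' The filter removes half the models when sampling essentially reached
#' full completeness (max >= 0.95) and a quarter otherwise.
#'
#' @param records list of [model_record()].
#' @return 0.25 or 0.5.
#' @export
choose_filter_fraction <- function(records) {
  if (max(records_field(records, "completeness")) >= 0.95) 0.5 else 0.25
}

#' Split an ensemble into score strata
#'
#' The \emph{low} set contains the 20% of the models with the most
#' favorable (lowest) total score; the \emph{high} set the remainder.
#' Ties are broken deterministically by model id.
#'
#' @param records list of [model_record()].
#' @return list with elements \code{low} and \code{high}.
#' @export
split_by_score <- function(records) {
  n <- length(records)
  k <- floor(0.2 * n)
  o <- order(records_field(records, "total"), record_ids(records))
  list(low = records[o[seq_len(k)]],
       high = records[o[setdiff(seq_len(n), seq_len(k))]])
}

#' RMSD100 distance between two models
#'
#' Calpha RMSD after optimal superposition over the residues placed in
#' both models, normalized by the RMSD100 rule when at least 20 residues
#' are shared (plain RMSD below that, where the normalization is
#' meaningless).
#'
#' @param a,b [model_record()] or [protein_model()] objects.
#' @return distance in Angstrom (symmetric, 0 for identical shared
#'   coordinates).
#' @export
pairwise_model_distance <- function(a, b) {
  ca_a <- record_ca(a); ca_b <- record_ca(b)
  shared <- intersect(rownames(ca_a), rownames(ca_b))
  if (length(shared) < 3)
    stop("models share fewer than 3 placed residues")
  X <- ca_a[shared, , drop = FALSE]
  Y <- ca_b[shared, , drop = FALSE]
  r <- .kabsch_cpp(X, Y)$rmsd
  n <- length(shared)
  if (n >= 20) rmsd100(r, n) else r
}

record_ca <- function(x) {
  if (inherits(x, "protein_model")) return(model_ca(x))
  stopifnot(!is.null(x$ca))
  x$ca
}

#' Pairwise model-distance matrix
#'
#' @param records list of [model_record()].
#' @return symmetric matrix of RMSD100 distances.
#' @export
model_distance_matrix <- function(records) {
  n <- length(records)
  ca <- lapply(records, record_ca)
  D <- matrix(0, n, n, dimnames = list(record_ids(records),
                                       record_ids(records)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(rownames(ca[[i]]), rownames(ca[[j]]))
      d <- if (length(shared) < 3) NA_real_ else {
        r <- .kabsch_cpp(ca[[i]][shared, , drop = FALSE],
                         ca[[j]][shared, , drop = FALSE])$rmsd
        if (length(shared) >= 20) rmsd100(r, length(shared)) else r
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (anyNA(D)) {
    # models with no shared residues: assign the largest observed
    # distance so clustering keeps them apart
    D[is.na(D)] <- max(D, na.rm = TRUE) * 2
  }
  D
}

#' Score-stratified k-medoids clustering of a model ensemble
#'
#' Splits the records by score ([split_by_score()]) and clusters each
#' stratum independently by k-medoids (PAM) on the pairwise RMSD100
#' distance matrix.  The number of clusters is scanned over
#' \code{k_range}; the chosen k maximizes mean inter-medoid separation
#' minus mean cluster radius, subject to all radii being at most
#' \code{max_radius} when any k achieves that (otherwise the best-effort
#' solution is returned with \code{feasible = FALSE}).  Clusters holding
#' fewer than \code{min_pop} of all models are dropped.
#'
#' @param records list of [model_record()].
#' @param max_radius maximum allowed cluster radius (Angstrom; radius =
#'   largest member-to-medoid distance).
#' @param min_pop minimum cluster population as a fraction of all models
#'   passed in.
#' @param k_range integer vector of candidate cluster counts.
#' @param split cluster the score strata separately (the pipeline
#'   default) or the whole set at once.
#' @return if \code{split}, a list with \code{cluster_solution} elements
#'   \code{low} and \code{high}; otherwise a single
#'   \code{cluster_solution} (fields: k, assignment, medoid record ids,
#'   radii, population fractions, stratum label, feasibility flag).
#' @export
cluster_models <- function(records, max_radius = 5, min_pop = 0.005,
                           k_range = 1:8, split = TRUE) {
  n_total <- length(records)
  if (split) {
    st <- split_by_score(records)
    return(list(
      low = cluster_stratum(st$low, max_radius, min_pop, k_range,
                            n_total, "low"),
      high = cluster_stratum(st$high, max_radius, min_pop, k_range,
                             n_total, "high")))
  }
  cluster_stratum(records, max_radius, min_pop, k_range, n_total, "all")
}

cluster_stratum <- function(records, max_radius, min_pop, k_range,
                            n_total, stratum) {
  n <- length(records)
  if (n < 2) stop("need at least 2 records per stratum to cluster")
  D <- model_distance_matrix(records)
  ids <- record_ids(records)
  k_range <- k_range[k_range >= 1 & k_range < n]
  best <- NULL
  for (k in k_range) {
    sol <- if (k == 1) {
      med <- which.min(rowSums(D))
      list(assignment = rep(1L, n), medoid_idx = med)
    } else {
      pam <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
      list(assignment = as.integer(pam$clustering),
           medoid_idx = as.integer(pam$id.med))
    }
    radii <- vapply(seq_along(sol$medoid_idx), function(c) {
      members <- which(sol$assignment == c)
      max(D[members, sol$medoid_idx[c]])
    }, numeric(1))
    sep <- if (length(sol$medoid_idx) > 1) {
      mm <- D[sol$medoid_idx, sol$medoid_idx]
      mean(mm[upper.tri(mm)])
    } else 0
    cand <- list(k = k, assignment = sol$assignment,
                 medoid_idx = sol$medoid_idx, radii = radii,
                 objective = sep - mean(radii),
                 feasible = all(radii <= max_radius))
    # ties (within numerical noise) resolve to the smaller k
    if (is.null(best) ||
        (cand$feasible && !best$feasible) ||
        (cand$feasible == best$feasible &&
         cand$objective > best$objective + 1e-9))
      best <- cand
  }
  pop <- as.numeric(table(factor(best$assignment,
                                 levels = seq_len(best$k)))) / n_total
  keep <- pop >= min_pop
  structure(list(
    k = best$k, assignment = best$assignment,
    medoids = ids[best$medoid_idx][keep],
    medoid_records = records[best$medoid_idx][keep],
    radii = best$radii[keep], populations = pop[keep],
    dropped = sum(!keep), stratum = stratum,
    feasible = best$feasible, ids = ids), class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf(
    "<cluster_solution> stratum %s: k = %d (%d retained), %s\n",
    x$stratum, x$k, length(x$medoids),
    if (x$feasible) "feasible" else "radius bound not met"))
  if (length(x$medoids))
    print(data.frame(medoid = x$medoids, radius = round(x$radii, 2),
                     population = round(x$populations, 4)))
  invisible(x)
}

#' Enrichment of accurate models among the best-scoring models
#'
#' The sampled set S is split into P (the 10% most accurate models,
#' lowest RMSD100 by default) and N, and independently into PS (the 10%
#' best-scoring) and NS.  With TP = P intersect PS, the enrichment is
#' e = |TP| / |P| * 10, ranging from 0 to 10 with 1 indicating random
#' selection.  Ties are broken deterministically by model id; the 10%
#' cutoff is floor(|S| / 10).
#'
#' @param records list of [model_record()]; every record needs a total
#'   score and the accuracy metric.
#' @param metric accuracy metric name: \code{"rmsd100"} (lower = more
#'   accurate) or \code{"gdt_ts"} (higher = more accurate).
#' @return enrichment in [0, 10].
#' @export
compute_enrichment <- function(records, metric = c("rmsd100", "gdt_ts")) {
  metric <- match.arg(metric)
  n <- length(records)
  if (n < 10) stop("enrichment needs at least 10 records")
  acc <- record_metric(records, metric)
  total <- records_field(records, "total")
  if (anyNA(acc) || anyNA(total))
    stop("every record needs a total score and a '", metric, "' metric")
  ids <- record_ids(records)
  k <- floor(n / 10)
  acc_key <- if (metric == "gdt_ts") -acc else acc
  P <- order(acc_key, ids)[seq_len(k)]
  PS <- order(total, ids)[seq_len(k)]
  length(intersect(P, PS)) / k * 10
}
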