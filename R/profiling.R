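#' Within-cluster and stratum prevalence profiles
#'
#' For each cluster, the within-cluster prevalence of every condition
#' (the mean of the condition flag among patients assigned to that
#' cluster) alongside the overall stratum prevalence (the column mean
#' over all patients). Empty clusters are dropped with a warning.
#'
#' @param assignments Integer vector of modal cluster assignments,
#'   aligned with the rows of `data`.
#' @param data Binary `N x J` condition matrix (column names, when
#'   present, become the condition registry).
#' @return An object of class `cluster_profile`: `within` (`K x J`
#'   matrix), `overall` (length-`J` vector), `sizes`, `clusters`
#'   (cluster ids as row labels of `within`), `N`.
#' @export
prevalence_profile <- function(assignments, data) {
  data <- check_binary_matrix(data)
  if (length(assignments) != nrow(data))
    stop("assignments and data rows differ in length")
  ids <- sort(unique(assignments))
  expected <- seq_len(max(assignments))
  if (length(setdiff(expected, ids)))
    warning("empty cluster(s) dropped: ",
            paste(setdiff(expected, ids), collapse = ", "))
  within <- t(vapply(ids, function(k)
    colMeans(data[assignments == k, , drop = FALSE]),
    numeric(ncol(data))))
  rownames(within) <- ids
  structure(list(within = within, overall = colMeans(data),
                 sizes = as.integer(table(factor(assignments,
                                                 levels = ids))),
                 clusters = ids, N = nrow(data)),
            class = "cluster_profile")
}

#' Most distinctive (key and lead) conditions per cluster
#'
#' Ranks conditions within each cluster by distinctiveness - the
#' difference between within-cluster prevalence and stratum prevalence
#' - keeping only conditions that are more prevalent in the cluster
#' than in the stratum. The first `m` form the cluster's key
#' conditions and the first one its lead condition. Ties in
#' distinctiveness are broken by higher within-cluster prevalence,
#' then by registry order. A cluster with no positively distinctive
#' condition yields zero rows (flagged with a warning).
#'
#' @param profile A [prevalence_profile] result.
#' @param m Number of key conditions to keep (default 3).
#' @return Data frame with columns `cluster`, `rank`, `condition`,
#'   `within`, `overall`, `distinctiveness`.
#' @export
key_conditions <- function(profile, m = 3L) {
  stopifnot(inherits(profile, "cluster_profile"))
  J <- length(profile$overall)
  cond_names <- colnames(profile$within) %||% condition_cols(J)
  rows <- lapply(seq_along(profile$clusters), function(i) {
    d <- profile$within[i, ] - profile$overall
    ord <- order(-d, -profile$within[i, ], seq_len(J))
    ord <- ord[d[ord] > 0]
    if (!length(ord)) {
      warning("cluster ", profile$clusters[i],
              " has no condition above stratum prevalence")
      return(NULL)
    }
    ord <- ord[seq_len(min(m, length(ord)))]
    data.frame(cluster = profile$clusters[i],
               rank = seq_along(ord),
               condition = cond_names[ord],
               within = unname(profile$within[i, ord]),
               overall = unname(profile$overall[ord]),
               distinctiveness = unname(d[ord]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster = integer(0), rank = integer(0),
                      condition = character(0), within = numeric(0),
                      overall = numeric(0),
                      distinctiveness = numeric(0))
  rownames(out) <- NULL
  out
}

#' Compact text labels for clusters
#'
#' Formats each cluster's key conditions as
#' `"lead (NN%): key2 (NN%), key3 (NN%)"` with percentages rounded to
#' integers for display.
#'
#' @param profile A [prevalence_profile] result.
#' @param m Number of key conditions (default 3).
#' @return Named character vector, one label per cluster.
#' @export
cluster_labels <- function(profile, m = 3L) {
  kc <- key_conditions(profile, m)
  vapply(profile$clusters, function(k) {
    r <- kc[kc$cluster == k, , drop = FALSE]
    if (!nrow(r)) return("(no distinctive condition)")
    parts <- sprintf("%s (%.0f%%)", r$condition, 100 * r$within)
    if (length(parts) == 1) parts
    else paste0(parts[1], ": ", paste(parts[-1], collapse = ", "))
  }, "", USE.NAMES = FALSE) -> labs
  names(labs) <- profile$clusters
  labs
}

#' Per-cluster mortality and service-use summary
#'
#' One row per cluster with 2- and 5-year mortality percentages and
#' the mean, median and quartiles of GP consultations,
#' hospitalisations and regular medications. Both mean and median are
#' reported because the count distributions are right-skewed. Rows are
#' ordered by 5-year mortality, highest first. When a non-multimorbid
#' comparison cohort is supplied it is appended as a reference row
#' (excluded from the ordering contract of the clusters themselves).
#'
#' @param assignments Integer cluster assignments aligned with
#'   `cohort` rows.
#' @param cohort Cohort data frame with outcome columns.
#' @param nonmultimorbid Optional cohort data frame of patients with
#'   fewer than two conditions, summarised as a comparison row.
#' @return Data frame, one row per cluster (plus optional
#'   `non-multimorbid` row), with `n`, `pct`, mortality and outcome
#'   summaries.
#' @export
cluster_outcome_summary <- function(assignments, cohort,
                                    nonmultimorbid = NULL) {
  if (length(assignments) != nrow(cohort))
    stop("assignments and cohort rows differ in length")
  one <- function(d, label, total) {
    row <- data.frame(cluster = label, n = nrow(d),
                      pct = 100 * nrow(d) / total,
                      died_2yr_pct = 100 * mean(d$died_2yr),
                      died_5yr_pct = 100 * mean(d$died_5yr))
    for (oc in c("gp_consults", "hospitalisations", "regular_meds")) {
      q <- fmt_q(d[[oc]])
      row[[paste0(oc, "_mean")]] <- mean(d[[oc]])
      row[[paste0(oc, "_median")]] <- q$median
      row[[paste0(oc, "_q1")]] <- q$q1
      row[[paste0(oc, "_q3")]] <- q$q3
    }
    row
  }
  ids <- sort(unique(assignments))
  rows <- lapply(ids, function(k)
    one(cohort[assignments == k, , drop = FALSE], as.character(k),
        nrow(cohort)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$died_5yr_pct), , drop = FALSE]
  if (!is.null(nonmultimorbid) && nrow(nonmultimorbid))
    out <- rbind(out, one(nonmultimorbid, "non-multimorbid",
                          nrow(nonmultimorbid)))
  rownames(out) <- NULL
  out
}
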