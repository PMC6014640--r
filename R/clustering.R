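#' Clustering configuration
#'
#' The classification step always uses k = 3 clusters (maternal RS, fetal
#' RS, other waves/noise), squared-Euclidean dissimilarity, and the best of
#' `replicates` restarts of ++-seeded k-medoids.
#'
#' @param replicates number of ++-seeded restarts; the restart with minimal
#'   total cost wins.
#' @param seed integer seed; one seeded generator drives all replicates in
#'   sequence, so the result is a deterministic function of `seed`.
#' @param max_iter cap on assignment/update iterations per restart.
#' @return An object of class `cluster_config` (k is fixed at 3).
#' @export
cluster_config <- function(replicates = 20, seed = 1L, max_iter = 100) {
  replicates <- as.integer(replicates)
  if (replicates < 1L) stopf("'replicates' must be >= 1")
  structure(list(k = 3L, replicates = replicates, seed = as.integer(seed),
                 max_iter = as.integer(max_iter)),
            class = "cluster_config")
}

# ++ seeding: first medoid uniform; each next medoid sampled with
# probability proportional to the squared distance to the nearest chosen
# medoid.  Returns indices into `values`.
seed_pp <- function(values, k) {
  n <- length(values)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- (values - values[idx[1L]])^2
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      # all remaining points coincide with chosen medoids: pick any new value
      cand <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- cand[sample.int(length(cand), 1L)]
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, (values - values[idx[j]])^2)
  }
  idx
}

# One Voronoi-style k-medoids run from given medoid indices.  In 1-D with
# squared-Euclidean cost the in-cluster medoid update reduces to the member
# value closest to the cluster mean.  Returns NULL if a cluster empties.
kmedoids_run <- function(values, med_idx, k, max_iter) {
  medoids <- values[med_idx]
  labels <- integer(length(values))
  for (it in seq_len(max_iter)) {
    dmat <- vapply(medoids, function(m) (values - m)^2,
                   numeric(length(values)))
    new_labels <- max.col(-dmat, ties.method = "first")
    if (identical(new_labels, labels)) break
    labels <- new_labels
    if (length(unique(labels)) < k) return(NULL)
    for (j in seq_len(k)) {
      member <- values[labels == j]
      mu <- mean(member)
      medoids[j] <- member[which.min(abs(member - mu))]
    }
  }
  dmat <- vapply(medoids, function(m) (values - m)^2, numeric(length(values)))
  labels <- max.col(-dmat, ties.method = "first")
  if (length(unique(labels)) < k) return(NULL)
  cost <- sum(dmat[cbind(seq_along(values), labels)])
  list(labels = labels, medoids = medoids, cost = cost)
}

#' k-medoids clustering with ++ initialisation
#'
#' Partitions a 1-D feature series into 3 clusters by the best of
#' `replicates` restarts of ++-seeded k-medoids under squared-Euclidean
#' dissimilarity (Voronoi-style alternating assignment and in-cluster
#' medoid update until the labelling stabilises).
#'
#' @param values numeric feature series with at least 3 distinct values.
#' @param config a [cluster_config].
#' @return An object of class `kmedoids_result`: `labels` (1..3 per point),
#'   `medoids` (3 medoid values), `medians` (per-cluster medians),
#'   `total_cost` (sum of squared distances to assigned medoids), `roles`
#'   (`NA` until [assign_roles()] is applied), `sizes`.
#' @export
#' @examples
#' km <- kmedoids_pp(c(0, 0, 0, 5, 5, 5, 10, 10, 10), cluster_config(seed = 1))
#' sort(km$medoids)
kmedoids_pp <- function(values, config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  values <- as.numeric(values)
  if (length(unique(values)) < config$k)
    stopf("degenerate clustering input: fewer than %d distinct values",
          config$k)
  best <- NULL
  with_seed(config$seed, {
    for (r in seq_len(config$replicates)) {
      med_idx <- seed_pp(values, config$k)
      run <- kmedoids_run(values, med_idx, config$k, config$max_iter)
      if (!is.null(run) && (is.null(best) || run$cost < best$cost))
        best <- run
    }
  })
  if (is.null(best)) stopf("collapsed cluster in every replicate")
  medians <- vapply(seq_len(config$k),
                    function(j) stats::median(values[best$labels == j]),
                    numeric(1))
  sizes <- tabulate(best$labels, nbins = config$k)
  structure(list(labels = best$labels, medoids = best$medoids,
                 medians = medians, total_cost = best$cost,
                 roles = rep(NA_character_, config$k), sizes = sizes,
                 values = values, config = config),
            class = "kmedoids_result")
}

#' Assign physiological roles to the three clusters
#'
#' The cluster with the smallest median is labelled `noise`, the largest
#' `maternal`, and the one whose median lies between the other two is the
#' `fetal` cluster.  Ties between medians are broken by medoid value (the
#' tied cluster with the larger medoid takes the higher role), with a
#' warning.
#'
#' @param result a [kmedoids_pp()] result with 3 non-empty clusters.
#' @return The same `kmedoids_result` with `roles` filled
#'   (`roles[j]` is the role of cluster `j`).
#' @export
assign_roles <- function(result) {
  stopifnot(inherits(result, "kmedoids_result"))
  if (any(result$sizes == 0L)) stopf("collapsed cluster")
  med <- result$medians
  if (anyDuplicated(med)) {
    warnf("tied cluster medians; breaking tie by medoid value")
    o <- order(med, result$medoids)
  } else {
    o <- order(med)
  }
  roles <- character(3L)
  roles[o] <- c("noise", "fetal", "maternal")
  result$roles <- roles
  result
}

#' @export
print.kmedoids_result <- function(x, ...) {
  cat(sprintf(
    "<kmedoids_result> %d points, cost %.4g\n", length(x$labels),
    x$total_cost))
  for (j in 1:3)
    cat(sprintf("  cluster %d: n=%d, medoid=%.4g, median=%.4g, role=%s\n",
                j, x$sizes[j], x$medoids[j], x$medians[j], x$roles[j]))
  invisible(x)
}
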