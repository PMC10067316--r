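#' Pick the clustering method for a batch of routes
#'
#' Agglomerative clustering when the batch holds fewer than 15 routes, the
#' density-based method otherwise; an explicit override always wins.
#'
#' @param n_routes Number of routes.
#' @param override Optional `"agglomerative"` or `"density"`.
#' @return The method name.
#' @export
choose_clustering_method <- function(n_routes, override = NULL) {
  if (n_routes < 3L) {
    stop_synkit("insufficient_input",
                "clustering needs at least 3 routes; got ", n_routes)
  }
  if (!is.null(override)) {
    return(match.arg(override, c("agglomerative", "density")))
  }
  if (n_routes < 15L) "agglomerative" else "density"
}

validate_distance_matrix <- function(dm) {
  if (inherits(dm, "route_distance_matrix")) {
    d <- dm$values
  } else {
    d <- as.matrix(dm)
  }
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-9)) {
    stop_synkit("invalid_matrix", "distance matrix must be square and ",
                "symmetric")
  }
  if (any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    stop_synkit("invalid_matrix", "distance matrix must be non-negative ",
                "with a zero diagonal")
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("route_", seq_len(nrow(d)))
  }
  d
}

mean_silhouette <- function(labels, d, penalize_noise = FALSE) {
  keep <- labels != -1L
  labs <- labels[keep]
  if (length(unique(labs)) < 2L || length(labs) <= length(unique(labs))) {
    return(NA_real_)
  }
  sil <- cluster::silhouette(labs, dmatrix = d[keep, keep, drop = FALSE])
  widths <- sil[, "sil_width"]
  # noise-penalized variant: noise points contribute a zero width, so a
  # labelling that explains more routes wins over an equally tight one
  # that discards them
  if (penalize_noise) sum(widths) / length(labels) else mean(widths)
}

cluster_medoids <- function(labels, d) {
  ids <- rownames(d)
  out <- character(0)
  for (cl in sort(unique(labels[labels != -1L]))) {
    members <- which(labels == cl)
    sums <- rowSums(d[members, members, drop = FALSE])
    out[[as.character(cl)]] <- ids[members[which.min(sums)]]
  }
  out
}

# DBSCAN on a precomputed distance matrix. A point with at least min_pts
# neighbours within eps (itself included) is a core point; clusters are the
# connected components of core points plus their border points; everything
# else is noise (-1).
dbscan_distance <- function(d, eps, min_pts = 3L) {
  n <- nrow(d)
  labels <- rep(NA_integer_, n)
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_pts, TRUE)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier)) {
      nxt <- integer(0)
      for (p in frontier) {
        nbrs <- which(d[p, ] <= eps)
        for (q in nbrs) {
          if (is.na(labels[q]) || labels[q] == -1L) {
            grow <- is.na(labels[q]) && core[q]
            labels[q] <- cl
            if (grow) nxt <- c(nxt, q)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' Cluster routes from a GED distance matrix
#'
#' Two paths are available. The agglomerative path fits hierarchical
#' clustering on the precomputed distances (single linkage by default),
#' scans the cluster count k over \[2, n-1\], and keeps the k maximizing
#' the mean silhouette computed on the same distances, breaking ties
#' toward fewer clusters. The density path runs DBSCAN on the distance
#' matrix and may label routes as noise (-1); its `eps` is chosen by the
#' same silhouette scan over the distance quantiles unless given. Each
#' cluster is represented by its medoid, the member minimizing the summed
#' intra-cluster distance.
#'
#' An all-zero matrix (all routes equivalent) is degenerate: one cluster,
#' flagged in the result.
#'
#' @param dm A `route_distance_matrix` or symmetric numeric matrix.
#' @param method `"agglomerative"`, `"density"`, or NULL to apply the
#'   default size rule of [choose_clustering_method()].
#' @param linkage Agglomerative linkage (default `"single"`).
#' @param eps,min_pts Density-path parameters; `eps = NULL` triggers the
#'   silhouette scan.
#' @param routes Optional list of the clustered routes; when given, the
#'   per-cluster summary of [cluster_summary()] is attached.
#' @return A `route_cluster_result` with fields `labels` (named integer
#'   vector), `method_used`, `silhouette`, `medoids`, `degenerate`, and
#'   optionally `summary`.
#' @export
cluster_routes <- function(dm, method = NULL, linkage = "single",
                           eps = NULL, min_pts = 3L, routes = NULL) {
  d <- validate_distance_matrix(dm)
  n <- nrow(d)
  method <- choose_clustering_method(n, override = method)
  ids <- rownames(d)

  if (all(d == 0)) {
    labels <- stats::setNames(rep(1L, n), ids)
    res <- structure(
      list(labels = labels, method_used = method, silhouette = NA_real_,
           medoids = stats::setNames(ids[1], "1"), degenerate = TRUE),
      class = "route_cluster_result"
    )
    if (!is.null(routes)) res$summary <- cluster_summary(res, routes)
    return(res)
  }

  if (method == "agglomerative") {
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    best_k <- NA_integer_
    best_sil <- -Inf
    best_labels <- NULL
    for (k in 2:(n - 1)) {
      labels <- stats::cutree(hc, k = k)
      sil <- mean_silhouette(labels, d)
      if (!is.na(sil) && sil > best_sil + 1e-12) {
        best_sil <- sil
        best_k <- k
        best_labels <- labels
      }
    }
    if (is.null(best_labels)) {   # no k admitted a silhouette; fall back
      best_labels <- stats::cutree(hc, k = 2)
      best_sil <- NA_real_
    }
    labels <- stats::setNames(as.integer(best_labels), ids)
    sil <- if (is.finite(best_sil)) best_sil else NA_real_
  } else {
    if (is.null(eps)) {
      cand <- stats::quantile(d[upper.tri(d) & d > 0],
                              probs = seq(0.05, 0.95, by = 0.05),
                              names = FALSE)
      cand <- unique(cand)
      best_sil <- -Inf
      best_labels <- NULL
      for (e in cand) {
        labels <- dbscan_distance(d, e, min_pts)
        sil <- mean_silhouette(labels, d, penalize_noise = TRUE)
        if (!is.na(sil) && sil > best_sil + 1e-12) {
          best_sil <- sil
          best_labels <- labels
        }
      }
      if (is.null(best_labels)) {
        best_labels <- dbscan_distance(d, stats::median(d[d > 0]), min_pts)
      }
      labels <- stats::setNames(best_labels, ids)
      sil <- mean_silhouette(best_labels, d)
      if (!is.na(sil) && !is.finite(sil)) sil <- NA_real_
    } else {
      labels <- stats::setNames(dbscan_distance(d, eps, min_pts), ids)
      sil <- mean_silhouette(labels, d)
    }
  }

  res <- structure(
    list(labels = labels, method_used = method, silhouette = sil,
         medoids = cluster_medoids(labels, d), degenerate = FALSE),
    class = "route_cluster_result"
  )
  if (!is.null(routes)) res$summary <- cluster_summary(res, routes)
  res
}

#' Per-cluster summary table
#'
#' For each cluster: the number of routes, the mean number of steps and
#' the mean number of branches of its members. Noise routes (label -1,
#' density method) are reported as their own row.
#'
#' @param result A `route_cluster_result`.
#' @param routes List of the clustered `synroute` objects, aligned with
#'   `result$labels`.
#' @return Tibble with `cluster`, `n_routes`, `mean_steps`,
#'   `mean_branches`.
#' @export
cluster_summary <- function(result, routes) {
  stopifnot(inherits(result, "route_cluster_result"))
  if (length(routes) != length(result$labels)) {
    stop_synkit("alignment", "got ", length(routes), " routes for ",
                length(result$labels), " labels")
  }
  steps <- vapply(routes, n_steps, 0L)
  branches <- vapply(routes, n_branches, 0L)
  tibble::tibble(
    cluster = as.integer(result$labels),
    steps = as.numeric(steps),
    branches = as.numeric(branches)
  ) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_routes = dplyr::n(),
      mean_steps = mean(.data$steps),
      mean_branches = mean(.data$branches),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster)
}

#' @export
print.route_cluster_result <- function(x, ...) {
  k <- length(unique(x$labels[x$labels != -1L]))
  cat("<route_cluster_result> method: ", x$method_used, ", ", k,
      " cluster(s)", sep = "")
  if (any(x$labels == -1L)) cat(", ", sum(x$labels == -1L), " noise", sep = "")
  if (!is.na(x$silhouette)) cat(", silhouette ", round(x$silhouette, 3),
                                sep = "")
  if (isTRUE(x$degenerate)) cat("  [degenerate: all routes equivalent]")
  cat("\n")
  invisible(x)
}

#' @export
tidy.route_cluster_result <- function(x, ...) {
  tibble::tibble(
    route_id = names(x$labels),
    cluster = as.integer(x$labels),
    is_medoid = names(x$labels) %in% x$medoids
  )
}

#' @export
glance.route_cluster_result <- function(x, ...) {
  tibble::tibble(
    method = x$method_used,
    n_routes = length(x$labels),
    n_clusters = length(unique(x$labels[x$labels != -1L])),
    n_noise = sum(x$labels == -1L),
    silhouette = x$silhouette,
    degenerate = isTRUE(x$degenerate)
  )
}

#' @export
autoplot.route_cluster_result <- function(object, dm = NULL, ...) {
  df <- tidy(object)
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster, fill = .data$cluster)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "cluster", y = "routes",
                  title = paste0("Route clusters (",
                                 object$method_used, ")")) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
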