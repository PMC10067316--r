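test_that("the default method flips from agglomerative to density at 15 routes", {
  expect_identical(choose_clustering_method(10), "agglomerative")
  expect_identical(choose_clustering_method(14), "agglomerative")
  expect_identical(choose_clustering_method(15), "density")
  expect_identical(choose_clustering_method(40), "density")
  expect_identical(choose_clustering_method(20, override = "agglomerative"),
                   "agglomerative")
  expect_error(choose_clustering_method(2),
               class = "synkit_insufficient_input")
})

test_that("well-separated blocks are recovered with silhouette-chosen k and member medoids", {
  pb <- planted_block_matrix(101)
  res <- cluster_routes(pb$d)
  expect_identical(res$method_used, "agglomerative")
  expect_true(same_partition(res$labels, pb$labels))
  expect_gt(res$silhouette, 0.5)
  for (cl in names(res$medoids)) {
    expect_true(res$labels[[res$medoids[[cl]]]] == as.integer(cl))
  }
})

test_that("identical routes collapse to a flagged degenerate single cluster", {
  d <- matrix(0, 4, 4)
  res <- cluster_routes(d)
  expect_true(res$degenerate)
  expect_identical(unname(unique(res$labels)), 1L)
})

test_that("the density path labels outliers as noise and keeps them out of medoids", {
  pb <- planted_block_matrix(7)
  n <- nrow(pb$d)
  # append one far-away route
  d <- rbind(cbind(pb$d, stats::runif(n, 20, 25)), 0)
  d[n + 1, ] <- d[, n + 1]
  d[n + 1, n + 1] <- 0
  rownames(d) <- colnames(d) <- paste0("r", seq_len(n + 1))
  res <- cluster_routes(d, method = "density", min_pts = 3L)
  expect_identical(res$method_used, "density")
  expect_identical(unname(res$labels[n + 1]), -1L)
  expect_true(same_partition(res$labels[1:n], pb$labels))
  expect_false(rownames(d)[n + 1] %in% res$medoids)
})

test_that("permuting the route order permutes the labels consistently", {
  pb <- planted_block_matrix(55)
  perm <- withr::with_seed(1, sample(nrow(pb$d)))
  res1 <- cluster_routes(pb$d)
  res2 <- cluster_routes(pb$d[perm, perm])
  expect_true(same_partition(res2$labels, res1$labels[perm]))
})

test_that("cluster summaries report per-cluster size and mean descriptors, noise separately", {
  routes <- c(
    lapply(1:3, function(s) generate_route(route_spec(4, seed = s))$route),
    lapply(4:5, function(s) {
      generate_route(route_spec(2, branch_points = list(c(2, 1)),
                                seed = s))$route
    })
  )
  labels <- c(1L, 1L, 1L, 2L, 2L)
  res <- structure(
    list(labels = stats::setNames(labels, paste0("r", 1:5)),
         method_used = "agglomerative", silhouette = NA_real_,
         medoids = c("1" = "r1", "2" = "r4"), degenerate = FALSE),
    class = "route_cluster_result"
  )
  tbl <- cluster_summary(res, routes)
  expect_identical(tbl$n_routes, c(3L, 2L))
  expect_identical(tbl$mean_steps, c(4, 3))
  expect_identical(tbl$mean_branches, c(0, 1))

  res$labels[5] <- -1L
  tbl <- cluster_summary(res, routes)
  expect_identical(tbl$cluster[1], -1L)
  expect_error(cluster_summary(res, routes[1:3]),
               class = "synkit_alignment")
})

test_that("invalid distance matrices are rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(cluster_routes(bad), class = "synkit_invalid_matrix")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(cluster_routes(neg), class = "synkit_invalid_matrix")
})

test_that("clustering integrates with GED distance matrices from routes", {
  routes <- c(
    lapply(1:3, function(s) {
      perturb_route(generate_route(route_spec(4, seed = 900))$route,
                    1, seed = s)$route
    }),
    lapply(4:6, function(s) {
      perturb_route(generate_route(route_spec(2, seed = 901))$route,
                    1, seed = s)$route
    })
  )
  dm <- route_distance_matrix(routes)
  res <- cluster_routes(dm, routes = routes)
  expect_identical(res$method_used, "agglomerative")
  expect_identical(length(res$labels), 6L)
  expect_s3_class(res$summary, "tbl_df")
  g <- glance(res)
  expect_identical(g$n_routes, 6L)
  td <- tidy(res)
  expect_true(all(td$route_id[td$is_medoid] %in% res$medoids))
})
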