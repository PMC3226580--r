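test_that("condition-wise z-scoring uses the sample sd and is idempotent", {
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("p", 1:3), "c1"))
  z <- zscore_by_condition(m)
  expect_equal(unname(z[, 1]), c(-1, 0, 1))      # sample sd of 1,2,3 is 1
  expect_equal(zscore_by_condition(z), z)

  set.seed(3)
  big <- matrix(rnorm(200, sd = 4), 20, 10,
                dimnames = list(paste0("p", 1:20), paste0("c", 1:10)))
  big[sample(200, 20)] <- NA
  z2 <- zscore_by_condition(big)
  expect_equal(unname(colMeans(z2, na.rm = TRUE)), rep(0, 10))
  expect_equal(unname(apply(z2, 2, sd, na.rm = TRUE)), rep(1, 10))
  expect_identical(is.na(z2), is.na(big))

  const <- cbind(big[, 1, drop = FALSE], c2 = rep(5, 20))
  expect_warning(z3 <- zscore_by_condition(const), "zero variance")
  expect_true(all(is.na(z3[, "c2"])))
})

test_that("pairwise Pearson correlation and its t-based p behave as defined", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
             c = -c(1, 2, 3, 4, 5))
  pc <- pearson_with_p(m, min_overlap = 3)
  expect_equal(pc$pcc["a", "b"], 1)
  expect_equal(pc$pcc["a", "c"], -1)

  m2 <- rbind(x = c(1, 2, 3), y = c(1, 2, 4))
  pc2 <- pearson_with_p(m2, min_overlap = 3)
  expect_equal(pc2$pcc["x", "y"], 3 / sqrt(28 / 3), tolerance = 1e-12)
  # p agrees with cor.test on the same pair
  ct <- cor.test(m2["x", ], m2["y", ])
  expect_equal(pc2$p["x", "y"], ct$p.value, tolerance = 1e-9)

  # overlap below min_overlap -> missing
  m3 <- rbind(x = c(1, 2, NA, NA), y = c(1, 2, 3, 4), z = 4:1)
  pc3 <- pearson_with_p(m3, min_overlap = 3)
  expect_true(is.na(pc3$pcc["x", "y"]))
  expect_false(is.na(pc3$pcc["y", "z"]))

  # constant row over the overlap -> missing entry
  m4 <- rbind(x = rep(1, 5), y = rnorm(5))
  expect_true(is.na(pearson_with_p(m4, 3)$pcc["x", "y"]))
})

test_that("PCC is invariant under positive affine rescaling of rows", {
  set.seed(9)
  m <- matrix(rnorm(60), 6, 10, dimnames = list(paste0("p", 1:6), NULL))
  scaled <- m * runif(6, 0.5, 3) + rnorm(6)
  expect_equal(pearson_with_p(scaled, 3)$pcc, pearson_with_p(m, 3)$pcc,
               tolerance = 1e-10)
})

test_that("edges require |PCC| strictly above r_min and significant p", {
  nodes <- paste0("p", 1:3)
  pcc <- diag(1, 3); dimnames(pcc) <- list(nodes, nodes)
  pp <- matrix(1e-8, 3, 3, dimnames = dimnames(pcc))
  pcc["p1", "p2"] <- pcc["p2", "p1"] <- 0.5      # exactly at threshold
  pcc["p2", "p3"] <- pcc["p3", "p2"] <- 0.9
  net <- build_network(pcc, pp, r_min = 0.5, p_max = 1e-4)
  expect_equal(nrow(net$edges), 1)               # 0.5 is NOT an edge
  expect_identical(net$edges$from, "p2")
  expect_equal(net$edges$sign, 1L)

  # degrees over a 2-edge path
  pcc["p1", "p2"] <- pcc["p2", "p1"] <- 0.8
  net2 <- build_network(pcc, pp, r_min = 0.5, p_max = 1e-4)
  expect_identical(unname(net2$degree), c(1L, 2L, 1L))

  # insignificant p suppresses the edge
  pp["p2", "p3"] <- pp["p3", "p2"] <- 0.5
  net3 <- build_network(pcc, pp, r_min = 0.5, p_max = 1e-4)
  expect_equal(nrow(net3$edges), 1)
})

test_that("hubs require both responsiveness and connectivity thresholds", {
  n <- c(a = 10L, b = 9L, c = 43L)
  k <- c(a = 10L, b = 50L, c = 0L)
  expect_identical(identify_hubs(n, k), c(a = TRUE, b = FALSE, c = FALSE))
  expect_error(identify_hubs(n, k[1:2]), "same pathways")
})

test_that("signed bipartition matches exhaustive balance checking on triangles", {
  # oracle: try all 2^3 colorings, count minimum frustrated edges
  frustration <- function(edges, coloring) {
    sum(vapply(seq_len(nrow(edges)), function(i) {
      same <- coloring[[edges$from[i]]] == coloring[[edges$to[i]]]
      (edges$sign[i] > 0 && !same) || (edges$sign[i] < 0 && same)
    }, logical(1)))
  }
  min_frustration <- function(nodes, edges) {
    min(sapply(0:(2^length(nodes) - 1), function(b) {
      col <- setNames(as.integer(intToBits(b))[seq_along(nodes)], nodes)
      frustration(edges, col)
    }))
  }

  nodes <- c("x", "y", "z")
  ed1 <- data.frame(from = c("x", "x", "y"), to = c("y", "z", "z"),
                    sign = c(1, -1, -1))
  expect_equal(min_frustration(nodes, ed1), 0)   # balanced
  res <- partition_signed(mock_network(nodes, ed1))
  expect_true(res$balanced)
  grp <- res$groups
  expect_identical(grp[["x"]], grp[["y"]])
  expect_false(grp[["x"]] == grp[["z"]])

  ed2 <- data.frame(from = c("x", "x", "y"), to = c("y", "z", "z"),
                    sign = c(-1, -1, -1))
  expect_equal(min_frustration(nodes, ed2), 1)   # unavoidably frustrated
  res2 <- partition_signed(mock_network(nodes, ed2))
  expect_false(res2$balanced)
  expect_null(res2$groups)
  expect_gte(nrow(res2$frustrated), 1)

  ed3 <- data.frame(from = c("x", "x", "y"), to = c("y", "z", "z"),
                    sign = c(1, 1, 1))
  res3 <- partition_signed(mock_network(nodes, ed3))
  expect_true(res3$balanced)
  expect_identical(unname(res3$groups), c("A", "A", "A"))

  # anchor flips the labelling
  res4 <- partition_signed(mock_network(nodes, ed1), anchor = "z")
  expect_identical(res4$groups[["z"]], "A")
  expect_identical(res4$groups[["x"]], "B")

  expect_error(partition_signed(mock_network(nodes, ed1), nodes = character(0)),
               "empty")
})

test_that("a balanced partition satisfies the within/between sign contract", {
  set.seed(31)
  for (i in 1:10) {
    cfg <- simulation_config(n_pathways = 30, n_genes = 500,
                             n_conditions = 30, n_toxic_conditions = 15,
                             n_hubs_A = 5, n_hubs_B = 5,
                             background_fraction = 2 / 3, seed = 100 + i)
    nm <- simulate_nes_matrix(simulate_meta_activity(cfg), nes_noise_sd = 0.25)
    fit <- hub_analysis(nm, pipeline_config(theta_resp = 8, theta_deg = 4,
                                            min_overlap = 5, p_max = 1e-3))
    if (is.null(fit$groups)) next
    ed <- fit$network$edges
    lab <- fit$partition$groups
    hub_edges <- ed[ed$from %in% names(lab) & ed$to %in% names(lab), ]
    if (nrow(hub_edges) == 0) next
    same <- lab[hub_edges$from] == lab[hub_edges$to]
    expect_true(all(hub_edges$sign[same] > 0))
    expect_true(all(hub_edges$sign[!same] < 0))
  }
})

test_that("planted two-group structure is recovered from NES-level simulations", {
  ok <- 0L
  for (i in 1:10) {
    cfg <- simulation_config(n_pathways = 30, n_genes = 500,
                             n_conditions = 36, n_toxic_conditions = 18,
                             n_hubs_A = 5, n_hubs_B = 5,
                             background_fraction = 2 / 3, seed = 500 + i)
    truth <- simulate_meta_activity(cfg)
    nm <- simulate_nes_matrix(truth, nes_noise_sd = 0.2)
    fit <- hub_analysis(nm, pipeline_config(theta_resp = 8, theta_deg = 4,
                                            min_overlap = 5, p_max = 1e-3))
    if (is.null(fit$groups)) next
    lab <- fit$partition$groups
    hubs_true <- names(truth$pathway_role)[truth$pathway_role == "hub"]
    shared <- intersect(names(lab), hubs_true)
    if (length(shared) < 6) next
    agree <- mean(lab[shared] == truth$pathway_group[shared])
    ok <- ok + (max(agree, 1 - agree) == 1)
  }
  expect_gte(ok, 9)
})
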