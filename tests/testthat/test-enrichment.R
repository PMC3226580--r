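test_that("the running sum reproduces hand-walked enrichment scores", {
  rk <- ranked_list(paste0("g", 1:4), c(4, 3, 2, 1))
  r <- enrichment_score(rk, c("g1", "g3"), weight = 0)
  expect_equal(r$es, 0.5)                       # walk 0.5, 0, 0.5, 0
  expect_equal(r$running_sum, c(0.5, 0, 0.5, 0))
  expect_equal(enrichment_score(rk, c("g3", "g4"), weight = 0)$es, -1)
  expect_equal(enrichment_score(rk, "g1", weight = 0)$es, 1)

  expect_error(enrichment_score(rk, c("absent")), "not represented")
  expect_error(enrichment_score(rk, paste0("g", 1:4)), "covers every")
})

test_that("both weights agree with the step-by-step oracle on random subsets", {
  rk <- toy_ranked(10, seed = 3)
  set.seed(8)
  for (i in 1:30) {
    k <- sample(1:9, 1)
    idx <- sort(sample(10, k))
    set <- rk$gene[idx]
    for (w in c(0, 1)) {
      expect_equal(enrichment_score(rk, set, weight = w)$es,
                   oracle_es(rk$metric, idx, weight = w),
                   tolerance = 1e-12,
                   label = sprintf("k=%d w=%d rep=%d", k, w, i))
    }
  }
})

test_that("reversing the ranked list mirrors the weight-0 walk", {
  # the reversed walk is the sign-flipped mirror of the forward walk, so
  # es negates except when max and -min tie, where both resolve positive
  rk <- toy_ranked(9, seed = 21)
  rev_rk <- ranked_list(rk$gene, -rk$metric)
  set.seed(4)
  for (i in 1:10) {
    set <- sample(rk$gene, sample(2:7, 1))
    fwd <- enrichment_score(rk, set, weight = 0)
    bwd <- enrichment_score(rev_rk, set, weight = 0)
    top <- max(fwd$running_sum); bot <- min(fwd$running_sum)
    if (abs(top + bot) < 1e-12) {
      expect_equal(bwd$es, fwd$es, tolerance = 1e-12)   # tie: both positive
    } else {
      expect_equal(bwd$es, -fwd$es, tolerance = 1e-12)
    }
  }
})

test_that("weight-1 scores match the fgsea reference statistic", {
  rk <- toy_ranked(50, seed = 17)
  stats_vec <- setNames(rk$metric, rk$gene)
  set.seed(2)
  for (i in 1:10) {
    idx <- sort(sample(50, sample(3:15, 1)))
    ours <- enrichment_score(rk, rk$gene[idx], weight = 1)$es
    ref <- fgsea::calcGseaStat(stats_vec, selectedStats = idx, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("the permutation null enumerates, reproduces and stays bounded", {
  rk <- ranked_list(paste0("g", 1:4), c(2, 1.5, -0.5, -2))
  ex <- permutation_null(rk, 2, weight = 0, exhaustive = TRUE)
  expect_equal(sort(ex), sort(oracle_exhaustive_null(rk$metric, 2, 0)))
  expect_length(ex, choose(4, 2))

  a <- permutation_null(rk, 2, n_perm = 50, seed = 7)
  b <- permutation_null(rk, 2, n_perm = 50, seed = 7)
  expect_identical(a, b)
  expect_true(all(abs(a) <= 1))

  rk2 <- toy_ranked(30)
  null <- permutation_null(rk2, 10, n_perm = 500, seed = 1)
  expect_true(all(abs(null) <= 1))
  expect_error(permutation_null(rk2, 30, n_perm = 10), "set_size")
})

test_that("nominal p follows the same-signed add-one estimator", {
  expect_equal(nominal_p(0.5, c(0.6, 0.4, -0.5)), 2 / 3)
  # es above every one of 999 same-sign null values -> floor 1/1000
  expect_equal(nominal_p(0.9, seq(0.001, 0.8, length.out = 999)), 1 / 1000)
  # no same-sign null -> undefined
  expect_true(is.na(nominal_p(-0.4, c(0.2, 0.5))))
  expect_error(nominal_p(0.5, numeric(0)), "empty")
})

test_that("NES normalizes by the same-signed mean absolute null score", {
  expect_equal(normalized_es(0.5, c(0.3, 0.2, -0.9)), 2)
  expect_equal(normalized_es(-0.4, c(-0.4, 0.99)), -1)
  # null concentrated at |es| -> nes ~ +/-1
  expect_equal(normalized_es(0.3, rep(0.3, 100)), 1)
  expect_true(is.na(normalized_es(0.4, c(-0.1, -0.2))))
})

test_that("nominal p is (super-)uniform under a true null", {
  rk <- toy_ranked(60, seed = 33)
  set.seed(99)
  reject <- logical(400)
  for (i in seq_len(400)) {
    idx <- sort(sample(60, 8))
    es <- enrichment_score(rk, rk$gene[idx], weight = 1)$es
    null <- permutation_null(rk, 8, n_perm = 99, weight = 1,
                             seed = derive_seed(99, i))
    reject[i] <- isTRUE(nominal_p(es, null) <= 0.05)
  }
  # binomial 99.9% upper bound around 0.05 for a super-uniform p
  expect_lt(mean(reject), 0.05 + 3.29 * sqrt(0.05 * 0.95 / 400))
})

test_that("enrich_collection filters by size and ignores set order", {
  rk <- toy_ranked(40, seed = 12)
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(paste(c("big1", "d", rk$gene[seq(1, 24, 2)]), collapse = "\t"),
               paste(c("small", "d", rk$gene[1:5]), collapse = "\t"),
               paste(c("big2", "d", rk$gene[25:38]), collapse = "\t")), f)
  col <- read_gmt(f)
  res <- enrich_collection(rk, col, min_size = 10, n_perm = 100, seed = 5)
  expect_identical(res$skipped, "small")
  expect_setequal(res$results$pathway, c("big1", "big2"))
  expect_true(all(res$results$n_mapped >= 10))

  shuffled <- col
  shuffled$sets <- rev(shuffled$sets)
  shuffled$description <- rev(shuffled$description)
  res2 <- enrich_collection(rk, shuffled, min_size = 10, n_perm = 100, seed = 5)
  expect_identical(res2$results, res$results)

  expect_warning(enrich_collection(rk, col, min_size = 30, n_perm = 10),
                 "no gene set")
})

test_that("a planted activated set is detected with positive NES", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    metric <- rnorm(300)
    genes <- sprintf("g%03d", 1:300)
    planted <- sample(300, 15)
    metric[planted] <- metric[planted] + 2.5   # strong coherent up-shift
    rk <- ranked_list(genes, metric)
    es <- enrichment_score(rk, genes[planted], weight = 1)$es
    null <- permutation_null(rk, 15, n_perm = 200, weight = 1,
                             seed = derive_seed(s, "pn"))
    ok <- es > 0 && isTRUE(nominal_p(es, null) < 0.05)
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})

test_that("the NES matrix assembles per-condition results faithfully", {
  r1 <- data.frame(pathway = c("p1", "p2"), es = c(0.5, -0.4),
                   nes = c(1.5, -1.2), nominal_p = c(0.01, 0.2),
                   n_mapped = c(12L, 15L))
  r2 <- data.frame(pathway = c("p3"), es = 0.6, nes = 2.0,
                   nominal_p = 0.001, n_mapped = 11L)
  nm <- build_nes_matrix(list(condA = r1, condB = r2))
  expect_true(is.na(nm$nes["p3", "condA"]) && is.na(nm$nes["p1", "condB"]))
  expect_equal(nm$nes["p1", "condA"], 1.5)
  expect_identical(!is.na(nm$p) & nm$p < nm$alpha,
                   matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE), 3, 2,
                          dimnames = dimnames(nm$p)))
  expect_error(build_nes_matrix(setNames(list(r1, r2), c("c", "c"))),
               "duplicate")

  nf <- withr::local_tempfile(); pf <- withr::local_tempfile()
  write_nes_matrix(nm, nf, pf)
  back <- read_nes_matrix(nf, pf)
  expect_identical(back$nes, nm$nes)
})
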