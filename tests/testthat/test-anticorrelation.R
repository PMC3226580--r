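# shared fixture: 3 + 3 hubs with a clean inverted profile over 6 conditions,
# conditions 1-4 inverted (seeds), condition 5 concordant, condition 6 weak
make_fixture <- function() {
  pw <- c(paste0("hubA", 1:3), paste0("hubB", 1:3), "pwX", "pwY")
  cond <- paste0("c", 1:6)
  nes <- matrix(0.1, length(pw), length(cond), dimnames = list(pw, cond))
  sig <- matrix(FALSE, length(pw), length(cond), dimnames = list(pw, cond))
  for (j in 1:4) {                       # inverted: A up, B down
    nes[1:3, j] <- 2; nes[4:6, j] <- -2
    sig[1:6, j] <- TRUE
  }
  nes[1:6, 5] <- 2; sig[1:6, 5] <- TRUE  # both groups up: not a seed
  sig[, 6] <- FALSE                      # nothing significant
  # pwX follows A in c1-c3, follows B in c4
  nes["pwX", 1:3] <- 1.5; nes["pwX", 4] <- -1.5
  sig["pwX", 1:4] <- TRUE
  # pwY responds in too few seeds
  nes["pwY", 1] <- 1.5; sig["pwY", 1] <- TRUE
  mock_nes(nes, sig)
}

groupsAB <- list(A = paste0("hubA", 1:3), B = paste0("hubB", 1:3))

test_that("group consensus is the sign of the mean NES over significant hubs", {
  x <- make_fixture()
  expect_identical(consensus_direction(x, groupsAB$A, "c1"), 1L)
  expect_identical(consensus_direction(x, groupsAB$B, "c1"), -1L)
  # fewer than min_hubs significant -> undefined
  expect_true(is.na(consensus_direction(x, groupsAB$A, "c6")))
  two <- x
  two$p["hubA3", "c1"] <- 0.5    # only 2 of 3 A hubs significant now
  two <- nes_matrix(two$nes, two$p, two$alpha)
  expect_true(is.na(consensus_direction(two, groupsAB$A, "c1")))

  # mixed signs resolved by the mean: (+2, +2, -1) -> +1
  y <- x
  y$nes["hubA3", "c1"] <- -1
  y <- nes_matrix(y$nes, y$p, y$alpha)
  expect_identical(consensus_direction(y, groupsAB$A, "c1"), 1L)

  expect_error(consensus_direction(x, character(0), "c1"), "empty")
  expect_error(consensus_direction(x, groupsAB$A, "nope"), "unknown condition")
})

test_that("seed conditions are exactly those with opposite defined consensuses", {
  x <- make_fixture()
  seeds <- select_seed_conditions(x, groupsAB)
  expect_identical(seeds$condition, paste0("c", 1:4))
  expect_true(all(seeds$dir_A == -seeds$dir_B))

  expect_error(select_seed_conditions(x, groupsAB, manual = c("c1", "zz")),
               "unknown seed")
  expect_error(select_seed_conditions(x, groupsAB, manual = "c5"),
               "opposite")
  manual <- select_seed_conditions(x, groupsAB, manual = c("c2", "c3"))
  expect_identical(manual$condition, c("c2", "c3"))

  # no seeds at all -> error
  allsame <- x
  allsame$nes[4:6, 1:4] <- 2
  allsame <- nes_matrix(allsame$nes, allsame$p, allsame$alpha)
  expect_error(select_seed_conditions(allsame, groupsAB), "needs seeds")
})

test_that("the symmetric +/-1 transfer produces the documented scores", {
  x <- make_fixture()
  seeds <- select_seed_conditions(x, groupsAB)
  sc <- score_pathways(x, seeds)
  rownames(sc) <- sc$pathway

  # hub A pathways: 4 significant seed responses, all matching A
  expect_equal(sc["hubA1", "a_score"], 4)
  expect_equal(sc["hubA1", "b_score"], -4)
  expect_equal(sc["hubA1", "anti_score"], 1)
  # pwX: 3 matches with A, 1 with B -> a = 2*3 - 4 = 2, anti = 0.5
  expect_equal(sc["pwX", "a_score"], 2)
  expect_equal(sc["pwX", "n"], 4)
  expect_equal(sc["pwX", "anti_score"], 0.5)
  # pwY: n = 1 -> no assignment downstream
  expect_equal(sc["pwY", "n"], 1)

  assigned <- assign_groups(sc)
  rownames(assigned) <- assigned$pathway
  expect_identical(assigned["hubA1", "assigned_group"], "A")
  expect_true(assigned["hubA1", "anti_correlated"])
  expect_identical(assigned["pwX", "assigned_group"], "none")
  expect_identical(assigned["pwY", "assigned_group"], "none")
  expect_false(assigned["pwY", "anti_correlated"])

  # zero-sum law on every pathway
  expect_true(all(sc$a_score == -sc$b_score))
})

test_that("the anti-correlation score grid is (2k - n)/n with a strict 0.7 bar", {
  # 20 all-seed conditions, A consensus +1 everywhere
  n_max <- 20
  pw_hubs <- c(paste0("A", 1:3), paste0("B", 1:3))
  cases <- expand.grid(n = 3:n_max, k = 0:n_max)
  cases <- cases[cases$k <= cases$n, ]
  pw_cases <- sprintf("case_n%02d_k%02d", cases$n, cases$k)
  pw <- c(pw_hubs, pw_cases)
  cond <- sprintf("s%02d", 1:n_max)
  nes <- matrix(0.01, length(pw), n_max, dimnames = list(pw, cond))
  sig <- matrix(FALSE, length(pw), n_max, dimnames = list(pw, cond))
  nes[1:3, ] <- 2; nes[4:6, ] <- -2; sig[1:6, ] <- TRUE
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; k <- cases$k[i]
    nes[pw_cases[i], seq_len(n)] <- c(rep(2, k), rep(-2, n - k))
    sig[pw_cases[i], seq_len(n)] <- TRUE
  }
  x <- mock_nes(nes, sig)
  seeds <- select_seed_conditions(x, list(A = paste0("A", 1:3),
                                          B = paste0("B", 1:3)))
  expect_equal(nrow(seeds), n_max)
  res <- assign_groups(score_pathways(x, seeds, pathways = pw_cases))

  expect_equal(res$a_score, 2 * cases$k - cases$n)
  expect_equal(res$b_score, -res$a_score)                  # zero-sum law
  kw <- pmax(cases$k, cases$n - cases$k)                   # winning matches
  expect_equal(res$anti_score, (2 * kw - cases$n) / cases$n)
  expect_true(all(abs(res$a_score) <= res$n))

  # strictness of the 0.7 bar: n = 20, k = 17 gives exactly 0.7
  exact <- res[res$n == 20 & res$a_score == 14, ]
  expect_equal(exact$anti_score, 0.7)
  expect_identical(exact$assigned_group, "A")              # score bar passed
  expect_false(exact$anti_correlated)                      # strict >
  above <- res[res$n == 20 & res$a_score == 16, ]
  expect_true(above$anti_correlated)

  # assignment bar: a_score >= 3 with n >= 3
  three <- res[res$n == 3 & res$a_score == 3, ]
  expect_identical(three$assigned_group, "A")
  expect_true(three$anti_correlated)                       # anti = 1 > 0.7
})
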