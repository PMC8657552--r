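two_dmu_table <- function() {
  # B uses exactly double every input of A with identical outputs; with a
  # positive undesirable output the intensity on A is pinned to 1, so
  # rho(B) = 1 - mean(1/2) = 1/2 in closed form.
  dea_table(c("A", "B"),
            inputs = rbind(c(2, 5, 1), c(4, 10, 2)),
            good_outputs = rbind(c(7), c(7)),
            bad_outputs = rbind(c(3), c(3)))
}

test_that("a lone DMU is on its own frontier with zero slacks", {
  res <- sbm_scores(dea_table("only", rbind(c(1, 2)), rbind(4), rbind(2)))
  expect_identical(res$score, 1)
  expect_identical(res$input_slacks[[1]], c(0, 0))
  expect_identical(res$desirable_slacks[[1]], 0)
  expect_identical(res$undesirable_slacks[[1]], 0)
})

test_that("a DMU with doubled inputs scores 1/2 against its dominator", {
  res <- sbm_scores(two_dmu_table())
  expect_identical(res$score[1], 1)
  expect_equal(res$score[2], 0.5, tolerance = 1e-9)
  expect_equal(res$input_slacks[[2]], c(2, 5, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  # and the brute-force fractional-program oracle agrees
  expect_equal(res$score[2], oracle_sbm(two_dmu_table(), 2),
               tolerance = 1e-6)
})

test_that("scores are invariant to the units of any column", {
  tab <- two_dmu_table()
  base <- sbm_scores(tab)$score
  scaled <- dea_table(tab$dmu_ids,
                      tab$inputs %*% diag(c(1000, 1, 0.001)),
                      tab$good_outputs * 42,
                      tab$bad_outputs * 0.07)
  expect_equal(sbm_scores(scaled)$score, base, tolerance = 1e-9)
})

test_that("LP scores match the vertex-enumeration oracle on random small tables", {
  set.seed(60)
  for (rep in 1:6) {
    n <- sample(2:4, 1)
    tab <- dea_table(paste0("d", seq_len(n)),
                     inputs = matrix(runif(n * 2, 1, 10), n, 2),
                     good_outputs = matrix(runif(n, 1, 10), n, 1),
                     bad_outputs = matrix(runif(n, 1, 10), n, 1))
    lp <- sbm_scores(tab)$score
    for (k in seq_len(n)) {
      expect_equal(lp[k], oracle_sbm(tab, k), tolerance = 1e-6)
    }
    expect_true(all(lp > 0 & lp <= 1))
  }
})

test_that("rho = 1 exactly when the DMU is undominated with zero slacks", {
  set.seed(3)
  tab <- simulate_dea(panel_config(n_regions = 1, seed = 5))
  res <- sbm_scores(tab)
  eff <- res$score == 1
  for (k in which(eff)) {
    expect_identical(max(abs(res$input_slacks[[k]])), 0)
  }
  # the planted frontier DMU of the generator scores 1
  expect_identical(res$score[1], 1)
})

test_that("inflating an input or a pollutant never raises the score", {
  tab <- two_dmu_table()
  base <- sbm_scores(tab)$score[2]
  for (mult in c(1.2, 2, 5)) {
    worse_in <- tab
    worse_in$inputs[2, 1] <- tab$inputs[2, 1] * mult
    expect_lte(sbm_scores(worse_in)$score[2], base + 1e-9)
    worse_bad <- tab
    worse_bad$bad_outputs[2, 1] <- tab$bad_outputs[2, 1] * mult
    expect_lte(sbm_scores(worse_bad)$score[2], base + 1e-9)
  }
})

test_that("variable returns to scale never scores below constant returns", {
  set.seed(61)
  tab <- dea_table(paste0("d", 1:4),
                   inputs = matrix(runif(8, 1, 10), 4, 2),
                   good_outputs = matrix(runif(4, 1, 10), 4, 1),
                   bad_outputs = matrix(runif(4, 1, 10), 4, 1))
  crs <- sbm_scores(tab, rts = "crs")$score
  vrs <- sbm_scores(tab, rts = "vrs")$score
  expect_true(all(vrs >= crs - 1e-9))
})

test_that("attach_ree joins scores by region-year and is order-independent", {
  sim <- simulate_panel(panel_config(n_regions = 2, seed = 30))
  ids <- paste(sim$panel$region, sim$panel$year, sep = ":")
  scores <- data.frame(dmu_id = ids, score = runif(length(ids), 0.3, 1),
                       stringsAsFactors = FALSE)
  p1 <- attach_ree(sim$panel, scores)
  p2 <- attach_ree(sim$panel, scores[rev(seq_len(nrow(scores))), ])
  expect_identical(p1, p2)
  expect_identical(p1$REE, scores$score)
  # all-efficient scores give a constant REE column
  scores$score <- 1
  expect_identical(unique(attach_ree(sim$panel, scores)$REE), 1)
  expect_error(attach_ree(sim$panel, scores[-1, ]), "R01:2002")
})

test_that("non-positive data is rejected at table construction", {
  expect_error(dea_table("a", rbind(0), rbind(1), rbind(1)), "positive")
  expect_error(dea_table("a", rbind(1), rbind(-2), rbind(1)), "positive")
  expect_error(dea_table(c("a", "a"), rbind(1, 1), rbind(1, 1),
                         rbind(1, 1)), "duplicated")
})
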