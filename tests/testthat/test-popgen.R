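test_that("F'ST hits its closed-form values on hand-built populations", {
  # identical frequencies -> 0
  calls <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 0L), c(0L, 1L))
  gm <- make_gm(calls)
  pm <- stats::setNames(rep(c("A", "B"), each = 2), gm$samples)
  expect_equal(fst_prime(gm, pm, "A", "B"), 0)

  # fixed difference at a single locus: H_S = 0, H_T = 0.5 -> G_ST = F'ST = 1
  gm2 <- make_gm(matrix(c(0L, 0L, 2L, 2L), 4))
  pm2 <- stats::setNames(rep(c("A", "B"), each = 2), gm2$samples)
  expect_equal(fst_prime(gm2, pm2, "A", "B"), 1)

  # p_A = 0.2, p_B = 0.8: G_ST = 0.36, F'ST = 0.36 * 1.32 / 0.68
  gm3 <- make_gm(matrix(c(1L, 1L, 0L, 0L, 0L, 2L, 2L, 2L, 2L, 0L), 10))
  pm3 <- stats::setNames(rep(c("A", "B"), each = 5), gm3$samples)
  expect_equal(fst_prime(gm3, pm3, "A", "B"), 0.36 * 1.32 / 0.68)

  # symmetry and monomorphic degenerate case
  expect_equal(fst_prime(gm3, pm3, "B", "A"), fst_prime(gm3, pm3, "A", "B"))
  gm4 <- make_gm(matrix(0L, 4, 2))
  pm4 <- stats::setNames(rep(c("A", "B"), each = 2), gm4$samples)
  expect_warning(f <- fst_prime(gm4, pm4, "A", "B"), "monomorphic")
  expect_true(is.na(f))
})

test_that("multi-locus F'ST matches an independent per-count oracle", {
  # oracle: recompute from raw allele counts, scalar arithmetic per locus
  oracle <- function(gm, pm, a, b) {
    ha <- hs <- ht <- numeric(0)
    for (j in seq_len(ncol(gm$calls))) {
      ga <- gm$calls[pm == a, j]; gb <- gm$calls[pm == b, j]
      ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
      if (!length(ga) || !length(gb)) next
      pa <- sum(ga) / (2 * length(ga)); pb <- sum(gb) / (2 * length(gb))
      hs <- c(hs, (2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2)
      ht <- c(ht, 2 * ((pa + pb) / 2) * (1 - (pa + pb) / 2))
    }
    gst <- (sum(ht) - sum(hs)) / sum(ht)
    gst * (1 + mean(hs)) / (1 - mean(hs))
  }
  rnd <- rand_gm(c(A = 6, B = 8, C = 5), 60, seed = 14, miss = 0.15)
  f <- fst_prime_matrix(rnd$gm, rnd$pm)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    expect_equal(f[pair[1], pair[2]], oracle(rnd$gm, rnd$pm, pair[1], pair[2]))
  }
  # locus order is irrelevant
  gm_shuf <- gm_subset(rnd$gm, loci = sample(60))
  expect_equal(unclass(fst_prime_matrix(gm_shuf, rnd$pm)), unclass(f),
               ignore_attr = TRUE)
})

test_that("diversity statistics match a brute-force per-locus tally", {
  # two samples, calls (1,1): H_O = 1, pi = (4/3) * 0.5
  gm <- make_gm(matrix(c(1L, 1L), 2, 1))
  pm <- stats::setNames("A", character(0))
  pm <- c(sample_1 = "A", sample_2 = "A")
  d <- diversity_stats(gm, pm)
  expect_equal(d$H_O, 1)
  expect_equal(d$pi, (4 / 3) * 0.5)

  # private allele: alt present only in pop X
  calls <- rbind(c(1L, 1L), c(0L, 1L), c(0L, 1L), c(0L, 1L))
  gm2 <- make_gm(calls)
  pm2 <- stats::setNames(rep(c("X", "Y"), each = 2), gm2$samples)
  d2 <- diversity_stats(gm2, pm2)
  expect_equal(d2$private_alleles[d2$population == "X"], 1)
  expect_equal(d2$private_alleles[d2$population == "Y"], 0)

  rnd <- rand_gm(c(A = 5, B = 6, C = 4), 50, seed = 8, miss = 0.2)
  d3 <- diversity_stats(rnd$gm, rnd$pm)
  for (p in c("A", "B", "C")) {
    sub <- rnd$gm$calls[rnd$pm == p, , drop = FALSE]
    called <- colSums(!is.na(sub))
    ho <- mean((colSums(!is.na(sub) & sub == 1L) / called)[called > 0])
    pr <- colSums(sub, na.rm = TRUE) / (2 * called)
    pi <- mean(((2 * called / (2 * called - 1)) * 2 * pr * (1 - pr))[called > 0])
    row <- d3[d3$population == p, ]
    expect_equal(row$H_O, ho)
    expect_equal(row$pi, pi)
    expect_equal(row$missing_fraction, mean(is.na(sub)))
  }
})

test_that("folded AFS bins on the exact grid and normalises", {
  # k = 5 diploids: alt count 1/10 -> bin 0.1; 7/10 folds to 0.3
  calls <- cbind(c(1L, 0L, 0L, 0L, 0L),   # 1 alt copy
                 c(2L, 2L, 2L, 1L, 0L),   # 7 alt copies
                 c(0L, 0L, 0L, 0L, 0L))   # monomorphic
  gm <- make_gm(calls)
  pm <- stats::setNames(rep("P", 5), gm$samples)
  afs <- folded_afs(gm, pm, "P")
  expect_equal(unname(afs["0.1"]), 1 / 3)
  expect_equal(unname(afs["0.3"]), 1 / 3)
  expect_equal(unname(afs["0"]), 1 / 3)
  expect_equal(sum(afs), 1)

  # unequal called counts across loci are refused
  calls[1, 1] <- NA
  gm2 <- make_gm(calls)
  expect_error(folded_afs(gm2, pm, "P"), "same called count")
})

test_that("subsample summaries use the t interval and cover the mean", {
  s <- summarize_subsamples(rep(0.3, 5))
  expect_equal(s$ci_low, 0.3)
  expect_equal(s$ci_high, 0.3)

  s2 <- summarize_subsamples(c(0, 1))
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$ci_high - s2$mean, qt(0.975, 1) * sd(c(0, 1)) / sqrt(2),
               tolerance = 1e-12)

  cover <- withr::with_seed(19, {
    mean(replicate(400, {
      x <- rnorm(10, mean = 2)
      s <- summarize_subsamples(x)
      s$ci_low <= 2 && 2 <= s$ci_high
    }))
  })
  expect_gt(cover, 0.90)
  expect_lt(cover, 0.99)

  p <- summarize_subsamples(c(1:10), method = "percentile")
  expect_equal(p$ci_low, quantile(1:10, 0.025, names = FALSE))
})

test_that("row summaries of a pairwise matrix use mean and sample sd", {
  m <- pairwise_matrix(rbind(c(0, .1, .2, .3), c(.1, 0, .5, .6),
                             c(.2, .5, 0, .7), c(.3, .6, .7, 0)),
                       labels = c("w", "x", "y", "z"), semantics = "fst_prime")
  r <- mean_fst_to_others(m, "w")
  expect_equal(r$mean, 0.2)
  expect_equal(r$sd, 0.1)
  expect_error(mean_fst_to_others(m, "q"), "unknown")
})

test_that("balanced subsampling is balanced, seeded and reduces to identity", {
  rnd <- rand_gm(c(A = 8, B = 18, C = 11), 30, seed = 4, miss = 0.05)
  reps <- balanced_subsample(rnd$gm, rnd$pm, n_reps = 3, seed = 11)
  for (r in reps) expect_true(all(table(r$pm) == 8))  # k = min n
  reps2 <- balanced_subsample(rnd$gm, rnd$pm, n_reps = 3, seed = 11)
  expect_identical(lapply(reps, function(r) r$gm$calls),
                   lapply(reps2, function(r) r$gm$calls))
  reps3 <- balanced_subsample(rnd$gm, rnd$pm, n_reps = 3, seed = 12)
  expect_false(identical(reps[[1]]$gm$calls, reps3[[1]]$gm$calls))

  # k = population size without replacement: statistics equal full sample
  eq <- rand_gm(c(A = 6, B = 6), 40, seed = 21, miss = 0)
  one <- balanced_subsample(eq$gm, eq$pm, n_reps = 1, k = 6, replace = FALSE,
                            seed = 2)[[1]]
  expect_equal(fst_prime(one$gm, one$pm, "A", "B"),
               fst_prime(eq$gm, eq$pm, "A", "B"))
  expect_error(balanced_subsample(eq$gm, eq$pm, k = 0), "positive")
})
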