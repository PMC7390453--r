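test_that("great-circle distances hit closed forms and known city pairs", {
  s <- data.frame(population = c("o", "anti"), lat = c(0, 0), lon = c(0, 180),
                  marine = 1, aerial = 1)
  d <- geo_distance_matrix(s)
  expect_equal(d["o", "o"], 0)
  expect_equal(d["o", "anti"], 6371 * pi, tolerance = 1e-6)

  sb <- aedes_sites("albopictus")
  db <- geo_distance_matrix(sb)
  expect_equal(db["Singapore", "Johor"], 20, tolerance = 0.15)
  expect_equal(db["Guangzhou", "Hong Kong"], 130, tolerance = 0.15)
})

test_that("pairwise connectivity averages scores, keeping them on the diagonal", {
  sa <- aedes_sites("aegypti")
  cm <- connectivity_matrix(sa, "marine")
  expect_equal(cm["Jeddah", "Colombo"], (7.92 + 9.62) / 2)
  expect_equal(unname(diag(unclass(cm))), sa$marine)
  s_const <- data.frame(population = c("a", "b", "c"), lat = 0, lon = 1:3,
                        marine = 2, aerial = 5)
  expect_true(all(connectivity_matrix(s_const, "marine") == 2))
  s_na <- data.frame(population = "a", lat = 0, lon = 0, marine = NA, aerial = 1)
  expect_error(connectivity_matrix(s_na, "marine"), "NA")
})

test_that("PCNM truncates at the longest MST edge and reproduces PCoA", {
  # 4 collinear equidistant points: every MST edge has length 1
  pts <- data.frame(population = letters[1:4], lat = 0,
                    lon = c(0, 1, 2, 3) * 180 / (6371 * pi),  # 1 km spacing
                    marine = 1, aerial = 1)
  d <- geo_distance_matrix(pts)
  b <- pcnm_basis(d)
  expect_equal(b$threshold, 1, tolerance = 1e-6)

  # plane points, threshold beyond max distance: classical PCoA, distances
  # reconstructed to machine precision
  withr::with_seed(31, {
    xy <- matrix(rnorm(20), 10)
    D <- as.matrix(dist(xy))
    dimnames(D) <- list(paste0("p", 1:10), paste0("p", 1:10))
    pmx <- pairwise_matrix(D, semantics = "geo_km")
    b2 <- pcnm_basis(pmx, truncation = max(D) + 1)
    scores <- b2$vectors %*% diag(sqrt(b2$eigenvalues))
    expect_equal(as.matrix(dist(scores)), D, ignore_attr = TRUE,
                 tolerance = 1e-10)
    # orthonormality of the retained axes
    expect_equal(crossprod(b2$vectors), diag(ncol(b2$vectors)),
                 ignore_attr = TRUE, tolerance = 1e-10)
  })
})

test_that("PCNM agrees with vegan's reference implementation", {
  withr::with_seed(13, {
    xy <- matrix(rnorm(24), 12)
    D <- as.matrix(dist(xy))
    dimnames(D) <- list(paste0("p", 1:12), paste0("p", 1:12))
    b <- pcnm_basis(pairwise_matrix(D, semantics = "geo_km"))
    v <- vegan::pcnm(stats::as.dist(D))
    expect_equal(b$threshold, v$threshold)
    expect_equal(ncol(b$vectors), ncol(v$vectors))
    expect_equal(b$eigenvalues, unname(v$values[seq_len(ncol(b$vectors))]))
    for (j in 1:3)
      expect_equal(abs(stats::cor(b$vectors[, j], v$vectors[, j])), 1)
  })
})

test_that("dbRDA pseudo-F equals capscale's, conditioned or not", {
  withr::with_seed(23, {
    n <- 14
    D <- as.matrix(dist(matrix(rnorm(2 * n), n))) / 5
    dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
    resp <- pairwise_matrix(D, semantics = "fst_prime")
    X <- matrix(rnorm(n * 3), n, dimnames = list(rownames(D), paste0("x", 1:3)))
    Z <- matrix(rnorm(n * 2), n, dimnames = list(rownames(D), paste0("z", 1:2)))

    r <- dbrda(resp, X, n_perm = 0)
    cs <- vegan::capscale(stats::as.dist(D) ~ X)
    an <- as.data.frame(vegan::anova.cca(cs, permutations = 99))
    expect_equal(r$pseudo_F, an$F[1], tolerance = 1e-8)
    expect_equal(r$ss_model, an$SumOfSqs[1], tolerance = 1e-8)
    expect_equal(r$df_model, an$Df[1])
    expect_equal(r$df_residual, an$Df[2])

    rc <- dbrda(resp, X, condition = Z, n_perm = 0)
    cs2 <- vegan::capscale(stats::as.dist(D) ~ X + Condition(Z))
    an2 <- as.data.frame(vegan::anova.cca(cs2, permutations = 99))
    expect_equal(rc$pseudo_F, an2$F[1], tolerance = 1e-8)
    expect_equal(rc$ss_model, an2$SumOfSqs[1], tolerance = 1e-8)
    expect_equal(rc$df_residual, an2$Df[2])
  })
})

test_that("dbRDA is invariant to relabelling and flags saturation", {
  withr::with_seed(29, {
    n <- 10
    D <- as.matrix(dist(matrix(rnorm(2 * n), n)))
    dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
    resp <- pairwise_matrix(D, semantics = "fst_prime")
    X <- matrix(rnorm(n * 2), n, dimnames = list(rownames(D), c("a", "b")))
    r1 <- dbrda(resp, X, n_perm = 0)
    perm <- sample(n)
    resp_p <- pairwise_matrix(D[perm, perm], semantics = "fst_prime")
    r2 <- dbrda(resp_p, X[perm, , drop = FALSE], n_perm = 0)
    expect_equal(r2$pseudo_F, r1$pseudo_F)

    # regressing a distance matrix on its own full PCNM span saturates
    b <- pcnm_basis(resp, truncation = max(D) + 1)
    r3 <- dbrda(resp, b, n_perm = 0)
    expect_true(r3$saturated)
    expect_equal(r3$ss_residual / (r3$ss_model + r3$ss_residual), 0,
                 tolerance = 1e-8)
    # too many predictors is an error, not a silent fit
    Xbig <- matrix(rnorm(n * 9), n, dimnames = list(rownames(D), paste0("x", 1:9)))
    expect_error(dbrda(resp, Xbig, n_perm = 0), "saturated")
  })
})

test_that("permutation P is uniform under the null", {
  ps <- withr::with_seed(41, {
    vapply(seq_len(400), function(i) {
      n <- 12
      D <- as.matrix(dist(matrix(rnorm(2 * n), n)))
      dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
      X <- matrix(rnorm(n * 3), n, dimnames = list(rownames(D), paste0("x", 1:3)))
      dbrda(pairwise_matrix(D, semantics = "fst_prime"), X,
            n_perm = 99, seed = i)$permutation_P
    }, numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("single-axis screening selects near alpha under pure noise", {
  sel_frac <- withr::with_seed(43, {
    mean(vapply(seq_len(60), function(i) {
      n <- 12
      D <- as.matrix(dist(matrix(rnorm(2 * n), n)))
      dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
      D2 <- as.matrix(dist(matrix(rnorm(2 * n), n)))
      dimnames(D2) <- dimnames(D)
      B <- pcnm_basis(pairwise_matrix(D2, semantics = "geo_km"))
      sel <- select_significant_axes(pairwise_matrix(D, semantics = "fst_prime"),
                                     B, alpha = 0.1, n_perm = 99, seed = i)
      ncol(sel) / ncol(B$vectors)
    }, numeric(1)))
  })
  expect_equal(sel_frac, 0.1, tolerance = 0.5)
})

test_that("directionality returns signed standardised slopes", {
  withr::with_seed(47, {
    D <- as.matrix(dist(matrix(rnorm(16), 8)))
    dimnames(D) <- list(paste0("p", 1:8), paste0("p", 1:8))
    resp <- pairwise_matrix(D, semantics = "fst_prime")
    expect_equal(directionality(resp, resp), 1)
    neg <- pairwise_matrix(-D, semantics = "geo_km")
    expect_equal(directionality(resp, neg), -1)
    flat <- pairwise_matrix(matrix(1, 8, 8, dimnames = dimnames(D)),
                            semantics = "geo_km")
    expect_error(directionality(resp, flat), "zero-variance")
  })

  # isolation by distance gives a positive distance slope in every run
  sa <- aedes_sites("aegypti")
  slopes <- vapply(1:5, function(i) {
    sim <- simulate_snp_data(sim_config(sites = sa, n_ind = 5, n_loci = 800,
                                        sigma = 1, missing_rate = 0),
                             seed = 500 + i)
    fst <- fst_prime_matrix(sim$gm, sim$pm)
    directionality(fst, align_pm(geo_distance_matrix(sa), rownames(fst)))
  }, numeric(1))
  expect_true(all(slopes > 0))
})

test_that("the landscape stage reproduces the study's model dimensions", {
  sa <- aedes_sites("aegypti")
  sb <- aedes_sites("albopictus")
  sb <- sb[sb$population != "Colombo-1", ]
  expect_equal(ncol(pcnm_basis(geo_distance_matrix(sa))$vectors), 9)
  expect_equal(ncol(pcnm_basis(connectivity_matrix(sa, "marine"))$vectors), 12)
  expect_equal(ncol(pcnm_basis(connectivity_matrix(sa, "aerial"))$vectors), 11)
  expect_equal(ncol(pcnm_basis(geo_distance_matrix(sb))$vectors), 9)
  expect_equal(ncol(pcnm_basis(connectivity_matrix(sb, "marine"))$vectors), 15)
  expect_equal(ncol(pcnm_basis(connectivity_matrix(sb, "aerial"))$vectors), 13)
})
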