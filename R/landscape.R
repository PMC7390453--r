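#' Great-circle distance matrix between populations
#'
#' Haversine distances (sphere radius 6371 km) between the population
#' coordinates of a site table.
#'
#' @param sites data.frame from [read_sites()] / [aedes_sites()].
#' @return [pairwise_matrix()] of km with semantics `geo_km`.
#' @export
geo_distance_matrix <- function(sites) {
  if (anyNA(sites$lat) || anyNA(sites$lon)) stop("missing coordinate in site table")
  xy <- cbind(sites$lon, sites$lat)
  d <- geosphere::distm(
    xy, fun = function(a, b) geosphere::distHaversine(a, b, r = 6371000)
  ) / 1000
  pairwise_matrix(d, labels = sites$population, semantics = "geo_km")
}

#' Pairwise transport-connectivity matrix
#'
#' The connectivity of a population pair to a transport network is the
#' average of the two populations' scores for that network; the diagonal
#' carries the population's own score.
#'
#' @param sites data.frame from [read_sites()].
#' @param which `"marine"` or `"aerial"`.
#' @return [pairwise_matrix()] with the matching semantics tag.
#' @export
connectivity_matrix <- function(sites, which = c("marine", "aerial")) {
  which <- match.arg(which)
  s <- sites[[which]]
  if (anyNA(s))
    stop("NA ", which, " score for: ",
         paste(sites$population[is.na(s)], collapse = ", "),
         " — drop these populations first")
  if (any(s < 0)) stop("negative connectivity score")
  m <- outer(s, s, "+") / 2
  diag(m) <- s
  pairwise_matrix(m, labels = sites$population,
                  semantics = paste0("connectivity_", which))
}

#' PCNM spatial eigenvectors of a pairwise matrix
#'
#' Principal coordinates of neighbour matrices: the pairwise matrix is
#' truncated at threshold `t` (default: the longest edge of its minimum
#' spanning tree), entries above `t` are replaced by `4t`, and the
#' truncated matrix is double-centred (Gower, on -D^2/2) and
#' eigendecomposed. Axes with eigenvalue > 1e-8 times the largest are
#' retained as orthonormal vectors — the rectangular spatial predictors a
#' dbRDA needs.
#'
#' @param m a [pairwise_matrix()] (the diagonal is ignored, as in a
#'   distance object).
#' @param truncation truncation threshold; default (`NULL`) the longest
#'   minimum-spanning-tree edge.
#' @return list of class `pcnm_basis`: `vectors` (populations x axes,
#'   orthonormal, columns `PCNM1..`), `eigenvalues`, `threshold`,
#'   `semantics`.
#' @export
pcnm_basis <- function(m, truncation = NULL) {
  d <- as.matrix(m)
  diag(d) <- 0
  if (max(d) <= 0) stop("degenerate matrix: all entries equal")
  if (is.null(truncation)) {
    mst <- ape::mst(stats::as.dist(d))
    truncation <- max(d[mst == 1])
  }
  trunc <- d
  trunc[trunc > truncation] <- 4 * truncation
  diag(trunc) <- 0
  n <- nrow(trunc)
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% (trunc^2) %*% C
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  keep <- which(e$values > 1e-8 * max(e$values))
  vectors <- e$vectors[, keep, drop = FALSE]
  dimnames(vectors) <- list(rownames(d), paste0("PCNM", seq_along(keep)))
  structure(list(vectors = vectors, eigenvalues = e$values[keep],
                 threshold = truncation,
                 semantics = attr(m, "semantics")),
            class = "pcnm_basis")
}

# internal: principal-coordinate site scores of a distance matrix
# (positive eigenvalues only, scaled by sqrt(eigenvalue))
pcoa_scores <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  n <- nrow(d)
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% (d^2) %*% C
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  keep <- which(e$values > tol * max(abs(e$values)))
  Y <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                length(keep))
  rownames(Y) <- rownames(d)
  Y
}

#' Distance-based redundancy analysis with permutation test
#'
#' Constrained ordination of a distance matrix on explanatory axes:
#' (1) principal-coordinate site scores of the response distances (real,
#' positive-eigenvalue axes only, as `capscale`-style analyses use);
#' (2) optional conditioning — response scores and predictors are
#' residualised on the condition axes by least squares; (3) multivariate
#' least squares of the scores on the predictors, giving
#' pseudo-F = (SS_model/df_model) / (SS_residual/df_residual) with
#' df_model = number of predictor axes and
#' df_residual = n - 1 - df_model - n_condition; (4) a Freedman-Lane
#' permutation test: rows of the residualised scores are permuted (and
#' re-residualised on the condition axes) `n_perm` times, and
#' P = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param response a [pairwise_matrix()] of distances (e.g. F'ST).
#' @param predictors matrix of predictor axes (rows = populations, in the
#'   response's order) or a `pcnm_basis`.
#' @param condition optional matrix of conditioning axes (or `pcnm_basis`).
#' @param n_perm number of permutations; default 9999. Use 0 to skip the
#'   test.
#' @param seed integer seed for the permutations.
#' @return list of class `dbrda_result`: `pseudo_F`, `df_model`,
#'   `df_residual`, `ss_model`, `ss_residual`, `permutation_P`, `n_permutations`,
#'   `conditioned_axes`, `saturated`, `seed`.
#' @export
dbrda <- function(response, predictors, condition = NULL, n_perm = 9999,
                  seed = NULL) {
  X <- if (inherits(predictors, "pcnm_basis")) predictors$vectors else
    as.matrix(predictors)
  Z <- if (inherits(condition, "pcnm_basis")) condition$vectors else
    if (is.null(condition)) NULL else as.matrix(condition)
  labs <- rownames(response)
  if (!is.null(rownames(X)) && !identical(rownames(X), labs)) {
    if (!all(labs %in% rownames(X))) stop("predictor labels do not match response")
    X <- X[labs, , drop = FALSE]
  }
  if (!is.null(Z) && !is.null(rownames(Z)) && !identical(rownames(Z), labs)) {
    if (!all(labs %in% rownames(Z))) stop("condition labels do not match response")
    Z <- Z[labs, , drop = FALSE]
  }
  n <- nrow(response)
  Y <- pcoa_scores(response)
  n_cond <- if (is.null(Z)) 0L else ncol(Z)
  df_model <- ncol(X)
  df_resid <- n - 1L - df_model - n_cond
  if (df_resid <= 0) stop("saturated model: df_residual <= 0")

  center <- function(M) sweep(M, 2, colMeans(M))
  Y <- center(Y); X <- center(X)
  if (!is.null(Z)) {
    Z <- center(Z)
    qz <- qr(Z)
    resid_on_Z <- function(M) M - qr.fitted(qz, M)
    Y <- resid_on_Z(Y)
    X <- resid_on_Z(X)
  } else {
    resid_on_Z <- identity
  }
  qx <- qr(X)
  Qx <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]

  ss_tot <- sum(Y^2)
  ss_model <- sum((crossprod(Qx, Y))^2)
  ss_resid <- ss_tot - ss_model
  saturated <- ss_resid < 1e-10 * ss_tot
  F_obs <- if (saturated) Inf else
    (ss_model / df_model) / (ss_resid / df_resid)

  P <- NA_real_
  if (n_perm > 0 && !saturated) {
    F_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        Yp <- Y[sample.int(n), , drop = FALSE]
        Yp <- resid_on_Z(Yp)
        ssm <- sum((crossprod(Qx, Yp))^2)
        sst <- sum(Yp^2)
        (ssm / df_model) / ((sst - ssm) / df_resid)
      }, numeric(1))
    })
    P <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  }
  structure(list(
    pseudo_F = F_obs, df_model = df_model, df_residual = df_resid,
    ss_model = ss_model, ss_residual = ss_resid,
    permutation_P = P, n_permutations = n_perm,
    conditioned_axes = if (is.null(Z)) character(0) else colnames(Z),
    saturated = saturated, seed = seed
  ), class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("dbRDA: F(%d, %d) = %.3f, SS model %.4g, SS resid %.4g, P = %s%s\n",
              x$df_model, x$df_residual, x$pseudo_F, x$ss_model,
              x$ss_residual,
              ifelse(is.na(x$permutation_P), "NA",
                     format(x$permutation_P, digits = 3)),
              if (length(x$conditioned_axes))
                paste0(" | conditioned on ",
                       length(x$conditioned_axes), " axes") else ""))
  invisible(x)
}

#' Screen PCNM axes one at a time
#'
#' Runs a single-axis dbRDA per basis vector and keeps those with
#' permutation P below `alpha` — the screening used to pick geographic
#' conditioning axes for connectivity models.
#'
#' @param response a [pairwise_matrix()] of distances.
#' @param basis a `pcnm_basis`.
#' @param alpha selection threshold; default 0.01.
#' @param n_perm permutations per axis test; default 9999.
#' @param seed integer seed (incremented per axis).
#' @return matrix of the selected axes (possibly 0 columns) with attribute
#'   `p_values` (named, all axes).
#' @export
select_significant_axes <- function(response, basis, alpha = 0.01,
                                    n_perm = 9999, seed = NULL) {
  V <- basis$vectors
  p <- vapply(seq_len(ncol(V)), function(j) {
    dbrda(response, V[, j, drop = FALSE], n_perm = n_perm,
          seed = if (is.null(seed)) NULL else seed + j)$permutation_P
  }, numeric(1))
  names(p) <- colnames(V)
  sel <- V[, p < alpha, drop = FALSE]
  attr(sel, "p_values") <- p
  sel
}

#' Directionality of a pairwise association
#'
#' PCNM axes lose the sign of an association, so direction is recovered
#' separately: the off-diagonal upper-triangle entries of each matrix are
#' z-score normalised and the response is regressed on the predictor by
#' ordinary least squares. The slope is a signed standardised coefficient;
#' it is not a significance test (pairwise entries are not independent).
#'
#' @param response,predictor [pairwise_matrix()] objects with matching
#'   labels.
#' @return the regression slope (scalar).
#' @export
directionality <- function(response, predictor) {
  if (!identical(rownames(response), rownames(predictor)))
    stop("matrix labels do not match")
  ut <- upper.tri(response)
  y <- response[ut]; x <- predictor[ut]
  if (stats::sd(x) == 0) stop("zero-variance predictor")
  y <- (y - mean(y)) / stats::sd(y)
  x <- (x - mean(x)) / stats::sd(x)
  unname(stats::coef(stats::lm(y ~ x))[2])
}
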