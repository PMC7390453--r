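#' Configuration for the synthetic SNP generator
#'
#' The generator emulates the statistical structure that the rest of the
#' package is designed to detect: population allele frequencies whose
#' divergence grows with effective distance, where connectivity to
#' transport networks shrinks effective distance. It is a logit-normal
#' spatial emulator, not a demographic model.
#'
#' @param sites site table (population, lat, lon, marine, aerial); default
#'   the bundled Ae. aegypti table, so simulated studies share the study's
#'   landscape geometry.
#' @param n_ind genotypes per population: a single number or a vector named
#'   by population. Default 5 (the balanced-subsample size of the study
#'   design).
#' @param n_loci number of biallelic loci. Default 1000.
#' @param maf_range ancestral minor-allele-frequency interval. Default
#'   c(0.05, 0.5).
#' @param maf_law shape of the ancestral MAF law on `maf_range`:
#'   `"uniform"` (default) or `"neutral"` (density proportional to 1/x,
#'   i.e. log-uniform — the rare-allele-heavy shape of a neutral site
#'   frequency spectrum, needed for bottleneck emulation to show the
#'   classic loss-of-rare-alleles signature).
#' @param sigma spatial standard deviation on the logit scale; 0 gives
#'   panmixia. Default 1.
#' @param rho spatial range in km of the exponential covariance; default
#'   (`NULL`) half the landscape diameter.
#' @param gamma connectivity leverage (>= 0): effective distance is
#'   d_geo / (1 + gamma * mean pairwise connectivity). Default 0.
#' @param connectivity which score modulates distance, `"marine"` or
#'   `"aerial"`. Connectivity scores are rescaled to [0, 1] before use so
#'   gamma is comparable across networks.
#' @param f_extra per-population extra drift (logit-scale variance added on
#'   the diagonal), emulating bottleneck/founder signatures; single number
#'   or named vector. Default 0.
#' @param missing_rate per-call missing probability. Default 0.05.
#' @param depth_mean,depth_disp negative-binomial read-depth law (mean,
#'   dispersion `size`). Defaults 20 and 8, matching typical
#'   reduced-representation coverage.
#' @param kin_plan named integer vector: full-sib pairs to plant per
#'   population. Default none.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(sites = aedes_sites("aegypti"), n_ind = 5,
                       n_loci = 1000, maf_range = c(0.05, 0.5),
                       maf_law = c("uniform", "neutral"), sigma = 1,
                       rho = NULL, gamma = 0,
                       connectivity = c("marine", "aerial"), f_extra = 0,
                       missing_rate = 0.05, depth_mean = 20, depth_disp = 8,
                       kin_plan = NULL) {
  connectivity <- match.arg(connectivity)
  maf_law <- match.arg(maf_law)
  pops <- sites$population
  expand <- function(x, what) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, length(pops)), pops)
    if (!all(pops %in% names(x))) stop(what, " must cover every population")
    x[pops]
  }
  stopifnot(sigma >= 0, gamma >= 0, n_loci >= 1,
            missing_rate >= 0, missing_rate <= 1)
  cfg <- list(sites = sites, n_ind = expand(n_ind, "n_ind"), n_loci = n_loci,
              maf_range = maf_range, maf_law = maf_law,
              sigma = sigma, rho = rho, gamma = gamma,
              connectivity = connectivity,
              f_extra = expand(f_extra, "f_extra"),
              missing_rate = missing_rate, depth_mean = depth_mean,
              depth_disp = depth_disp, kin_plan = kin_plan)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-population diploid SNP dataset
#'
#' Per locus l, an ancestral frequency p_l is drawn and population
#' deviations z on the logit scale follow a multivariate normal with
#' covariance `sigma^2 * exp(-d_eff / rho)` plus `f_extra` on the diagonal,
#' where effective distance `d_eff = d_geo / (1 + gamma * c_bar)` shrinks
#' with the pairwise mean connectivity `c_bar` (rescaled to [0, 1]).
#' Population frequencies are `plogis(logit(p_l) + z)`; individual dosages
#' are Binomial(2, p). Calls are masked missing at the configured rate and
#' per-call depths drawn from a negative binomial. Planted full-sib pairs
#' (if any) replace existing individuals via Mendelian segregation from two
#' simulated parents.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; identical seeds reproduce identical output.
#' @return list: `gm` ([genotype_matrix()]), `pm` (named population map),
#'   `sites` (the site table), `truth` (per-locus population frequencies,
#'   effective-distance matrix, kin registry, generating config).
#' @export
simulate_snp_data <- function(cfg, seed = NULL) {
  with_seed(seed, {
    sites <- cfg$sites
    pops <- sites$population
    n_pop <- length(pops)
    d_geo <- geo_distance_matrix(sites)
    cbar <- matrix(0, n_pop, n_pop)
    if (cfg$gamma > 0) {
      s <- sites[[cfg$connectivity]]
      if (anyNA(s)) stop("NA connectivity score with gamma > 0")
      s <- if (max(s) > 0) s / max(s) else s
      cbar <- outer(s, s, "+") / 2
    }
    d_eff <- unclass(d_geo) / (1 + cfg$gamma * cbar)
    rho <- if (is.null(cfg$rho)) max(d_eff) / 2 else cfg$rho
    Sigma <- cfg$sigma^2 * exp(-d_eff / rho) + diag(cfg$f_extra, n_pop)
    # the exponential kernel on shrunk (non-metric) distances need not be
    # positive definite; lift the spectrum just enough when it is not
    eigmin <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (eigmin < 1e-10) {
      lift <- abs(eigmin) + 1e-8 * max(1, max(diag(Sigma)))
      message("covariance not positive definite; diagonal lifted by ",
              signif(lift, 3))
      Sigma <- Sigma + lift * diag(n_pop)
    }
    L <- chol(Sigma)
    p_anc <- if (identical(cfg$maf_law, "neutral"))
      exp(stats::runif(cfg$n_loci, log(cfg$maf_range[1]),
                       log(cfg$maf_range[2])))
    else
      stats::runif(cfg$n_loci, cfg$maf_range[1], cfg$maf_range[2])
    mu <- stats::qlogis(p_anc)
    z <- t(L) %*% matrix(stats::rnorm(n_pop * cfg$n_loci), n_pop)
    p <- stats::plogis(sweep(z, 2, mu, "+"))  # pops x loci
    rownames(p) <- pops

    n_tot <- sum(cfg$n_ind)
    calls <- matrix(NA_integer_, n_tot, cfg$n_loci)
    pm <- character(n_tot)
    ids <- character(n_tot)
    row <- 0L
    for (k in seq_len(n_pop)) {
      nk <- cfg$n_ind[k]
      calls[row + seq_len(nk), ] <- matrix(
        stats::rbinom(nk * cfg$n_loci, 2L, rep(p[k, ], each = nk)), nk)
      pm[row + seq_len(nk)] <- pops[k]
      ids[row + seq_len(nk)] <- paste0(gsub("[^A-Za-z0-9]", "", pops[k]),
                                       "_", seq_len(nk))
      row <- row + nk
    }
    rownames(calls) <- ids
    colnames(calls) <- paste0("locus_", seq_len(cfg$n_loci))
    loci <- data.frame(chrom = "1", pos = seq_len(cfg$n_loci),
                       ref = "A", alt = "T", multiallelic = FALSE,
                       stringsAsFactors = FALSE)
    pm <- stats::setNames(pm, ids)

    truth <- list(freq = p, d_eff = d_eff, config = cfg,
                  kin = data.frame(sample1 = character(),
                                   sample2 = character(),
                                   population = character(),
                                   expected_phi = numeric()))
    gm <- genotype_matrix(calls, loci)
    if (!is.null(cfg$kin_plan)) {
      planted <- plant_kin(gm, pm, cfg$kin_plan, freq = p)
      gm <- planted$gm
      truth$kin <- planted$registry
    }

    miss <- matrix(stats::runif(length(gm$calls)) < cfg$missing_rate,
                   nrow(gm$calls))
    gm$calls[miss] <- NA_integer_
    depth <- matrix(stats::rnbinom(length(gm$calls), mu = cfg$depth_mean,
                                   size = cfg$depth_disp), nrow(gm$calls),
                    dimnames = dimnames(gm$calls))
    depth[is.na(gm$calls)] <- 0L
    gm <- genotype_matrix(gm$calls, gm$loci, depth)
    list(gm = gm, pm = pm, sites = sites, truth = truth)
  })
}

#' Plant full-sibling pairs into a genotype matrix
#'
#' For each planned pair, two parents are drawn from the population's
#' per-locus allele frequencies and two full-sib offspring are produced by
#' Mendelian segregation, replacing two existing members of that
#' population. Expected KING kinship between planted sibs is 0.25.
#'
#' @param gm a [genotype_matrix()] (complete calls).
#' @param pm population map.
#' @param kin_plan named integer vector: number of full-sib pairs per
#'   population.
#' @param freq populations x loci allele-frequency matrix (e.g. from
#'   `simulate_snp_data()` truth).
#' @param seed optional seed.
#' @return list: `gm` with the replacements applied, `registry` data.frame
#'   of planted pairs.
#' @export
plant_kin <- function(gm, pm, kin_plan, freq, seed = NULL) {
  with_seed(seed, {
    pm <- check_popmap(gm, pm)
    registry <- list()
    calls <- gm$calls
    L <- ncol(calls)
    mendel_child <- function(g1, g2) {
      # one allele from each parent: P(transmit alt) = dosage/2
      a1 <- stats::rbinom(L, 1L, g1 / 2)
      a2 <- stats::rbinom(L, 1L, g2 / 2)
      a1 + a2
    }
    for (pop in names(kin_plan)) {
      n_pairs <- kin_plan[[pop]]
      if (n_pairs == 0) next
      members <- which(pm == pop)
      if (2 * n_pairs > length(members))
        stop("kin plan exceeds population size for ", pop)
      slots <- members[seq_len(2 * n_pairs)]
      pf <- freq[pop, ]
      for (q in seq_len(n_pairs)) {
        par1 <- stats::rbinom(L, 2L, pf)
        par2 <- stats::rbinom(L, 2L, pf)
        i <- slots[2 * q - 1]; j <- slots[2 * q]
        calls[i, ] <- mendel_child(par1, par2)
        calls[j, ] <- mendel_child(par1, par2)
        registry[[length(registry) + 1]] <- data.frame(
          sample1 = gm$samples[i], sample2 = gm$samples[j],
          population = pop, expected_phi = 0.25, stringsAsFactors = FALSE)
      }
    }
    list(gm = genotype_matrix(calls, gm$loci, gm$depth),
         registry = if (length(registry)) do.call(rbind, registry) else
           data.frame(sample1 = character(), sample2 = character(),
                      population = character(), expected_phi = numeric()))
  })
}
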