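#' Correlation between marine and aerial connectivity scores
#'
#' Ordinary least squares of aerial score on marine score across the
#' populations of a site table — the check that the two transport networks
#' measure different things before both are tested against genetic
#' differentiation. Populations with an NA score are dropped.
#'
#' @param sites data.frame from [read_sites()].
#' @return list: `r_squared`, `p_value` (F test), `n`.
#' @export
connectivity_correlation <- function(sites) {
  ok <- stats::complete.cases(sites[, c("marine", "aerial")])
  s <- sites[ok, ]
  if (nrow(s) < 3) stop("need at least 3 populations with both scores")
  if (stats::sd(s$marine) == 0 || stats::sd(s$aerial) == 0)
    stop("zero-variance connectivity scores")
  fit <- summary(stats::lm(aerial ~ marine, data = s))
  fs <- fit$fstatistic
  list(r_squared = fit$r.squared,
       p_value = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       n = nrow(s))
}

#' Full landscape-genomic hypothesis tests
#'
#' Runs the study's landscape stage for one species: PCNM transforms of the
#' geographic-distance and connectivity matrices, an isolation-by-distance
#' dbRDA (all geographic PCNM axes as predictors), single-axis screening of
#' the geographic axes at `alpha` to pick conditioning axes, marine and
#' aerial connectivity dbRDAs conditioned on the selected axes, and signed
#' directionality slopes for each predictor.
#'
#' @param fst a [pairwise_matrix()] of F'ST values.
#' @param sites site table covering the same populations (NA-score
#'   populations must already be dropped).
#' @param n_perm permutations per test; default 9999.
#' @param alpha screening threshold for conditioning axes; default 0.01.
#' @param seed integer seed.
#' @return list: `ibd`, `marine`, `aerial` (each a `dbrda_result`),
#'   `conditioning` (selected axes matrix with p-values), `directionality`
#'   (named slopes for geo/marine/aerial), and the bases used.
#' @export
landscape_tests <- function(fst, sites, n_perm = 9999, alpha = 0.01,
                            seed = NULL) {
  sites <- sites[match(rownames(fst), sites$population), ]
  if (anyNA(sites$population))
    stop("site table does not cover all populations of the F'ST matrix")
  d_geo <- geo_distance_matrix(sites)
  m_mar <- connectivity_matrix(sites, "marine")
  m_aer <- connectivity_matrix(sites, "aerial")
  b_geo <- pcnm_basis(d_geo)
  b_mar <- pcnm_basis(m_mar)
  b_aer <- pcnm_basis(m_aer)
  ibd <- dbrda(fst, b_geo, n_perm = n_perm, seed = seed)
  cond <- select_significant_axes(fst, b_geo, alpha = alpha, n_perm = n_perm,
                                  seed = if (is.null(seed)) NULL else seed + 1000)
  cond_use <- if (ncol(cond) > 0) cond else NULL
  marine <- dbrda(fst, b_mar, condition = cond_use, n_perm = n_perm,
                  seed = if (is.null(seed)) NULL else seed + 2000)
  aerial <- dbrda(fst, b_aer, condition = cond_use, n_perm = n_perm,
                  seed = if (is.null(seed)) NULL else seed + 3000)
  list(
    ibd = ibd, marine = marine, aerial = aerial, conditioning = cond,
    directionality = c(
      geo = directionality(fst, d_geo),
      marine = directionality(fst, m_mar),
      aerial = directionality(fst, m_aer)
    ),
    bases = list(geo = b_geo, marine = b_mar, aerial = b_aer)
  )
}

# internal: coerce an ANOVA-style row out of a dbrda_result
dbrda_row <- function(term, res) {
  data.frame(term = term, Df = res$df_model,
             SumOfSquares = res$ss_model, F = res$pseudo_F,
             P = res$permutation_P, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates: input (VCF/popmap/sites or the synthetic generator) ->
#' SNP filters -> kin pruning -> balanced subsampling with per-replicate
#' F'ST and diversity statistics -> DAPC cluster scan -> landscape dbRDAs.
#' Stages can be switched off; each takes its own seed so a re-run of an
#' identical config is identical.
#'
#' @param config a list, or path to a YAML file, with (all optional unless
#'   noted) keys:
#' \describe{
#'   \item{input}{list with `vcf`, `popmap`, `sites` paths — or}
#'   \item{simulate}{list of [sim_config()] arguments plus `seed`; `sites`
#'     may be `"aegypti"`, `"albopictus"` or a TSV path}
#'   \item{filter}{`max_missing`, `min_depth`, `max_depth`, `pop_coverage`}
#'   \item{prune}{`enabled`, `threshold`, `max_per_pop`}
#'   \item{split_population}{list of `label` and `samples`: reassigns the
#'     listed sample ids to a new population label}
#'   \item{subsample}{`n_reps`, `k`, `seed`}
#'   \item{dapc}{`enabled`, `K_max`, `n_starts`, `seed`}
#'   \item{landscape}{`enabled`, `omit` (labels excluded, e.g. an outlier
#'     subpopulation), `n_perm`, `alpha`, `seed`}
#' }
#' @return list of class `run_report` with per-stage results and logs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(...) {
    x <- config
    for (k in c(...)) {
      if (is.null(x[[k]])) return(NULL)
      x <- x[[k]]
    }
    x
  }
  default <- function(x, d) if (is.null(x)) d else x
  report <- list(stages = character(), config = config)
  log_stage <- function(name) {
    message("[", name, "] ...")
    report$stages <<- c(report$stages, name)
  }

  # --- input ---------------------------------------------------------
  if (!is.null(cfg("simulate"))) {
    log_stage("simulate")
    sc <- cfg("simulate")
    sim_seed <- sc$seed; sc$seed <- NULL
    if (is.character(sc$sites))
      sc$sites <- if (sc$sites %in% c("aegypti", "albopictus"))
        aedes_sites(sc$sites) else read_sites(sc$sites)
    sc$n_ind <- default(sc$n_ind, 5)
    if (!is.null(sc$kin_plan)) sc$kin_plan <- unlist(sc$kin_plan)
    sim <- do.call(sim_config, sc)
    out <- simulate_snp_data(sim, seed = default(sim_seed, 1))
    gm <- out$gm; pm <- out$pm; sites <- out$sites
    report$truth <- out$truth
  } else if (!is.null(cfg("input"))) {
    log_stage("input")
    if (is.null(cfg("input", "vcf"))) stop("stage input: no VCF given")
    gm <- read_vcf(cfg("input", "vcf"))
    pm <- read_popmap(cfg("input", "popmap"))
    sites <- if (!is.null(cfg("input", "sites")))
      read_sites(cfg("input", "sites")) else NULL
  } else stop("config must name either 'input' or 'simulate'")

  if (!is.null(cfg("split_population"))) {
    sp <- cfg("split_population")
    pm[unlist(sp$samples)] <- sp$label
  }

  # --- filters -------------------------------------------------------
  log_stage("filter")
  gm <- filter_snps(gm,
                    max_missing = default(cfg("filter", "max_missing"), 0.20),
                    min_depth = default(cfg("filter", "min_depth"), 3),
                    max_depth = default(cfg("filter", "max_depth"), 45))
  report$filter_removed <- attr(gm, "removed")
  gm <- population_coverage_filter(
    gm, pm, min_called = default(cfg("filter", "pop_coverage"), 0.75))
  report$coverage_removed <- attr(gm, "removed_loci")
  if (n_loci(gm) == 0) stop("stage filter: no loci survived")

  # --- kin pruning ---------------------------------------------------
  if (default(cfg("prune", "enabled"), TRUE)) {
    log_stage("prune")
    kin <- king_kinship(gm)
    gm <- prune_kin(gm, pm, kin,
                    first_order_threshold = default(cfg("prune", "threshold"), 0.177),
                    max_per_pop = default(cfg("prune", "max_per_pop"), 18))
    report$pruning_log <- attr(gm, "removal_log")
    pm <- pm[gm$samples]
  }

  # --- balanced subsampling + statistics -----------------------------
  log_stage("stats")
  n_reps <- default(cfg("subsample", "n_reps"), 10)
  reps <- balanced_subsample(gm, pm, n_reps = n_reps,
                             k = cfg("subsample", "k"),
                             seed = default(cfg("subsample", "seed"), 1))
  pops <- sort(unique(pm))
  np <- length(pops)
  fst_reps <- array(NA_real_, c(n_reps, np, np),
                    dimnames = list(NULL, pops, pops))
  div_reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    fst_reps[r, , ] <- unclass(fst_prime_matrix(reps[[r]]$gm, reps[[r]]$pm))
    div_reps[[r]] <- diversity_stats(reps[[r]]$gm, reps[[r]]$pm)
  }
  fst_mean <- apply(fst_reps, c(2, 3), mean)
  report$fst <- pairwise_matrix(fst_mean, semantics = "fst_prime")
  ut <- which(upper.tri(fst_mean), arr.ind = TRUE)
  pair_vals <- apply(ut, 1, function(ij) fst_reps[, ij[1], ij[2]])
  colnames(pair_vals) <- paste(pops[ut[, 1]], pops[ut[, 2]], sep = " - ")
  report$fst_summary <- summarize_subsamples(pair_vals)
  for (stat in c("H_O", "pi", "private_alleles", "missing_fraction")) {
    vals <- do.call(rbind, lapply(div_reps, function(d)
      stats::setNames(d[[stat]], d$population)))
    report$diversity[[stat]] <- summarize_subsamples(vals)
  }

  # --- DAPC ----------------------------------------------------------
  if (default(cfg("dapc", "enabled"), TRUE)) {
    log_stage("dapc")
    message("imputing missing calls with per-locus modal dosage ",
            "(simple completion, not phasing-based imputation)")
    gi <- impute_missing(gm)
    scores <- pca_reduce(gi)
    scan <- find_clusters(scores,
                          K_max = default(cfg("dapc", "K_max"),
                                          min(np, n_samples(gm) - 1)),
                          n_starts = default(cfg("dapc", "n_starts"), 100),
                          seed = default(cfg("dapc", "seed"), 1))
    report$cluster_scan <- scan
    report$dapc <- dapc_assign(scores, scan$assignments)
  }

  # --- landscape -----------------------------------------------------
  if (default(cfg("landscape", "enabled"), TRUE)) {
    if (is.null(sites)) stop("stage landscape: no site table given")
    log_stage("landscape")
    omit <- cfg("landscape", "omit")
    keep <- setdiff(rownames(report$fst), omit)
    fst_l <- pairwise_matrix(unclass(report$fst)[keep, keep],
                             semantics = "fst_prime")
    lt <- landscape_tests(fst_l, sites[match(keep, sites$population), ],
                          n_perm = default(cfg("landscape", "n_perm"), 9999),
                          alpha = default(cfg("landscape", "alpha"), 0.01),
                          seed = default(cfg("landscape", "seed"), 1))
    report$landscape <- lt
    report$anova_table <- rbind(
      dbrda_row("Geographical distance", lt$ibd),
      dbrda_row("Marine connectivity", lt$marine),
      dbrda_row("Aerial connectivity", lt$aerial)
    )
  }

  report$session <- list(package_version = as.character(utils::packageVersion("landgen")),
                         r_version = R.version.string)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("landgen run report — stages:", paste(x$stages, collapse = " -> "), "\n")
  if (!is.null(x$fst))
    cat(sprintf("mean pairwise F'ST over %d populations: %.4f\n",
                nrow(x$fst), mean(x$fst[upper.tri(x$fst)])))
  if (!is.null(x$cluster_scan))
    cat(sprintf("cluster scan: K(BIC) = %d, K(AIC) = %d\n",
                x$cluster_scan$K_bic, x$cluster_scan$K_aic))
  if (!is.null(x$anova_table)) {
    cat("landscape dbRDAs:\n")
    print(x$anova_table, row.names = FALSE)
  }
  invisible(x)
}
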