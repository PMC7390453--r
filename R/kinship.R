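#' KING-robust pairwise kinship
#'
#' Estimates the kinship coefficient phi for every sample pair with the
#' KING-robust between-family estimator, which needs no allele-frequency
#' estimates: over the loci where both samples are called,
#' \deqn{\phi = (N_{het,het} - 2 N_{opp.hom}) / (N_{het}(i) + N_{het}(j))}
#' where \eqn{N_{het,het}} counts loci heterozygous in both, \eqn{N_{opp.hom}}
#' counts opposite homozygotes, and \eqn{N_{het}(i)} counts loci heterozygous
#' in sample i among the shared loci. Expected values: ~0.5 for duplicates,
#' ~0.25 for first-order kin (parent-offspring, full sibs), ~0 for
#' unrelated pairs.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples.
#' @return a list of class `kinship_matrix`: `phi` (symmetric matrix, NA on
#'   the diagonal and for undefined pairs) and `n_shared` (loci used per
#'   pair). Pairs with no shared heterozygous sites have undefined phi and
#'   are flagged in `undefined_pairs`.
#' @export
king_kinship <- function(gm) {
  if (nrow(gm$calls) < 2) stop("need at least 2 samples")
  X <- gm$calls
  M <- (!is.na(X)) * 1       # called indicator
  H <- (!is.na(X) & X == 1L) * 1
  A0 <- (!is.na(X) & X == 0L) * 1
  A2 <- (!is.na(X) & X == 2L) * 1
  n_hethet <- H %*% t(H)
  n_opp <- A0 %*% t(A2) + A2 %*% t(A0)
  n_het_shared <- H %*% t(M)           # het in i among loci called in j
  denom <- n_het_shared + t(n_het_shared)
  phi <- (n_hethet - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  diag(phi) <- NA_real_
  n_shared <- M %*% t(M)
  undef <- which(denom == 0 & upper.tri(denom), arr.ind = TRUE)
  undefined_pairs <- data.frame(
    sample1 = rownames(X)[undef[, 1]],
    sample2 = rownames(X)[undef[, 2]],
    stringsAsFactors = FALSE
  )
  structure(list(phi = phi, n_shared = n_shared,
                 undefined_pairs = undefined_pairs),
            class = "kinship_matrix")
}

#' Prune first-order kin and cap population sample sizes
#'
#' Applies a two-stage greedy rule. Stage 1: while any within-population
#' pair has kinship `phi >= first_order_threshold`, remove the sample with
#' the most missing data among those involved in a flagged pair (ties broken
#' toward the lexicographically later sample id). Stage 2: for any
#' population still holding more than `max_per_pop` samples, remove its
#' highest-missingness samples (same tie rule) until the cap holds.
#'
#' @param gm a [genotype_matrix()]
#' @param pm population map (named character vector)
#' @param kin a `kinship_matrix` from [king_kinship()] covering the samples
#'   of `gm`.
#' @param first_order_threshold kinship cutoff for first-order pairs;
#'   default 0.177 (= 2^-2.5), the conventional boundary between first- and
#'   second-degree relationships.
#' @param max_per_pop maximum genotypes retained per population; default 18.
#' @return pruned [genotype_matrix()] with attribute `removal_log`, a
#'   data.frame (sample, population, reason, phi, missingness).
#' @export
prune_kin <- function(gm, pm, kin, first_order_threshold = 0.177,
                      max_per_pop = 18) {
  if (first_order_threshold <= 0) stop("first_order_threshold must be > 0")
  pm <- check_popmap(gm, pm)
  miss <- sample_missingness(gm)
  phi <- kin$phi[gm$samples, gm$samples, drop = FALSE]
  keep <- gm$samples
  log <- list()

  # order for "most missing, tie -> lexicographically later": sort keys
  worst_of <- function(ids) {
    ids[order(miss[ids], ids, decreasing = TRUE)][1]
  }

  repeat {
    sub <- phi[keep, keep, drop = FALSE]
    same_pop <- outer(pm[keep], pm[keep], "==")
    flagged <- !is.na(sub) & sub >= first_order_threshold & same_pop
    flagged[lower.tri(flagged, diag = TRUE)] <- FALSE
    if (!any(flagged)) break
    involved <- unique(c(keep[row(flagged)[flagged]], keep[col(flagged)[flagged]]))
    victim <- worst_of(involved)
    partners <- keep[which(flagged[match(victim, keep), ] |
                             flagged[, match(victim, keep)])]
    log[[length(log) + 1]] <- data.frame(
      sample = victim, population = unname(pm[victim]), reason = "first_order_kin",
      phi = max(sub[match(victim, keep), ], sub[, match(victim, keep)], na.rm = TRUE),
      missingness = unname(miss[victim]), stringsAsFactors = FALSE
    )
    keep <- setdiff(keep, victim)
  }

  for (pop in unique(pm)) {
    members <- keep[pm[keep] == pop]
    while (length(members) > max_per_pop) {
      victim <- worst_of(members)
      log[[length(log) + 1]] <- data.frame(
        sample = victim, population = pop, reason = "population_cap",
        phi = NA_real_, missingness = unname(miss[victim]),
        stringsAsFactors = FALSE
      )
      members <- setdiff(members, victim)
      keep <- setdiff(keep, victim)
    }
  }

  out <- gm_subset(gm, samples = match(keep, gm$samples))
  attr(out, "removal_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(sample = character(), population = character(),
               reason = character(), phi = numeric(), missingness = numeric())
  out
}
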