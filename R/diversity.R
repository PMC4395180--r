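#' Unbiased within-population gene diversity
#'
#' Nei's unbiased gene (haplotype) diversity for a single population,
#' `h = n/(n-1) * (1 - sum(p_i^2))`; zero for monomorphic samples and for
#' `n = 1`.
#'
#' @param counts haplotype count vector for one population.
#' @return diversity in `[0, 1]`.
#' @export
within_pop_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 1) stop("empty count vector")
  if (n == 1 || length(counts) == 1L) return(0)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Pooled unbiased gene diversity for a group
#'
#' Pools all individuals of one group (species) across its populations and
#' applies the unbiased estimator to the pooled haplotype frequencies.
#'
#' @param ht haplotable with a grouping.
#' @param group group label.
#' @export
pooled_diversity <- function(ht, group) {
  sub <- subset_group(ht, group)
  pooled <- colSums(sub$counts)
  if (sum(pooled) < 2) stop("group has fewer than 2 individuals")
  within_pop_diversity(pooled)
}

#' Unordered diversity statistics (H_S, H_T, G_ST)
#'
#' Pons & Petit style estimators for haplotype frequency data over K
#' populations. `H_S` is the unweighted mean of per-population unbiased
#' diversities. `H_T` is the unbiased total diversity built from the
#' unweighted mean haplotype frequencies `xbar_i`, corrected for the sampling
#' variance of those means: `H_T = 1 - sum(xbar_i^2) + (1/K) sum_i s_i^2`,
#' where `s_i^2` is the sample variance of haplotype `i`'s frequency across
#' populations. `G_ST = (H_T - H_S)/H_T`.
#'
#' @param ht haplotable (K >= 2 populations).
#' @return list with `H_S`, `H_T`, `G_ST`, `K`, `n_tilde` (harmonic mean
#'   sample size).
#' @export
unordered_stats <- function(ht) {
  counts <- ht$counts
  K <- nrow(counts)
  if (K < 2) stop("need at least 2 populations")
  n_k <- rowSums(counts)
  if (any(n_k == 0)) stop("population with zero individuals")
  p <- counts / n_k
  H_S <- mean(apply(counts, 1L, within_pop_diversity))
  xbar <- colMeans(p)
  s2 <- apply(p, 2L, var)
  H_T <- 1 - sum(xbar^2) + sum(s2) / K
  G_ST <- if (H_T > 0) (H_T - H_S) / H_T else NA_real_
  list(H_S = H_S, H_T = H_T, G_ST = G_ST, K = K, n_tilde = K / sum(1 / n_k))
}

#' Ordered diversity statistics (v_S, v_T, N_ST)
#'
#' Distance-weighted analogues of [unordered_stats()]: haplotype pairs are
#' weighted by their genetic distance `pi_ij` instead of the 0/1 mismatch
#' kernel. Within-population diversity becomes
#' `v_k = n/(n-1) * sum_ij pi_ij p_ik p_jk`, and the total uses the unbiased
#' covariance correction `v_T = sum_ij pi_ij xbar_i xbar_j -
#' (1/K) sum_ij pi_ij Chat_ij` with `Chat` the across-population frequency
#' covariance matrix. Under unit distances these reduce exactly to the
#' unordered statistics.
#'
#' @param ht haplotable.
#' @param dm haplotype distance matrix covering all haplotypes of `ht`.
#' @return list with `v_S`, `v_T`, `N_ST`.
#' @export
ordered_stats <- function(ht, dm) {
  counts <- ht$counts
  haps <- colnames(counts)
  if (!all(haps %in% rownames(dm))) stop("distance matrix does not cover all haplotypes")
  pim <- as.matrix(dm)[haps, haps]
  K <- nrow(counts)
  if (K < 2) stop("need at least 2 populations")
  n_k <- rowSums(counts)
  p <- counts / n_k
  v_k <- vapply(seq_len(K), function(k) {
    n <- n_k[k]
    if (n < 2) return(0)
    n / (n - 1) * drop(p[k, ] %*% pim %*% p[k, ])
  }, numeric(1))
  v_S <- mean(v_k)
  xbar <- colMeans(p)
  Chat <- cov(p)                      # (K-1)-denominator covariance across populations
  v_T <- drop(xbar %*% pim %*% xbar) - sum(pim * Chat) / K
  N_ST <- if (v_T > 0) (v_T - v_S) / v_T else NA_real_
  list(v_S = v_S, v_T = v_T, N_ST = N_ST)
}

#' Permutation contrast test of N_ST against distance-free structure
#'
#' Randomly relabels haplotype identities on the distance matrix `n_perm`
#' times and recomputes `N_ST` each time; the observed `N_ST` exceeding the
#' permuted ones indicates that genetically similar haplotypes co-occur
#' (phylogeographic structure). `p = (1 + #{N_ST_perm >= N_ST_obs}) /
#' (n_perm + 1)`.
#'
#' @param ht haplotable.
#' @param dm haplotype distance matrix.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return list with `N_ST`, `G_ST`, `p`.
#' @export
permut_test <- function(ht, dm, n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 1)
  haps <- colnames(ht$counts)
  pim <- as.matrix(dm)[haps, haps]
  if (all(pim == 0)) stop("degenerate distance matrix (all zero)")
  obs <- ordered_stats(ht, pim)$N_ST
  k <- length(haps)
  perm_vals <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    o <- sample.int(k)
    pm2 <- pim[o, o, drop = FALSE]
    dimnames(pm2) <- list(haps, haps)
    ordered_stats(ht, pm2)$N_ST
  }, numeric(1)))
  p <- (1 + sum(perm_vals >= obs, na.rm = TRUE)) / (n_perm + 1)
  list(N_ST = obs, G_ST = unordered_stats(ht)$G_ST, p = p)
}

#' Full diversity report per group and overall
#'
#' Computes H_S, H_T, G_ST (and, given a distance matrix, v_S, v_T, N_ST with
#' the permutation contrast p-value) for each group of a haplotype table and
#' for all populations combined, mirroring the layout used in chloroplast
#' phylogeography papers.
#'
#' @param ht haplotable with grouping.
#' @param dm optional haplotype distance matrix.
#' @param n_perm permutations for the contrast test.
#' @param seed RNG seed.
#' @return data frame with one row per group plus `Total`.
#' @export
diversity_stats <- function(ht, dm = NULL, n_perm = 1000, seed = NULL) {
  blocks <- list()
  if (!is.null(ht$grouping)) for (g in unique(ht$grouping)) blocks[[g]] <- subset_group(ht, g)
  blocks[["Total"]] <- ht
  rows <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    u <- unordered_stats(b)
    row <- data.frame(group = nm, K = u$K, H_S = u$H_S, H_T = u$H_T, G_ST = u$G_ST,
                      v_S = NA_real_, v_T = NA_real_, N_ST = NA_real_, p_perm = NA_real_)
    if (!is.null(dm)) {
      o <- ordered_stats(b, dm)
      row$v_S <- o$v_S; row$v_T <- o$v_T; row$N_ST <- o$N_ST
      sub_dm <- as.matrix(dm)[colnames(b$counts), colnames(b$counts)]
      if (any(sub_dm > 0))
        row$p_perm <- permut_test(b, sub_dm, n_perm = n_perm, seed = seed)$p
    }
    row
  })
  do.call(rbind, rows)
}
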