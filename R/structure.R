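# Sums of squares for a set of individuals partitioned by a factor, from a
# matrix of *squared* inter-haplotype distances and per-individual haplotype
# indices. SS(total, within a partition cell) = sum_{i<j in cell} d2 / n_cell.
.ss_within <- function(d2, hap_idx, cell) {
  ss <- 0
  for (cl in unique(cell)) {
    sel <- hap_idx[cell == cl]
    cnt <- tabulate(sel, nbins = nrow(d2))
    ss <- ss + drop(cnt %*% d2 %*% cnt) / (2 * length(sel))
  }
  ss
}

.amova_one_level <- function(d2, hap_idx, pop) {
  N <- length(hap_idx)
  pops <- unique(pop)
  K <- length(pops)
  n_k <- as.vector(table(factor(pop, levels = pops)))
  cnt_tot <- tabulate(hap_idx, nbins = nrow(d2))
  ss_tot <- drop(cnt_tot %*% d2 %*% cnt_tot) / (2 * N)
  ss_wp <- .ss_within(d2, hap_idx, pop)
  ss_ap <- ss_tot - ss_wp
  df_ap <- K - 1L; df_wp <- N - K
  sigma_w <- if (df_wp > 0) ss_wp / df_wp else 0
  n_prime <- (N - sum(n_k^2) / N) / df_ap
  sigma_a <- (ss_ap / df_ap - sigma_w) / n_prime
  tot <- sigma_a + sigma_w
  phi <- if (tot > 0) sigma_a / tot else NA_real_
  list(ss = c(among = ss_ap, within = ss_wp, total = ss_tot),
       df = c(among = df_ap, within = df_wp, total = N - 1L),
       sigma = c(among = sigma_a, within = sigma_w),
       phi_st = phi)
}

.amova_two_level <- function(d2, hap_idx, pop, grp_of_pop) {
  N <- length(hap_idx)
  pops <- unique(pop)
  K <- length(pops)
  grp <- grp_of_pop[pop]
  groups <- unique(grp_of_pop[pops])
  G <- length(groups)
  n_k <- as.vector(table(factor(pop, levels = pops)))
  N_g <- as.vector(table(factor(grp, levels = groups)))

  cnt_tot <- tabulate(hap_idx, nbins = nrow(d2))
  ss_tot <- drop(cnt_tot %*% d2 %*% cnt_tot) / (2 * N)
  ss_wp <- .ss_within(d2, hap_idx, pop)
  ss_wg <- .ss_within(d2, hap_idx, grp)     # total SS within each group
  ss_ap_wg <- ss_wg - ss_wp
  ss_ag <- ss_tot - ss_wg

  df_ag <- G - 1L; df_ap <- K - G; df_wp <- N - K
  # expected mean square coefficients (Excoffier et al. 1992)
  sum_nk2_within_g <- vapply(groups, function(g) {
    sel <- grp_of_pop[pops] == g
    sum(n_k[sel]^2) / sum(n_k[sel])
  }, numeric(1))
  n1 <- (N - sum(sum_nk2_within_g)) / df_ap
  n2 <- (sum(sum_nk2_within_g) - sum(n_k^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag

  sigma_c <- if (df_wp > 0) ss_wp / df_wp else 0
  sigma_b <- (ss_ap_wg / df_ap - sigma_c) / n1
  sigma_a <- (ss_ag / df_ag - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  list(ss = c(among_groups = ss_ag, among_pops = ss_ap_wg, within = ss_wp, total = ss_tot),
       df = c(among_groups = df_ag, among_pops = df_ap, within = df_wp, total = N - 1L),
       sigma = c(among_groups = sigma_a, among_pops = sigma_b, within = sigma_c),
       phi = c(phi_ct = if (tot > 0) sigma_a / tot else NA_real_,
               phi_sc = if (sigma_b + sigma_c > 0) sigma_b / (sigma_b + sigma_c) else NA_real_,
               phi_st = if (tot > 0) (sigma_a + sigma_b) / tot else NA_real_))
}

# expand a haplotype table into per-individual haplotype index / population
.expand_individuals <- function(ht) {
  counts <- ht$counts
  hap_idx <- integer(0); pop <- character(0)
  for (k in seq_len(nrow(counts))) for (h in seq_len(ncol(counts))) {
    c_ <- counts[k, h]
    if (c_ > 0) {
      hap_idx <- c(hap_idx, rep.int(h, c_))
      pop <- c(pop, rep.int(rownames(counts)[k], c_))
    }
  }
  list(hap_idx = hap_idx, pop = pop)
}

#' Distance-based analysis of molecular variance
#'
#' Excoffier-Quattro-Smouse decomposition of squared inter-individual
#' distances (individuals inherit the distance between their haplotype
#' representatives, so members of one haplotype sit at distance zero) into
#' hierarchical variance components with Phi fixation indices. One level
#' partitions populations; two levels add a grouping (species) above them.
#' Significance is assessed by permuting individuals among populations
#' (within groups, for the two-level design) for `Phi_ST`/`Phi_SC`, and by
#' permuting whole populations among groups for `Phi_CT`.
#'
#' @param ht haplotable (its grouping supplies the two-level design).
#' @param dm haplotype distance matrix (squared internally).
#' @param levels 1 or 2.
#' @param n_perm permutations for p-values (0 to skip).
#' @param seed RNG seed.
#' @return object of class `amova`: `table` (source, df, SS, variance,
#'   percent), `phi`, `p`.
#' @export
amova <- function(ht, dm, levels = if (!is.null(ht$grouping) && length(unique(ht$grouping)) > 1) 2 else 1,
                  n_perm = 0, seed = NULL) {
  stopifnot(inherits(ht, "haplotable"))
  haps <- colnames(ht$counts)
  d2 <- (as.matrix(dm)[haps, haps, drop = FALSE])^2
  ex <- .expand_individuals(ht)
  if (levels == 1) {
    if (nrow(ht$counts) < 2) stop("need at least 2 populations")
    res <- .amova_one_level(d2, ex$hap_idx, ex$pop)
    sig <- res$sigma
    if (any(sig < 0)) warning("negative variance component reported as-is")
    tot_var <- sum(sig)
    tab <- data.frame(
      source = c("Among populations", "Within populations", "Total"),
      df = as.integer(res$df),
      SS = as.numeric(res$ss),
      variance = c(sig, sum(sig)),
      percent = c(if (tot_var != 0) 100 * sig / tot_var else rep(NA_real_, 2), NA))
    phi <- c(phi_st = res$phi_st)
    p <- NULL
    if (n_perm > 0 && is.finite(res$phi_st)) {
      perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
        .amova_one_level(d2, sample(ex$hap_idx), ex$pop)$phi_st
      }, numeric(1)))
      p <- c(phi_st = (1 + sum(perm >= res$phi_st, na.rm = TRUE)) / (n_perm + 1))
    }
  } else {
    if (is.null(ht$grouping)) stop("two-level design needs a grouping")
    grp_of_pop <- ht$grouping
    if (length(unique(grp_of_pop)) < 2) stop("need at least 2 groups")
    res <- .amova_two_level(d2, ex$hap_idx, ex$pop, grp_of_pop)
    sig <- res$sigma
    if (any(sig < 0)) warning("negative variance component reported as-is")
    tot_var <- sum(sig)
    tab <- data.frame(
      source = c("Among groups", "Among populations within groups",
                 "Within populations", "Total"),
      df = as.integer(res$df),
      SS = as.numeric(res$ss),
      variance = c(sig, sum(sig)),
      percent = c(if (tot_var != 0) 100 * sig / tot_var else rep(NA_real_, 3), NA))
    phi <- res$phi
    p <- NULL
    if (n_perm > 0) {
      stats <- with_seed(seed, {
        vapply(seq_len(n_perm), function(i) {
          # individuals among populations within groups -> Phi_SC, Phi_ST
          grp_ind <- grp_of_pop[ex$pop]
          idx <- ex$hap_idx
          for (g in unique(grp_ind)) {
            sel <- which(grp_ind == g)
            idx[sel] <- idx[sample(sel)]
          }
          r1 <- .amova_two_level(d2, idx, ex$pop, grp_of_pop)
          # whole populations among groups -> Phi_CT
          g2 <- setNames(sample(unname(grp_of_pop)), names(grp_of_pop))
          r2 <- .amova_two_level(d2, ex$hap_idx, ex$pop, g2)
          c(r1$phi[["phi_sc"]], r1$phi[["phi_st"]], r2$phi[["phi_ct"]])
        }, numeric(3))
      })
      p <- c(phi_ct = (1 + sum(stats[3, ] >= phi[["phi_ct"]], na.rm = TRUE)) / (n_perm + 1),
             phi_sc = (1 + sum(stats[1, ] >= phi[["phi_sc"]], na.rm = TRUE)) / (n_perm + 1),
             phi_st = (1 + sum(stats[2, ] >= phi[["phi_st"]], na.rm = TRUE)) / (n_perm + 1))
    }
  }
  structure(list(table = tab, phi = phi, p = p, levels = levels), class = "amova")
}

#' @export
print.amova <- function(x, digits = 3, ...) {
  cat("AMOVA (", x$levels, "-level)\n", sep = "")
  tab <- x$table
  tab$SS <- round(tab$SS, digits); tab$variance <- round(tab$variance, digits)
  tab$percent <- round(tab$percent, 2)
  print(tab, row.names = FALSE)
  cat("Phi: ", paste(names(x$phi), round(x$phi, 3), sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$p))
    cat("P:   ", paste(names(x$p), signif(x$p, 3), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise population differentiation
#'
#' Two-population one-level AMOVA for every population pair.
#'
#' @param ht haplotable.
#' @param dm haplotype distance matrix.
#' @return symmetric matrix of pairwise Phi_ST (diagonal 0, `NA` where a pair
#'   is fixed for the same haplotype).
#' @export
pairwise_phist <- function(ht, dm) {
  pops <- rownames(ht$counts)
  K <- length(pops)
  if (K < 2) stop("need at least 2 populations")
  out <- matrix(0, K, K, dimnames = list(pops, pops))
  d2 <- (as.matrix(dm)[colnames(ht$counts), colnames(ht$counts), drop = FALSE])^2
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    sub <- ht$counts[c(i, j), , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    ht2 <- haplotype_table(sub)
    ex <- .expand_individuals(ht2)
    dd <- d2[colnames(sub), colnames(sub), drop = FALSE]
    r <- .amova_one_level(dd, ex$hap_idx, ex$pop)
    out[i, j] <- out[j, i] <- r$phi_st
  }
  out
}

#' Great-circle distances between populations
#'
#' Haversine distances on a sphere of radius 6371 km between population
#' coordinates.
#'
#' @param coords data frame with `population`, `lat`, `lon` columns (e.g.
#'   [population_coords()]).
#' @return symmetric matrix of kilometres.
#' @export
greatcircle_km <- function(coords) {
  if (any(is.na(coords$lat) | is.na(coords$lon))) stop("missing coordinates")
  m <- geosphere::distm(cbind(coords$lon, coords$lat),
                        fun = function(a, b) geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(m) <- list(coords$population, coords$population)
  m
}

#' Mantel test
#'
#' Pearson correlation between the upper triangles of two distance matrices,
#' with a one-tailed permutation p-value obtained by simultaneous row/column
#' permutation of the second matrix. With `transform = "log"` the second
#' (geographic) matrix is natural-log transformed and zero-distance pairs are
#' dropped pairwise, the convention for isolation-by-distance regressions.
#'
#' @param X genetic distance matrix.
#' @param Y geographic (or other) distance matrix.
#' @param n_perm random permutations; when `exhaustive = TRUE` (or `n_perm`
#'   is at least `factorial(n)`) all permutations are enumerated and the
#'   p-value is exact.
#' @param seed RNG seed.
#' @param transform `"none"` or `"log"` (applied to `Y`).
#' @param floor_zero floor negative entries of `X` at zero before
#'   correlating (practical for Phi_ST input).
#' @param exhaustive force exact enumeration.
#' @return list with `r`, `r2`, `p`, `n_perm`, `exhaustive`.
#' @export
mantel_test <- function(X, Y, n_perm = 999, seed = NULL,
                        transform = c("none", "log"), floor_zero = FALSE,
                        exhaustive = FALSE) {
  transform <- match.arg(transform)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(all(dim(X) == dim(Y)), n >= 3)
  if (floor_zero) X <- pmax(X, 0)
  ut <- upper.tri(X)
  stat <- function(Xm) {
    ok <- ut & is.finite(Xm) & is.finite(Y)         # pairwise deletion of missing
    if (transform == "log") ok <- ok & Y > 0
    x <- Xm[ok]
    y <- Y[ok]
    if (transform == "log") y <- log(y)
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance in Mantel input")
    cor(x, y)
  }
  r_obs <- stat(X)
  if (exhaustive || n_perm + 1 >= factorial(n)) {
    perms <- .permutations(n)
    vals <- apply(perms, 1L, function(o) stat(X[o, o]))
    p <- mean(vals >= r_obs - 1e-12)
    n_used <- nrow(perms); exh <- TRUE
  } else {
    vals <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      o <- sample.int(n)
      stat(X[o, o])
    }, numeric(1)))
    p <- (1 + sum(vals >= r_obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm; exh <- FALSE
  }
  list(r = r_obs, r2 = r_obs^2, p = p, n_perm = n_used, exhaustive = exh)
}

# all permutations of 1..n as a matrix (n small)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
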