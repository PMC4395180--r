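# pairwise character-difference matrix between individuals of a recoded
# matrix (pairwise deletion of missing characters); only variable columns
# can contribute, so the computation is restricted to them
.pairwise_diffs <- function(rm, subset = NULL, substitutions_only = FALSE) {
  m <- rm$mat
  if (substitutions_only) m <- m[, rm$kind == "nuc", drop = FALSE]
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("need at least 2 individuals")
  keep <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]; length(unique(v[!is.na(v)])) > 1L
  }, logical(1))
  m <- m[, keep, drop = FALSE]
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    neq <- outer(v, v, "!=")
    neq[!ok, ] <- FALSE; neq[, !ok] <- FALSE
    D <- D + neq
  }
  D
}

#' Observed mismatch distribution
#'
#' Histogram of pairwise character differences over all unordered pairs of
#' individuals, normalised to probabilities over classes `0..max`.
#'
#' @param rm a [recode_indels()] result (or any object with `mat`/`kind`).
#' @param subset optional individual ids.
#' @param substitutions_only drop binary indel characters first.
#' @return numeric vector of probabilities; attribute `pi` holds the mean
#'   pairwise difference.
#' @export
mismatch_observed <- function(rm, subset = NULL, substitutions_only = FALSE) {
  D <- .pairwise_diffs(rm, subset, substitutions_only)
  d <- D[upper.tri(D)]
  obs <- tabulate(d + 1L, nbins = max(d) + 1L) / length(d)
  names(obs) <- 0:(length(obs) - 1L)
  attr(obs, "pi") <- mean(d)
  obs
}

# geometric equilibrium mismatch for scaled size theta
.f_geom <- function(i, theta) theta^i / (1 + theta)^(i + 1)

#' Expected mismatch distribution under an expansion model
#'
#' Sudden demographic expansion (Rogers-Harpending): a population at scaled
#' size `theta0` grows instantaneously to `theta1` at mutational time `tau`
#' before the present. Spatial expansion: at time `tau` an ancestral
#' population of size `theta0` colonises infinitely many demes of size
#' `theta1` exchanging migrants at scaled rate `M`; lineages sampled in one
#' deme coalesce only while together. Both give closed forms via incomplete
#' gamma functions.
#'
#' @param i_max largest difference class.
#' @param tau expansion time in mutational units.
#' @param theta0,theta1 pre-/post-expansion scaled sizes.
#' @param model `"demographic"` or `"spatial"`.
#' @param M scaled migration rate (spatial model).
#' @return probabilities for classes `0..i_max` (tail mass beyond `i_max` is
#'   not folded in).
#' @export
expected_mismatch <- function(i_max, tau, theta0, theta1,
                              model = c("demographic", "spatial"), M = 1) {
  model <- match.arg(model)
  i <- 0:i_max
  if (model == "demographic") {
    rate <- (1 + theta1) / theta1
    term1 <- .f_geom(i, theta1) * pgamma(tau * rate, shape = i + 1)
    surv <- exp(-tau / theta1)
  } else {
    rate <- (theta1 + 1 + M) / theta1
    term1 <- theta1^i / (theta1 + 1 + M)^(i + 1) * pgamma(tau * rate, shape = i + 1)
    surv <- 1 - (1 - exp(-(1 + M) * tau / theta1)) / (1 + M)
  }
  pois <- stats::dpois(i, tau)
  anc <- .f_geom(i, theta0)
  term2 <- surv * vapply(i, function(k) sum(pois[1:(k + 1)] * anc[(k + 1):1]), numeric(1))
  term1 + term2
}

#' Harpending's raggedness index
#'
#' Sum of squared successive differences of the mismatch probabilities. The
#' default convention pads the distribution with zero classes on both sides
#' (so an isolated spike contributes both an entering and a leaving step);
#' `trailing = FALSE` drops the final step to zero, the variant some programs
#' use.
#'
#' @param obs probability vector over difference classes.
#' @param trailing include the final step down to zero.
#' @export
raggedness <- function(obs, trailing = TRUE) {
  stopifnot(length(obs) >= 1)
  x <- if (trailing) c(0, obs, 0) else c(0, obs)
  sum(diff(x)^2)
}

#' Fit an expansion model to a mismatch distribution
#'
#' Minimises the sum of squared deviations between observed and expected
#' mismatch probabilities over `(tau, theta0, theta1)` (plus `M` for the
#' spatial model): a coarse log-spaced grid locates the basin, then `nlminb`
#' refines within bounds. Deterministic.
#'
#' @param obs observed probability vector (classes `0..d`).
#' @param model `"demographic"` or `"spatial"`.
#' @return object of class `mismatch_fit` with elements `tau`, `theta0`,
#'   `theta1`, `M`, `SSD`, `raggedness`, `expected`, `converged`.
#' @export
fit_expansion <- function(obs, model = c("demographic", "spatial")) {
  model <- match.arg(model)
  stopifnot(all(obs >= 0), abs(sum(obs) - 1) < 1e-6)
  i_max <- length(obs) - 1L
  mean_d <- sum((0:i_max) * obs)
  ssd_of <- function(par) {
    e <- expected_mismatch(i_max, par[1], par[2], par[3], model = model,
                           M = if (model == "spatial") par[4] else 1)
    sum((obs - e)^2)
  }
  tau_grid <- unique(c(0.01, 0.1, 0.5, 1, 2, 4, 8, max(2 * mean_d, 1)))
  th_grid <- c(1e-4, 0.01, 0.1, 1, 10, 100)
  M_grid <- if (model == "spatial") c(0.1, 1, 10) else NA
  best <- NULL; best_val <- Inf
  for (tau in tau_grid) for (t0 in th_grid) for (t1 in th_grid) for (M in M_grid) {
    par <- c(tau, t0, t1, if (model == "spatial") M)
    v <- ssd_of(par)
    if (v < best_val) { best_val <- v; best <- par }
  }
  lower <- c(1e-8, 1e-8, 1e-8, if (model == "spatial") 1e-4)
  upper <- c(500, 500, 5000, if (model == "spatial") 1e4)
  opt <- nlminb(best, ssd_of, lower = lower, upper = upper)
  par <- opt$par
  e <- expected_mismatch(i_max, par[1], par[2], par[3], model = model,
                         M = if (model == "spatial") par[4] else 1)
  structure(list(model = model, tau = par[1], theta0 = par[2], theta1 = par[3],
                 M = if (model == "spatial") par[4] else NA_real_,
                 SSD = opt$objective, raggedness = raggedness(obs),
                 observed = obs, expected = e,
                 converged = opt$convergence == 0), class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat("Mismatch", x$model, "expansion fit:\n")
  cat(sprintf("  tau = %.3g  theta0 = %.3g  theta1 = %.3g%s\n", x$tau, x$theta0,
              x$theta1, if (!is.na(x$M)) sprintf("  M = %.3g", x$M) else ""))
  cat(sprintf("  SSD = %.4g  raggedness = %.4g\n", x$SSD, x$raggedness))
  invisible(x)
}

#' @export
plot.mismatch_fit <- function(x, ...) {
  i <- seq_along(x$observed) - 1L
  graphics::plot(i, x$observed, type = "b", lty = 2, xlab = "Pairwise differences",
                 ylab = "Frequency", ...)
  graphics::lines(i, x$expected, type = "l")
  graphics::legend("topright", legend = c("observed", "expected"),
                   lty = c(2, 1), bty = "n")
  invisible(x)
}

# single-population coalescent sample in mutational units: theta(t) = theta1
# before tau, theta0 after (demographic), or the infinite-island spatial
# expansion; returns the vector of pairwise difference counts
.sim_mismatch_sample <- function(n, tau, theta0, theta1,
                                 model = "demographic", M = 1) {
  id <- seq_len(n)
  deme <- rep(1L, n)               # spatial model: sampled from one deme
  next_deme <- 2L
  t_now <- 0
  parent <- integer(2 * n - 1); t_node <- numeric(2 * n - 1)
  nxt <- n + 1L
  repeat {
    k <- length(id)
    if (k == 1L) break
    if (t_now < tau) {
      if (model == "demographic") {
        rate_c <- k * (k - 1) / 2 / theta1
        rate_m <- 0
      } else {
        tab <- table(deme)
        pairs_same <- sum(tab * (tab - 1) / 2)
        rate_c <- pairs_same / theta1
        rate_m <- k * M / (2 * theta1)
      }
      rate <- rate_c + rate_m
      dt <- if (rate > 0) rexp(1, rate) else Inf
      if (t_now + dt >= tau) { t_now <- tau } else {
        t_now <- t_now + dt
        if (runif(1) < rate_m / rate) {
          # a migrant moves to a brand-new deme (infinite islands)
          i <- sample.int(k, 1)
          deme[i] <- next_deme; next_deme <- next_deme + 1L
          next
        }
        # coalesce a random same-deme pair
        if (model == "demographic") {
          pr <- sample.int(k, 2)
        } else {
          tab <- table(deme)
          cand <- as.integer(names(tab)[tab >= 2])
          w <- tab[tab >= 2] * (tab[tab >= 2] - 1) / 2
          dm_pick <- cand[sample.int(length(cand), 1, prob = w)]
          pr <- sample(which(deme == dm_pick), 2)
        }
        t_node[nxt] <- t_now
        parent[id[pr]] <- nxt
        id <- c(id[-pr], nxt); deme <- c(deme[-pr], deme[pr[1]])
        nxt <- nxt + 1L
        next
      }
    }
    # ancestral epoch: one panmictic population of size theta0
    k <- length(id)
    t_now <- max(t_now, tau) + rexp(1, k * (k - 1) / 2 / theta0)
    pr <- sample.int(k, 2)
    t_node[nxt] <- t_now
    parent[id[pr]] <- nxt
    id <- c(id[-pr], nxt); deme <- c(deme[-pr], 1L)
    nxt <- nxt + 1L
  }
  root <- id[1]
  # mutations: Poisson(branch length / 2) per branch, infinite sites
  muts <- vector("list", 2 * n - 1)
  for (v in seq_len(root - 1L)) {
    len <- t_node[parent[v]] - (if (v <= n) 0 else t_node[v])
    m <- rpois(1, len / 2)
    if (m > 0) muts[[v]] <- m
  }
  # accumulate per-tip mutation counts of shared/unique sites via sets:
  # represent each branch's mutations as distinct site ids
  site <- 0L
  tip_sites <- vector("list", n)
  below <- vector("list", 2 * n - 1)
  for (v in seq_len(n)) below[[v]] <- v
  ord <- order(t_node[(n + 1L):(2L * n - 1L)]) + n
  for (v in ord) below[[v]] <- unlist(below[which(parent == v)])
  for (v in seq_len(2L * n - 2L)) {
    if (is.null(muts[[v]])) next
    ids <- site + seq_len(muts[[v]]); site <- site + muts[[v]]
    for (tp in below[[v]]) tip_sites[[tp]] <- c(tip_sites[[tp]], ids)
  }
  d <- numeric(n * (n - 1) / 2)
  idx <- 1L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- tip_sites[[i]]; b <- tip_sites[[j]]
    d[idx] <- length(a) + length(b) - 2 * length(intersect(a, b))
    idx <- idx + 1L
  }
  d
}

#' Parametric bootstrap p-values for SSD and raggedness
#'
#' Simulates `n_boot` coalescent samples of size `n` under the fitted
#' expansion, refits the model to each simulated mismatch distribution
#' (honest null: parameters re-estimated per replicate), and returns the
#' proportion of simulated SSD / raggedness values at least as large as the
#' observed ones.
#'
#' @param fitted a [fit_expansion()] result.
#' @param n sample size to simulate.
#' @param n_boot bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return list with `p_SSD`, `p_rag`.
#' @export
bootstrap_p <- function(fitted, n, n_boot = 100, seed = NULL) {
  stopifnot(inherits(fitted, "mismatch_fit"), n_boot >= 1)
  sims <- with_seed(seed, lapply(seq_len(n_boot), function(b) {
    d <- .sim_mismatch_sample(n, fitted$tau, fitted$theta0, fitted$theta1,
                              model = fitted$model, M = if (is.na(fitted$M)) 1 else fitted$M)
    obs <- tabulate(d + 1L, nbins = max(d) + 1L) / length(d)
    f <- fit_expansion(obs, model = fitted$model)
    c(f$SSD, raggedness(obs))
  }))
  ssd <- vapply(sims, `[`, numeric(1), 1L)
  rag <- vapply(sims, `[`, numeric(1), 2L)
  list(p_SSD = mean(ssd >= fitted$SSD), p_rag = mean(rag >= fitted$raggedness))
}

#' Tajima's D
#'
#' @param S number of segregating characters.
#' @param pi mean pairwise differences.
#' @param n sample size (>= 4).
#' @return `D`; attribute `undefined` is `TRUE` when `S = 0` (then `D = 0`).
#' @export
tajimas_d <- function(S, pi, n) {
  stopifnot(n >= 4, S >= 0)
  if (S == 0) return(structure(0, undefined = TRUE))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  structure((pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)), undefined = FALSE)
}

# log P(K = k | theta, n) under the Ewens sampling formula, vectorised over k
.log_ewens <- function(k, theta, n) {
  ls <- log_stirling_row(n)
  ls[k + 1L] + k * log(theta) - sum(log(theta + 0:(n - 1)))
}

#' Fu's F_S
#'
#' `S' = P(K >= k_obs | theta = pi)` under the Ewens sampling formula (log
#' space Stirling numbers of the first kind), and `F_S = ln(S'/(1 - S'))`.
#'
#' @param n sample size.
#' @param k_obs observed number of haplotypes.
#' @param pi mean pairwise differences (used as theta).
#' @return `F_S`; `+Inf` with attribute `undefined = TRUE` when `k_obs = 1`
#'   or `theta = 0` (S' = 1 exactly).
#' @export
fus_fs <- function(n, k_obs, pi) {
  stopifnot(n >= 2, k_obs >= 1, k_obs <= n)
  if (k_obs == 1L || pi <= 0) return(structure(Inf, undefined = TRUE))
  lp <- vapply(seq_len(n), .log_ewens, numeric(1), theta = pi, n = n)
  p_lt <- exp(logsumexp(lp[seq_len(k_obs - 1L)]))   # P(K < k_obs)
  p_lt <- min(max(p_lt, 1e-300), 1 - 1e-16)
  structure(log((1 - p_lt) / p_lt), undefined = FALSE)
}

#' Simulation p-value for a neutrality statistic
#'
#' Simulates constant-size neutral coalescent samples conditioned on
#' `theta = pi`, recomputes the statistic, and compares with the observed
#' value: two-tailed via quantiles for Tajima's D, lower-tailed
#' (`P(Fs_sim <= Fs_obs)`) for Fu's F_S, where population expansion pushes
#' the statistic negative.
#'
#' @param stat `"D"` or `"Fs"`.
#' @param observed observed statistic.
#' @param n sample size.
#' @param theta scaled mutation parameter for the null (use the observed pi).
#' @param n_sim simulations (>= 1).
#' @param seed RNG seed.
#' @return p-value.
#' @export
neutrality_p <- function(stat = c("D", "Fs"), observed, n, theta, n_sim = 1000,
                         seed = NULL) {
  stat <- match.arg(stat)
  stopifnot(n_sim >= 1)
  sims <- with_seed(seed, vapply(seq_len(n_sim), function(b) {
    g <- .sim_scaled_genotypes(n, theta)
    pi_s <- mean(.geno_pairwise(g))
    S_s <- ncol(g)
    if (stat == "D") {
      if (S_s == 0) 0 else as.numeric(tajimas_d(S_s, pi_s, n))
    } else {
      k_s <- length(unique(.hap_key(g)))
      v <- fus_fs(n, k_s, pi_s)
      if (is.infinite(v)) 20 else as.numeric(v)
    }
  }, numeric(1)))
  obs <- if (is.infinite(observed)) 20 else observed
  if (stat == "D") {
    lo <- (1 + sum(sims <= obs)) / (n_sim + 1)
    hi <- (1 + sum(sims >= obs)) / (n_sim + 1)
    min(1, 2 * min(lo, hi))
  } else {
    (1 + sum(sims <= obs)) / (n_sim + 1)
  }
}

# constant-size coalescent genotypes (infinite sites) in mutational units:
# returns an n x S binary matrix (S may be 0)
.sim_scaled_genotypes <- function(n, theta) {
  id <- seq_len(n)
  t_now <- 0
  parent <- integer(2 * n - 1); t_node <- numeric(2 * n - 1)
  nxt <- n + 1L
  while (length(id) > 1L) {
    k <- length(id)
    t_now <- t_now + rexp(1, k * (k - 1) / 2 / theta)
    pr <- sample.int(k, 2)
    t_node[nxt] <- t_now
    parent[id[pr]] <- nxt
    id <- c(id[-pr], nxt)
    nxt <- nxt + 1L
  }
  root <- id[1]
  below <- vector("list", 2 * n - 1)
  for (v in seq_len(n)) below[[v]] <- v
  for (v in (n + 1L):(2L * n - 1L)) below[[v]] <- unlist(below[which(parent == v)])
  cols <- list()
  for (v in seq_len(2L * n - 2L)) {
    len <- t_node[parent[v]] - (if (v <= n) 0 else t_node[v])
    m <- rpois(1, len / 2)
    if (m > 0) for (s in seq_len(m)) {
      col <- integer(n); col[below[[v]]] <- 1L
      cols[[length(cols) + 1L]] <- col
    }
  }
  if (!length(cols)) matrix(0L, n, 0) else do.call(cbind, cols)
}

# pairwise difference vector from a binary genotype matrix
.geno_pairwise <- function(g) {
  if (ncol(g) == 0) return(numeric(nrow(g) * (nrow(g) - 1) / 2))
  gd <- g %*% t(1 - g)
  D <- gd + t(gd)
  D[upper.tri(D)]
}
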