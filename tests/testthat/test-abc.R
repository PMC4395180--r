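test_that("summary statistics match exhaustive enumeration on a hand-built sample", {
  # 4 + 4 individuals, 3 variable columns
  geno <- rbind(c(1L, 0L, 0L),
                c(1L, 0L, 0L),
                c(0L, 1L, 0L),
                c(0L, 0L, 0L),
                c(0L, 0L, 1L),
                c(0L, 0L, 1L),
                c(0L, 0L, 1L),
                c(0L, 0L, 1L))
  species <- rep(c("east", "west"), each = 4)
  s <- compute_sumstats(geno, species)

  expect_equal(unname(s[["k_east"]]), 3)           # {100, 010, 000}
  expect_equal(unname(s[["k_west"]]), 1)
  expect_equal(unname(s[["S_east"]]), 2)           # cols 1, 2 segregate in east
  expect_equal(unname(s[["S_west"]]), 0)           # col 3 fixed within west
  expect_equal(unname(s[["priv_east"]]), 2)
  expect_equal(unname(s[["priv_west"]]), 0)
  D <- as.matrix(dist(geno, method = "manhattan"))
  de <- D[1:4, 1:4]; dw <- D[5:8, 5:8]
  expect_equal(unname(s[["pi_east"]]), mean(de[upper.tri(de)]))
  expect_equal(unname(s[["pi_west"]]), 0)
  expect_equal(unname(s[["pi_between"]]), mean(D[1:4, 5:8]))
  expect_equal(unname(s[["S_total"]]), 3)
  expect_equal(unname(s[["D_east"]]),
               as.numeric(tajimas_d(2, mean(de[upper.tri(de)]), 4)))
  expect_equal(unname(s[["D_west"]]), 0)           # monomorphic sentinel
  expect_equal(unname(s[["Fs_west"]]), 0)          # undefined -> sentinel
  # brute-force two-group Phi_ST from explicit sums of squares
  ss_tot <- sum(D[upper.tri(D)]) / 8
  ss_w <- sum(de[upper.tri(de)]) / 4 + sum(dw[upper.tri(dw)]) / 4
  sigma_w <- ss_w / 6
  sigma_a <- ((ss_tot - ss_w) / 1 - sigma_w) / 4
  expect_equal(unname(s[["fst"]]), sigma_a / (sigma_a + sigma_w), tolerance = 1e-12)

  # identical species samples: no differentiation, no private sites
  geno2 <- rbind(geno[1:4, ], geno[1:4, ])
  s2 <- compute_sumstats(geno2, species)
  expect_lte(s2[["fst"]], 0.05)
  expect_equal(unname(s2[["priv_east"]] + s2[["priv_west"]]), 0)
  expect_equal(unname(s2[["k_east"]]), unname(s2[["k_west"]]))
})

test_that("the realized fixture reproduces the published polymorphism summary", {
  rz <- realize_alignment(table1_fixture())
  rm <- recode_indels(rz$aln)
  geno <- recoded_to_geno(rm)
  species <- ifelse(rz$popmap$species == "cyathophorum", "east", "west")
  s <- compute_sumstats(geno, species)
  expect_equal(unname(s[["k_east"]]), 12)
  expect_equal(unname(s[["k_west"]]), 2)
  expect_equal(unname(s[["S_total"]]), 17)
})

test_that("prior draws are coherent, uniform and reproducible", {
  pr <- prior_spec()
  set.seed(5)
  draws <- t(vapply(1:5000, function(i) haplogeo:::.draw_params(pr, "A"), numeric(7)))
  expect_true(all(draws[, "T_e"] <= draws[, "T_b"]))
  expect_true(all(draws[, "T_b"] < draws[, "T_div"]))
  ks <- suppressWarnings(ks.test(draws[, "N_a"], "punif", pr$N_a[1], pr$N_a[2]))
  expect_gt(ks$p.value, 0.01)
  expect_error(prior_spec(T_e = c(5e4, 6e4)), "incoherent")

  r1 <- build_reference("A", pr, n_sims = 40, n_east = 8, n_west = 6, seed = 77)
  r2 <- build_reference("A", pr, n_sims = 40, n_east = 8, n_west = 6, seed = 77)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$params, r2$params)
})

test_that("larger sizes shift diversity statistics upward in the reference table", {
  pr_small <- prior_spec(N_AS = c(1e2, 1e3))
  pr_big <- prior_spec(N_AS = c(5e4, 1e5))
  a <- build_reference("B", pr_small, n_sims = 120, n_east = 6, n_west = 20, seed = 8)
  b <- build_reference("B", pr_big, n_sims = 120, n_east = 6, n_west = 20, seed = 9)
  expect_gt(mean(b$stats[, "pi_west"]), mean(a$stats[, "pi_west"]))
})

test_that("the Box-Cox/PLS transform reduces, decorrelates and projects", {
  set.seed(12)
  n <- 600
  P <- cbind(runif(n, 0, 10), runif(n, -5, 5), runif(n, 1, 2))
  X <- cbind(P %*% matrix(rnorm(15 * 3), 3, 15))[, 1:15] + matrix(rnorm(n * 15, 0, 0.5), n)
  colnames(X) <- paste0("s", 1:15)
  tr <- pls_transform(X, P, n_components = 11)
  sc <- tr$project(X)
  expect_equal(ncol(sc), 11L)
  cors <- cor(sc)
  expect_true(all(abs(cors[upper.tri(cors)]) < 1e-8))
  # deterministic projection
  expect_identical(sc, tr$project(X))
  # full-rank limit: scores carry all the information in the statistics
  tr_full <- pls_transform(X, P, n_components = 15)
  sc_full <- tr_full$project(X)
  expect_equal(ncol(sc_full), 15L)
  # reconstruction on the transformed scale: scores span the full space
  Xbc <- sapply(seq_len(ncol(X)), function(j) {
    x <- X[, j] + tr_full$shift[j]; lm_ <- tr_full$lambda[j]
    y <- if (abs(lm_) < 1e-8) log(x) else (x^lm_ - 1) / lm_
    (y - tr_full$center[j]) / tr_full$scale[j]
  })
  fitback <- lm(Xbc ~ sc_full)
  expect_lt(max(abs(resid(fitback))), 1e-6)
  # constant statistics are dropped with a warning
  Xc <- cbind(X, s16 = 1)
  expect_warning(pls_transform(Xc, P, n_components = 5), "constant")
})

test_that("rejection retains nearest simulations deterministically", {
  pr <- prior_spec()
  ref <- build_reference("A", pr, n_sims = 150, n_east = 10, n_west = 8, seed = 13)
  tr <- pls_transform(ref$stats, ref$params, n_components = 5)
  obs <- ref$stats[7, ]
  rej <- abc_reject(obs, ref, tr, n_retain = 20)
  expect_equal(rej$idx[1], 7L)
  expect_lt(rej$dist[1], 1e-10)
  expect_true(all(diff(rej$dist) >= 0))
  all_in <- abc_reject(obs, ref, tr, n_retain = 150)
  expect_equal(sort(all_in$idx), 1:150)
  expect_identical(rej$idx, abc_reject(obs, ref, tr, n_retain = 20)$idx)
})

test_that("the GLM adjustment matches the conjugate oracle and the noise limit", {
  set.seed(42)
  n <- 2000
  C <- matrix(c(1, 0.5, 0, 1, 1, -1), 3, 2, byrow = TRUE)
  c0 <- c(0.2, -0.1, 0)
  th <- cbind(runif(n, -5, 5), runif(n, -5, 5))
  S <- t(c0 + C %*% t(th)) + matrix(rnorm(n * 3, 0, 0.7), n, 3)
  obs <- c0 + as.numeric(C %*% c(1, 2))
  box <- rbind(c(-5, -5), c(5, 5))
  adj <- glm_adjust(th, S, obs, box, seed = 3)
  Tp <- t(C) %*% C / 0.49
  m_true <- solve(Tp, t(C) %*% (obs - c0) / 0.49)
  pm <- colSums(adj$posterior * adj$weights)
  expect_lt(max(abs(pm - m_true)), 0.1)
  sd_true <- sqrt(diag(solve(Tp)))
  expect_lt(max(abs(apply(adj$posterior, 2, sd) / sd_true - 1)), 0.15)

  # uninformative statistics: posterior reverts to the prior
  S2 <- matrix(rnorm(n * 3), n, 3)
  adj2 <- glm_adjust(th, S2, c(0, 0, 0), box, seed = 4)
  expect_gt(suppressWarnings(ks.test(adj2$posterior[, 1], "punif", -5, 5)$p.value),
            0.01)
})

test_that("Bayes factors obey their arithmetic contract", {
  expect_equal(bayes_factor(1, 1), 1)
  expect_equal(bayes_factor(2.33, 1), 2.33)
  expect_equal(bayes_factor(3, 7), 1 / bayes_factor(7, 3), tolerance = 1e-12)
  expect_warning(bf <- bayes_factor(1, 0), "zero")
  expect_true(is.infinite(bf))
})

test_that("posterior summaries recover closed-form intervals", {
  expect_equal(unlist(posterior_summary(rep(3, 200))), c(mode = 3, lower = 3, upper = 3))
  set.seed(6)
  z <- rnorm(1e5)
  sm <- posterior_summary(z)
  expect_lt(abs(sm$lower + 1.96), 0.05)
  expect_lt(abs(sm$upper - 1.96), 0.05)
  expect_lt(abs(sm$mode), 0.1)
  u <- runif(1e5)
  su <- posterior_summary(u)
  expect_lt(abs((su$upper - su$lower) - 0.95), 0.02)
  expect_error(posterior_summary(rnorm(50)), "100")
})
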