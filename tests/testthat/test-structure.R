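test_that("AMOVA reproduces the printed monomorphic-species block exactly", {
  west <- subset_group(table1_fixture(), "spicata")
  for (d in c(1, 3)) {
    dm <- matrix(c(0, d, d, 0), 2, dimnames = list(c("H13", "H14"), c("H13", "H14")))
    a <- amova(west, dm, levels = 1)
    expect_equal(unname(a$phi["phi_st"]), 1)
    expect_equal(a$table$percent[1], 100)
  }
  dm1 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("H13", "H14"), c("H13", "H14")))
  a1 <- amova(west, dm1, levels = 1)
  expect_equal(round(a1$table$SS[1], 3), 5.438)
  expect_equal(round(a1$table$variance[1], 3), 0.102)
  expect_equal(a1$table$df[1:2], c(7L, 56L))
})

test_that("degenerate and toy AMOVA cases match brute-force sums of squares", {
  # all individuals one haplotype: zero SS, undefined Phi
  ht0 <- haplotype_table(matrix(c(3L, 3L), 2, 1, dimnames = list(c("p1", "p2"), "H1")))
  a0 <- amova(ht0, matrix(0, 1, 1, dimnames = list("H1", "H1")), levels = 1)
  expect_equal(sum(a0$table$SS), 0)
  expect_true(is.na(a0$phi["phi_st"]))

  dmAB <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  # (A,A) vs (B,B): complete fixation
  ht1 <- haplotype_table(matrix(c(2L, 0L, 0L, 2L), 2, byrow = TRUE,
                                dimnames = list(c("p1", "p2"), c("A", "B"))))
  expect_equal(unname(amova(ht1, dmAB, levels = 1)$phi["phi_st"]), 1)
  # (A,B) vs (A,B): all variation within
  ht2 <- haplotype_table(matrix(c(1L, 1L, 1L, 1L), 2, byrow = TRUE,
                                dimnames = list(c("p1", "p2"), c("A", "B"))))
  expect_warning(a2 <- amova(ht2, dmAB, levels = 1), "negative variance")
  expect_lte(unname(a2$phi["phi_st"]), 0)

  # brute-force total/within SS on explicit individuals
  for (ht in list(ht1, ht2)) {
    a <- suppressWarnings(amova(ht, dmAB, levels = 1))
    # rebuild individual-level squared distances by explicit expansion
    pop_i <- rep(rownames(ht$counts), rowSums(ht$counts))
    hap_i <- unlist(lapply(seq_len(nrow(ht$counts)),
                           function(k) rep(colnames(ht$counts), ht$counts[k, ])))
    d2 <- (dmAB[hap_i, hap_i])^2
    ss_tot <- brute_ss(d2)
    ss_w <- sum(vapply(unique(pop_i), function(p) {
      sel <- pop_i == p
      brute_ss(d2[sel, sel, drop = FALSE])
    }, numeric(1)))
    expect_equal(a$table$SS[3], ss_tot, tolerance = 1e-12)
    expect_equal(a$table$SS[2], ss_w, tolerance = 1e-12)
  }
})

test_that("two-level AMOVA partitions the fixture coherently", {
  ht <- table1_fixture()
  a <- amova(ht, fixture_dm(), levels = 2, n_perm = 99, seed = 5)
  expect_equal(sum(a$table$df[1:3]), 149L)
  expect_equal(sum(a$table$percent[1:3]), 100, tolerance = 0.01)
  expect_equal(a$table$variance[4], sum(a$table$variance[1:3]), tolerance = 1e-12)
  expect_gt(a$phi[["phi_ct"]], 0.5)          # strong between-species divergence
  expect_gt(a$phi[["phi_st"]], 0.95)
  expect_true(all(a$p <= 0.05))
  # one-level within each species agrees with the printed pattern of high
  # among-population structure
  ae <- amova(subset_group(ht, "cyathophorum"), fixture_dm()[1:12, 1:12], levels = 1)
  expect_gt(unname(ae$phi["phi_st"]), 0.9)
})

test_that("pairwise Phi_ST is symmetric and consistent with per-pair AMOVA", {
  ht <- subset_group(table1_fixture(), "cyathophorum")
  dm <- fixture_dm()[1:12, 1:12]
  pp <- pairwise_phist(ht, dm)
  expect_true(isSymmetric(unname(pp)))
  expect_equal(unname(diag(pp)), rep(0, nrow(pp)))
  for (pair in list(c(1, 2), c(3, 7), c(2, 11))) {
    sub <- ht$counts[pair, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    a <- amova(haplotype_table(sub), dm[colnames(sub), colnames(sub)], levels = 1)
    expect_equal(pp[pair[1], pair[2]], unname(a$phi["phi_st"]), tolerance = 1e-12)
  }
  # fixed different haplotypes -> 1; identical compositions -> <= 0 or NA
  htf <- haplotype_table(matrix(c(4L, 0L, 0L, 4L), 2, byrow = TRUE,
                                dimnames = list(c("p1", "p2"), c("A", "B"))))
  dmAB <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(pairwise_phist(htf, dmAB)[1, 2], 1)
  hts <- haplotype_table(matrix(c(3L, 3L, 3L, 3L), 2, byrow = TRUE,
                                dimnames = list(c("p1", "p2"), c("A", "B"))))
  expect_lte(pairwise_phist(hts, dmAB)[1, 2], 0)
  htm <- haplotype_table(matrix(c(3L, 3L), 2, 1, dimnames = list(c("p1", "p2"), "A")))
  expect_true(is.na(pairwise_phist(htm, matrix(0, 1, 1, dimnames = list("A", "A")))[1, 2]))
})

test_that("great-circle distances use the 6371 km sphere", {
  same <- data.frame(population = c("a", "b"), lat = c(10, 10), lon = c(20, 20))
  expect_equal(greatcircle_km(same)[1, 2], 0)
  quarter <- data.frame(population = c("a", "b"), lat = c(0, 0), lon = c(0, 90))
  expect_lt(abs(greatcircle_km(quarter)[1, 2] - 10007.5), 1)
  co <- table1_coords()
  G <- greatcircle_km(co)
  expect_lt(G["P17", "P18"], 0.2)     # near-coincident printed sites
  expect_gt(G["P17", "P18"], 0)
  expect_error(greatcircle_km(data.frame(population = "a", lat = NA, lon = 1)), "missing")
})

test_that("the Mantel test matches identity cases, enumeration and vegan", {
  set.seed(3)
  X <- as.matrix(dist(matrix(rnorm(16), 8)))
  expect_equal(mantel_test(X, X, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(X, -X + 10, n_perm = 99, seed = 1)$r, -1)
  expect_error(mantel_test(X * 0, X, n_perm = 9), "zero variance")

  # exact enumeration for n = 4 equals an independent loop over all 24 perms
  X4 <- as.matrix(dist(matrix(rnorm(8), 4)))
  Y4 <- as.matrix(dist(matrix(rnorm(8), 4)))
  res <- mantel_test(X4, Y4, exhaustive = TRUE)
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  ut <- upper.tri(X4)
  vals <- apply(perms, 1L, function(o) {
    o <- as.integer(o)
    cor(X4[o, o][ut], Y4[ut])
  })
  expect_equal(res$n_perm, 24L)
  expect_equal(res$p, mean(vals >= res$r - 1e-12))

  # agreement with vegan on a random case
  Y <- as.matrix(dist(matrix(rnorm(16), 8)))
  ours <- mantel_test(X, Y, n_perm = 999, seed = 42)
  ref <- vegan::mantel(X, Y, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)

  # log transform drops zero-distance pairs pairwise
  Yz <- Y; Yz[1, 2] <- Yz[2, 1] <- 0
  expect_silent(mantel_test(X, Yz, n_perm = 19, seed = 1, transform = "log"))
})

test_that("isolation by distance runs end to end on the fixture geometry", {
  ht <- subset_group(table1_fixture(), "cyathophorum")
  pp <- pairwise_phist(ht, fixture_dm()[1:12, 1:12])
  co <- table1_coords()
  G <- greatcircle_km(co[co$species == "cyathophorum", ])
  res <- mantel_test(pp, G[rownames(pp), rownames(pp)], n_perm = 199, seed = 9,
                     transform = "log", floor_zero = TRUE)
  expect_true(is.finite(res$r))
  expect_gte(res$p, 0); expect_lte(res$p, 1)
})
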