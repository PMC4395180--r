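test_that("simple indel coding collapses shared gap runs to one character", {
  aln <- alignment(c("ACGT", "A--T", "ACGT"))
  rm <- recode_indels(aln)
  expect_equal(sum(rm$kind == "nuc"), 2L)      # columns 1 and 4 survive
  expect_equal(sum(rm$kind == "indel"), 1L)
  expect_equal(unname(rm$mat[, rm$kind == "indel"]), c("0", "1", "0"))
  expect_equal(unname(rm$mat[, 1]), c("A", "A", "A"))

  # no gaps: identity, zero indel characters
  rm2 <- recode_indels(alignment(c("ACGT", "ACTT")))
  expect_equal(sum(rm2$kind == "indel"), 0L)
  expect_equal(ncol(rm2$mat), 4L)

  # nested, non-identical runs become distinct characters scored missing
  rm3 <- recode_indels(alignment(c("AACGT", "A---T", "AA-GT")))
  expect_equal(sum(rm3$kind == "indel"), 2L)
  ind <- rm3$mat[, rm3$kind == "indel", drop = FALSE]
  expect_true(any(is.na(ind[2, ])) || any(is.na(ind[3, ])))

  # an all-sequence gap run is dropped with a warning
  expect_warning(rm4 <- recode_indels(alignment(c("A-T", "A-T"))), "dropped")
  expect_equal(sum(rm4$kind == "indel"), 0L)
})

test_that("recoding the realized study-scale alignment finds the planted indels", {
  rz <- realize_alignment(table1_fixture())
  rm <- recode_indels(rz$aln)
  expect_equal(sum(rm$kind == "indel"), 7L)
  # 17 variable characters in total
  n_var <- sum(apply(rm$mat, 2L, function(v) length(unique(v[!is.na(v)])) > 1))
  expect_equal(n_var, 17L)
})

test_that("haplotype collapsing is exact, idempotent and order-stable", {
  # three identical sequences -> one haplotype of count 3
  rm <- as_recoded(matrix(rep(c("A", "C"), each = 3), 3))
  ht <- collapse_haplotypes(rm)
  expect_equal(unname(ht$counts[1, 1]), 3L)
  expect_equal(ncol(ht$counts), 1L)

  rz <- realize_alignment(table1_fixture())
  rmx <- recode_indels(rz$aln)
  ht2 <- collapse_haplotypes(rmx, rz$popmap)
  expect_equal(ncol(ht2$counts), 14L)
  expect_equal(sum(ht2$counts), 150)
  # the collapse partition equals the generator's own assignment
  key <- apply(ht2$counts, 1L, function(x) paste(sort(x[x > 0]), collapse = ","))
  want <- apply(table(rz$popmap$population, rz$hap_of_individual), 1L,
                function(x) paste(sort(x[x > 0]), collapse = ","))
  expect_identical(unname(key[names(want)]), unname(want))
  hap_lab <- character(0)
  for (i in rownames(rmx$mat)) hap_lab[i] <- names(which(vapply(
    ht2$representative, function(r) identical(unname(r), unname(rmx$mat[i, ])), logical(1))))
  cross <- table(hap_lab, rz$hap_of_individual[names(hap_lab)])
  expect_true(all(rowSums(cross > 0) == 1) && all(colSums(cross > 0) == 1))

  # permuting record order permutes labels but not the multiset of counts
  perm <- rev(seq_len(nrow(rmx$mat)))
  rm_p <- as_recoded(rmx$mat[perm, ], rmx$kind)
  ht3 <- collapse_haplotypes(rm_p, rz$popmap)
  expect_equal(sort(colSums(ht3$counts)), sort(colSums(ht2$counts)), ignore_attr = TRUE)

  # differing missingness patterns stay distinct
  m <- matrix(c("A", "A", NA, "A"), 2)
  expect_equal(ncol(collapse_haplotypes(as_recoded(m))$counts), 2L)
})

test_that("haplotype distances count differing characters", {
  reps <- list(H1 = c("A", "C", "G", "T", "0"), H2 = c("A", "G", "G", "T", "1"),
               H3 = c("A", "C", "G", "T", "0"))
  ht <- haplotype_table(matrix(c(1L, 1L, 1L), 1, 3,
                               dimnames = list("p", c("H1", "H2", "H3"))),
                        representative = reps)
  dm <- haplotype_distances(ht)
  expect_equal(unname(dm["H1", "H2"]), 2)
  expect_equal(unname(dm["H1", "H3"]), 0)
  expect_true(isSymmetric(dm))
  expect_equal(unname(diag(dm)), rep(0, 3))

  # triangle inequality on the realized fixture distances
  d <- fixture_dm()
  for (i in 1:14) for (j in 1:14) for (k in 1:14)
    expect_lte(d[i, k], d[i, j] + d[j, k])
})

test_that("the minimum spanning network retains every tie-equal MST edge", {
  ht1 <- haplotype_table(matrix(5L, 1, 1, dimnames = list("p", "H1")),
                         representative = list(H1 = c("A")))
  net1 <- build_network(ht1, matrix(0, 1, 1, dimnames = list("H1", "H1")), n_sites = 10)
  expect_equal(nrow(net1$edges), 0L)
  expect_equal(nrow(net1$nodes), 1L)

  dm2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  ht2 <- haplotype_table(matrix(c(2L, 1L), 1, 2, dimnames = list("p", c("H1", "H2"))))
  net2 <- build_network(ht2, dm2, n_sites = 1000)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$steps, 3)

  # brute force: a spanning tree of minimum total weight exists inside the MSN
  set.seed(7)
  for (rep in 1:5) {
    k <- 5
    pts <- matrix(sample(0:4, k * 3, replace = TRUE), k)
    dm <- as.matrix(dist(pts, method = "manhattan"))
    dimnames(dm) <- list(paste0("H", 1:k), paste0("H", 1:k))
    ht <- haplotype_table(matrix(1L, 1, k, dimnames = list("p", paste0("H", 1:k))))
    net <- build_network(ht, dm, conf = NULL)
    # enumerate all labelled spanning trees via Pruefer sequences
    all_w <- apply(as.matrix(expand.grid(rep(list(1:k), k - 2))), 1L, function(pruefer) {
      deg <- rep(1L, k); for (v in pruefer) deg[v] <- deg[v] + 1L
      w <- 0; pr <- as.integer(pruefer)
      for (v in pr) {
        leaf <- min(which(deg == 1L))
        w <- w + dm[leaf, v]
        deg[leaf] <- 0L; deg[v] <- deg[v] - 1L
      }
      last <- which(deg == 1L)
      w + dm[last[1], last[2]]
    })
    edges <- net$edges
    # minimum spanning tree weight achievable using only MSN edges
    best <- Inf
    cmb <- combn(seq_len(nrow(edges)), k - 1)
    for (ci in seq_len(ncol(cmb))) {
      sel <- edges[cmb[, ci], ]
      comp <- seq_len(k); names(comp) <- rownames(dm)
      for (e in seq_len(nrow(sel))) {
        a <- comp[sel$from[e]]; b <- comp[sel$to[e]]
        comp[comp == b] <- a
      }
      if (length(unique(comp)) == 1L) best <- min(best, sum(sel$steps))
    }
    expect_equal(best, min(all_w))
  }
})

test_that("the parsimony limit scales with alignment length and cuts long edges", {
  expect_gte(parsimony_limit(1448), 8)
  expect_lt(parsimony_limit(50), parsimony_limit(5000))
  # an edge beyond the limit disconnects the network
  dm <- matrix(c(0, 40, 40, 0), 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  ht <- haplotype_table(matrix(c(1L, 1L), 1, 2, dimnames = list("p", c("H1", "H2"))))
  net <- build_network(ht, dm, n_sites = 100)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(build_network(ht, dm, conf = NULL)$edges), 1L)
})

test_that("the realized fixture separates into the two published-style clades", {
  ht <- table1_fixture()
  dm <- fixture_dm()
  net <- build_network(ht, dm, n_sites = 1448)
  west <- c("H13", "H14")
  cross <- net$edges[xor(net$edges$from %in% west, net$edges$to %in% west), ]
  expect_true(all(cross$steps >= 3))
  within_w <- net$edges[net$edges$from %in% west & net$edges$to %in% west, ]
  expect_equal(within_w$steps, 1)
})
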