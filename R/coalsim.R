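#' Demographic model for the two-species coalescent
#'
#' Parameter container for the divergence models of a pair of sister species
#' sampled for a haploid, non-recombining marker. Model `"A"`
#' (divergence-with-bottleneck): the western species sits at its current
#' size `N_AS`, was squeezed to `N_aM` between `T_e` and `T_b` (ago), and at
#' size `N_AS` again back to the split at `T`. Model `"B"`
#' (progenitor-derivation): the western species expanded instantaneously at
#' `T_e` from a persistently small population of size `N_aM`. The eastern
#' species stays at `N_AC` until the split; both merge into an ancestor of
#' size `N_a`. Model `"single"` is one constant-size population of `N_a`
#' haploid individuals.
#'
#' @param model_id `"A"`, `"B"` or `"single"`.
#' @param N_a ancestral effective size (haploid individuals).
#' @param N_AC current eastern size.
#' @param N_AS current western size.
#' @param N_aM western size during its small phase.
#' @param T_div divergence time in generations.
#' @param T_b,T_e beginning / end (ago) of the western bottleneck (model A);
#'   `T_e` alone is the expansion time for model B.
#' @param mu mutation rate per site per year.
#' @param L number of sites.
#' @param generation_time years per generation (default 1, making the
#'   generation and year scales of the model coincide).
#' @param N_west_pre western size on `[T_b, T)` in model A; defaults to
#'   `N_AS`.
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(model_id = c("A", "B", "single"),
                              N_a, N_AC = NULL, N_AS = NULL, N_aM = NULL,
                              T_div = NULL, T_b = NULL, T_e = NULL,
                              mu = 1.5e-9, L = 1448, generation_time = 1,
                              N_west_pre = NULL) {
  model_id <- match.arg(model_id)
  stopifnot(mu > 0, L >= 1, N_a >= 1)
  if (model_id != "single") {
    stopifnot(N_AC >= 1, N_AS >= 1, N_aM >= 1, T_div > 0, T_e > 0)
    if (model_id == "A") {
      if (is.null(T_b)) stop("model A needs T_b")
      if (!(T_e <= T_b)) stop("model A requires T_e <= T_b")
      if (!(T_b < T_div)) stop("model A requires T_b < T")
    } else {
      if (!(T_e < T_div)) stop("model B requires T_e < T")
    }
  }
  if (is.null(N_west_pre)) N_west_pre <- N_AS
  structure(list(model_id = model_id, N_a = N_a, N_AC = N_AC, N_AS = N_AS,
                 N_aM = N_aM, T_div = T_div, T_b = T_b, T_e = T_e, mu = mu,
                 L = L, generation_time = generation_time,
                 N_west_pre = N_west_pre),
            class = "demographic_model")
}

# western-lineage size at time t (generations ago)
.west_size <- function(model, t) {
  if (model$model_id == "A") {
    if (t < model$T_e) model$N_AS
    else if (t < model$T_b) model$N_aM
    else model$N_west_pre
  } else {                      # model B
    if (t < model$T_e) model$N_AS else model$N_aM
  }
}

#' Simulate a two-species sample under the coalescent
#'
#' Standard coalescent with piecewise-constant haploid sizes (pair
#' coalescence rate `k(k-1)/(2N)` per generation per population), lineages
#' of the two species merging into the ancestor at the divergence time, and
#' infinite-sites mutation: each branch receives Poisson(`mu * L *
#' generation_time * length`) mutations, every mutation hitting a fresh
#' site.
#'
#' @param model a [demographic_model()].
#' @param n_east,n_west sample sizes (for `"single"`, `n_east` individuals
#'   are drawn from the one population and `n_west` must be 0).
#' @param seed RNG seed.
#' @return object of class `simdata`: `geno` (n x S binary matrix of derived
#'   alleles), `species` (factor `east`/`west`), `tree_height` (generations),
#'   `n_mutations`, `model`.
#' @export
simulate_coalescent <- function(model, n_east, n_west = 0, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  if (model$model_id == "single" && n_west != 0) stop("single-population model: n_west must be 0")
  n <- n_east + n_west
  if (n < 2) stop("need at least 2 sampled lineages")
  with_seed(seed, {
    species <- c(rep("east", n_east), rep("west", n_west))
    node <- seq_len(n)
    pop <- if (model$model_id == "single") rep(3L, n) else ifelse(species == "east", 1L, 2L)
    parent <- integer(2 * n - 1); t_node <- numeric(2 * n - 1)
    nxt <- n + 1L
    t_now <- 0
    bounds <- switch(model$model_id,
                     A = c(model$T_e, model$T_b, model$T_div, Inf),
                     B = c(model$T_e, model$T_div, Inf),
                     single = Inf)
    merged <- model$model_id == "single"
    size_of <- function(p, t) {
      if (p == 1L) model$N_AC
      else if (p == 2L) .west_size(model, t)
      else model$N_a
    }
    while (length(node) > 1L) {
      if (!merged && t_now >= model$T_div) { pop[] <- 3L; merged <- TRUE }
      ks <- tabulate(pop, 3L)
      rates <- numeric(3)
      for (p in 1:3) if (ks[p] >= 2L)
        rates[p] <- ks[p] * (ks[p] - 1) / (2 * size_of(p, t_now))
      R <- sum(rates)
      tb <- min(bounds[bounds > t_now])
      if (R == 0) { t_now <- tb; next }
      dt <- rexp(1, R)
      if (t_now + dt >= tb) { t_now <- tb; next }
      t_now <- t_now + dt
      p_sel <- sample.int(3, 1, prob = rates)
      idx <- which(pop == p_sel)
      pr <- idx[sample.int(length(idx), 2)]
      t_node[nxt] <- t_now
      parent[node[pr]] <- nxt
      node <- c(node[-pr], nxt)
      pop <- c(pop[-pr], p_sel)
      nxt <- nxt + 1L
    }
    root <- node[1]
    rate_site <- model$mu * model$L * model$generation_time
    nb <- 2L * n - 2L
    lens <- t_node[parent[seq_len(nb)]] -
      c(numeric(n), if (nb > n) t_node[(n + 1L):nb])
    m_b <- rpois(nb, rate_site * lens)
    geno <- matrix(0L, n, sum(m_b))
    if (sum(m_b) > 0) {
      below <- vector("list", 2 * n - 1)
      for (v in seq_len(n)) below[[v]] <- v
      ord <- order(t_node[(n + 1L):(2L * n - 1L)]) + n
      kids <- split(seq_len(nb), parent[seq_len(nb)])
      for (v in ord) below[[v]] <- unlist(below[kids[[as.character(v)]]], use.names = FALSE)
      colidx <- 1L
      for (v in which(m_b > 0)) {
        geno[below[[v]], colidx:(colidx + m_b[v] - 1L)] <- 1L
        colidx <- colidx + m_b[v]
      }
    }
    rownames(geno) <- c(sprintf("east_%03d", seq_len(n_east)),
                        if (n_west > 0) sprintf("west_%03d", seq_len(n_west)))
    structure(list(geno = geno, species = species, tree_height = t_node[root],
                   n_mutations = ncol(geno), model = model),
              class = "simdata")
  })
}

#' @export
print.simdata <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$geno), "haploid individuals,",
      x$n_mutations, "mutations, tree height", signif(x$tree_height, 4), "generations\n")
  invisible(x)
}

#' Convert a simulated dataset into an alignment
#'
#' Maps the infinite-sites mutations onto a deterministic monomorphic
#' backbone of length `L`: mutation `m` goes to position
#' `floor((m-1) L / M) + 1`, the backbone cycles `ACGT`, and the derived
#' state is the transition partner of the backbone base. Deterministic given
#' the dataset.
#'
#' @param ds a [simulate_coalescent()] result.
#' @param popmap optional popmap data frame assigning the simulated
#'   individuals to populations; by default each species is one population.
#' @return list with `aln` ([alignment()]) and `popmap` (data frame with
#'   `individual`, `population`, `species`).
#' @export
to_alignment <- function(ds, popmap = NULL) {
  stopifnot(inherits(ds, "simdata"))
  L <- ds$model$L
  M <- ds$n_mutations
  if (M > L) stop("more mutations than sites; increase L")
  backbone <- rep(c("A", "C", "G", "T"), length.out = L)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  pos <- if (M > 0) floor((seq_len(M) - 1) * L / M) + 1L else integer(0)
  n <- nrow(ds$geno)
  mat <- matrix(rep(backbone, each = n), nrow = n)
  for (m in seq_len(M)) {
    carriers <- ds$geno[, m] == 1L
    mat[carriers, pos[m]] <- transition[[backbone[pos[m]]]]
  }
  rownames(mat) <- rownames(ds$geno)
  aln <- alignment(mat)
  if (is.null(popmap))
    popmap <- data.frame(individual = rownames(mat),
                         population = ds$species,
                         species = ds$species)
  list(aln = aln, popmap = popmap)
}
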