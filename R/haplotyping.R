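#' Recode alignment gaps as binary indel characters
#'
#' Simple indel coding: every maximal gap run that shares identical start and
#' end coordinates across the sequences carrying it becomes a single binary
#' character (1 = deletion present, 0 = absent). Sequences whose own gap run
#' overlaps a character's span without matching it exactly are scored missing
#' for that character. All alignment columns touched by any gap are removed
#' from the nucleotide partition, so nucleotide columns never contain `-`.
#'
#' @param aln a [alignment()] object.
#' @return object of class `recoded`: list with `mat` (individuals x
#'   characters character matrix; nucleotide states `A/C/G/T`, indel states
#'   `"0"/"1"`, `NA` = missing), `kind` (per-column `"nuc"` or `"indel"`),
#'   `n_sites` (alignment columns backing the matrix, used for the parsimony
#'   connection limit).
#' @export
recode_indels <- function(aln) {
  stopifnot(inherits(aln, "haplogeo_alignment"))
  mat <- aln$mat
  n <- nrow(mat); L <- ncol(mat)

  # maximal gap runs per sequence as (start, end) pairs
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    g <- mat[i, ] == "-"
    if (!any(g)) { runs[[i]] <- matrix(integer(0), 0, 2); next }
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs[[i]] <- cbind(starts[r$values], ends[r$values])
  }

  all_runs <- do.call(rbind, runs)
  chars <- unique(all_runs)
  if (!is.null(chars) && nrow(chars)) {
    chars <- chars[order(chars[, 1], chars[, 2]), , drop = FALSE]
  } else {
    chars <- matrix(integer(0), 0, 2)
  }

  indel_cols <- NULL
  indel_names <- character(0)
  dropped <- 0L
  for (ci in seq_len(nrow(chars))) {
    s <- chars[ci, 1]; e <- chars[ci, 2]
    states <- character(n)
    for (i in seq_len(n)) {
      ri <- runs[[i]]
      if (nrow(ri) && any(ri[, 1] == s & ri[, 2] == e)) {
        states[i] <- "1"
      } else if (nrow(ri) && any(ri[, 1] <= e & ri[, 2] >= s)) {
        states[i] <- NA_character_   # superimposed non-identical run
      } else states[i] <- "0"
    }
    if (all(states == "1", na.rm = TRUE) && !anyNA(states)) {
      # a deletion shared by every sequence carries no information
      dropped <- dropped + 1L
      next
    }
    indel_cols <- cbind(indel_cols, states)
    indel_names <- c(indel_names, sprintf("indel_%d_%d", s, e))
  }
  if (dropped) warning(dropped, " all-sequence gap run(s) dropped")

  gap_col <- colSums(mat == "-") > 0
  nuc <- mat[, !gap_col, drop = FALSE]
  nuc[nuc == "N"] <- NA_character_
  colnames(nuc) <- paste0("s", which(!gap_col))

  out <- cbind(nuc, indel_cols)
  if (!is.null(indel_cols)) colnames(out) <- c(colnames(nuc), indel_names)
  rownames(out) <- rownames(mat)
  structure(list(mat = out,
                 kind = c(rep("nuc", ncol(nuc)), rep("indel", length(indel_names))),
                 n_sites = ncol(nuc) + length(indel_names)),
            class = "recoded")
}

#' @export
print.recoded <- function(x, ...) {
  cat("Recoded matrix:", nrow(x$mat), "individuals x", ncol(x$mat),
      "characters (", sum(x$kind == "indel"), "indel )\n")
  invisible(x)
}

# character key treating NA as a distinct symbol (identical missingness
# patterns collapse together, differing patterns stay apart)
.hap_key <- function(m) {
  m[is.na(m)] <- "?"
  apply(m, 1L, paste, collapse = "\r")
}

#' Collapse individuals into haplotypes
#'
#' Individuals with identical recoded character vectors (including an
#' identical missing-data pattern) share a haplotype. Haplotypes are labelled
#' `H1`, `H2`, ... by order of first appearance in the input, and counts are
#' cross-tabulated by population.
#'
#' @param rm a [recode_indels()] result.
#' @param pm optional popmap data frame (columns `individual`, `population`,
#'   `species`); when missing all individuals form one population.
#' @return a [haplotype_table()] carrying one representative character vector
#'   per haplotype.
#' @export
collapse_haplotypes <- function(rm, pm = NULL) {
  stopifnot(inherits(rm, "recoded"))
  if (is.null(rownames(rm$mat)))
    rownames(rm$mat) <- paste0("ind", seq_len(nrow(rm$mat)))
  ids <- rownames(rm$mat)
  if (is.null(pm)) {
    pop <- setNames(rep("all", length(ids)), ids)
    species <- NULL
  } else {
    if (!all(ids %in% pm$individual))
      stop("popmap does not cover individuals: ",
           paste(head(setdiff(ids, pm$individual)), collapse = ", "))
    pop <- setNames(pm$population, pm$individual)[ids]
    species <- if ("species" %in% names(pm))
      setNames(pm$species, pm$population)[unique(pop)]
  }
  key <- .hap_key(rm$mat)
  first <- !duplicated(key)
  labels <- setNames(paste0("H", seq_len(sum(first))), key[first])
  hap <- labels[key]
  pops <- unique(pop)
  counts <- matrix(0L, length(pops), length(labels),
                   dimnames = list(pops, unname(labels)))
  for (i in seq_along(ids)) counts[pop[i], hap[i]] <- counts[pop[i], hap[i]] + 1L
  reps <- lapply(which(first), function(i) rm$mat[i, ])
  names(reps) <- labels
  grouping <- if (!is.null(species)) setNames(unname(species[pops]), pops)
  haplotype_table(counts, grouping = grouping, representative = reps)
}

#' Pairwise character distances between haplotypes
#'
#' Number of characters at which the representative vectors differ, with
#' pairwise deletion of missing characters; binary indel characters count one
#' step each.
#'
#' @param ht haplotable with representatives.
#' @return symmetric integer matrix with zero diagonal.
#' @export
haplotype_distances <- function(ht) {
  if (is.null(ht$representative)) stop("haplotype table has no representatives")
  reps <- ht$representative
  k <- length(reps)
  m <- do.call(rbind, reps)
  d <- matrix(0, k, k, dimnames = list(names(reps), names(reps)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok])
  }
  d
}

#' Binary genotype matrix from a recoded alignment
#'
#' Converts the variable columns of a recoded matrix into a 0/1 matrix of
#' minor-allele presence (the representation the summary-statistic and ABC
#' machinery consume). Requires every variable character to be biallelic,
#' which holds for infinite-sites-style chloroplast data.
#'
#' @param rm a [recode_indels()] result.
#' @return n x S binary matrix, one column per variable character.
#' @export
recoded_to_geno <- function(rm) {
  m <- rm$mat
  cols <- list()
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    states <- unique(v[!is.na(v)])
    if (length(states) < 2L) next
    if (length(states) > 2L)
      stop("character ", colnames(m)[j], " has more than two states")
    tab <- table(factor(v, levels = states))
    minor <- states[which.min(tab)]
    cols[[length(cols) + 1L]] <- as.integer(v == minor)
  }
  out <- if (length(cols)) do.call(cbind, cols) else matrix(0L, nrow(m), 0)
  rownames(out) <- rownames(m)
  out
}

#' Statistical-parsimony connection limit
#'
#' Largest number of steps `j` for which two haplotypes differing at `j` of
#' `n_sites` characters are connected with probability of multiple
#' substitution below `1 - conf`. Per-site substitution counts are modelled
#' as Poisson with Jukes-Cantor state changes; the per-site rate is solved
#' from the corrected divergence at `j` observed differences, and the
#' parsimony probability is P(every differing site had exactly one hit and
#' every identical site had none).
#'
#' @param n_sites number of characters in the data.
#' @param conf confidence level (default 0.95).
#' @return integer connection limit (>= 1).
#' @export
parsimony_limit <- function(n_sites, conf = 0.95) {
  stopifnot(n_sites >= 1)
  p_pars <- function(j) {
    p <- j / n_sites
    if (p >= 0.75) return(0)
    lam <- -3 / 4 * log(1 - 4 * p / 3)      # JC-corrected per-site rate
    pdiff <- 3 / 4 * (1 - exp(-4 * lam / 3))
    if (pdiff <= 0) return(1)
    psingle <- lam * exp(-lam) / pdiff       # one hit given an observed difference
    pnone <- exp(-lam) / (1 - pdiff)         # zero hits given an identical site
    psingle^j * pnone^(n_sites - j)
  }
  j <- 1L
  while (j < n_sites && p_pars(j + 1L) >= conf) j <- j + 1L
  j
}

# all minimum-spanning-network edges: process distance classes in increasing
# order; within a class, keep every edge that joins two components as they
# stood before the class (so tie-equal alternatives are all retained)
.msn_edges <- function(dm, limit = Inf) {
  k <- nrow(dm)
  ids <- rownames(dm)
  if (k == 1L) return(data.frame(from = character(0), to = character(0), steps = numeric(0)))
  comp <- seq_len(k)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  w <- dm[pairs]
  keep <- w <= limit
  pairs <- pairs[keep, , drop = FALSE]; w <- w[keep]
  out <- NULL
  for (d in sort(unique(w))) {
    sel <- which(w == d)
    before <- comp
    added <- FALSE
    for (s in sel) {
      i <- pairs[s, 1]; j <- pairs[s, 2]
      if (before[i] != before[j]) {
        out <- rbind(out, data.frame(from = ids[i], to = ids[j], steps = d))
        if (comp[i] != comp[j]) { comp[comp == comp[j]] <- comp[i]; added <- TRUE }
      }
    }
    if (added && all(comp == comp[1])) next
  }
  if (is.null(out)) data.frame(from = character(0), to = character(0), steps = numeric(0)) else out
}

#' Build a haplotype network
#'
#' Minimum-spanning network: the union of every minimum spanning tree edge
#' and all tie-equal alternatives, with connections longer than the
#' statistical-parsimony limit cut (possibly leaving separate components),
#' mirroring the behaviour of parsimony network programs on chloroplast data.
#'
#' @param ht haplotable (node frequencies come from its column sums).
#' @param dm haplotype distance matrix.
#' @param conf parsimony confidence; `NULL` disables the limit (pure MSN).
#' @param n_sites characters behind `dm`; defaults to the representative
#'   length when available.
#' @return object of class `haplonet` with `nodes`, `edges`, `limit`.
#' @export
build_network <- function(ht, dm, conf = 0.95, n_sites = NULL) {
  stopifnot(inherits(ht, "haplotable"))
  haps <- colnames(ht$counts)
  dm <- dm[haps, haps, drop = FALSE]
  if (is.null(n_sites) && !is.null(ht$representative))
    n_sites <- length(ht$representative[[1]])
  limit <- if (is.null(conf)) Inf else parsimony_limit(n_sites, conf)
  edges <- .msn_edges(dm, limit)
  structure(list(nodes = data.frame(haplotype = haps, freq = colSums(ht$counts)),
                 edges = edges, limit = limit),
            class = "haplonet")
}

#' @export
print.haplonet <- function(x, ...) {
  cat("Haplotype network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (connection limit", x$limit, "steps)\n")
  invisible(x)
}

#' Write a haplotype network
#' @param net haplonet object.
#' @param path output path.
#' @param format `"tsv"` edge list or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @export
plot.haplonet <- function(x, ...) {
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE, vertices = x$nodes)
  igraph::plot.igraph(g, vertex.size = 5 + 3 * sqrt(x$nodes$freq),
                      edge.label = x$edges$steps, ...)
  invisible(x)
}
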