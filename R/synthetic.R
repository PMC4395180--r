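#' Published-style haplotype count fixture
#'
#' The bundled 19-population x 14-chlorotype count table for the two sister
#' *Allium* species (86 eastern + 64 western individuals), with species
#' grouping and DMS coordinates, shipped as a plain-text fixture so that
#' every analysis stage runs without any download.
#'
#' @return a [haplotype_table()].
#' @export
table1_fixture <- function() {
  read_haplotype_table(system.file("extdata", "table1_chlorotypes.tsv",
                                   package = "haplogeo", mustWork = TRUE))
}

#' Population coordinates of the bundled fixture
#' @return data frame with `population`, `species`, `name`, `lat`, `lon`,
#'   `alt_m` (decimal degrees).
#' @export
table1_coords <- function() {
  d <- read.delim(system.file("extdata", "table1_chlorotypes.tsv",
                              package = "haplogeo", mustWork = TRUE),
                  stringsAsFactors = FALSE)
  data.frame(population = d$population, species = d$species, name = d$location,
             lat = parse_dms(d$lat_dms), lon = parse_dms(d$lon_dms),
             alt_m = d$alt_m)
}

#' Character plan realizing the fixture's haplotypes
#'
#' A deterministic 14 x 17 state design: 10 nucleotide substitutions (4
#' transitions, 6 transversions) and 7 binary indel characters arranged on a
#' two-clade topology (the two western haplotypes separated from the eastern
#' clade by three shared steps), matching the polymorphism the study system
#' shows at the sequence level.
#'
#' @return list with `states` (14 x 17 0/1 matrix), `kind` (`"nuc"`/
#'   `"indel"` per character), `transition` (logical per nucleotide
#'   character).
#' @export
study_character_plan <- function() {
  chars <- paste0("c", 1:17)
  haps <- paste0("H", 1:14)
  st <- matrix(0L, 14, 17, dimnames = list(haps, chars))
  carry <- list(
    H1 = "c5", H2 = character(0), H3 = "c6", H4 = "c7",
    H5 = "c8", H6 = c("c8", "c9"),
    H7 = c("c10", "c11", "c12"), H8 = c("c10", "c11", "c12", "c13"),
    H9 = c("c10", "c11", "c12", "c14"), H10 = "c16", H11 = c("c16", "c17"),
    H12 = c("c10", "c11", "c12", "c15"),
    H13 = c("c1", "c2", "c3"), H14 = c("c1", "c2", "c3", "c4"))
  for (h in names(carry)) st[h, carry[[h]]] <- 1L
  kind <- rep("nuc", 17)
  kind[c(1, 5, 7, 9, 11, 14, 16)] <- "indel"
  names(kind) <- chars
  transition <- setNames(rep(FALSE, 17), chars)
  transition[c("c2", "c4", "c8", "c13")] <- TRUE   # 4 transitions, 6 transversions
  list(states = st, kind = kind, transition = transition)
}

#' Realize an alignment from a haplotype table and a character plan
#'
#' Builds a concrete aligned FASTA-writable dataset whose individuals
#' collapse back exactly to the given count table: each haplotype receives
#' the substitutions and gap runs its plan row prescribes on a seeded random
#' backbone, and populations are filled in file order. Indel characters are
#' written as shared gap runs with identical boundaries, so indel recoding
#' recovers one binary character per planted indel.
#'
#' @param ht haplotable to realize (haplotypes must match the plan's rows).
#' @param plan a [study_character_plan()]-shaped design.
#' @param L alignment length.
#' @param seed backbone seed.
#' @return list with `aln`, `popmap`, `hap_of_individual` (the generator's
#'   own assignment, for round-trip checks), `positions`.
#' @export
realize_alignment <- function(ht, plan = study_character_plan(), L = 1448, seed = 1) {
  haps <- colnames(ht$counts)
  if (!all(haps %in% rownames(plan$states)))
    stop("plan does not cover haplotypes: ",
         paste(setdiff(haps, rownames(plan$states)), collapse = ", "))
  st <- plan$states[haps, , drop = FALSE]
  if (anyDuplicated(apply(st, 1L, paste, collapse = "")))
    stop("unsatisfiable plan: two haplotypes share identical states")
  n_char <- ncol(st)
  gap_len <- rep(c(1L, 2L, 3L), length.out = n_char)   # indel run lengths
  spacing <- L %/% (n_char + 1)
  pos <- spacing * seq_len(n_char)                      # run/site start positions
  backbone <- with_seed(seed, sample(c("A", "C", "G", "T"), L, replace = TRUE))
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversion <- c(A = "C", G = "T", C = "G", T = "A")
  hap_seqs <- lapply(haps, function(h) {
    s <- backbone
    for (j in seq_len(n_char)) {
      if (st[h, j] == 0L) next
      p <- pos[j]
      if (plan$kind[j] == "indel") {
        s[p:(p + gap_len[j] - 1L)] <- "-"
      } else {
        s[p] <- if (plan$transition[j]) transition[[backbone[p]]] else transversion[[backbone[p]]]
      }
    }
    s
  })
  names(hap_seqs) <- haps
  ids <- character(0); pops <- character(0); hap_of <- character(0)
  rowsq <- list()
  for (k in seq_len(nrow(ht$counts))) {
    pk <- rownames(ht$counts)[k]
    cnt_i <- 0L
    for (h in haps) {
      cnt <- ht$counts[k, h]
      if (cnt == 0) next
      for (r in seq_len(cnt)) {
        cnt_i <- cnt_i + 1L
        ids <- c(ids, sprintf("%s_%02d", pk, cnt_i))
        pops <- c(pops, pk)
        hap_of <- c(hap_of, h)
        rowsq[[length(rowsq) + 1L]] <- hap_seqs[[h]]
      }
    }
  }
  mat <- do.call(rbind, rowsq)
  rownames(mat) <- ids
  popmap <- data.frame(individual = ids, population = pops,
                       species = if (!is.null(ht$grouping)) unname(ht$grouping[pops]) else "all")
  list(aln = alignment(mat), popmap = popmap,
       hap_of_individual = setNames(hap_of, ids), positions = pos)
}

# the fixture's per-population sample sizes, east then west
.fixture_sizes <- function() {
  ht <- table1_fixture()
  rowSums(ht$counts)
}

#' Simulate a study-like dataset at the published posterior modes
#'
#' Runs the two-species coalescent at the posterior-mode parameters of the
#' divergence-with-bottleneck analysis (N_a = 133870, N_AC = 355630,
#' N_aM = 334, N_AS = 9821, T = 778572, T_b = 36066, T_e = 10049, mu =
#' 1.5e-9, L = 1448), samples 86 eastern + 64 western individuals, and
#' scatters them over pseudo-populations with the fixture's sample sizes
#' (the divergence models are panmictic per species, so the assignment is
#' random).
#'
#' @param model `"A"` or `"B"`.
#' @param seed RNG seed.
#' @return list with `aln`, `popmap`, `sim` (the raw `simdata`).
#' @export
study_like_dataset <- function(model = c("A", "B"), seed = 1) {
  model <- match.arg(model)
  md <- demographic_model(model, N_a = 133870, N_AC = 355630, N_AS = 9821,
                          N_aM = 334, T_div = 778572,
                          T_b = if (model == "A") 36066 else NULL,
                          T_e = 10049, mu = 1.5e-9, L = 1448)
  ds <- simulate_coalescent(md, n_east = 86, n_west = 64, seed = seed)
  sizes <- .fixture_sizes()
  coords <- table1_coords()
  east_pops <- coords$population[coords$species == "cyathophorum"]
  west_pops <- coords$population[coords$species == "spicata"]
  pop <- character(nrow(ds$geno))
  with_seed(seed + 1L, {
    pop[ds$species == "east"] <- sample(rep(east_pops, sizes[east_pops]))
    pop[ds$species == "west"] <- sample(rep(west_pops, sizes[west_pops]))
  })
  species_of_pop <- setNames(coords$species, coords$population)
  pm <- data.frame(individual = rownames(ds$geno), population = pop,
                   species = unname(species_of_pop[pop]))
  out <- to_alignment(ds, popmap = pm)
  list(aln = out$aln, popmap = pm, sim = ds)
}
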