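# small shared builders for the test suite

tiny_alignment <- function(seqs, ids = NULL) alignment(seqs, ids)

# write a FASTA to a temp file and return the path
write_tmp_fasta <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) writeLines(c(paste0(">", ids[i]), seqs[i]), con)
  path
}

# a recoded-matrix stand-in built directly from a character matrix
as_recoded <- function(mat, kind = rep("nuc", ncol(mat))) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("ind", seq_len(nrow(mat)))
  structure(list(mat = mat, kind = kind, n_sites = ncol(mat)), class = "recoded")
}

# unit distance matrix over haplotype names
unit_dm <- function(haps) {
  d <- matrix(1, length(haps), length(haps), dimnames = list(haps, haps))
  diag(d) <- 0
  d
}

# distance matrix between the fixture's 14 haplotypes implied by the
# published-style character plan
fixture_dm <- function() {
  st <- study_character_plan()$states
  as.matrix(dist(st, method = "manhattan"))
}

# brute-force AMOVA sums of squares from explicit pairwise loops
brute_ss <- function(d2_ind) {
  n <- nrow(d2_ind)
  sum(d2_ind[upper.tri(d2_ind)]) / n
}
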