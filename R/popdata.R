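#' @importFrom stats var sd optimize optim nlminb rnorm runif rexp rpois density
#'   quantile ks.test setNames aggregate cor pgamma dist rbinom cov lm coef resid
#' @importFrom utils read.delim write.table head combn
NULL

ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Aligned haploid sequences
#'
#' Constructs the alignment container used throughout the package: a set of
#' equal-length haploid sequences (chloroplast or other organellar DNA) over
#' the alphabet `A,C,G,T,N,-`, where `N` is missing data and `-` is an
#' alignment gap consumed later by indel recoding.
#'
#' @param seqs character vector of sequences (all the same length), or a
#'   character matrix with one row per individual and one aligned column per
#'   matrix column.
#' @param ids individual identifiers, unique, same length as `seqs`.
#' @return an object of class `haplogeo_alignment`: a list with `mat` (n x L
#'   character matrix, rownames = ids) and `length` (L).
#' @export
alignment <- function(seqs, ids = NULL) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    if (!is.null(ids)) rownames(mat) <- ids
  } else {
    seqs <- toupper(as.character(seqs))
    if (is.null(ids)) ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("ind", seq_along(seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths differ (", paste(unique(lens), collapse = ", "), ")")
    mat <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE,
                  dimnames = list(ids, NULL))
  }
  if (nrow(mat) < 1L || ncol(mat) < 1L) stop("empty alignment")
  if (anyDuplicated(rownames(mat))) stop("individual ids must be unique")
  bad <- setdiff(unique(as.vector(mat)), ALPHABET)
  if (length(bad))
    stop("invalid characters in alignment (DNA only): ", paste(bad, collapse = " "))
  structure(list(mat = mat, length = ncol(mat)), class = "haplogeo_alignment")
}

#' @export
print.haplogeo_alignment <- function(x, ...) {
  cat("Alignment:", nrow(x$mat), "sequences x", x$length, "columns\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path path to a FASTA file of pre-aligned sequences.
#' @param format alignment format; only `"fasta"` is supported.
#' @return a [alignment()] object.
#' @export
read_alignment <- function(path, format = "fasta") {
  format <- match.arg(format, "fasta")
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  seq_lines <- raw[!startsWith(raw, ">")]
  if (!any(startsWith(raw, ">")) || !any(nzchar(seq_lines)))
    stop("format error: no records in ", path)
  if (any(grepl("[Uu]", seq_lines)))
    stop("invalid characters in alignment (DNA only): U")
  d <- suppressWarnings(tryCatch(ape::read.FASTA(path),
                                 error = function(e) stop("format error: ", conditionMessage(e))))
  if (is.null(d) || length(d) == 0L) stop("format error: no records in ", path)
  if (length(d) < 2L) stop("need at least 2 records")
  ch <- as.character(d)                      # list of character vectors
  lens <- lengths(ch)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths differ (", paste(unique(lens), collapse = ", "), ")")
  mat <- toupper(do.call(rbind, ch))
  mat[mat == "?"] <- "N"
  if (any(mat == "U")) stop("invalid characters in alignment (DNA only): U")
  alignment(mat, ids = names(d))
}

#' Write an alignment to FASTA
#' @param aln a [alignment()] object.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "haplogeo_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$mat)))
    writeLines(c(paste0(">", rownames(aln$mat)[i]),
                 paste(aln$mat[i, ], collapse = "")), con)
  invisible(path)
}

#' Parse degree-minute-second coordinates
#'
#' Converts strings such as `N27°50′11″` to signed decimal
#' degrees (`S` and `W` negative). Accepts the typographic variants for the
#' minute/second marks that field tables mix freely (straight quotes, primes,
#' doubled primes, apostrophes).
#'
#' @param text character vector of DMS strings.
#' @return numeric vector of decimal degrees.
#' @export
parse_dms <- function(text) {
  text <- trimws(as.character(text))
  min_mark <- "[′'’]"
  sec_mark <- "(?:″|′′|''|\"|’’|′’|'’|′|’|')"
  pat <- paste0("^([NSEWnsew])\\s*(\\d+(?:\\.\\d+)?)°\\s*(\\d+(?:\\.\\d+)?)",
                min_mark, "\\s*(\\d+(?:\\.\\d+)?)", sec_mark, "$")
  m <- regmatches(text, regexec(pat, text, perl = TRUE))
  vapply(seq_along(text), function(i) {
    g <- m[[i]]
    if (length(g) != 5L) stop("cannot parse DMS coordinate: '", text[i], "'")
    d <- as.numeric(g[3]); mi <- as.numeric(g[4]); s <- as.numeric(g[5])
    if (mi >= 60 || s >= 60) stop("minutes/seconds out of range in '", text[i], "'")
    sgn <- if (toupper(g[2]) %in% c("S", "W")) -1 else 1
    sgn * (d + mi / 60 + s / 3600)
  }, numeric(1))
}

#' Read a population map
#'
#' Tab-separated file with columns `individual`, `population`, `species`,
#' `name`, `lat_dms`, `lon_dms`, `alt_m`. Coordinates are parsed from DMS to
#' decimal degrees at this boundary; everything downstream works in decimal
#' degrees.
#'
#' @param path TSV path.
#' @return data frame of class `haplogeo_popmap` with one row per individual
#'   and numeric `lat`, `lon` columns.
#' @export
read_popmap <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "species", "name", "lat_dms", "lon_dms", "alt_m")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("popmap missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$individual)) stop("duplicate individual ids in popmap")
  d$lat <- parse_dms(d$lat_dms)
  d$lon <- parse_dms(d$lon_dms)
  if (any(abs(d$lat) > 90) || any(abs(d$lon) > 180)) stop("coordinates out of range")
  class(d) <- c("haplogeo_popmap", "data.frame")
  d
}

#' Population-level coordinate table from a popmap
#' @param pm popmap data frame.
#' @return data frame with one row per population (`population`, `species`,
#'   `name`, `lat`, `lon`, `alt_m`).
#' @export
population_coords <- function(pm) {
  u <- pm[!duplicated(pm$population),
          c("population", "species", "name", "lat", "lon", "alt_m")]
  rownames(u) <- NULL
  u
}

#' Haplotype count table
#'
#' Populations x haplotypes matrix of non-negative counts with a species
#' grouping per population and (optionally) one representative recoded
#' character vector per haplotype.
#'
#' @param counts integer matrix, rows = populations, columns = haplotypes.
#' @param grouping named character vector: population -> group (species) label.
#' @param representative optional named list: haplotype -> character vector of
#'   recoded states.
#' @return object of class `haplotable`.
#' @export
haplotype_table <- function(counts, grouping = NULL, representative = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L) stop("empty haplotype table")
  if (any(counts < 0)) stop("negative count in haplotype table")
  if (any(counts != round(counts))) stop("non-integer count in haplotype table")
  if (anyDuplicated(rownames(counts))) stop("duplicate population id")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("pop", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("H", seq_len(ncol(counts)))
  if (any(colSums(counts) == 0)) stop("all-zero haplotype column")
  if (!is.null(grouping)) {
    grouping <- grouping[rownames(counts)]
    if (any(is.na(grouping))) stop("grouping must cover every population")
  }
  if (!is.null(representative)) {
    miss <- setdiff(colnames(counts), names(representative))
    if (length(miss)) stop("representatives missing for: ", paste(miss, collapse = ", "))
    representative <- representative[colnames(counts)]
  }
  structure(list(counts = counts, grouping = grouping, representative = representative),
            class = "haplotable")
}

#' @export
print.haplotable <- function(x, ...) {
  cat("Haplotype table:", nrow(x$counts), "populations x", ncol(x$counts),
      "haplotypes,", sum(x$counts), "individuals\n")
  if (!is.null(x$grouping)) {
    tg <- table(x$grouping)
    cat("Groups:", paste(names(tg), tg, sep = ":", collapse = ", "), "(populations)\n")
  }
  invisible(x)
}

#' Restrict a haplotype table to one group
#' @param ht haplotable.
#' @param group group (species) label.
#' @export
subset_group <- function(ht, group) {
  if (is.null(ht$grouping)) stop("table has no grouping")
  if (!group %in% ht$grouping) stop("unknown group: ", group)
  keep <- names(ht$grouping)[ht$grouping == group]
  counts <- ht$counts[keep, , drop = FALSE]
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  haplotype_table(counts, grouping = ht$grouping[keep],
                  representative = if (!is.null(ht$representative)) ht$representative[colnames(counts)])
}

# parse "H1(5), H2(3)" cells into a named count vector
parse_count_list <- function(cell) {
  cell <- trimws(cell)
  if (cell == "" || is.na(cell)) return(integer(0))
  parts <- trimws(strsplit(cell, ",")[[1]])
  m <- regmatches(parts, regexec("^([A-Za-z0-9_.-]+)\\((\\d+)\\)$", parts))
  if (any(lengths(m) != 3L)) stop("cannot parse count list cell: '", cell, "'")
  setNames(as.integer(vapply(m, `[`, "", 3L)), vapply(m, `[`, "", 2L))
}

#' Read a haplotype count table
#'
#' Two layouts are accepted: (i) a wide TSV whose haplotype columns are named
#' `H*` and hold integer counts, or (ii) a field-table layout with a
#' `chlorotypes` column of `Hk(n)` lists. Both need a `population` column; a
#' `species` column, when present, becomes the grouping.
#'
#' @param path TSV path.
#' @return a [haplotype_table()].
#' @export
read_haplotype_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(d) == 0L) stop("empty haplotype table file")
  if (!"population" %in% names(d)) stop("need a 'population' column")
  if (anyDuplicated(d$population)) stop("duplicate population id")
  if ("chlorotypes" %in% names(d)) {
    lst <- lapply(d$chlorotypes, parse_count_list)
    haps <- unique(unlist(lapply(lst, names)))
    haps <- haps[order(suppressWarnings(as.integer(sub("^[A-Za-z]+", "", haps))), haps)]
    counts <- matrix(0L, nrow(d), length(haps), dimnames = list(d$population, haps))
    for (i in seq_along(lst)) counts[i, names(lst[[i]])] <- lst[[i]]
  } else {
    hap_cols <- grep("^H", names(d), value = TRUE)
    if (!length(hap_cols)) stop("no haplotype columns found")
    counts <- as.matrix(d[, hap_cols, drop = FALSE])
    storage.mode(counts) <- "integer"
    rownames(counts) <- d$population
  }
  grouping <- if ("species" %in% names(d)) setNames(d$species, d$population)
  haplotype_table(counts, grouping = grouping)
}

#' Write a haplotype table as a wide TSV
#' @param ht haplotable.
#' @param path output path.
#' @export
write_haplotype_table <- function(ht, path) {
  d <- data.frame(population = rownames(ht$counts),
                  species = if (!is.null(ht$grouping)) unname(ht$grouping) else NA,
                  ht$counts, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
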