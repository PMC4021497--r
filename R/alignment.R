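#' Read an aligned FASTA file of marker sequences
#'
#' Reads a per-locus alignment (e.g. the *ITS* spacer or the *NifD* gene of
#' nodule isolates) into a simple character-matrix alignment object. Headers
#' are taken up to the first whitespace and must carry the isolate ids used
#' in the nodule table.
#'
#' @param path Path to an aligned FASTA file.
#' @param locus Locus label attached to the alignment (e.g. `"ITS"`,
#'   `"NifD"`).
#' @return An object of class `haplo_alignment`: a list with elements
#'   `locus`, `ids` and `seq` (character matrix, one row per isolate, one
#'   column per alignment site, residues in `A,C,G,T,N,-`).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">i1", "ACGT", ">i2", "ACGA"), fa)
#' aln <- read_alignment(fa, locus = "demo")
#' dim(aln$seq)
#' @export
read_alignment <- function(path, locus = "ITS") {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) stop("parse error: '", path, "' is empty")
  if (!startsWith(trimws(raw[[1L]]), ">"))
    stop("parse error: '", path, "' does not start with a FASTA header")
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("parse error: no sequences in '", path, "'")
  ids <- vapply(strsplit(names(dna), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("parse error: duplicated isolate id '", ids[duplicated(ids)][1L], "'")
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) {
    bad <- ids[which(lens != lens[1L])[1L]]
    stop("alignment error: record '", bad, "' has length ", lens[lens != lens[1L]][1L],
         ", expected ", lens[1L])
  }
  seq <- toupper(do.call(rbind, as.character(dna)))
  rownames(seq) <- ids
  new_haplo_alignment(locus, seq)
}

new_haplo_alignment <- function(locus, seq) {
  stopifnot(is.matrix(seq), nrow(seq) >= 1L)
  ok <- seq %in% c("A", "C", "G", "T", "N", "-")
  if (!all(ok)) {
    bad <- unique(seq[!ok])
    stop("alignment error: unsupported residue(s) ", paste(bad, collapse = ", "),
         " (expected A,C,G,T,N,-)")
  }
  structure(list(locus = locus, ids = rownames(seq), seq = seq),
            class = "haplo_alignment")
}

#' Write an alignment to FASTA
#'
#' @param aln A `haplo_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "haplo_alignment"))
  lines <- character(2L * nrow(aln$seq))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  lines[c(FALSE, TRUE)] <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.haplo_alignment <- function(x, ...) {
  cat("Haplotype alignment (", x$locus, "): ", nrow(x$seq), " sequences x ",
      ncol(x$seq), " sites\n", sep = "")
  gaps <- sum(apply(x$seq == "-", 2L, any))
  if (gaps > 0L) cat("  ", gaps, " column(s) contain gaps\n", sep = "")
  invisible(x)
}

#' Remove alignment columns containing indels
#'
#' Columns in which any sequence carries a gap (`-`) are removed before
#' genotype calling and distance computation; indel-containing regions of
#' the *ITS* spacer are ambiguous to score as point differences, so every
#' gapped column is dropped. Column order is preserved.
#'
#' @param aln A `haplo_alignment`.
#' @return The gap-free `haplo_alignment`, with attribute
#'   `"columns_removed"` giving the number of columns dropped.
#' @export
strip_indel_columns <- function(aln) {
  stopifnot(inherits(aln, "haplo_alignment"))
  gap <- apply(aln$seq == "-", 2L, any)
  if (all(gap))
    stop("all ", length(gap), " columns contain gaps: no informative sites remain")
  out <- new_haplo_alignment(aln$locus, aln$seq[, !gap, drop = FALSE])
  attr(out, "columns_removed") <- sum(gap)
  out
}

#' Collapse aligned sequences into genotypes
#'
#' Sequences that differ at one or more nucleotide sites are distinct
#' genotypes; identical sequences share a genotype. Labels `G1, G2, ...`
#' are assigned in order of first appearance, so the assignment is
#' deterministic and, for unambiguous sequences, invariant (up to label
#' renaming) under permutation of the input.
#'
#' @param aln A `haplo_alignment`, normally indel-stripped first (a warning
#'   is issued if gap characters are present).
#' @param ignore_ambiguous If `TRUE` (default), sites at which either
#'   sequence is `N` are excluded from the identity comparison; if `FALSE`,
#'   `N` mismatches any other residue. With ambiguous bases present the
#'   N-tolerant match is applied greedily against genotype representatives
#'   in first-appearance order.
#' @return An object of class `genotype_assignment`: list with `locus`,
#'   `assignment` (named character vector isolate -> label),
#'   `representatives` (named character vector label -> sequence) and
#'   `n_genotypes`.
#' @export
call_genotypes <- function(aln, ignore_ambiguous = TRUE) {
  stopifnot(inherits(aln, "haplo_alignment"))
  if (any(aln$seq == "-"))
    warning("alignment contains gap characters; run strip_indel_columns() first")
  n <- nrow(aln$seq)
  labels <- character(n)
  reps <- list()           # representative rows, one per genotype
  for (i in seq_len(n)) {
    s <- aln$seq[i, ]
    hit <- 0L
    for (g in seq_along(reps)) {
      if (identical_seq(s, reps[[g]], ignore_ambiguous)) { hit <- g; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- s
      hit <- length(reps)
    }
    labels[i] <- paste0("G", hit)
  }
  names(labels) <- aln$ids
  rep_str <- vapply(reps, paste, "", collapse = "")
  names(rep_str) <- paste0("G", seq_along(reps))
  structure(list(locus = aln$locus, assignment = labels,
                 representatives = rep_str, n_genotypes = length(reps)),
            class = "genotype_assignment")
}

identical_seq <- function(a, b, ignore_ambiguous) {
  if (ignore_ambiguous) {
    use <- a != "N" & b != "N"
    all(a[use] == b[use])
  } else {
    all(a == b)
  }
}

#' @export
print.genotype_assignment <- function(x, ...) {
  cat("Genotype assignment (", x$locus, "): ", length(x$assignment),
      " isolates -> ", x$n_genotypes, " genotypes\n", sep = "")
  print(table(genotype = x$assignment))
  invisible(x)
}

#' Pairwise nucleotide differences between aligned sequences
#'
#' Entry (i, j) counts the sites at which sequences i and j carry different
#' residues. Sites at which either sequence is `N` are skipped when
#' `ignore_ambiguous = TRUE` (default).
#'
#' @param aln A `haplo_alignment` with equal-length sequences.
#' @param ignore_ambiguous Skip sites where either residue is `N`.
#' @return A symmetric integer matrix with zero diagonal, labelled by
#'   isolate id.
#' @export
pairwise_differences <- function(aln, ignore_ambiguous = TRUE) {
  stopifnot(inherits(aln, "haplo_alignment"))
  seq_matrix_differences(aln$seq, ignore_ambiguous)
}

seq_matrix_differences <- function(m, ignore_ambiguous = TRUE) {
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(d)
  for (i in 1:(n - 1L)) {
    a <- m[i, ]
    for (j in (i + 1L):n) {
      b <- m[j, ]
      diff <- a != b
      if (ignore_ambiguous) diff <- diff & a != "N" & b != "N"
      d[i, j] <- d[j, i] <- sum(diff)
    }
  }
  d
}

#' Pairwise differences between genotype representative sequences
#'
#' @param gt A `genotype_assignment`.
#' @param ignore_ambiguous Skip `N` sites.
#' @return Symmetric matrix of nucleotide differences labelled by genotype.
#' @export
genotype_distances <- function(gt, ignore_ambiguous = TRUE) {
  stopifnot(inherits(gt, "genotype_assignment"))
  m <- do.call(rbind, strsplit(gt$representatives, ""))
  rownames(m) <- names(gt$representatives)
  seq_matrix_differences(m, ignore_ambiguous)
}

#' Count joint genotype combinations across two loci
#'
#' Over isolates typed at both loci, counts the number of distinct
#' (label at locus 1, label at locus 2) pairs.
#'
#' @param gt1,gt2 `genotype_assignment` objects for the two loci.
#' @return Integer count of unique genotype combinations.
#' @export
genotype_combinations <- function(gt1, gt2) {
  shared <- intersect(names(gt1$assignment), names(gt2$assignment))
  length(unique(paste(gt1$assignment[shared], gt2$assignment[shared])))
}

#' Write a labelled distance matrix as TSV
#' @param d Symmetric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(data.frame(label = rownames(d), d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled distance matrix from TSV
#' @param path Path written by [write_distance_matrix()].
#' @return Symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE)
  d <- as.matrix(x[, -1L, drop = FALSE])
  rownames(d) <- x[[1L]]
  storage.mode(d) <- "double"
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix is not symmetric")
  d
}

#' Write a per-isolate genotype table as TSV
#' @param gt A `genotype_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path) {
  utils::write.table(
    data.frame(isolate_id = names(gt$assignment), locus = gt$locus,
               genotype_label = unname(gt$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
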