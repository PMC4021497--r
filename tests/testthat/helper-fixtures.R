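# Build an alignment in code from residue strings
make_aln <- function(..., locus = "ITS") {
  s <- c(...)
  m <- do.call(rbind, strsplit(toupper(s), ""))
  rownames(m) <- if (is.null(names(s))) paste0("i", seq_along(s)) else names(s)
  symbiospec:::new_haplo_alignment(locus, m)
}

write_fasta_tmp <- function(..., ids = NULL) {
  s <- c(...)
  if (is.null(ids)) ids <- paste0("i", seq_along(s))
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), s)), path)
  path
}

# Independent brute-force PDI: sort descending, sum of gaps to the top
oracle_pdi <- function(p, denominator = length(p) - 1) {
  s <- sort(p, decreasing = TRUE)
  sum(s[1] - s[-1]) / denominator
}

# Brute-force SSD partition computed element by element from its definition:
# SSD of a set = (1/n) * sum over unordered pairs of squared distance
oracle_ssd_partition <- function(d, pop, grp_of_pop) {
  d2 <- d^2
  n <- length(pop)
  ssd_set <- function(idx) {
    if (length(idx) < 2) return(0)
    tot <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b) tot <- tot + d2[idx[a], idx[b]]
    }
    tot / length(idx)
  }
  total <- ssd_set(seq_len(n))
  wp <- 0
  for (p in unique(pop)) wp <- wp + ssd_set(which(pop == p))
  grp <- grp_of_pop[pop]
  wg <- 0
  for (g in unique(grp)) wg <- wg + ssd_set(which(grp == g))
  list(total = total, within_pop = wp,
       among_pop_within = wg - wp, among_grp = total - wg)
}

# Per-site brute-force distance count over ungapped columns
oracle_pairwise_diff <- function(strings) {
  chars <- strsplit(strings, "")
  L <- length(chars[[1]])
  keep <- !vapply(seq_len(L), function(j)
    any(vapply(chars, function(s) s[j] == "-", TRUE)), TRUE)
  n <- length(chars)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (k in which(keep)) {
      a <- chars[[i]][k]; b <- chars[[j]][k]
      if (a != b && a != "N" && b != "N") d[i, j] <- d[i, j] + 1L
    }
  }
  d
}

# All n! permutations of 1..n as rows (recursive, for tiny n)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Small exchangeable sequence sample: iid draws from a haplotype pool
random_pool_dist <- function(n, n_haplo = 4, length = 60) {
  pool <- replicate(n_haplo, sample(c("A", "C", "G", "T"), length, TRUE),
                    simplify = FALSE)
  m <- do.call(rbind, pool[sample.int(n_haplo, n, replace = TRUE)])
  rownames(m) <- paste0("i", seq_len(n))
  symbiospec:::seq_matrix_differences(m)
}
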