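#' @name popgen
#' @title Sequence-based population structure
#' @description
#' Population structure of symbiont sequences sampled from different host
#' species: mean pairwise nucleotide differences within and between
#' populations (with the standard within-diversity correction), pairwise
#' Phi-st estimated from AMOVA variance components of squared distances,
#' and a two-level hierarchical AMOVA (within populations / between
#' populations within groups / between groups) with permutation tests.
#' Distances are raw pairwise nucleotide differences; squared distances
#' enter the sums of squared deviations, following the standard molecular
#' variance formulation.
NULL

check_part <- function(d, pop) {
  if (is.null(rownames(d))) stop("distance matrix must have row/col labels")
  if (is.null(names(pop))) stop("population assignment must be named by isolate id")
  miss <- setdiff(rownames(d), names(pop))
  if (length(miss))
    stop("isolate(s) without population assignment: ", paste(miss, collapse = ", "))
  pop[rownames(d)]
}

# One-level AMOVA components from a squared-distance matrix and population factor.
amova_components_1 <- function(D2, pop) {
  n <- length(pop)
  sets <- split(seq_len(n), pop)
  P <- length(sets)
  np <- lengths(sets)
  ssd_total <- sum(D2) / (2 * n)
  ssd_wp <- sum(vapply(sets, function(i) sum(D2[i, i, drop = FALSE]), 0) / (2 * np))
  ssd_ap <- ssd_total - ssd_wp
  df_ap <- P - 1L
  df_wp <- n - P
  sigma_w <- ssd_wp / df_wp
  n0 <- (n - sum(np^2) / n) / (P - 1)
  sigma_a <- (ssd_ap / df_ap - sigma_w) / n0
  list(ssd_total = ssd_total, ssd_among = ssd_ap, ssd_within = ssd_wp,
       df_among = df_ap, df_within = df_wp,
       sigma_a = sigma_a, sigma_w = sigma_w,
       phi_st = sigma_a / (sigma_a + sigma_w))
}

#' Pairwise Phi-st between two populations with a permutation test
#'
#' Phi-st is the analogue of Wright's F_ST that weights haplotypes by
#' their sequence divergence as well as their frequency: the proportion of
#' molecular variance (from squared pairwise nucleotide differences)
#' attributable to the between-population level. Significance is assessed
#' by permuting isolates between the two populations.
#'
#' @param dist Symmetric matrix of pairwise nucleotide differences between
#'   isolates (labelled).
#' @param pop Named character/factor vector mapping isolate id to one of
#'   exactly two population labels; each population needs >= 2 isolates.
#' @param perms Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return Object of class `phi_st`: list with `phi_st`, `p` (+1-corrected
#'   upper-tail permutation p), `sigma` components, `perms`, `seed`. When
#'   all sequences are identical Phi-st is undefined and reported `NA`
#'   with p = 1.
#' @export
phi_st <- function(dist, pop, perms = 10000L, seed = NULL) {
  pop <- as.character(check_part(dist, pop))
  if (length(unique(pop)) != 2L)
    stop("phi_st needs exactly 2 populations, got ", length(unique(pop)))
  if (any(table(pop) < 2L)) stop("each population needs at least 2 isolates")
  D2 <- dist^2
  obs <- amova_components_1(D2, pop)
  if (obs$sigma_a + obs$sigma_w == 0 || !is.finite(obs$phi_st)) {
    return(structure(list(phi_st = NA_real_, p = 1, sigma = obs, perms = 0L,
                          seed = seed), class = "phi_st"))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(pop)
  ge <- 0L
  for (k in seq_len(perms)) {
    st <- amova_components_1(D2, pop[sample.int(n)])$phi_st
    if (is.finite(st) && st >= obs$phi_st) ge <- ge + 1L
  }
  structure(list(phi_st = obs$phi_st, p = (ge + 1) / (perms + 1),
                 sigma = obs, perms = as.integer(perms), seed = seed),
            class = "phi_st")
}

#' @export
print.phi_st <- function(x, digits = 4, ...) {
  cat("Phi-st = ", format(x$phi_st, digits = digits),
      " (p = ", format(x$p, digits = 3), ", ", x$perms, " permutations)\n",
      sep = "")
  invisible(x)
}

#' Two-level hierarchical AMOVA with permutation tests
#'
#' Partitions the total sum of squared pairwise distances into three
#' levels -- between groups (e.g. host genera), between populations within
#' groups (host species within genus), and within populations -- and
#' estimates the corresponding variance components sigma_a, sigma_b,
#' sigma_c by equating observed and expected mean squares. Negative
#' components are reported as computed, not truncated. Permutation
#' schemes per level: within (Phi_ST) permutes isolates freely; between
#' populations within groups (Phi_SC) permutes isolates among populations
#' of the same group; between groups (Phi_CT) permutes whole populations
#' among groups.
#'
#' @param dist Labelled symmetric matrix of pairwise nucleotide
#'   differences between isolates.
#' @param pop Named vector: isolate id -> population label.
#' @param group Named vector: population label -> group label. With a
#'   single group the group level is dropped (df 0) and the result
#'   matches the one-level partition.
#' @param perms Number of permutations per level (default 10000).
#' @param seed Optional integer seed.
#' @return Object of class `amova`: list with a per-level `table`
#'   (df, SSD, variance component, percent of variance, permutation p),
#'   `phi` statistics, `perms`, `seed`, and
#'   `n_group_relabelings` (number of distinct assignments of populations
#'   to groups; with few populations the attainable minimum p for the
#'   group level is bounded below by its reciprocal).
#' @export
amova_two_level <- function(dist, pop, group, perms = 10000L, seed = NULL) {
  pop <- as.character(check_part(dist, pop))
  if (is.null(names(group))) stop("'group' must be named by population label")
  if (!all(unique(pop) %in% names(group)))
    stop("population(s) without group assignment: ",
         paste(setdiff(unique(pop), names(group)), collapse = ", "))
  grp_of_pop <- as.character(group[unique(pop)])
  names(grp_of_pop) <- unique(pop)
  grp <- grp_of_pop[pop]
  n <- length(pop)
  if (n < 4L) stop("need at least 4 isolates")
  D2 <- dist^2
  obs <- amova_components_2(D2, pop, grp)
  single_pop_groups <- names(which(tapply(pop, grp, function(x) length(unique(x))) == 1L))
  if (length(single_pop_groups) && length(unique(grp)) > 1L)
    warning("group(s) with a single population (",
            paste(single_pop_groups, collapse = ", "),
            "): between-population component estimated from the pooled coefficient")
  if (!is.null(seed)) set.seed(seed)
  pops_by_grp <- split(seq_len(n), grp)
  # permutation p per level
  ge <- c(ct = 0L, sc = 0L, st = 0L)
  nper <- c(ct = 0L, sc = 0L, st = 0L)
  if (perms > 0L) {
    for (k in seq_len(perms)) {
      # Phi_ST: permute isolates freely (both pop and group follow the isolate slot)
      i <- sample.int(n)
      st <- amova_components_2(D2, pop[i], grp[i])$phi["st"]
      if (is.finite(st)) { nper["st"] <- nper["st"] + 1L
        if (st >= obs$phi["st"]) ge["st"] <- ge["st"] + 1L }
      # Phi_SC: permute isolates among populations within each group
      p2 <- pop
      for (g in pops_by_grp) p2[g] <- pop[g][sample.int(length(g))]
      sc <- amova_components_2(D2, p2, grp)$phi["sc"]
      if (is.finite(sc)) { nper["sc"] <- nper["sc"] + 1L
        if (sc >= obs$phi["sc"]) ge["sc"] <- ge["sc"] + 1L }
      # Phi_CT: permute whole populations among groups
      g2 <- grp_of_pop
      g2[] <- grp_of_pop[sample.int(length(grp_of_pop))]
      ct <- amova_components_2(D2, pop, g2[pop])$phi["ct"]
      if (is.finite(ct)) { nper["ct"] <- nper["ct"] + 1L
        if (ct >= obs$phi["ct"]) ge["ct"] <- ge["ct"] + 1L }
    }
  }
  pvals <- ifelse(nper > 0L, (ge + 1) / (nper + 1), NA_real_)
  sig <- obs$sigma
  pct <- 100 * sig / sum(sig)
  tab <- data.frame(
    source = c("Between groups", "Between populations within groups",
               "Within populations", "Total"),
    df = c(obs$df, sum(obs$df)),
    SSD = c(obs$ssd, sum(obs$ssd)),
    sigma2 = c(sig, sum(sig)),
    percent = c(pct, NA),
    p = c(pvals[["ct"]], pvals[["sc"]], pvals[["st"]], NA))
  P <- length(grp_of_pop)
  n_relab <- factorial(P) / prod(factorial(table(grp_of_pop)))
  structure(list(table = tab, phi = obs$phi, perms = as.integer(perms),
                 seed = seed, n_group_relabelings = n_relab),
            class = "amova")
}

# Two-level variance components; grp has one group label per isolate.
amova_components_2 <- function(D2, pop, grp) {
  n <- length(pop)
  key <- paste(grp, pop, sep = "\r")
  pops <- split(seq_len(n), key)
  np <- lengths(pops)
  grp_of_pop <- vapply(strsplit(names(pops), "\r", fixed = TRUE), `[[`, "", 1L)
  groups <- split(seq_len(n), grp)
  Ng <- lengths(groups)
  P <- length(pops)
  G <- length(groups)
  ssd_total <- sum(D2) / (2 * n)
  ssd_wp <- sum(vapply(pops, function(i) sum(D2[i, i, drop = FALSE]), 0) / (2 * np))
  ssd_wg <- sum(vapply(groups, function(i) sum(D2[i, i, drop = FALSE]), 0) / (2 * Ng))
  ssd_ap <- ssd_wg - ssd_wp        # among populations within groups
  ssd_ag <- ssd_total - ssd_wg     # among groups
  df <- c(G - 1L, P - G, n - P)
  sigma_c <- if (df[3L] > 0L) ssd_wp / df[3L] else 0
  # expected-mean-square coefficients (unbalanced design):
  # Sg = sum over groups of (sum of n_p^2 within the group) / group size
  Sg <- sum(vapply(names(groups), function(g) {
    i <- grp_of_pop == g
    sum(np[i]^2) / sum(np[i])
  }, 0))
  if (G > 1L && P > G) {
    n1 <- (n - Sg) / (P - G)
    sigma_b <- (ssd_ap / df[2L] - sigma_c) / n1
  } else if (G == 1L && P > 1L) {
    n1 <- (n - sum(np^2) / n) / (P - 1)
    sigma_b <- (ssd_ap / df[2L] - sigma_c) / n1
  } else sigma_b <- 0
  if (G > 1L) {
    n2 <- (Sg - sum(np^2) / n) / (G - 1)
    n3 <- (n - sum(Ng^2) / n) / (G - 1)
    sigma_a <- (ssd_ag / df[1L] - sigma_c - n2 * sigma_b) / n3
  } else sigma_a <- 0
  tot <- sigma_a + sigma_b + sigma_c
  phi <- c(ct = sigma_a / tot,
           sc = sigma_b / (sigma_b + sigma_c),
           st = (sigma_a + sigma_b) / tot)
  list(ssd = c(ssd_ag, ssd_ap, ssd_wp), df = df,
       sigma = c(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c),
       phi = phi, ssd_total = ssd_total)
}

#' @export
print.amova <- function(x, digits = 4, ...) {
  cat("Two-level hierarchical AMOVA (", x$perms, " permutations)\n", sep = "")
  tab <- x$table
  tab$SSD <- round(tab$SSD, 3)
  tab$sigma2 <- round(tab$sigma2, digits)
  tab$percent <- round(tab$percent, 2)
  print(tab, row.names = FALSE)
  cat("Phi_CT = ", format(x$phi[["ct"]], digits = digits),
      ", Phi_SC = ", format(x$phi[["sc"]], digits = digits),
      ", Phi_ST = ", format(x$phi[["st"]], digits = digits), "\n", sep = "")
  if (x$n_group_relabelings < 25)
    cat("note: only ", x$n_group_relabelings, " distinct population-to-group ",
        "relabelings exist; attainable minimum p for the group level is ~1/",
        x$n_group_relabelings, "\n", sep = "")
  invisible(x)
}

#' Within/between-population diversity summary with pairwise Phi-st
#'
#' Produces the classic square summary of population structure: diagonal
#' entries are mean within-population pairwise nucleotide differences;
#' below the diagonal, corrected mean between-population differences
#' (raw cross-population mean minus the average of the two within-
#' population means); above the diagonal, pairwise Phi-st with a
#' permutation significance category.
#'
#' @param dist Labelled symmetric matrix of pairwise differences.
#' @param pop Named vector isolate id -> population label.
#' @param perms Permutations for each pairwise Phi-st test.
#' @param seed Optional integer seed.
#' @return Object of class `diversity_matrix`: list with `within` (named
#'   vector; `NA` for singleton populations), `between_raw`,
#'   `between_corrected`, `phist`, `p` matrices, a combined display
#'   `matrix` (lower = corrected differences, upper = Phi-st), and a
#'   `long` data frame with one row per population pair.
#' @export
diversity_matrix <- function(dist, pop, perms = 1000L, seed = NULL) {
  pop <- as.character(check_part(dist, pop))
  pops <- unique(pop)
  K <- length(pops)
  if (K < 2L) stop("need at least 2 populations")
  idx <- split(seq_len(nrow(dist)), factor(pop, levels = pops))
  within <- vapply(pops, function(p) {
    i <- idx[[p]]
    if (length(i) < 2L) return(NA_real_)
    sum(dist[i, i]) / (length(i) * (length(i) - 1L))
  }, 0)
  braw <- bcor <- phm <- pm <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  if (!is.null(seed)) set.seed(seed)
  for (a in 1:(K - 1L)) for (b in (a + 1L):K) {
    ia <- idx[[a]]; ib <- idx[[b]]
    raw <- mean(dist[ia, ib])
    braw[a, b] <- braw[b, a] <- raw
    bcor[a, b] <- bcor[b, a] <- raw - (within[a] + within[b]) / 2
    if (length(ia) >= 2L && length(ib) >= 2L) {
      sub <- c(ia, ib)
      ph <- phi_st(dist[sub, sub], stats::setNames(pop[sub], rownames(dist)[sub]),
                   perms = perms)
      phm[a, b] <- phm[b, a] <- ph$phi_st
      pm[a, b] <- pm[b, a] <- ph$p
    }
  }
  disp <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  diag(disp) <- within
  disp[lower.tri(disp)] <- bcor[lower.tri(bcor)]
  disp[upper.tri(disp)] <- phm[upper.tri(phm)]
  pairs <- which(upper.tri(braw), arr.ind = TRUE)
  long <- data.frame(
    pop1 = pops[pairs[, 1L]], pop2 = pops[pairs[, 2L]],
    within1 = within[pairs[, 1L]], within2 = within[pairs[, 2L]],
    between_raw = braw[pairs], between_corrected = bcor[pairs],
    phi_st = phm[pairs], p = pm[pairs], row.names = NULL)
  structure(list(within = within, between_raw = braw, between_corrected = bcor,
                 phist = phm, p = pm, matrix = disp, long = long,
                 perms = as.integer(perms), seed = seed),
            class = "diversity_matrix")
}

#' @export
print.diversity_matrix <- function(x, digits = 4, ...) {
  cat("Population diversity summary\n",
      "(diagonal: mean within-population differences; lower: corrected ",
      "between-population differences; upper: pairwise Phi-st)\n", sep = "")
  m <- format(round(x$matrix, digits))
  stars <- ifelse(is.na(x$p), "", ifelse(x$p <= 0.001, "***",
            ifelse(x$p <= 0.01, "**", ifelse(x$p <= 0.05, "*", "ns"))))
  m[upper.tri(m)] <- paste0(m[upper.tri(m)], stars[upper.tri(stars)])
  print(m, quote = FALSE)
  invisible(x)
}

#' Write the long-format diversity summary as TSV
#' @param dm A `diversity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diversity_matrix <- function(dm, path) {
  utils::write.table(dm$long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
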