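#' Simulate a multi-host nodule-association survey
#'
#' Generates a nodule-isolate table in which each host species draws its
#' nodules multinomially from a host-specific genotype preference profile
#' over a shared genotype pool. The default shape mirrors a four-host
#' field survey genotyped at 22 symbiont genotypes with per-host sample
#' sizes 19/18/21/23. Preference profiles can be supplied explicitly or
#' drawn from a symmetric Dirichlet: small `alpha` gives spiky
#' (specialist) profiles, large `alpha` flat (generalist) ones.
#'
#' @param n_genotypes Number of genotypes in the pool (>= 2).
#' @param nodules Named integer vector of nodules per host; names are the
#'   host species codes.
#' @param host_genus Named map host species -> genus (defaults pair the
#'   four default hosts into two genera).
#' @param profiles Optional hosts x genotypes matrix of preference
#'   probabilities (rows sum to 1). Overrides `alpha`.
#' @param alpha Dirichlet concentration used to draw each host's profile
#'   when `profiles` is `NULL` (default 0.2: strongly skewed pools, the
#'   regime in which field hosts show marked specialization).
#' @param nodules_per_plant Nodules sampled per plant when assembling
#'   plant/nodule ids (default 5).
#' @param seed Optional integer seed.
#' @return Object of class `association_sim`: list with `table` (a
#'   nodule-isolate data frame with identical `genotype_ITS` and
#'   `genotype_NifD` labels, standing for fully linked loci), `profiles`
#'   (the generating truth), `counts` and `seed`.
#' @export
simulate_association <- function(n_genotypes = 22L,
                                 nodules = c(ACHE = 19L, ACST = 18L,
                                             LUAR = 21L, LUBI = 23L),
                                 host_genus = NULL,
                                 profiles = NULL, alpha = 0.2,
                                 nodules_per_plant = 5L, seed = NULL) {
  if (n_genotypes < 2L) stop("need at least 2 genotypes")
  if (is.null(names(nodules)) || any(nodules < 1L))
    stop("'nodules' must be a named vector of counts >= 1")
  hosts <- names(nodules)
  if (is.null(host_genus)) {
    host_genus <- stats::setNames(substr(hosts, 1L, 2L), hosts)
    if (identical(sort(hosts), c("ACHE", "ACST", "LUAR", "LUBI")))
      host_genus <- c(ACHE = "Acmispon", ACST = "Acmispon",
                      LUAR = "Lupinus", LUBI = "Lupinus")
  }
  if (!is.null(seed)) set.seed(seed)
  G <- as.integer(n_genotypes)
  if (is.null(profiles)) {
    profiles <- t(vapply(hosts, function(h) {
      g <- stats::rgamma(G, shape = alpha)
      g / sum(g)
    }, numeric(G)))
  } else {
    profiles <- as.matrix(profiles)
    if (nrow(profiles) != length(hosts) || ncol(profiles) != G)
      stop("'profiles' must be ", length(hosts), " x ", G)
    if (any(abs(rowSums(profiles) - 1) > 1e-9))
      stop("profile rows must sum to 1")
  }
  rownames(profiles) <- hosts
  colnames(profiles) <- paste0("G", seq_len(G))
  rows <- list()
  counts <- matrix(0L, length(hosts), G, dimnames = dimnames(profiles))
  iso <- 0L
  for (h in hosts) {
    cnt <- stats::rmultinom(1L, nodules[[h]], profiles[h, ])[, 1L]
    counts[h, ] <- cnt
    geno <- rep(colnames(profiles), cnt)
    geno <- sample(geno)              # shuffle nodule order within host
    n_h <- length(geno)
    plant <- paste0(h, "_p", ((seq_len(n_h) - 1L) %/% nodules_per_plant) + 1L)
    nod <- paste0("n", stats::ave(seq_len(n_h), plant, FUN = seq_along))
    ids <- paste0(h, "_i", sprintf("%02d", seq_len(n_h)))
    rows[[h]] <- data.frame(
      isolate_id = ids, host_species = h, host_genus = host_genus[[h]],
      plant_id = plant, nodule_id = nod,
      genotype_ITS = geno, genotype_NifD = geno)
    iso <- iso + n_h
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, profiles = profiles, counts = counts,
                 seed = seed),
            class = "association_sim")
}

#' Simulate a two-cluster haplotype alignment
#'
#' Generates aligned marker sequences with the genetic structure the
#' population analyses assume: a random root sequence, cluster consensus
#' sequences diverged from the root so that consensuses of different
#' clusters differ at about `between` sites, and genotypes diverged from
#' their cluster consensus at about `within`/2 sites each (so within-
#' cluster pairs differ at about `within` sites). Optionally a fraction
#' of columns receives gap characters in a random subset of sequences,
#' emulating indel-containing spacer regions.
#'
#' @param n_clusters Number of clusters (default 2, emulating host-genus
#'   clustering).
#' @param genotypes_per_cluster Genotypes per cluster.
#' @param isolates_per_genotype Isolates carrying each genotype
#'   (default 1).
#' @param length Alignment length in nucleotides (>= 50).
#' @param within Expected pairwise differences within a cluster.
#' @param between Expected pairwise differences between clusters
#'   (>= `within`).
#' @param indel_rate Fraction of columns to convert into gap-bearing
#'   columns (default 0).
#' @param locus Locus label for the alignment.
#' @param seed Optional integer seed.
#' @return Object of class `sequence_sim`: list with `alignment`
#'   (a `haplo_alignment`), `cluster` (named vector isolate -> cluster),
#'   `genotype` (named vector isolate -> true genotype index) and `seed`.
#' @export
simulate_sequences <- function(n_clusters = 2L, genotypes_per_cluster = 11L,
                               isolates_per_genotype = 1L, length = 800L,
                               within = 2, between = 20, indel_rate = 0,
                               locus = "NifD", seed = NULL) {
  if (length < 50L) stop("alignment length must be >= 50")
  if (between < within) stop("'between' divergence must be >= 'within'")
  if (between > length) stop("requested divergence exceeds sequence length")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, length, replace = TRUE)
  mutate <- function(s, k) {
    k <- min(k, base::length(s))
    if (k < 1L) return(s)
    sites <- sample.int(base::length(s), k)
    s[sites] <- vapply(s[sites], function(b) sample(setdiff(bases, b), 1L), "")
    s
  }
  seqs <- list(); cl <- c(); gt <- c()
  for (c_i in seq_len(n_clusters)) {
    consensus <- mutate(root, stats::rpois(1L, between / 2))
    for (g_i in seq_len(genotypes_per_cluster)) {
      geno_seq <- mutate(consensus, stats::rpois(1L, within / 2))
      for (r in seq_len(isolates_per_genotype)) {
        id <- sprintf("c%dg%02dr%d", c_i, g_i, r)
        seqs[[id]] <- geno_seq
        cl[id] <- paste0("cluster", c_i)
        gt[id] <- sprintf("c%dg%02d", c_i, g_i)
      }
    }
  }
  m <- do.call(rbind, seqs)
  if (indel_rate > 0) {
    n_gap <- max(1L, round(indel_rate * length))
    cols <- sample.int(length, n_gap)
    for (col in cols) {
      # a proper, nonempty subset of sequences carries the gap
      k <- sample.int(nrow(m) - 1L, 1L)
      m[sample.int(nrow(m), k), col] <- "-"
    }
  }
  structure(list(alignment = new_haplo_alignment(locus, m),
                 cluster = cl, genotype = gt, seed = seed),
            class = "sequence_sim")
}

#' Simulate a complete field survey: nodule table plus marker alignments
#'
#' Combines [simulate_association()] and [simulate_sequences()] into a
#' pipeline-ready bundle: the nodule-isolate table of a multi-host survey
#' together with per-locus alignments in which every isolate carries the
#' sequence of its genotype. Genotypes are split into two sequence
#' clusters (emulating host-genus clustering of symbiont lineages); the
#' two loci share genotype labels (fully linked markers) but have
#' independent sequences, with marker-realistic default lengths and
#' indel columns injected only into the spacer locus.
#'
#' @param seed Integer seed driving the whole bundle.
#' @param its_length,nifd_length Alignment lengths (defaults 1256 and
#'   756 nt).
#' @param within,between Expected within-/between-cluster pairwise
#'   differences for the sequence clusters.
#' @param its_indel_rate Fraction of spacer columns carrying gaps.
#' @param ... Passed to [simulate_association()].
#' @return Object of class `field_survey_sim`: list with `table`,
#'   `alignments` (named list of `haplo_alignment`, loci `ITS` and
#'   `NifD`), `association` (the full `association_sim`) and `clusters`
#'   (genotype -> cluster map).
#' @export
simulate_field_survey <- function(seed = NULL, its_length = 1256L,
                                  nifd_length = 756L, within = 2,
                                  between = 20, its_indel_rate = 0.01, ...) {
  if (!is.null(seed)) set.seed(seed)
  assoc <- simulate_association(...)
  G <- ncol(assoc$profiles)
  per_cluster <- ceiling(G / 2)
  mk_locus <- function(len, indel, locus) {
    sq <- simulate_sequences(n_clusters = 2L,
                             genotypes_per_cluster = per_cluster,
                             isolates_per_genotype = 1L, length = len,
                             within = within, between = between,
                             indel_rate = indel, locus = locus)
    # genotype Gk of the association table carries the k-th simulated
    # genotype's sequence
    geno_ids <- names(sq$genotype)[seq_len(G)]
    tabcol <- assoc$table[[paste0("genotype_", locus)]]
    k <- as.integer(sub("^G", "", tabcol))
    m <- sq$alignment$seq[geno_ids[k], , drop = FALSE]
    rownames(m) <- assoc$table$isolate_id
    list(aln = new_haplo_alignment(locus, m),
         cluster = stats::setNames(sq$cluster[geno_ids],
                                   paste0("G", seq_len(G))))
  }
  nifd <- mk_locus(nifd_length, 0, "NifD")
  its <- mk_locus(its_length, its_indel_rate, "ITS")
  structure(list(table = assoc$table,
                 alignments = list(ITS = its$aln, NifD = nifd$aln),
                 association = assoc,
                 clusters = list(ITS = its$cluster, NifD = nifd$cluster),
                 seed = seed),
            class = "field_survey_sim")
}

#' Simulate a blocked single-strain inoculation experiment
#'
#' Emulates the structure of a 2-host x 31-strain x 10-block greenhouse
#' trial with 5 uninoculated controls per host and block. Shoot dry
#' weight is gamma-distributed with a log-scale linear predictor (host
#' baseline + inoculation boost + origin-match bonus + strain effect +
#' host x strain interaction + block effect); nodule counts are negative
#' binomial with a host baseline and strain-specific log-scale effects;
#' total nodule area is the sum of per-nodule log-normal areas. Controls
#' receive the host/block baseline weight and zero nodules, except for
#' contamination events (probability `contamination_prob`) that produce a
#' few small nodules.
#'
#' Default magnitudes reproduce the study conditions the analyses target:
#' inoculation raising shoot weight roughly 2.8-3x over controls,
#' symbiont strains drawn 12/19 from the two host genera, and a 7%
#' control contamination rate.
#'
#' @param hosts Host species codes (default `c("ACST", "LUBI")`).
#' @param n_strains Number of inoculated strains (default 31).
#' @param blocks Number of spatial blocks (default 10).
#' @param controls_per_block Controls per host and block (default 5).
#' @param control_mean Named baseline control shoot weight (g) per host.
#' @param inoc_effect Named log-scale inoculation effect per host
#'   (default log(3.8) and log(3.9): ~2.8- and 2.9-fold increases).
#' @param origin_match_effect Log-scale bonus when the strain's origin
#'   species matches the test host (default 0.25).
#' @param strain_sd Log-scale sd of strain main effects (default 0.2).
#' @param gxg_sd Named log-scale sd of host x strain interaction effects,
#'   one per host (a single value is recycled; default 0.3).
#' @param block_sd Log-scale sd of block effects (default 0.15).
#' @param gamma_shape Gamma shape of shoot weight (default 8).
#' @param count_mean Named baseline nodule count per host.
#' @param count_gxg_sd Log-scale sd of strain effects on nodule count
#'   per host (recycled; default 0.3).
#' @param count_dispersion Negative-binomial size parameter (default 5).
#' @param area_meanlog,area_sdlog Log-normal parameters of individual
#'   nodule area (cm^2); defaults log(0.02) and 0.3.
#' @param contamination_prob Probability a control plant is cross-
#'   contaminated (default 0.07).
#' @param seed Optional integer seed.
#' @return Object of class `greenhouse_sim`: list with `records` (the
#'   plant table), `effects` (all true effect draws) and `seed`.
#' @export
simulate_greenhouse <- function(hosts = c("ACST", "LUBI"), n_strains = 31L,
                                blocks = 10L, controls_per_block = 5L,
                                control_mean = c(ACST = 0.05, LUBI = 0.15),
                                inoc_effect = c(ACST = log(3.8), LUBI = log(3.9)),
                                origin_match_effect = 0.25,
                                strain_sd = 0.2, gxg_sd = 0.3,
                                block_sd = 0.15, gamma_shape = 8,
                                count_mean = c(ACST = 25, LUBI = 10),
                                count_gxg_sd = 0.3, count_dispersion = 5,
                                area_meanlog = log(0.02), area_sdlog = 0.3,
                                contamination_prob = 0.07, seed = NULL) {
  stopifnot(all(hosts %in% names(control_mean)),
            all(hosts %in% names(inoc_effect)),
            all(hosts %in% names(count_mean)),
            gamma_shape > 0, count_dispersion > 0,
            contamination_prob >= 0, contamination_prob <= 1,
            strain_sd >= 0, block_sd >= 0)
  if (is.null(names(gxg_sd))) gxg_sd <- stats::setNames(rep(gxg_sd, length(hosts))[seq_along(hosts)], hosts)
  if (is.null(names(count_gxg_sd)))
    count_gxg_sd <- stats::setNames(rep(count_gxg_sd, length(hosts))[seq_along(hosts)], hosts)
  if (!is.null(seed)) set.seed(seed)
  strains <- paste0("T", seq_len(n_strains))
  # origin labels mirror a 12/19 split between two source genera
  n_acm <- min(n_strains, 12L)
  origin_species <- c(rep(c("ACST", "ACHE"), length.out = n_acm),
                      rep(c("LUBI", "LUAR"), length.out = n_strains - n_acm))
  origin_genus <- ifelse(origin_species %in% c("ACST", "ACHE"),
                         "Acmispon", "Lupinus")
  names(origin_species) <- names(origin_genus) <- strains
  strain_eff <- stats::setNames(stats::rnorm(n_strains, 0, strain_sd), strains)
  count_eff <- lapply(stats::setNames(hosts, hosts), function(h)
    stats::setNames(stats::rnorm(n_strains, 0, count_gxg_sd[[h]]), strains))
  gxg <- lapply(stats::setNames(hosts, hosts), function(h)
    stats::setNames(stats::rnorm(n_strains, 0, gxg_sd[[h]]), strains))
  block_eff <- lapply(stats::setNames(hosts, hosts), function(h)
    stats::setNames(stats::rnorm(blocks, 0, block_sd), paste0("B", seq_len(blocks))))
  rgamma_mean <- function(n, mean) stats::rgamma(n, shape = gamma_shape,
                                                 rate = gamma_shape / mean)
  rows <- list()
  for (h in hosts) for (b in paste0("B", seq_len(blocks))) {
    # inoculated plants: one per strain per block
    eta <- log(control_mean[[h]]) + inoc_effect[[h]] +
      ifelse(origin_species[strains] == h, origin_match_effect, 0) +
      strain_eff[strains] + gxg[[h]][strains] + block_eff[[h]][b]
    w <- rgamma_mean(n_strains, exp(eta))
    mu_cnt <- count_mean[[h]] * exp(count_eff[[h]][strains])
    cnt <- stats::rnbinom(n_strains, size = count_dispersion, mu = mu_cnt)
    area <- vapply(cnt, function(k)
      if (k == 0L) 0 else sum(stats::rlnorm(k, area_meanlog, area_sdlog)), 0)
    rows[[paste(h, b, "trt")]] <- data.frame(
      plant_id = paste(h, b, strains, sep = "_"),
      host_species = h, block = b, treatment = strains,
      origin_species = unname(origin_species[strains]),
      origin_genus = unname(origin_genus[strains]),
      shoot_dry_weight_g = w, nodule_count = as.integer(cnt),
      total_nodule_area_cm2 = area)
    # controls
    wc <- rgamma_mean(controls_per_block,
                      exp(log(control_mean[[h]]) + block_eff[[h]][b]))
    contam <- stats::runif(controls_per_block) < contamination_prob
    ccnt <- ifelse(contam, stats::rpois(controls_per_block, 2) + 1L, 0L)
    carea <- vapply(ccnt, function(k)
      if (k == 0L) 0 else sum(stats::rlnorm(k, area_meanlog - 1, area_sdlog)), 0)
    rows[[paste(h, b, "ctl")]] <- data.frame(
      plant_id = paste(h, b, "C", seq_len(controls_per_block), sep = "_"),
      host_species = h, block = b, treatment = CONTROL,
      origin_species = NA_character_, origin_genus = NA_character_,
      shoot_dry_weight_g = wc, nodule_count = as.integer(ccnt),
      total_nodule_area_cm2 = carea)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  structure(list(records = records,
                 effects = list(strain = strain_eff, gxg = gxg,
                                count = count_eff, block = block_eff,
                                origin_species = origin_species),
                 seed = seed),
            class = "greenhouse_sim")
}
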