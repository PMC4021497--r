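#' Run the field-survey pipeline
#'
#' Chains the field-survey stages: read per-locus alignments, strip indel
#' columns, call genotypes, attach genotype labels to the nodule table,
#' build the host x genotype link matrix, compute per-host and joint
#' PDIs, simulate the null joint PDI from pooled genotype frequencies,
#' and run the population-structure analyses (diversity summary and
#' two-level AMOVA with host species nested in host genus). All report
#' files plus a manifest (parameters, seeds, input checksums, package
#' version) are written under `out_dir`; a rerun with the same inputs
#' and seeds is numerically identical.
#'
#' @param nodule_table Nodule-isolate data frame or path to its TSV.
#' @param alignments Named list of `haplo_alignment` objects or FASTA
#'   paths, one per locus (names are the locus labels).
#' @param out_dir Output directory (created if needed).
#' @param pdi_locus Locus whose genotypes define the link matrix
#'   (default `"NifD"`).
#' @param reps Replicates for the null joint PDI (default 1000).
#' @param nodules_per_host Nodules per simulated host population in the
#'   null (default 20).
#' @param perms Permutations for Phi-st/AMOVA tests (default 999).
#' @param seed Integer seed controlling every stochastic stage.
#' @param denominator Passed to the PDI functions.
#' @return Invisibly, a list with all stage results (`genotypes`,
#'   `link_matrix`, `host_pdi`, `joint_pdi`, `null`, `comparisons`,
#'   `diversity`, `amova`, `manifest`).
#' @export
run_field_pipeline <- function(nodule_table, alignments, out_dir,
                               pdi_locus = "NifD", reps = 1000L,
                               nodules_per_host = 20L, perms = 999L,
                               seed = 1L, denominator = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- list()
  if (is.character(nodule_table)) {
    checksums[["nodule_table"]] <- unname(tools::md5sum(nodule_table))
    nodule_table <- read_nodule_table(nodule_table)
  }
  alns <- list()
  for (loc in names(alignments)) {
    a <- alignments[[loc]]
    if (is.character(a)) {
      checksums[[paste0("alignment_", loc)]] <- unname(tools::md5sum(a))
      a <- read_alignment(a, locus = loc)
    }
    alns[[loc]] <- a
  }
  if (!pdi_locus %in% names(alns))
    stop("no alignment supplied for PDI locus '", pdi_locus, "'")
  genotypes <- list(); dists <- list()
  for (loc in names(alns)) {
    orphans <- setdiff(alns[[loc]]$ids, nodule_table$isolate_id)
    if (length(orphans))
      stop("alignment ids absent from nodule table (", loc, "): ",
           paste(orphans, collapse = ", "))
    aln <- strip_indel_columns(alns[[loc]])
    gt <- call_genotypes(aln)
    genotypes[[loc]] <- gt
    dists[[loc]] <- pairwise_differences(aln)
    col <- paste0("genotype_", loc)
    nodule_table[[col]] <- NA_character_
    hit <- match(nodule_table$isolate_id, names(gt$assignment))
    nodule_table[[col]][!is.na(hit)] <- gt$assignment[hit[!is.na(hit)]]
    write_genotype_table(gt, file.path(out_dir, paste0("genotypes_", loc, ".tsv")))
    write_distance_matrix(dists[[loc]],
                          file.path(out_dir, paste0("distances_", loc, ".tsv")))
  }
  lm <- build_link_matrix(nodule_table, locus = pdi_locus)
  write_link_matrix(lm, file.path(out_dir, "link_matrix_counts.tsv"),
                    file.path(out_dir, "link_matrix_props.tsv"))
  hp <- host_pdi(lm, denominator = denominator)
  jp <- joint_pdi(lm, denominator = denominator)
  freqs <- colSums(lm$counts) / sum(lm$counts)
  null <- simulate_null_joint_pdi(freqs, n_hosts = nrow(lm$counts),
                                  nodules_per_host = nodules_per_host,
                                  reps = reps, seed = seed,
                                  denominator = denominator)
  comparisons <- lapply(stats::setNames(hp$pdi, hp$host),
                        compare_pdi_to_null, null = null)
  pdi_report <- list(
    locus = pdi_locus,
    denominator = if (is.null(denominator)) "partners_minus_1" else denominator,
    hosts = hp, joint_pdi = jp,
    null = list(mean = null$mean, sd = null$sd, ci = as.list(null$ci),
                quantiles = as.list(null$quantiles), reps = null$reps,
                seed = seed),
    comparison = lapply(comparisons, function(cc)
      list(observed = cc$observed, significant = cc$significant,
           tail_upper = cc$tail_upper, tail_lower = cc$tail_lower)))
  jsonlite::write_json(pdi_report, file.path(out_dir, "pdi_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pops <- stats::setNames(nodule_table$host_species, nodule_table$isolate_id)
  groups <- stats::setNames(nodule_table$host_genus, nodule_table$host_species)
  groups <- groups[!duplicated(names(groups))]
  diversity <- list(); amova <- list()
  for (loc in names(alns)) {
    d <- dists[[loc]]
    keep <- intersect(rownames(d), names(pops))
    d <- d[keep, keep]
    diversity[[loc]] <- diversity_matrix(d, pops[keep], perms = perms,
                                         seed = seed)
    write_diversity_matrix(diversity[[loc]],
                           file.path(out_dir, paste0("diversity_", loc, ".tsv")))
    amova[[loc]] <- amova_two_level(d, pops[keep], groups, perms = perms,
                                    seed = seed)
    jsonlite::write_json(list(table = amova[[loc]]$table,
                              phi = as.list(amova[[loc]]$phi),
                              perms = perms, seed = seed),
                         file.path(out_dir, paste0("amova_", loc, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest <- list(
    pipeline = "field",
    package_version = as.character(utils::packageVersion("symbiospec")),
    parameters = list(pdi_locus = pdi_locus, reps = reps,
                      nodules_per_host = nodules_per_host, perms = perms,
                      seed = seed,
                      denominator = if (is.null(denominator))
                        "partners_minus_1" else denominator),
    input_checksums = checksums,
    n_isolates = nrow(nodule_table),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genotypes = genotypes, distances = dists, link_matrix = lm,
                 host_pdi = hp, joint_pdi = jp, null = null,
                 comparisons = comparisons, diversity = diversity,
                 amova = amova, manifest = manifest))
}

#' Run the greenhouse-experiment pipeline
#'
#' Chains the inoculation-experiment stages: contamination filtering,
#' response PDIs per host, effect PDIs for both nodule fitness
#' components, per-genotype trait means, fitness-feedback correlations,
#' and (when a strain-level genetic distance matrix is supplied) Mantel
#' tests of genotype-phenotype association for shoot weight and mean
#' nodule area. Reports and a manifest are written under `out_dir`.
#'
#' @param records Greenhouse data frame or path to its TSV.
#' @param out_dir Output directory.
#' @param genetic_dist Optional labelled strain x strain genetic distance
#'   matrix (or TSV path) for the Mantel tests; strains missing from it
#'   are excluded from the phenotype matrices.
#' @param perms Mantel permutations (default 999).
#' @param seed Integer seed for the Mantel permutations.
#' @return Invisibly, a list with all stage results.
#' @export
run_greenhouse_pipeline <- function(records, out_dir, genetic_dist = NULL,
                                    perms = 999L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- list()
  if (is.character(records)) {
    checksums[["greenhouse_table"]] <- unname(tools::md5sum(records))
    records <- read_greenhouse_table(records)
  }
  if (is.character(genetic_dist)) {
    checksums[["genetic_dist"]] <- unname(tools::md5sum(genetic_dist))
    genetic_dist <- read_distance_matrix(genetic_dist)
  }
  filtered <- filter_contaminated(records)
  hosts <- setdiff(unique(records$host_species), NA)
  resp <- lapply(stats::setNames(hosts, hosts), function(h)
    response_pdi(filtered, h))
  eff_cnt <- lapply(stats::setNames(hosts, hosts), function(h)
    effect_pdi(filtered, h, trait = "nodule_count"))
  eff_area <- lapply(stats::setNames(hosts, hosts), function(h)
    effect_pdi(filtered, h, trait = "total_nodule_area"))
  means <- genotype_means(filtered)
  utils::write.table(means, file.path(out_dir, "genotype_means.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  feedback <- lapply(stats::setNames(hosts, hosts), function(h)
    feedback_correlations(means, h))
  mantel <- NULL
  if (!is.null(genetic_dist)) {
    mantel <- list()
    for (h in hosts) for (tr in c("shoot_weight", "mean_nodule_area")) {
      ph <- phenotype_difference_matrix(
        means, h, tr,
        exclude = setdiff(unique(means$strain), rownames(genetic_dist)))
      lab <- intersect(rownames(genetic_dist), rownames(ph))
      mantel[[paste(h, tr, sep = ".")]] <-
        mantel_test(genetic_dist[lab, lab], ph[lab, lab],
                    perms = perms, seed = seed)
    }
  }
  sum_block <- function(x) list(mean = x$mean, se = x$se, ci = as.list(x$ci),
                                n_blocks = x$n_blocks,
                                block_values = as.list(x$block_values))
  report <- list(
    exclusions = filtered$report,
    response_pdi = lapply(resp, sum_block),
    effect_pdi = list(nodule_count = lapply(eff_cnt, sum_block),
                      total_nodule_area = lapply(eff_area, sum_block)),
    feedback_correlations = feedback,
    mantel = if (!is.null(mantel)) lapply(mantel, function(m)
      list(r = m$r, p = m$p, perms = m$perms, n = length(m$labels))))
  jsonlite::write_json(report, file.path(out_dir, "greenhouse_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    pipeline = "greenhouse",
    package_version = as.character(utils::packageVersion("symbiospec")),
    parameters = list(perms = perms, seed = seed),
    input_checksums = checksums,
    n_records_in = nrow(records),
    n_records_used = nrow(filtered$records),
    n_excluded = nrow(filtered$excluded),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(filtered = filtered, response_pdi = resp,
                 effect_pdi_count = eff_cnt, effect_pdi_area = eff_area,
                 genotype_means = means, feedback = feedback,
                 mantel = mantel, manifest = manifest))
}
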