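#' @name greenhouse
#' @title Blocked single-strain inoculation experiment analysis
#' @description
#' Analysis of a blocked greenhouse inoculation experiment in which
#' seedlings of each test host species are inoculated with single symbiont
#' strains (plus uninoculated water controls) in randomized spatial
#' blocks. Covers control contamination filtering, per-block fitness
#' effects and response/effect specialization indices, per-genotype trait
#' means, fitness-feedback correlations, and Mantel tests of association
#' between genetic and phenotypic distance matrices.
NULL

CONTROL <- "CONTROL"

check_greenhouse <- function(records) {
  need <- c("plant_id", "host_species", "block", "treatment",
            "shoot_dry_weight_g", "nodule_count", "total_nodule_area_cm2")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("greenhouse table lacks column(s): ", paste(miss, collapse = ", "))
  records
}

#' Flag and exclude cross-contaminated control plants
#'
#' Uninoculated controls that formed nodules indicate cross-contamination
#' and are excluded from all downstream analyses; inoculated plants are
#' never excluded by this rule. Blocks in which every conspecific control
#' was contaminated leave the block fitness-effect baseline undefined and
#' raise an error.
#'
#' @param records Greenhouse data frame (see [read_greenhouse_table()] for
#'   the column contract).
#' @return Object of class `filtered_greenhouse`: list with `records`
#'   (retained rows), `excluded` (contaminated control rows) and `report`
#'   (exclusion counts per host and block).
#' @export
filter_contaminated <- function(records) {
  check_greenhouse(records)
  ctrl <- records$treatment == CONTROL
  contaminated <- ctrl & !is.na(records$nodule_count) & records$nodule_count > 0
  kept <- records[!contaminated, , drop = FALSE]
  # every (host, block) must retain at least one usable control
  combos <- unique(records[ctrl, c("host_species", "block")])
  for (i in seq_len(nrow(combos))) {
    ok <- kept$treatment == CONTROL &
      kept$host_species == combos$host_species[i] &
      kept$block == combos$block[i] &
      !is.na(kept$shoot_dry_weight_g)
    if (!any(ok))
      stop("block ", combos$block[i], " (", combos$host_species[i],
           ") has no uncontaminated control plants; fitness effects undefined")
  }
  excl <- records[contaminated, , drop = FALSE]
  report <- if (nrow(excl)) {
    stats::aggregate(list(n_excluded = excl$plant_id),
                     by = list(host_species = excl$host_species, block = excl$block),
                     FUN = length)
  } else {
    data.frame(host_species = character(), block = character(),
               n_excluded = integer())
  }
  structure(list(records = kept, excluded = excl, report = report),
            class = "filtered_greenhouse")
}

#' @export
print.filtered_greenhouse <- function(x, ...) {
  cat("Greenhouse records: ", nrow(x$records), " retained, ",
      nrow(x$excluded), " contaminated control(s) excluded\n", sep = "")
  if (nrow(x$report)) print(x$report, row.names = FALSE)
  invisible(x)
}

#' Fitness effect of inoculation on a host plant
#'
#' The benefit the plant derived from its symbiont, scaled by the plant's
#' own size: (w - w_control) / w. Bounded above by 1, unbounded below.
#'
#' @param w Shoot dry weight (g) of the inoculated plant; must be > 0.
#' @param w_control Shoot dry weight (g) of the block's uninoculated
#'   conspecific control baseline; must be > 0.
#' @return Numeric fitness effect(s).
#' @examples
#' fitness_effect(0.2, 0.1)   # 0.5
#' fitness_effect(0.05, 0.1)  # -1
#' @export
fitness_effect <- function(w, w_control) {
  if (any(!is.finite(w)) || any(w <= 0)) stop("'w' must be positive")
  if (any(!is.finite(w_control)) || any(w_control <= 0))
    stop("'w_control' must be positive")
  (w - w_control) / w
}

#' Fold increase of an inoculated plant over the control baseline
#'
#' @inheritParams fitness_effect
#' @return (w - w_control) / w_control; > -1 always.
#' @examples
#' fold_increase(0.3, 0.1)  # 2
#' @export
fold_increase <- function(w, w_control) {
  if (any(!is.finite(w)) || any(w <= 0)) stop("'w' must be positive")
  if (any(!is.finite(w_control)) || any(w_control <= 0))
    stop("'w_control' must be positive")
  (w - w_control) / w_control
}

#' Within-block Paired Differences Index
#'
#' Applies the PDI to a block's per-strain values: the sum of differences
#' between the block's largest value and each other value, divided by the
#' number of strains minus one (or an explicit denominator, e.g. a fixed
#' strain count shared across blocks). Unlike [pdi()] on proportions, the
#' inputs may be negative (fitness effects below the control baseline),
#' so no bound applies and no warning is issued.
#'
#' @param values Per-strain values within one block (length >= 2,
#'   `NA` dropped).
#' @param denominator `NULL` (strains present minus one) or explicit.
#' @return The block PDI.
#' @examples
#' block_pdi(c(3, 1, 0))  # ((3-1)+(3-0))/2 = 2.5
#' @export
block_pdi <- function(values, denominator = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 strain values in the block")
  if (is.null(denominator)) denominator <- length(values) - 1L
  top <- max(values)
  sum(top - values[-which.max(values)]) / denominator
}

summarize_blocks <- function(block_values, host, trait, conf = 0.95) {
  k <- length(block_values)
  m <- mean(block_values)
  se <- stats::sd(block_values) / sqrt(k)
  tq <- if (k > 1L) stats::qt(1 - (1 - conf) / 2, k - 1L) else NA_real_
  structure(list(host = host, trait = trait, block_values = block_values,
                 n_blocks = k, mean = m, se = se,
                 ci = c(lower = m - tq * se, upper = m + tq * se)),
            class = "block_pdi_summary")
}

#' @export
print.block_pdi_summary <- function(x, digits = 3, ...) {
  cat(x$trait, " PDI for ", x$host, ": mean ", format(x$mean, digits = digits),
      " +/- 1 SE ", format(x$se, digits = 2),
      " (95% CI ", format(x$ci[["lower"]], digits = digits), " to ",
      format(x$ci[["upper"]], digits = digits), "; ",
      x$n_blocks, " blocks)\n", sep = "")
  invisible(x)
}

block_strain_values <- function(records, host, value_col) {
  rec <- records[records$host_species == host & records$treatment != CONTROL, ]
  if (!nrow(rec)) stop("no inoculated records for host '", host, "'")
  split(rec, rec$block)
}

#' Response-specificity PDI of a test host
#'
#' Measures how unevenly the host's growth benefit is spread across
#' symbiont strains. For each block the fitness effect of every strain is
#' computed against the block mean of surviving conspecific controls
#' ([fitness_effect()]), the block PDI is taken over those effects, and
#' the per-block PDIs are summarized as mean, SE (sd/sqrt(blocks)) and a
#' t-based 95% CI across blocks.
#'
#' @param records A `filtered_greenhouse` or a pre-filtered data frame.
#' @param host Host species to analyse.
#' @param denominator Passed to [block_pdi()] (e.g. a constant strain
#'   count); default: strains present in the block minus one.
#' @param effect One of `"fitness_effect"` (default; (w - wC)/w) or
#'   `"fold_increase"` ((w - wC)/wC) as the per-strain response measure.
#' @return A `block_pdi_summary`.
#' @export
response_pdi <- function(records, host, denominator = NULL,
                         effect = c("fitness_effect", "fold_increase")) {
  effect <- match.arg(effect)
  if (inherits(records, "filtered_greenhouse")) records <- records$records
  check_greenhouse(records)
  effect_fun <- if (effect == "fitness_effect") fitness_effect else fold_increase
  ctrl <- records[records$host_species == host & records$treatment == CONTROL &
                    !is.na(records$shoot_dry_weight_g), ]
  if (!nrow(ctrl)) stop("no control records for host '", host, "'")
  w_ctrl <- tapply(ctrl$shoot_dry_weight_g, ctrl$block, mean)
  blocks <- block_strain_values(records, host)
  vals <- c()
  for (b in names(blocks)) {
    rec <- blocks[[b]]
    rec <- rec[!is.na(rec$shoot_dry_weight_g), ]
    if (is.na(w_ctrl[b])) stop("block ", b, " (", host, ") has no usable control")
    if (nrow(rec) < 2L) {
      warning("block ", b, " has fewer than 2 strains with weights; skipped")
      next
    }
    w <- tapply(rec$shoot_dry_weight_g, rec$treatment, mean)
    p_jk <- effect_fun(as.numeric(w), w_ctrl[[b]])
    vals[b] <- block_pdi(p_jk, denominator = denominator)
  }
  if (!length(vals)) stop("no usable blocks for host '", host, "'")
  summarize_blocks(vals, host, "response")
}

#' Effect-specificity PDI of a test host on symbiont fitness
#'
#' Measures how unevenly the host distributes fitness across symbiont
#' strains, using a nodule fitness component (nodule number or total
#' projected nodule area) in place of the growth response. Controls carry
#' no nodules, so transformed trait values enter the block PDI directly
#' (no control subtraction). Defaults follow the usual
#' variance-stabilising choices: natural log for counts, square root for
#' areas; `ln` falls back to `ln(x + 1)` with a message when zeros are
#' present.
#'
#' @inheritParams response_pdi
#' @param trait `"nodule_count"` or `"total_nodule_area"`.
#' @param transform `"default"` (ln for counts, sqrt for area), `"ln"`,
#'   `"sqrt"` or `"none"`.
#' @return A `block_pdi_summary`.
#' @export
effect_pdi <- function(records, host,
                       trait = c("nodule_count", "total_nodule_area"),
                       transform = c("default", "ln", "sqrt", "none"),
                       denominator = NULL) {
  trait <- match.arg(trait)
  transform <- match.arg(transform)
  if (transform == "default")
    transform <- if (trait == "nodule_count") "ln" else "sqrt"
  if (inherits(records, "filtered_greenhouse")) records <- records$records
  check_greenhouse(records)
  col <- if (trait == "nodule_count") "nodule_count" else "total_nodule_area_cm2"
  blocks <- block_strain_values(records, host)
  all_vals <- unlist(lapply(blocks, function(r) r[[col]]))
  tf <- switch(transform,
    ln = if (any(all_vals == 0, na.rm = TRUE)) {
      message("zero ", trait, " present; using ln(x + 1)")
      function(x) log(x + 1)
    } else log,
    sqrt = sqrt,
    none = identity)
  vals <- c()
  for (b in names(blocks)) {
    rec <- blocks[[b]]
    rec <- rec[!is.na(rec[[col]]), ]
    if (nrow(rec) < 2L) {
      warning("block ", b, " has fewer than 2 strains with ", trait, "; skipped")
      next
    }
    v <- tapply(rec[[col]], rec$treatment, mean)
    vals[b] <- block_pdi(tf(as.numeric(v)), denominator = denominator)
  }
  if (!length(vals)) stop("no usable blocks for host '", host, "'")
  summarize_blocks(vals, host, trait)
}

#' Per-genotype trait means in the inoculation experiment
#'
#' Arithmetic mean and standard error per (host, strain) of shoot dry
#' weight, nodule count, total nodule area, and mean individual nodule
#' area (total area / count, computed per plant before averaging; plants
#' with zero nodules contribute `NA`). Controls and missing values are
#' excluded trait-wise.
#'
#' @param records A `filtered_greenhouse` or pre-filtered data frame.
#' @return Data frame of class `genotype_means` with one row per
#'   (host_species, strain) and columns `<trait>_mean`, `<trait>_se`,
#'   `<trait>_n` for each trait.
#' @export
genotype_means <- function(records) {
  if (inherits(records, "filtered_greenhouse")) records <- records$records
  check_greenhouse(records)
  rec <- records[records$treatment != CONTROL, , drop = FALSE]
  rec$mean_nodule_area <- ifelse(!is.na(rec$nodule_count) & rec$nodule_count > 0,
                                 rec$total_nodule_area_cm2 / rec$nodule_count,
                                 NA_real_)
  traits <- c(shoot_weight = "shoot_dry_weight_g", nodule_count = "nodule_count",
              total_nodule_area = "total_nodule_area_cm2",
              mean_nodule_area = "mean_nodule_area")
  key <- interaction(rec$host_species, rec$treatment, drop = TRUE)
  out <- data.frame(
    host_species = tapply(as.character(rec$host_species), key, `[`, 1L),
    strain = tapply(as.character(rec$treatment), key, `[`, 1L),
    row.names = NULL)
  for (t in names(traits)) {
    v <- rec[[traits[[t]]]]
    out[[paste0(t, "_mean")]] <- as.numeric(tapply(v, key, mean, na.rm = TRUE))
    out[[paste0(t, "_se")]] <- as.numeric(tapply(v, key, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
    }))
    out[[paste0(t, "_n")]] <- as.integer(tapply(v, key, function(x) sum(!is.na(x))))
  }
  zero <- out$shoot_weight_n == 0
  if (any(zero))
    warning("strain(s) with zero surviving replicates: ",
            paste(out$strain[zero], collapse = ", "))
  out <- out[order(out$host_species, out$strain), ]
  rownames(out) <- NULL
  class(out) <- c("genotype_means", "data.frame")
  out
}

#' Fitness-feedback correlations between host and symbiont fitness
#'
#' Pearson correlations, across strain means on one host, between host
#' fitness (shoot dry weight) and each symbiont fitness component
#' (nodule count, total nodule area, mean individual nodule area), with a
#' two-sided t-test on n - 2 df. A positive correlation indicates fitness
#' feedback: strains that benefit the host are themselves rewarded.
#'
#' @param means A `genotype_means` table.
#' @param host Host species to analyse.
#' @param log_nodule If `TRUE`, the nodule variable is natural-log
#'   transformed (ln(x + 1) when zeros occur) before correlating.
#' @return Data frame with `trait`, `r`, `p`, `n` per fitness component;
#'   components with zero variance yield `NA` with a warning.
#' @export
feedback_correlations <- function(means, host, log_nodule = FALSE) {
  m <- means[means$host_species == host, , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 strains with means for host '", host, "'")
  comps <- c("nodule_count", "total_nodule_area", "mean_nodule_area")
  out <- data.frame(trait = comps, r = NA_real_, p = NA_real_, n = NA_integer_)
  for (i in seq_along(comps)) {
    x <- m[[paste0(comps[i], "_mean")]]
    y <- m$shoot_weight_mean
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (log_nodule) x <- if (any(x == 0)) log(x + 1) else log(x)
    out$n[i] <- length(x)
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("correlation undefined for ", comps[i], " on ", host)
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out
}

#' Pairwise phenotypic difference matrix between strains
#'
#' Entry (a, b) is the absolute difference of the strains' trait means on
#' the given host. Strains can be excluded (e.g. reference addenda not
#' part of the original sample, or strains unsequenced at the locus the
#' matrix will be compared against).
#'
#' @param means A `genotype_means` table.
#' @param host Host species.
#' @param trait One of `"shoot_weight"`, `"nodule_count"`,
#'   `"total_nodule_area"`, `"mean_nodule_area"`.
#' @param exclude Character vector of strain ids to drop.
#' @return Symmetric matrix of absolute mean differences, labelled by
#'   strain.
#' @export
phenotype_difference_matrix <- function(means, host, trait = "shoot_weight",
                                        exclude = character()) {
  col <- paste0(trait, "_mean")
  if (!col %in% names(means)) stop("unknown trait '", trait, "'")
  m <- means[means$host_species == host & !means$strain %in% exclude, ]
  m <- m[!is.na(m[[col]]), ]
  if (nrow(m) < 3L) stop("need at least 3 strains with '", trait, "' means")
  v <- stats::setNames(m[[col]], m$strain)
  abs(outer(v, v, `-`))
}

#' Mantel test of association between two distance matrices
#'
#' Pearson correlation between the strictly-lower-triangle entries of two
#' labelled distance matrices (e.g. genetic distances between strains vs
#' their phenotypic differences), with significance from jointly
#' permuting the rows and columns of the second matrix. The p-value is
#' the +1-corrected upper-tail proportion.
#'
#' @param genetic,phenotypic Symmetric matrices with identical labels in
#'   identical order, zero diagonals, >= 4 labels.
#' @param perms Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @return Object of class `mantel_result`: list with `r`, `p`, `perms`,
#'   `seed`, `labels`.
#' @export
mantel_test <- function(genetic, phenotypic, perms = 9999L, seed = NULL) {
  if (!identical(rownames(genetic), rownames(phenotypic)))
    stop("matrices must share identical labels in identical order")
  n <- nrow(genetic)
  if (n < 4L) stop("need at least 4 labels")
  if (any(diag(genetic) != 0) || any(diag(phenotypic) != 0))
    stop("distance matrices must have zero diagonals")
  lt <- lower.tri(genetic)
  x <- genetic[lt]
  if (stats::sd(x) == 0 || stats::sd(phenotypic[lt]) == 0)
    stop("constant off-diagonal entries: Mantel r undefined")
  r_obs <- stats::cor(x, phenotypic[lt])
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (k in seq_len(perms)) {
    i <- sample.int(n)
    if (stats::cor(x, phenotypic[i, i][lt]) >= r_obs) ge <- ge + 1L
  }
  structure(list(r = r_obs, p = (ge + 1) / (perms + 1),
                 perms = as.integer(perms), seed = seed,
                 labels = rownames(genetic)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, digits = 4, ...) {
  cat("Mantel r = ", format(x$r, digits = digits), " (p = ",
      format(x$p, digits = 3), ", ", x$perms, " permutations, ",
      length(x$labels), " labels)\n", sep = "")
  invisible(x)
}

#' Read / write greenhouse and nodule tables
#'
#' TSV round-trip for the two tabular inputs. The greenhouse table has
#' columns `plant_id`, `host_species`, `block`, `treatment` (strain id or
#' `CONTROL`), `origin_species`, `origin_genus`, `shoot_dry_weight_g`,
#' `nodule_count`, `total_nodule_area_cm2`; the nodule-isolate table has
#' `isolate_id`, `host_species`, `host_genus`, `plant_id`, `nodule_id`,
#' `genotype_ITS`, `genotype_NifD`. Empty cells are missing values.
#'
#' @param path File path.
#' @param records,table Data frame to write.
#' @return The data frame (readers) or `path` invisibly (writers).
#' @export
read_greenhouse_table <- function(path) {
  x <- utils::read.delim(path, na.strings = c("NA", ""),
                         colClasses = c(block = "character"))
  check_greenhouse(x)
}

#' @rdname read_greenhouse_table
#' @export
write_greenhouse_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_greenhouse_table
#' @export
read_nodule_table <- function(path) {
  x <- utils::read.delim(path, na.strings = c("NA", ""),
                         colClasses = "character")
  need <- c("isolate_id", "host_species", "host_genus", "plant_id", "nodule_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("nodule table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x[c("plant_id", "nodule_id")]))
    stop("duplicated (plant_id, nodule_id) pairs in nodule table")
  gm <- unique(x[c("host_species", "host_genus")])
  if (anyDuplicated(gm$host_species))
    stop("host_species maps to more than one host_genus")
  x
}

#' @rdname read_greenhouse_table
#' @export
write_nodule_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
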