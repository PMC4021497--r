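#' Build a host x genotype link-strength matrix from a nodule table
#'
#' The link strength of host i with symbiont genotype j is the proportion
#' of the host's sampled nodules occupied by that genotype,
#' P_ij = n_ij / n_i. Columns span the union of genotypes observed in any
#' host at the locus, so hosts are penalised in the specialization index
#' for available genotypes they never use.
#'
#' @param table Nodule-isolate data frame with columns `isolate_id`,
#'   `host_species`, `host_genus`, `plant_id`, `nodule_id` and per-locus
#'   genotype columns `genotype_<locus>` (empty string or `NA` = isolate
#'   not typed at that locus).
#' @param locus Locus whose genotype column defines the links
#'   (e.g. `"NifD"`).
#' @param genotypes Optional character vector fixing the genotype
#'   universe (matrix columns); defaults to the union of genotypes
#'   observed in any host. Supply the full pool when it is known (e.g.
#'   from a simulation truth) so unobserved genotypes keep zero columns.
#' @return Object of class `link_matrix`: list with `counts` (n_ij),
#'   `prop` (P_ij), `n` (per-host totals n_i) and `locus`.
#' @export
build_link_matrix <- function(table, locus = "NifD", genotypes = NULL) {
  col <- paste0("genotype_", locus)
  if (!col %in% names(table))
    stop("nodule table has no column '", col, "'")
  need <- c("isolate_id", "host_species")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("nodule table lacks column(s): ", paste(miss, collapse = ", "))
  g <- as.character(table[[col]])
  typed <- !is.na(g) & nzchar(g)
  hosts <- unique(as.character(table$host_species))
  untyped_hosts <- setdiff(hosts, unique(as.character(table$host_species)[typed]))
  if (length(untyped_hosts))
    stop("host(s) with zero genotyped nodules at ", locus, ": ",
         paste(untyped_hosts, collapse = ", "))
  if (is.null(genotypes)) genotypes <- sort(unique(g[typed]))
  orphan <- setdiff(g[typed], genotypes)
  if (length(orphan))
    stop("genotype(s) outside the supplied universe: ",
         paste(orphan, collapse = ", "))
  tab <- table(factor(as.character(table$host_species)[typed], levels = hosts),
               factor(g[typed], levels = genotypes))
  counts <- unclass(tab)
  dimnames(counts) <- dimnames(tab)
  n <- rowSums(counts)
  structure(list(counts = counts, prop = counts / n, n = n, locus = locus),
            class = "link_matrix")
}

#' @export
print.link_matrix <- function(x, digits = 3, ...) {
  cat("Link-strength matrix (", x$locus, "): ", nrow(x$counts), " hosts x ",
      ncol(x$counts), " genotypes\n", sep = "")
  cat("nodules per host: ", paste(names(x$n), x$n, sep = "=", collapse = ", "),
      "\n", sep = "")
  print(round(x$prop, digits))
  invisible(x)
}

#' Paired Differences Index of a link-strength vector
#'
#' PDI summarises how unevenly a consumer spreads its interactions: with
#' link strengths P_1 >= P_2 >= ... >= P_N it is
#' \deqn{PDI = \sum_{j=2}^{N} (P_1 - P_j) / D,}
#' where the default denominator D is the number of partner categories
#' minus one. On proportions that convention bounds PDI in \[0, 1\]: 1 for
#' a perfect specialist (all interaction with one partner), 0 for a
#' perfect generalist (uniform link strengths). An explicit `denominator`
#' reproduces alternative printed conventions (e.g. nodules sampled minus
#' one).
#'
#' @param p Numeric vector of link strengths (length >= 2). Negative
#'   entries trigger a warning (they arise legitimately for fitness-effect
#'   PDIs; see [block_pdi()]).
#' @param denominator `NULL` (default: `length(p) - 1`) or an explicit
#'   positive number.
#' @return A single PDI value.
#' @examples
#' pdi(c(1, 0, 0, 0))        # perfect specialist -> 1
#' pdi(c(0.25, 0.25, 0.25, 0.25))  # perfect generalist -> 0
#' pdi(c(0.5, 0.3, 0.2))     # ((0.5-0.3)+(0.5-0.2))/2 = 0.25
#' @export
pdi <- function(p, denominator = NULL) {
  if (length(p) < 2L) stop("need at least 2 link strengths, got ", length(p))
  if (anyNA(p) || any(!is.finite(p))) stop("link strengths must be finite")
  if (any(p < 0)) warning("negative link strengths; PDI is no longer bounded in [0, 1]")
  if (is.null(denominator)) denominator <- length(p) - 1L
  if (!is.numeric(denominator) || length(denominator) != 1L || denominator <= 0)
    stop("'denominator' must be a single positive number")
  pmax1 <- max(p)
  sum(pmax1 - p[-which.max(p)]) / denominator
}

#' Per-host PDIs from a link-strength matrix
#'
#' @param lm A `link_matrix`.
#' @param denominator Passed to [pdi()].
#' @return Data frame (class `pdi_field`) with one row per host: `host`,
#'   `pdi`, `n_genotypes`, `n_nodules`.
#' @export
host_pdi <- function(lm, denominator = NULL) {
  stopifnot(inherits(lm, "link_matrix"))
  out <- data.frame(
    host = rownames(lm$prop),
    pdi = apply(lm$prop, 1L, pdi, denominator = denominator),
    n_genotypes = ncol(lm$prop),
    n_nodules = as.integer(lm$n),
    row.names = NULL)
  class(out) <- c("pdi_field", "data.frame")
  out
}

#' Joint PDI across hosts
#'
#' Averages each genotype's link strength across hosts, then applies
#' [pdi()] to the averaged vector. With a single host this reduces to the
#' host's own PDI.
#'
#' @param lm A `link_matrix`, or a numeric matrix of link strengths with
#'   hosts in rows.
#' @param denominator Passed to [pdi()].
#' @return A single joint PDI value.
#' @export
joint_pdi <- function(lm, denominator = NULL) {
  prop <- if (inherits(lm, "link_matrix")) lm$prop else as.matrix(lm)
  if (nrow(prop) < 1L || ncol(prop) < 2L)
    stop("need at least 1 host and 2 genotypes")
  pdi(colMeans(prop), denominator = denominator)
}

#' Simulated null distribution of the joint PDI
#'
#' Simulates host populations sampling nodules at random from a common
#' genotype pool: in each replicate every host draws `nodules_per_host`
#' nodules multinomially from `genotype_freqs`, per-host link strengths
#' are formed, and the joint PDI of the replicate is recorded. The result
#' is the null expectation of the joint PDI when hosts show no
#' preference, against which observed PDIs are compared.
#'
#' @param genotype_freqs Probability vector of genotype availability
#'   (e.g. observed frequencies in the pooled sample); must sum to 1.
#' @param n_hosts Number of hosts per replicate (default 4).
#' @param nodules_per_host Nodules drawn per host (default 20).
#' @param reps Number of replicates (default 1000).
#' @param seed Optional integer seed for exact reproducibility.
#' @param denominator Passed to [pdi()].
#' @param design `"per_host"` (default): every host draws its own
#'   population per replicate; `"single"`: one shared population is drawn
#'   per replicate and copied to all hosts.
#' @return Object of class `pdi_null`: list with `replicates`, `reps`,
#'   `mean`, `sd`, `ci` (95% limits of the mean, half-width
#'   1.96 sd/sqrt(reps)), `quantiles` (empirical 2.5/97.5 percentiles of
#'   the replicate distribution), `seed` and the sampling parameters.
#' @export
simulate_null_joint_pdi <- function(genotype_freqs, n_hosts = 4L,
                                    nodules_per_host = 20L, reps = 1000L,
                                    seed = NULL, denominator = NULL,
                                    design = c("per_host", "single")) {
  design <- match.arg(design)
  if (abs(sum(genotype_freqs) - 1) > 1e-9)
    stop("genotype frequencies must sum to 1")
  if (any(genotype_freqs < 0)) stop("genotype frequencies must be non-negative")
  if (reps < 1L) stop("'reps' must be >= 1")
  G <- length(genotype_freqs)
  if (!is.null(seed)) set.seed(seed)
  vals <- numeric(reps)
  if (G < 2L) {
    # degenerate pool: a single genotype cannot show specialization
    vals[] <- 0
  } else {
    for (r in seq_len(reps)) {
      if (design == "per_host") {
        cnt <- stats::rmultinom(n_hosts, nodules_per_host, genotype_freqs)
      } else {
        cnt <- matrix(stats::rmultinom(1L, nodules_per_host, genotype_freqs),
                      nrow = G, ncol = n_hosts)
      }
      vals[r] <- pdi(rowMeans(cnt) / nodules_per_host, denominator = denominator)
    }
  }
  m <- mean(vals)
  s <- stats::sd(vals)
  hw <- 1.96 * s / sqrt(reps)
  structure(list(
    replicates = vals, reps = as.integer(reps), mean = m, sd = s,
    ci = c(lower = m - hw, upper = m + hw),
    quantiles = stats::quantile(vals, c(0.025, 0.975), names = TRUE),
    seed = seed,
    params = list(genotype_freqs = genotype_freqs, n_hosts = n_hosts,
                  nodules_per_host = nodules_per_host, design = design)),
    class = "pdi_null")
}

#' @export
print.pdi_null <- function(x, digits = 4, ...) {
  cat("Null joint PDI: mean ", format(x$mean, digits = digits),
      " +/- 95% CL ", format(x$ci[["upper"]] - x$mean, digits = 2),
      " (", x$reps, " replicates, ", x$params$n_hosts, " hosts x ",
      x$params$nodules_per_host, " nodules)\n", sep = "")
  cat("replicate 2.5/97.5 percentiles: ",
      paste(format(x$quantiles, digits = digits), collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' @describeIn simulate_null_joint_pdi Histogram of the replicate joint
#'   PDIs with the empirical 95% band; pass `observed =` to overlay an
#'   observed value.
#' @param x A `pdi_null`.
#' @param observed Optional observed PDI to draw as a vertical line.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.pdi_null <- function(x, observed = NULL, ...) {
  graphics::hist(x$replicates, main = "Null joint PDI",
                 xlab = "joint PDI", col = "grey85", border = "white",
                 xlim = range(c(x$replicates, observed)), ...)
  graphics::abline(v = x$quantiles, lty = 2)
  if (!is.null(observed)) graphics::abline(v = observed, col = 2, lwd = 2)
  invisible(x)
}

#' Compare an observed PDI with its simulated null
#'
#' @param observed Observed PDI value (or a one-row `pdi_field` entry).
#' @param null A `pdi_null`.
#' @return Object of class `pdi_comparison`: list with the observed value,
#'   `significant` (observed outside the empirical 2.5/97.5 percentile
#'   band of the null replicates), `tail_upper` and `tail_lower`
#'   (+1-corrected empirical tail proportions).
#' @export
compare_pdi_to_null <- function(observed, null) {
  stopifnot(inherits(null, "pdi_null"))
  if (is.data.frame(observed)) observed <- observed$pdi
  stopifnot(is.numeric(observed), length(observed) == 1L)
  if (null$reps < 2L) stop("null distribution needs at least 2 replicates")
  up <- (sum(null$replicates >= observed) + 1) / (null$reps + 1)
  lo <- (sum(null$replicates <= observed) + 1) / (null$reps + 1)
  structure(list(
    observed = observed,
    significant = observed < null$quantiles[[1L]] || observed > null$quantiles[[2L]],
    tail_upper = up, tail_lower = lo, null = null),
    class = "pdi_comparison")
}

#' @export
print.pdi_comparison <- function(x, digits = 4, ...) {
  cat("Observed PDI ", format(x$observed, digits = digits), " vs null mean ",
      format(x$null$mean, digits = digits), ": ",
      if (x$significant) "outside" else "within", " the null 95% band\n",
      "upper-tail p = ", format(x$tail_upper, digits = 3),
      ", lower-tail p = ", format(x$tail_lower, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Write link matrix counts and proportions as TSV
#' @param lm A `link_matrix`.
#' @param counts_path,prop_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_link_matrix <- function(lm, counts_path, prop_path) {
  stopifnot(inherits(lm, "link_matrix"))
  wr <- function(m, p) utils::write.table(
    data.frame(host = rownames(m), m, check.names = FALSE),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  wr(lm$counts, counts_path)
  wr(lm$prop, prop_path)
  invisible(c(counts_path, prop_path))
}
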