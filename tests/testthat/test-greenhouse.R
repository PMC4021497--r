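gh_fixture <- function(n_strains = 4, blocks = 2, w_fun = NULL, counts = NULL) {
  # deterministic miniature experiment table built in code
  strains <- paste0("T", seq_len(n_strains))
  rows <- list()
  for (b in paste0("B", seq_len(blocks))) {
    w <- if (is.null(w_fun)) rep(0.2, n_strains) else w_fun(b, strains)
    cnt <- if (is.null(counts)) rep(10L, n_strains) else counts(b, strains)
    rows[[paste0(b, "t")]] <- data.frame(
      plant_id = paste("H", b, strains, sep = "_"), host_species = "H",
      block = b, treatment = strains, origin_species = "H", origin_genus = "G",
      shoot_dry_weight_g = w, nodule_count = cnt,
      total_nodule_area_cm2 = cnt * 0.02)
    rows[[paste0(b, "c")]] <- data.frame(
      plant_id = paste("H", b, "C", 1:2, sep = "_"), host_species = "H",
      block = b, treatment = "CONTROL", origin_species = NA, origin_genus = NA,
      shoot_dry_weight_g = c(0.1, 0.1), nodule_count = 0L,
      total_nodule_area_cm2 = 0)
  }
  do.call(rbind, rows)
}

test_that("filter_contaminated excludes nodulated controls only", {
  rec <- gh_fixture()
  rec$nodule_count[rec$plant_id == "H_B1_C_1"] <- 3L
  f <- filter_contaminated(rec)
  expect_equal(nrow(f$excluded), 1L)
  expect_equal(f$excluded$plant_id, "H_B1_C_1")
  expect_equal(f$report$n_excluded, 1L)
  # treatment plants with nodules are never excluded
  expect_true(all(rec$treatment[rec$nodule_count > 0 & rec$treatment != "CONTROL"]
                  %in% f$records$treatment))
  # a block whose controls all nodulated is an error naming the block
  rec2 <- gh_fixture()
  rec2$nodule_count[rec2$treatment == "CONTROL" & rec2$block == "B2"] <- 2L
  expect_error(filter_contaminated(rec2), "B2")
})

test_that("fitness_effect and fold_increase match hand arithmetic and agree in sign", {
  expect_equal(fitness_effect(0.1, 0.1), 0)
  expect_equal(fitness_effect(0.2, 0.1), 0.5)
  expect_equal(fitness_effect(0.05, 0.1), -1)
  expect_equal(fold_increase(0.1, 0.1), 0)
  expect_equal(fold_increase(0.3, 0.1), 2)
  expect_error(fitness_effect(-1, 0.1), "positive")
  expect_error(fold_increase(0.1, 0), "positive")
  set.seed(6)
  w <- runif(100, 0.01, 1)
  wc <- runif(100, 0.01, 1)
  expect_equal(sign(fitness_effect(w, wc)), sign(fold_increase(w, wc)))
  # fitness effect bounded above by 1, fold increase bounded below by -1
  expect_true(all(fitness_effect(w, wc) < 1))
  expect_true(all(fold_increase(w, wc) > -1))
})

test_that("block_pdi matches hand computation and is scale-equivariant", {
  expect_equal(block_pdi(c(3, 1, 0)), 2.5)
  expect_equal(block_pdi(c(2, 2, 2)), 0)
  expect_error(block_pdi(3), "at least 2")
  set.seed(13)
  for (rep in 1:20) {
    v <- rnorm(8)
    cc <- runif(1, 0.1, 10)
    expect_equal(block_pdi(cc * v), cc * block_pdi(v))
    expect_equal(block_pdi(v), oracle_pdi(v))
  }
})

test_that("response_pdi is zero when all strains equal the control", {
  rec <- gh_fixture(w_fun = function(b, s) rep(0.1, length(s)))
  rp <- response_pdi(rec, "H")
  expect_equal(rp$mean, 0)
  expect_equal(unname(rp$ci[["upper"]] - rp$ci[["lower"]]), 0)
})

test_that("response_pdi recovers a one-outlier profile in closed form", {
  # one strain doubles weight, others sit at the control level:
  # within each block p = (0.5, 0, 0, ...), PDI = (N-1)*0.5/(N-1) = 0.5
  rec <- gh_fixture(n_strains = 30,
                    w_fun = function(b, s) c(0.2, rep(0.1, length(s) - 1)))
  rp <- response_pdi(rec, "H")
  expect_equal(rp$mean, 0.5, tolerance = 1e-12)
  # fold-increase variant: p = (1, 0, 0, ...) -> PDI = 1
  rp2 <- response_pdi(rec, "H", effect = "fold_increase")
  expect_equal(rp2$mean, 1, tolerance = 1e-12)
  # constant-strain-count denominator convention
  rp3 <- response_pdi(rec, "H", denominator = 30)
  expect_equal(rp3$mean, 0.5 * 29 / 30, tolerance = 1e-12)
})

test_that("effect_pdi applies the documented transforms", {
  # one strain with e^2-fold more nodules on the ln scale:
  # ln values differ by 2 for the outlier, 0 elsewhere -> PDI = 2/(N-1)*(N-1)...
  rec <- gh_fixture(n_strains = 5,
                    counts = function(b, s) c(round(exp(2) * 10), rep(10L, 4)))
  ep <- effect_pdi(rec, "H", trait = "nodule_count", transform = "ln")
  hand <- block_pdi(log(c(round(exp(2) * 10), rep(10, 4))))
  expect_equal(ep$mean, hand, tolerance = 1e-12)
  # equal trait values -> 0
  flat <- effect_pdi(gh_fixture(), "H", trait = "total_nodule_area")
  expect_equal(flat$mean, 0)
  # zeros under ln fall back to ln(x + 1) with a message
  rec0 <- gh_fixture(counts = function(b, s) c(0L, 5L, 5L, 5L))
  expect_message(ep0 <- effect_pdi(rec0, "H", trait = "nodule_count"),
                 "ln\\(x \\+ 1\\)")
  expect_equal(ep0$mean, block_pdi(log(c(0, 5, 5, 5) + 1)), tolerance = 1e-12)
})

test_that("genotype_means computes per-strain means, SEs and nodule ratios", {
  rec <- rbind(gh_fixture(blocks = 2,
                          w_fun = function(b, s) if (b == "B1") rep(2, 4) else rep(4, 4)))
  gm <- genotype_means(rec)
  expect_equal(nrow(gm), 4L)
  expect_equal(gm$shoot_weight_mean, rep(3, 4))   # replicates (2, 4) -> mean 3
  expect_equal(gm$shoot_weight_se, rep(1, 4))     # SE = 1
  expect_equal(gm$mean_nodule_area_mean, rep(0.02, 4))
  # single replicate: mean equals the value, SE missing
  gm1 <- genotype_means(gh_fixture(blocks = 1))
  expect_true(all(is.na(gm1$shoot_weight_se)))
  expect_equal(gm1$shoot_weight_n, rep(1L, 4))
})

test_that("feedback_correlations reproduce exact hand-computed correlations", {
  gm <- data.frame(
    host_species = "H", strain = paste0("T", 1:3),
    shoot_weight_mean = c(6, 4, 2),
    nodule_count_mean = c(1, 2, 3),
    total_nodule_area_mean = c(6, 4, 2),
    mean_nodule_area_mean = c(1, 1, 1))
  class(gm) <- c("genotype_means", "data.frame")
  expect_warning(fc <- feedback_correlations(gm, "H"), "undefined")
  expect_equal(fc$r[fc$trait == "nodule_count"], -1)
  expect_equal(fc$r[fc$trait == "total_nodule_area"], 1)
  expect_true(is.na(fc$r[fc$trait == "mean_nodule_area"]))  # zero variance
})

test_that("phenotype_difference_matrix takes absolute mean differences with exclusions", {
  gm <- data.frame(
    host_species = "H", strain = paste0("T", 1:4),
    shoot_weight_mean = c(1, 4, 2, 9))
  class(gm) <- c("genotype_means", "data.frame")
  ph <- phenotype_difference_matrix(gm, "H", "shoot_weight", exclude = "T4")
  expect_equal(rownames(ph), paste0("T", 1:3))
  expect_equal(ph["T1", "T2"], 3)
  expect_true(all(diag(ph) == 0))
  flat <- phenotype_difference_matrix(
    within(gm, shoot_weight_mean <- 1), "H", "shoot_weight")
  expect_true(all(flat == 0))
})

test_that("mantel_test: self-comparison, determinism, and exact 4-label enumeration", {
  set.seed(17)
  m <- matrix(runif(25, 1, 10), 5)
  d1 <- m + t(m)
  diag(d1) <- 0
  rownames(d1) <- colnames(d1) <- paste0("T", 1:5)
  self <- mantel_test(d1, d1, perms = 999, seed = 3)
  expect_equal(self$r, 1)
  # p is bounded below by 1/(perms+1); identity draws among the uniform
  # random permutations can add a few ties at r = 1, nothing more
  expect_gte(self$p, 1 / 1000)
  expect_lt(self$p, 0.02)
  expect_identical(mantel_test(d1, d1, perms = 999, seed = 3)$p, self$p)
  # exact enumeration at n = 4: all 24 joint row/column permutations
  m2 <- matrix(runif(16, 1, 10), 4)
  d2a <- m2 + t(m2); diag(d2a) <- 0
  m3 <- matrix(runif(16, 1, 10), 4)
  d2b <- m3 + t(m3); diag(d2b) <- 0
  rownames(d2a) <- colnames(d2a) <- rownames(d2b) <- colnames(d2b) <- paste0("T", 1:4)
  lt <- lower.tri(d2a)
  r_obs <- cor(d2a[lt], d2b[lt])
  all_p <- all_permutations(4)
  rs <- apply(all_p, 1, function(i) cor(d2a[lt], d2b[i, i][lt]))
  exact_p <- mean(rs >= r_obs)
  got <- mantel_test(d2a, d2b, perms = 4999, seed = 11)
  expect_equal(got$r, r_obs)
  expect_lt(abs(got$p - exact_p), 0.03)
  # degenerate: constant off-diagonals are rejected
  cst <- matrix(1, 4, 4); diag(cst) <- 0
  rownames(cst) <- colnames(cst) <- paste0("T", 1:4)
  expect_error(mantel_test(cst, d2b), "constant")
})

test_that("mantel r is invariant to relabeling both matrices identically", {
  set.seed(19)
  m <- matrix(runif(36, 1, 10), 6)
  d1 <- m + t(m); diag(d1) <- 0
  m2 <- matrix(runif(36, 1, 10), 6)
  d2 <- m2 + t(m2); diag(d2) <- 0
  rownames(d1) <- colnames(d1) <- rownames(d2) <- colnames(d2) <- paste0("T", 1:6)
  i <- sample(6)
  a <- mantel_test(d1, d2, perms = 0)
  b <- mantel_test(d1[i, i], d2[i, i], perms = 0)
  expect_equal(a$r, b$r)
})

test_that("mantel r agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(29)
  m <- matrix(runif(49, 1, 10), 7)
  d1 <- m + t(m); diag(d1) <- 0
  m2 <- matrix(runif(49, 1, 10), 7)
  d2 <- m2 + t(m2); diag(d2) <- 0
  rownames(d1) <- colnames(d1) <- rownames(d2) <- colnames(d2) <- paste0("T", 1:7)
  ours <- mantel_test(d1, d2, perms = 999, seed = 1)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("greenhouse table TSV round-trips through the reader", {
  rec <- gh_fixture()
  rec$nodule_count[3] <- NA
  p <- tempfile(fileext = ".tsv")
  write_greenhouse_table(rec, p)
  back <- read_greenhouse_table(p)
  expect_equal(back$shoot_dry_weight_g, rec$shoot_dry_weight_g)
  expect_equal(back$nodule_count, rec$nodule_count)
  expect_true(is.na(back$origin_species[back$treatment == "CONTROL"][1]))
})
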