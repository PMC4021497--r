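two_pop_fixture <- function() {
  # pop A: three identical haplotypes h1; pop B: three identical h2; d(h1,h2)=5
  d <- matrix(5, 6, 6)
  d[1:3, 1:3] <- 0
  d[4:6, 4:6] <- 0
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("i", 1:6)
  list(d = d, pop = setNames(rep(c("A", "B"), each = 3), rownames(d)))
}

test_that("phi_st is 1 with zero within-population variance", {
  fx <- two_pop_fixture()
  ph <- phi_st(fx$d, fx$pop, perms = 99, seed = 1)
  expect_equal(ph$phi_st, 1)
  expect_lt(ph$p, 0.2)
})

test_that("phi_st is ~0 and non-significant for duplicated populations", {
  set.seed(8)
  pool <- replicate(4, sample(c("A", "C", "G", "T"), 40, TRUE), simplify = FALSE)
  m <- do.call(rbind, pool[c(1, 1, 2, 3, 4, 1, 1, 2, 3, 4)])
  rownames(m) <- paste0("i", 1:10)
  d <- symbiospec:::seq_matrix_differences(m)
  pop <- setNames(rep(c("X", "Y"), each = 5), rownames(m))
  ph <- phi_st(d, pop, perms = 199, seed = 3)
  expect_lte(ph$phi_st, 0.05)
  expect_gt(ph$p, 0.05)
})

test_that("phi_st handles the all-identical degenerate case", {
  d <- matrix(0, 4, 4, dimnames = list(paste0("i", 1:4), paste0("i", 1:4)))
  pop <- setNames(rep(c("A", "B"), each = 2), rownames(d))
  ph <- phi_st(d, pop, perms = 19, seed = 1)
  expect_true(is.na(ph$phi_st))
  expect_equal(ph$p, 1)
})

test_that("phi_st permutation p matches exhaustive 3+3 relabeling", {
  set.seed(14)
  pool <- replicate(5, sample(c("A", "C", "G", "T"), 50, TRUE), simplify = FALSE)
  m <- do.call(rbind, pool[c(1, 1, 2, 3, 4, 5)])
  rownames(m) <- paste0("i", 1:6)
  d <- symbiospec:::seq_matrix_differences(m)
  pop <- setNames(rep(c("A", "B"), each = 3), rownames(m))
  obs <- phi_st(d, pop, perms = 0)
  # enumerate all 20 balanced splits of 6 isolates into 3+3
  splits <- utils::combn(6, 3)
  stats <- apply(splits, 2, function(ia) {
    lab <- rep("B", 6)
    lab[ia] <- "A"
    symbiospec:::amova_components_1(d^2, lab)$phi_st
  })
  exact_p <- mean(stats >= obs$phi_st)
  sampled <- phi_st(d, pop, perms = 3999, seed = 5)
  expect_lt(abs(sampled$p - exact_p), 0.04)
})

test_that("SSD additivity is exact on random distance matrices", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(6:16, 1)
    m <- matrix(runif(n * n, 0, 10), n)
    d <- m + t(m)
    diag(d) <- 0
    rownames(d) <- colnames(d) <- paste0("i", 1:n)
    pop <- sample(paste0("P", 1:4), n, replace = TRUE)
    # ensure >= 2 pops, >= 1 member each
    pop[1:4] <- paste0("P", 1:4)
    grp_of_pop <- setNames(c("g1", "g1", "g2", "g2"), paste0("P", 1:4))
    cmp <- symbiospec:::amova_components_2(d^2, pop, grp_of_pop[pop])
    expect_equal(sum(cmp$ssd), cmp$ssd_total, tolerance = 1e-9)
    # and against the element-by-element definitional oracle
    orc <- oracle_ssd_partition(d, pop, grp_of_pop)
    expect_equal(cmp$ssd[1], orc$among_grp, tolerance = 1e-9)
    expect_equal(cmp$ssd[2], orc$among_pop_within, tolerance = 1e-9)
    expect_equal(cmp$ssd[3], orc$within_pop, tolerance = 1e-9)
  }
})

test_that("amova_two_level df sum to n-1 and recovers a planted hierarchy", {
  # 2 genera x 2 species x 4 isolates; between-genus distance 20,
  # between-species 2, within 0
  n <- 16
  pop <- rep(paste0("S", 1:4), each = 4)
  grp <- setNames(c("G1", "G1", "G2", "G2"), paste0("S", 1:4))
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (pop[i] != pop[j]) d[i, j] <- if (grp[pop[i]] != grp[pop[j]]) 20 else 2
  }
  rownames(d) <- colnames(d) <- paste0("i", 1:n)
  names(pop) <- rownames(d)
  am <- amova_two_level(d, pop, grp, perms = 99, seed = 7)
  tab <- am$table
  expect_equal(tab$df[4], n - 1)
  expect_equal(sum(tab$df[1:3]), tab$df[4])
  expect_equal(sum(tab$SSD[1:3]), tab$SSD[4], tolerance = 1e-9)
  expect_gt(tab$percent[1], 80)            # genus level dominates
  expect_equal(sum(tab$percent[1:3]), 100, tolerance = 1e-6)
  # definitional oracle agreement on the same fixture
  orc <- oracle_ssd_partition(d, pop, grp)
  expect_equal(tab$SSD[1], orc$among_grp, tolerance = 1e-9)
  expect_equal(tab$SSD[2], orc$among_pop_within, tolerance = 1e-9)
  expect_equal(tab$SSD[3], orc$within_pop, tolerance = 1e-9)
  expect_equal(tab$SSD[4], orc$total, tolerance = 1e-9)
})

test_that("amova handles all-identical sequences and reports zero components", {
  d <- matrix(0, 8, 8, dimnames = list(paste0("i", 1:8), paste0("i", 1:8)))
  pop <- setNames(rep(paste0("S", 1:2), each = 4), rownames(d))
  grp <- setNames(c("G1", "G2"), paste0("S", 1:2))
  expect_warning(am <- amova_two_level(d, pop, grp, perms = 9, seed = 1),
                 "single population")
  expect_equal(am$table$sigma2[1:3], rep(0, 3))
})

test_that("phi_st equals one-group amova_two_level on two populations", {
  set.seed(31)
  d <- random_pool_dist(12)
  pop <- setNames(rep(c("A", "B"), each = 6), rownames(d))
  grp <- setNames(c("only", "only"), c("A", "B"))
  ph <- phi_st(d, pop, perms = 0)
  am <- amova_two_level(d, pop, grp, perms = 0)
  expect_equal(am$phi[["sc"]], ph$phi_st, tolerance = 1e-12)
  expect_equal(am$table$sigma2[2], ph$sigma$sigma_a, tolerance = 1e-12)
  expect_equal(am$table$sigma2[3], ph$sigma$sigma_w, tolerance = 1e-12)
})

test_that("negative variance components are reported, not truncated", {
  set.seed(4)
  # exchangeable data often yield slightly negative among components
  found_negative <- FALSE
  for (rep in 1:30) {
    d <- random_pool_dist(10)
    pop <- setNames(rep(c("A", "B"), 5), rownames(d))
    ph <- phi_st(d, pop, perms = 0)
    if (!is.na(ph$phi_st) && ph$phi_st < 0) found_negative <- TRUE
  }
  expect_true(found_negative)
})

test_that("permutation results are identical across runs with the same seed", {
  set.seed(2)
  d <- random_pool_dist(12)
  pop <- setNames(rep(c("A", "B"), each = 6), rownames(d))
  expect_identical(phi_st(d, pop, perms = 99, seed = 10)$p,
                   phi_st(d, pop, perms = 99, seed = 10)$p)
  grp <- setNames(c("g1", "g2"), c("A", "B"))
  expect_identical(
    suppressWarnings(amova_two_level(d, pop, grp, perms = 49, seed = 10)$table$p),
    suppressWarnings(amova_two_level(d, pop, grp, perms = 49, seed = 10)$table$p))
})

test_that("diversity_matrix computes within, raw and corrected between", {
  # pop X: two identical; pop Y: two identical; cross distance 5
  fx <- two_pop_fixture()
  d <- fx$d[c(1, 2, 4, 5), c(1, 2, 4, 5)]
  pop <- setNames(c("X", "X", "Y", "Y"), rownames(d))
  dm <- diversity_matrix(d, pop, perms = 19, seed = 1)
  expect_equal(unname(dm$within), c(0, 0))
  expect_equal(dm$between_raw["X", "Y"], 5)
  expect_equal(dm$between_corrected["X", "Y"], 5)
  # two copies of one population (same multiset): the raw cross mean
  # includes the n zero-distance copy pairs, so the corrected value is the
  # analytic finite-sample quantity 2T/n^2 - T/(n(n-1)) = -T/n^2 (with T
  # the summed pairwise distances of the base set), not exactly zero
  set.seed(9)
  pool <- replicate(3, sample(c("A", "C", "G", "T"), 30, TRUE), simplify = FALSE)
  m <- do.call(rbind, pool[c(1, 2, 3, 1, 2, 3)])
  rownames(m) <- paste0("i", 1:6)
  d2 <- symbiospec:::seq_matrix_differences(m)
  T_base <- d2[1, 2] + d2[1, 3] + d2[2, 3]
  pop2 <- setNames(rep(c("P", "Q"), each = 3), rownames(m))
  dm2 <- diversity_matrix(d2, pop2, perms = 19, seed = 2)
  expect_equal(unname(dm2$between_corrected["P", "Q"]), -T_base / 9,
               tolerance = 1e-9)
  # singleton population reported as missing within
  pop3 <- setNames(c("P", "P", "P", "P", "P", "Q"), rownames(m))
  dm3 <- diversity_matrix(d2, pop3, perms = 0)
  expect_true(is.na(dm3$within[["Q"]]))
})
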