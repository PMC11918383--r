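test_that("hap_distance counts differences over pairwise-complete sites", {
  expect_equal(hap_distance(c(0, 1, 0, 1), c(0, 1, 0, 1)), 0)
  expect_equal(hap_distance(c(0, 1, 0, 1), c(0, 0, 0, 0)), 0.5)
  expect_equal(hap_distance(c(0, 1, NA, NA), c(0, 0, 0, 0)), 0.5)
  expect_true(is.na(hap_distance(c(NA, NA), c(0, 1))))
  expect_error(hap_distance(c(0, 1), c(0, 1, 0)), "length")
})

test_that("windowed stats hit the fixed-difference and exchangeable corners", {
  # pop1 fixed 0, pop2 fixed 1 at every site
  A <- rbind(matrix(0L, 4, 50), matrix(1L, 4, 50))
  h <- make_hapset(A, pos = seq(10, 500, by = 10), chrom_length = 500)
  pops <- tibble(haplotype_id = h$haplotype_ids,
                 group = rep(c("p1", "p2"), each = 4))
  ws <- windowed_stats(h, pops, window_bp = 500, min_sites = 10)
  expect_equal(ws$pi1, 0)
  expect_equal(ws$pi2, 0)
  expect_equal(ws$dxy, 1)
  expect_equal(ws$da, 1)
  expect_equal(ws$fst, 1)

  # two "populations" drawn from one pool: da ~ 0, fst ~ 0
  cfg <- sim_config(seed = 5, chrom_length = 5e5, n_sites = 5000,
                    groups = tibble(label = c("x", "y"), f = 0, n_panel = 20L))
  sim <- simulate_cohort(cfg)
  h2 <- split_haplotypes(sim$genos)
  ws2 <- windowed_stats(h2, sim$panels, window_bp = 5e4)
  expect_lt(abs(mean(ws2$fst)), 0.02)
  expect_lt(abs(mean(ws2$da)), 0.02)
})

test_that("every emitted window satisfies the da identity to machine precision", {
  cfg <- sim_config(seed = 9, chrom_length = 4e5, n_sites = 3000,
                    groups = tibble(label = c("A", "B"), f = 0.15, n_panel = 10L),
                    missing_rate = 0.1)
  sim <- simulate_cohort(cfg)
  h <- split_haplotypes(sim$genos)
  ws <- windowed_stats(h, sim$panels, window_bp = 5e4)
  ok <- !is.na(ws$da)
  expect_true(any(ok))
  expect_lt(max(abs(ws$da[ok] - (ws$dxy[ok] - (ws$pi1[ok] + ws$pi2[ok]) / 2))),
            1e-12)
})

test_that("windowed stats agree with a naive per-pair oracle, with missing data", {
  set.seed(31)
  A <- matrix(rbinom(12 * 120, 1, 0.4), 12, 120)
  A[sample(length(A), 150)] <- NA
  h <- make_hapset(A, pos = sort(sample.int(5e4, 120)), chrom_length = 5e4)
  pops <- tibble(haplotype_id = h$haplotype_ids,
                 group = rep(c("p1", "p2"), each = 6))
  ws <- windowed_stats(h, pops, window_bp = 5e4, min_sites = 5)
  expect_equal(nrow(ws), 1L)
  oracle <- naive_window_stats(A, 1:6, 7:12)
  expect_equal(ws$pi1, oracle$pi1, tolerance = 1e-12)
  expect_equal(ws$pi2, oracle$pi2, tolerance = 1e-12)
  expect_equal(ws$dxy, oracle$dxy, tolerance = 1e-12)
  expect_equal(ws$fst, oracle$fst, tolerance = 1e-12)
})

test_that("statistics are invariant to haplotype ordering within populations", {
  set.seed(13)
  A <- matrix(rbinom(8 * 200, 1, 0.3), 8, 200)
  h <- make_hapset(A, chrom_length = 2010)
  pops <- tibble(haplotype_id = h$haplotype_ids,
                 group = rep(c("p1", "p2"), each = 4))
  ws1 <- windowed_stats(h, pops, window_bp = 3000, min_sites = 5)
  perm <- c(3, 1, 4, 2, 7, 8, 5, 6)
  h2 <- make_hapset(A[perm, ], ids = h$haplotype_ids[perm], chrom_length = 2010)
  ws2 <- windowed_stats(h2, pops, window_bp = 3000, min_sites = 5)
  expect_equal(ws1$pi1, ws2$pi1)
  expect_equal(ws1$dxy, ws2$dxy)
  expect_equal(ws1$fst, ws2$fst)
})

test_that("diploid distance matrix averages the four haplotype pairs", {
  # sample1 = 0|0, sample2 = 1|1, sample3 = 0|1 at one site
  A <- rbind(c(0L), c(0L), c(1L), c(1L), c(0L), c(1L))
  h <- make_hapset(A, pos = 100L)
  m <- diploid_distance_matrix(h)
  expect_equal(m["s1", "s2"], 1)
  expect_equal(m["s1", "s3"], 0.5)    # mean(0, 1) over the two cross-pairs x2
  expect_equal(m["s2", "s3"], 0.5)
  expect_equal(m["s1", "s1"], 0)      # homozygous: own two haplotypes equal
  expect_equal(m["s3", "s3"], 1)      # heterozygous at the only site
  expect_true(isSymmetric(m))
  # identical homozygous samples are at distance zero
  expect_equal(diploid_distance_matrix(
    make_hapset(matrix(0L, 4, 3)))["s1", "s2"], 0)
})

test_that("ld_r2 matches the textbook corners", {
  # perfect LD: haplotypes 00,00,11,11
  A <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L))
  expect_equal(ld_r2(make_hapset(A))$r2, 1)
  # equilibrium: equal counts of 00,01,10,11
  B <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  expect_equal(ld_r2(make_hapset(B))$r2, 0)
  # counts 6x00, 2x01, 2x10, 0x11 -> D = -0.04, r2 = 0.0016/0.0256
  C <- rbind(matrix(rep(c(0L, 0L), 6), ncol = 2, byrow = TRUE),
             matrix(rep(c(0L, 1L), 2), ncol = 2, byrow = TRUE),
             matrix(rep(c(1L, 0L), 2), ncol = 2, byrow = TRUE))
  expect_equal(ld_r2(make_hapset(C, ids = paste0("s", 1:10, "_A")))$r2, 0.0625)
})

test_that("ld_r2 applies the MAF filter and seeded thinning", {
  set.seed(3)
  A <- matrix(rbinom(20 * 40, 1, runif(40, 0.02, 0.5)[col(matrix(0, 20, 40))]), 20, 40)
  h <- make_hapset(A, ids = paste0("h", 1:20, "_A"))
  p <- colMeans(A)
  keep <- pmin(p, 1 - p) >= 0.2
  out <- ld_r2(h, maf_min = 0.2)
  expect_setequal(unique(c(out$pos_i, out$pos_j)), h$sites$pos[keep])
  t1 <- ld_r2(h, maf_min = 0.2, thin_to = 5, seed = 99)
  t2 <- ld_r2(h, maf_min = 0.2, thin_to = 5, seed = 99)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), choose(5, 2))
})

test_that("migration-rate conversion applies Me = 4 Ne me", {
  expect_equal(convert_migration_rate(0, 1e5)$Me, 0)
  expect_equal(convert_migration_rate(1e-6, 2.5e5)$Me, 1.0)
  expect_equal(signif(convert_migration_rate(2.42e-11, 3.12e5)$Me, 3), 3.02e-5)
  expect_error(convert_migration_rate(-1, 1), "non-negative")
})
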