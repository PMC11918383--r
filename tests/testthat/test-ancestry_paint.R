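test_that("rank_sum_test: separated samples, symmetry, exact corner", {
  x <- 1:6; y <- 11:16
  expect_equal(rank_sum_test(x, y), 1 / choose(12, 6))
  p_same <- rank_sum_test(c(1, 3, 5, 8), c(1, 3, 5, 8))
  expect_gte(p_same, 0.5)
  expect_error(rank_sum_test(numeric(0), y), "empty")
})

test_that("rank_sum_test exact branch equals enumeration on spot checks", {
  set.seed(17)
  for (rep in 1:5) {
    x <- runif(4); y <- runif(5)
    expect_equal(rank_sum_test(x, y), enumerate_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
})

# panels A and B diverged at ~30% of sites, plus a query equal to a panel-A
# haplotype; returns the haplotype set and panel table
paint_fixture <- function(seed = 23, n_sites = 600, n_panel = 10) {
  set.seed(seed)
  base <- rbinom(n_sites, 1, 0.5)
  flip <- runif(n_sites) < 0.3
  hap_a <- function() { h <- base; noise <- runif(n_sites) < 0.03
    h[noise] <- 1L - h[noise]; h }
  hap_b <- function() { h <- ifelse(flip, 1L - base, base)
    noise <- runif(n_sites) < 0.03; h[noise] <- 1L - h[noise]; as.integer(h) }
  A <- do.call(rbind, c(replicate(n_panel, hap_a(), simplify = FALSE),
                        replicate(n_panel, hap_b(), simplify = FALSE)))
  ids <- c(paste0("a", seq_len(n_panel), "_A"),
           paste0("b", seq_len(n_panel), "_A"))
  query <- A[1, ]
  A <- rbind(A, query)
  ids <- c(ids, "q_A")
  h <- make_hapset(A, pos = seq_len(n_sites) * 100L, ids = ids,
                   chrom_length = n_sites * 100L)
  panels <- tibble(haplotype_id = ids[seq_len(2 * n_panel)],
                   group = rep(c("A", "B"), each = n_panel))
  list(h = h, panels = panels)
}

test_that("a query matching panel A is painted A in every window", {
  fx <- paint_fixture()
  ps <- paint_all(fx$h, fx$panels, paint_config(window_snps = 200),
                  queries = "q_A")
  expect_equal(unique(ps$windows$label), "A")
  expect_true(all(vapply(ps$windows$p_value, function(p) p[["B"]] <= 0.01, TRUE)))
  expect_equal(nrow(ps$tracts), 1L)
})

test_that("identical panels relabelled yield UNDEFINED everywhere", {
  fx <- paint_fixture()
  # both "panels" are the same haplotypes: A's rows duplicated under label B
  dup <- fx$h
  dup$alleles <- rbind(fx$h$alleles[1:10, ], fx$h$alleles[1:10, ],
                       fx$h$alleles["q_A", , drop = FALSE])
  ids <- c(paste0("a", 1:10, "_A"), paste0("dupb", 1:10, "_A"), "q_A")
  dup <- make_hapset(dup$alleles, pos = fx$h$sites$pos, ids = ids,
                     chrom_length = 60000L)
  panels <- tibble(haplotype_id = ids[1:20],
                   group = rep(c("A", "B"), each = 10))
  ps <- paint_all(dup, panels, paint_config(window_snps = 200), queries = "q_A")
  expect_equal(unique(ps$windows$label), UNDEFINED_LABEL)
})

test_that("leave-one-out excludes the query from its own panel's sample", {
  fx <- paint_fixture()
  panels <- fx$panels
  # make the query itself a member of panel A
  panels <- dplyr::bind_rows(panels, tibble(haplotype_id = "q_A", group = "A"))
  ps <- paint_all(fx$h, panels, paint_config(window_snps = 200), queries = "q_A")
  # the query duplicates panel hap a1_A, so without LOO the A-sample would
  # contain a zero self-distance; with LOO the minimum mean stays positive
  mins <- vapply(ps$windows$mean_dist, function(m) m[["A"]], 1.0)
  expect_true(all(mins > 0))
  expect_equal(unique(ps$windows$label), "A")
  ps2 <- paint_all(fx$h, panels,
                   paint_config(window_snps = 200, leave_one_out = FALSE),
                   queries = "q_A")
  mins2 <- vapply(ps2$windows$mean_dist, function(m) m[["A"]], 1.0)
  expect_true(all(mins2 < mins))
})

test_that("panels below min_panel_size are rejected by name", {
  fx <- paint_fixture(n_panel = 3)
  expect_error(paint_all(fx$h, fx$panels, paint_config(min_panel_size = 4)),
               "min_panel_size.*A")
})

test_that("windows merge into tracts by maximal runs, UNDEFINED unbridged", {
  w <- tibble(haplotype_id = "h_A", chrom = "c", window = 1:5,
              start = c(1, 101, 201, 301, 401),
              end = c(100, 200, 300, 400, 500),
              label = c("A", "A", "B", "B", "B"))
  tr <- windows_to_tracts(w)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$end, c(200, 500))

  w$label <- rep("A", 5)
  expect_equal(nrow(windows_to_tracts(w)), 1L)

  w$label <- c("A", UNDEFINED_LABEL, "A", "A", "A")
  tr3 <- windows_to_tracts(w)
  expect_equal(tr3$label, c("A", UNDEFINED_LABEL, "A"))
})

test_that("painting is deterministic and label-permutation-invariant", {
  fx <- paint_fixture()
  ps1 <- paint_all(fx$h, fx$panels, paint_config(window_snps = 150),
                   queries = "q_A")
  ps2 <- paint_all(fx$h, fx$panels, paint_config(window_snps = 150),
                   queries = "q_A")
  expect_identical(ps1$windows$label, ps2$windows$label)
  # swapping panel names swaps labels only
  swapped <- fx$panels
  swapped$group <- ifelse(swapped$group == "A", "B", "A")
  ps3 <- paint_all(fx$h, swapped, paint_config(window_snps = 150),
                   queries = "q_A")
  expect_equal(ps3$windows$label,
               ifelse(ps1$windows$label == "A", "B",
                      ifelse(ps1$windows$label == "B", "A",
                             ps1$windows$label)))
})

test_that("tract boundaries coincide with window boundaries", {
  cfg <- sim_config(seed = 41, chrom_length = 6e5, n_sites = 2400,
                    groups = tibble(label = c("A", "B"), f = 0.3, n_panel = 10L),
                    cohort = tibble(sample = "q",
                                    hap_a = list(mosaic(c("A", "B"), c(3e5, 6e5))),
                                    hap_b = list("B")))
  sim <- simulate_cohort(cfg)
  h <- split_haplotypes(sim$genos)
  ps <- paint_all(h, sim$panels, paint_config(window_snps = 200),
                  queries = c("q_A", "q_B"))
  starts_ok <- ps$tracts$start %in% ps$windows$start
  ends_ok <- ps$tracts$end %in% ps$windows$end
  expect_true(all(starts_ok) && all(ends_ok))
})

test_that("painting accuracy among assigned windows grows with divergence", {
  acc_at_f <- function(f) {
    cfg <- sim_config(seed = 71, chrom_length = 4e5, n_sites = 2000,
                      groups = tibble(label = c("A", "B"), f = f, n_panel = 12L),
                      cohort = tibble(sample = c("q1", "q2"),
                                      hap_a = list("A", "B"),
                                      hap_b = list("B", "A")))
    sim <- simulate_cohort(cfg)
    h <- split_haplotypes(sim$genos)
    ps <- paint_all(h, sim$panels, paint_config(window_snps = 200),
                    queries = paste0(rep(c("q1", "q2"), each = 2), c("_A", "_B")))
    acc <- painting_accuracy(ps, sim$truth$tracts)
    acc$accuracy
  }
  accs <- vapply(c(0.05, 0.1, 0.3), acc_at_f, 1.0)
  expect_true(all(diff(accs) >= 0) || accs[3] >= 0.99)
  expect_gt(accs[3], accs[1] - 1e-9)
})
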