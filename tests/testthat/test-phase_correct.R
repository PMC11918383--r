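# small literal tract tables are the easiest substrate for the corrector
tr_row <- function(hid, start, end, label) {
  tibble(haplotype_id = hid, chrom = "c", start = as.integer(start),
         end = as.integer(end), label = label)
}

test_that("build_label_matrix forms the union partition", {
  tracts <- dplyr::bind_rows(
    tr_row("s1_A", 1, 100, "A"), tr_row("s1_A", 101, 300, "B"),
    tr_row("s1_B", 1, 200, "B"), tr_row("s1_B", 201, 300, "A"))
  m <- build_label_matrix(tracts)
  expect_equal(nrow(m$intervals), 3L)
  expect_equal(m$intervals$start, c(1L, 101L, 201L))
  expect_equal(m$intervals$end, c(100L, 200L, 300L))
  expect_equal(unname(m$labels["s1_A", ]), c("A", "B", "B"))
  expect_equal(unname(m$labels["s1_B", ]), c("B", "B", "A"))
  # labels constant within intervals by construction; round-trip to tracts
  rt <- label_matrix_to_tracts(m)
  expect_equal(rt$label[rt$haplotype_id == "s1_A"], c("A", "B"))
})

test_that("a single haplotype's partition equals its own tracts", {
  tracts <- dplyr::bind_rows(tr_row("h_A", 1, 50, "A"), tr_row("h_A", 51, 80, "B"))
  m <- build_label_matrix(tracts)
  expect_equal(m$intervals$start, c(1L, 51L))
  expect_equal(m$intervals$end, c(50L, 80L))
})

test_that("duplicate boundaries deduplicate without zero-length intervals", {
  tracts <- dplyr::bind_rows(
    tr_row("x_A", 1, 100, "A"), tr_row("x_A", 101, 200, "B"),
    tr_row("x_B", 1, 100, "B"), tr_row("x_B", 101, 200, "A"))
  m <- build_label_matrix(tracts)
  expect_equal(nrow(m$intervals), 2L)
  expect_true(all(m$intervals$length > 0))
})

test_that("pair_similarity is length-weighted over defined intervals", {
  lens <- c(300, 100)
  expect_equal(pair_similarity(c("A", "B"), c("A", "B"), lens), 1)
  expect_equal(pair_similarity(c("A", "B"), c("B", "A"), lens), 0)
  expect_equal(pair_similarity(c("A", "A"), c("A", "B"), lens), 0.75)
  expect_equal(pair_similarity(c("A", UNDEFINED_LABEL),
                               c("A", "B"), lens), 1)
  expect_equal(pair_similarity(c(UNDEFINED_LABEL, UNDEFINED_LABEL),
                               c("A", "B"), lens), 0)
})

# a cohort of intact A and B haplotypes plus one individual with a planted
# switch error downstream of interval `switch_at`
switch_fixture <- function(n_donor_samples = 4, K = 6, switch_at = 3) {
  rows <- list()
  for (i in seq_len(n_donor_samples)) {
    rows[[paste0("d", i, "_A")]] <- rep("A", K)
    rows[[paste0("d", i, "_B")]] <- rep("B", K)
  }
  qa <- rep("A", K); qb <- rep("B", K)
  idx <- (switch_at + 1):K
  qa[idx] <- "B"; qb[idx] <- "A"
  rows[["q_A"]] <- qa; rows[["q_B"]] <- qb
  labels <- do.call(rbind, rows)
  structure(list(labels = labels,
                 intervals = tibble(start = seq(1, K * 100, by = 100),
                                    end = seq(100, K * 100, by = 100),
                                    length = rep(100, K)),
                 sample_of = sub("_[AB]$", "", rownames(labels)),
                 chrom = "c"),
            class = "label_matrix")
}

test_that("a planted switch error is repaired against intact donors", {
  m <- switch_fixture()
  res <- phasepaint_correct(m, max_iter = 20)
  expect_equal(unname(res$labels$labels["q_A", ]), rep("A", 6))
  expect_equal(unname(res$labels$labels["q_B", ]), rep("B", 6))
  expect_true(all(res$log$sample == "q"))
  expect_setequal(res$log$interval, 4:6)
  expect_true(res$converged)
})

test_that("clean input is a fixed point and max_iter beyond convergence is moot", {
  m <- switch_fixture()
  m$labels["q_A", ] <- "A"; m$labels["q_B", ] <- "B"
  res <- phasepaint_correct(m, max_iter = 20)
  expect_equal(nrow(res$log), 0L)
  expect_identical(res$labels$labels, m$labels)

  m2 <- switch_fixture()
  r1 <- phasepaint_correct(m2, max_iter = 5)
  r2 <- phasepaint_correct(m2, max_iter = 500)
  expect_identical(r1$labels$labels, r2$labels$labels)
})

test_that("swaps conserve the per-sample label multiset at every interval", {
  m <- switch_fixture(n_donor_samples = 3, K = 8, switch_at = 5)
  res <- phasepaint_correct(m)
  for (s in unique(m$sample_of)) {
    rows <- which(m$sample_of == s)
    for (j in seq_len(ncol(m$labels))) {
      expect_setequal(unname(res$labels$labels[rows, j]),
                      unname(m$labels[rows, j]))
    }
  }
})

test_that("the switch log replays to the corrected output, deterministically", {
  m <- switch_fixture()
  r1 <- phasepaint_correct(m)
  r2 <- phasepaint_correct(m)
  expect_identical(r1$log, r2$log)
  replayed <- apply_switch_log(m, r1$log)
  expect_identical(replayed$labels, r1$labels$labels)
})

test_that("fewer than four haplotypes is an error", {
  m <- switch_fixture(n_donor_samples = 1)
  m$labels <- m$labels[1:3, ]
  m$sample_of <- m$sample_of[1:3]
  expect_error(phasepaint_correct(m), "at least 4")
})

test_that("correction never increases per-sample breakpoint counts on sims", {
  cfg <- sim_config(seed = 83, chrom_length = 5e5, n_sites = 2500,
                    groups = tibble(label = c("A", "B", "C"), f = 0.3,
                                    n_panel = c(8L, 8L, 8L)),
                    cohort = tibble(
                      sample = paste0("q", 1:6),
                      hap_a = list("A", "A", "B", "C", "A", "B"),
                      hap_b = list("B", "C", "C", "C", "B", "B")),
                    switch_errors = tibble(sample = c("q1", "q3"),
                                           pos = c(2e5, 3e5)))
  sim <- simulate_cohort(cfg)
  h <- split_haplotypes(sim$genos)
  ps <- paint_all(h, sim$panels, paint_config(window_snps = 200))
  m <- build_label_matrix(ps)
  before <- haplopaint:::count_breakpoints(m)
  res <- phasepaint_correct(m)
  after <- haplopaint:::count_breakpoints(res$labels)
  cmp <- dplyr::left_join(before, after, by = "sample",
                          suffix = c("_pre", "_post"))
  expect_true(all(cmp$n_breakpoints_post <= cmp$n_breakpoints_pre))
})
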