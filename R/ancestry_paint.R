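# Window-based ancestry painting: each query haplotype is compared, in
# consecutive blocks of SNPs, to reference panels by genetic distance, and a
# window is assigned to the closest panel only when a one-sided Wilcoxon
# rank-sum test says its distances are significantly lower than those to
# every other panel. Runs of identically-labelled windows merge into tracts.

#' Painting parameters
#'
#' @param window_snps SNPs per window (consecutive non-overlapping blocks; a
#'   trailing window shorter than `window_snps / 2` is dropped).
#' @param alpha significance threshold for the rank-sum gate; a window is
#'   assigned only if `p <= alpha` against every competing panel.
#' @param min_panel_size minimum panel haplotypes available after
#'   leave-one-out exclusion of the query.
#' @param leave_one_out exclude the query haplotype from its own panel's
#'   distance sample.
#' @param min_complete_fraction a panel haplotype sharing fewer than this
#'   fraction of a window's sites with the query is dropped from that
#'   window's sample.
#' @return a `paint_config` list.
#' @export
paint_config <- function(window_snps = 200L, alpha = 0.01,
                         min_panel_size = 4L, leave_one_out = TRUE,
                         min_complete_fraction = 0.25) {
  if (window_snps < 2) abort("window_snps must be >= 2")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  structure(list(window_snps = as.integer(window_snps), alpha = alpha,
                 min_panel_size = as.integer(min_panel_size),
                 leave_one_out = isTRUE(leave_one_out),
                 min_complete_fraction = min_complete_fraction),
            class = "paint_config")
}

#' One-sided Wilcoxon rank-sum test that `x` is stochastically smaller
#'
#' Exact null distribution when `length(x) + length(y) <= 20` and there are
#' no ties; otherwise the normal approximation with midrank tie correction
#' and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @return the one-sided p-value in (0, 1\].
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("empty sample in rank_sum_test")
  exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = "less", exact = exact,
                correct = TRUE)$p.value)
}

# window index blocks over the filtered site list
snp_windows <- function(n_sites, window_snps) {
  if (n_sites < window_snps / 2) return(list())
  starts <- seq(1L, n_sites, by = window_snps)
  wins <- lapply(starts, function(s) s:min(s + window_snps - 1L, n_sites))
  if (length(wins[[length(wins)]]) < window_snps / 2) {
    wins <- wins[-length(wins)]
  }
  wins
}

#' Paint query haplotypes against reference panels
#'
#' Partitions the site list into consecutive windows of `window_snps` SNPs.
#' For every window and query haplotype, the distance (proportion of
#' differing alleles over pairwise-complete sites) to every panel haplotype
#' is computed; the candidate panel is the one with the lowest mean distance,
#' and the window takes its label only if the query's distances to the
#' candidate are significantly lower than to *every* other panel
#' ([rank_sum_test()], `p <= alpha`); otherwise the window is `UNDEFINED`.
#' Equal candidate means also give `UNDEFINED`. A query belonging to a panel
#' is painted with itself excluded from that panel's sample
#' (`leave_one_out`).
#'
#' @param h a `haplotype_set` containing the query and panel haplotypes.
#' @param panels tibble (haplotype_id, group) defining reference panels.
#' @param cfg a [paint_config()].
#' @param queries haplotype ids to paint; default all haplotypes in `h`.
#' @return a `painted_set`: list with `windows` (per-haplotype per-window
#'   tibble with mean panel distances and rank-sum p-values as list-columns),
#'   `tracts` (tibble haplotype_id, chrom, start, end, label), `groups`, and
#'   `config`.
#' @export
paint_all <- function(h, panels, cfg = paint_config(), queries = NULL) {
  bind_panels(panels, h)
  queries <- queries %||% h$haplotype_ids
  stopifnot(all(queries %in% h$haplotype_ids))
  groups <- unique(panels$group)
  panel_idx <- lapply(groups, function(g) {
    match(panels$haplotype_id[panels$group == g], h$haplotype_ids)
  })
  names(panel_idx) <- groups
  sizes <- vapply(groups, function(g) {
    n0 <- length(panel_idx[[g]])
    loo <- cfg$leave_one_out && any(queries %in% panels$haplotype_id[panels$group == g])
    n0 - as.integer(loo)
  }, 1L)
  too_small <- groups[sizes < cfg$min_panel_size]
  if (length(too_small) > 0) {
    abort(paste0("panel(s) below min_panel_size after leave-one-out: ",
                 paste(too_small, collapse = ", ")))
  }
  wins <- snp_windows(nrow(h$sites), cfg$window_snps)
  chrom <- if (nrow(h$sites)) h$sites$chrom[1] else NA_character_
  qi <- match(queries, h$haplotype_ids)

  rows <- vector("list", length(wins))
  for (w in seq_along(wins)) {
    cols <- wins[[w]]
    m <- length(cols)
    pc <- pair_counts(h$alleles[, cols, drop = FALSE])
    dmat <- ifelse(pc$comp > 0, pc$diffs / pc$comp, NA_real_)
    usable <- pc$comp >= cfg$min_complete_fraction * m
    labs <- character(length(qi))
    mean_ds <- vector("list", length(qi))
    pvs <- vector("list", length(qi))
    for (k in seq_along(qi)) {
      q <- qi[k]
      dsamp <- lapply(groups, function(g) {
        p <- panel_idx[[g]]
        if (cfg$leave_one_out) p <- setdiff(p, q)
        d <- dmat[q, p]
        d[usable[q, p] & !is.na(d)]
      })
      names(dsamp) <- groups
      means <- vapply(dsamp, function(d) if (length(d)) mean(d) else NA_real_, 1.0)
      mean_ds[[k]] <- means
      lab <- UNDEFINED_LABEL
      pv <- setNames(rep(NA_real_, length(groups)), groups)
      if (!anyNA(means)) {
        best <- which(means == min(means))
        if (length(best) == 1) {
          cand <- groups[best]
          others <- setdiff(groups, cand)
          pv_o <- vapply(others, function(g) {
            rank_sum_test(dsamp[[cand]], dsamp[[g]])
          }, 1.0)
          pv[others] <- pv_o
          if (all(pv_o <= cfg$alpha)) lab <- cand
        }
      }
      labs[k] <- lab
      pvs[[k]] <- pv
    }
    rows[[w]] <- tibble(
      haplotype_id = queries, chrom = chrom, window = w,
      start = h$sites$pos[cols[1]], end = h$sites$pos[cols[m]],
      n_snps = m, label = labs, mean_dist = mean_ds, p_value = pvs)
  }
  windows <- bind_rows(rows) %>% arrange(.data$haplotype_id, .data$window)
  tracts <- windows_to_tracts(windows)
  structure(list(windows = windows, tracts = tracts, groups = groups,
                 config = cfg),
            class = "painted_set")
}

#' Merge per-window labels into ancestry tracts
#'
#' Maximal runs of identically-labelled consecutive windows become one tract
#' spanning the first to the last SNP of its windows. `UNDEFINED` runs form
#' their own tracts; defined labels are never bridged across them.
#'
#' @param windows tibble with columns haplotype_id, chrom, window, start,
#'   end, label (as in a `painted_set`'s `windows` element).
#' @return a tract tibble (haplotype_id, chrom, start, end, label).
#' @export
windows_to_tracts <- function(windows) {
  windows %>%
    arrange(.data$haplotype_id, .data$window) %>%
    group_by(.data$haplotype_id) %>%
    mutate(run = cumsum(c(TRUE, .data$label[-1] != .data$label[-dplyr::n()]))) %>%
    group_by(.data$haplotype_id, .data$chrom, .data$run) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              label = .data$label[1], .groups = "drop") %>%
    select("haplotype_id", "chrom", "start", "end", "label") %>%
    arrange(.data$haplotype_id, .data$start)
}

#' @export
print.painted_set <- function(x, ...) {
  n_h <- length(unique(x$windows$haplotype_id))
  n_w <- max(x$windows$window)
  af <- mean(x$windows$label != UNDEFINED_LABEL)
  cat(sprintf("<painted_set> %d haplotypes x %d windows; %.1f%% assigned; panels: %s\n",
              n_h, n_w, 100 * af, paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' @describeIn paint_all tidy method: returns the tract tibble.
#' @param x a `painted_set`.
#' @param ... unused.
#' @export
tidy.painted_set <- function(x, ...) x$tracts

#' @describeIn paint_all glance method: one-row summary (haplotypes, windows,
#'   assigned fraction, tract count).
#' @export
glance.painted_set <- function(x, ...) {
  tibble(
    n_haplotypes = length(unique(x$windows$haplotype_id)),
    n_windows = max(x$windows$window),
    assigned_fraction = mean(x$windows$label != UNDEFINED_LABEL),
    n_tracts = nrow(x$tracts))
}
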