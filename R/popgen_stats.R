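# Windowed diversity/divergence statistics, pairwise distances, LD r^2 and
# the effective-migrants unit conversion.
#
# All distances are proportions of differing alleles per pairwise-complete
# site: for each haplotype pair, only sites non-missing in both are counted.

#' Proportion of differing alleles between two haplotypes
#'
#' Counts differences over pairwise-complete sites only (sites missing in
#' either haplotype are ignored). Returns `NA` when no complete site exists.
#'
#' @param h1,h2 equal-length allele vectors over \{0, 1, NA\}.
#' @return a proportion in \[0, 1\], or `NA`.
#' @export
hap_distance <- function(h1, h2) {
  if (length(h1) != length(h2)) abort("haplotype vectors differ in length")
  ok <- !is.na(h1) & !is.na(h2)
  n <- sum(ok)
  if (n == 0) return(NA_real_)
  sum(h1[ok] != h2[ok]) / n
}

# All-pairs difference and complete-site counts for an allele matrix
# (haplotypes x sites). Returns list(diffs, comp) of n x n matrices.
pair_counts <- function(A) {
  M <- !is.na(A)
  storage.mode(M) <- "double"
  X <- A
  X[is.na(X)] <- 0
  storage.mode(X) <- "double"
  P <- X            # carries 1 where allele == 1 and site called
  Q <- M - X        # 1 where allele == 0 and site called
  diffs <- P %*% t(Q)
  diffs <- diffs + t(diffs)
  comp <- M %*% t(M)
  list(diffs = diffs, comp = comp)
}

mean_pair_ratio <- function(diffs, comp, rows, cols = rows, within = TRUE) {
  d <- diffs[rows, cols, drop = FALSE]
  k <- comp[rows, cols, drop = FALSE]
  if (within) {
    iu <- upper.tri(d)
    d <- d[iu]; k <- k[iu]
  } else {
    d <- as.vector(d); k <- as.vector(k)
  }
  ok <- k > 0
  if (!any(ok)) return(NA_real_)
  mean(d[ok] / k[ok])
}

sum_ratio <- function(diffs, comp, rows, cols = rows, within = TRUE) {
  d <- diffs[rows, cols, drop = FALSE]
  k <- comp[rows, cols, drop = FALSE]
  if (within) {
    iu <- upper.tri(d)
    d <- d[iu]; k <- k[iu]
  }
  if (sum(k) == 0) return(NA_real_)
  sum(d) / sum(k)
}

#' Windowed diversity and divergence statistics
#'
#' Computes, in non-overlapping physical windows (default 50 kb, half-open
#' `[start, start + size)` on 1-based starts), nucleotide diversity pi within
#' each population, absolute divergence dXY and net divergence
#' `da = dXY - (pi1 + pi2)/2` for each population pair, and Hudson's FST
#' `1 - Hw/Hb`, where `Hw`/`Hb` are the within/between mean per-site distances
#' computed as ratios of window sums over haplotype pairs. pi and dXY average
#' per-pair proportions, each pair over its own pairwise-complete sites.
#' Windows with fewer than `min_sites` usable sites carry `NA` statistics.
#'
#' @param h a `haplotype_set`.
#' @param pops tibble (haplotype_id, group) assigning haplotypes to
#'   populations; every population needs at least 2 haplotypes.
#' @param window_bp window size in bp.
#' @param chrom_length chromosome length tiled by windows; defaults to the
#'   `chrom_length` attribute of the site set, else the last site position.
#' @param min_sites minimum usable sites for a window to be evaluated.
#' @return a tibble with one row per window and population pair: `chrom`,
#'   `start`, `end` (half-open), `n_used_sites`, `pop1`, `pop2`, `pi1`, `pi2`,
#'   `dxy`, `da`, `fst`. With a single population, one row per window with
#'   `pop2` and the divergence columns `NA`.
#' @export
windowed_stats <- function(h, pops, window_bp = 50000L, chrom_length = NULL,
                           min_sites = 20L) {
  bind_panels(pops, h)
  groups <- unique(pops$group)
  idx <- lapply(groups, function(g) {
    match(pops$haplotype_id[pops$group == g], h$haplotype_ids)
  })
  names(idx) <- groups
  small <- groups[vapply(idx, length, 1L) < 2]
  if (length(small) > 0) {
    abort(paste0("population(s) with fewer than 2 haplotypes: ",
                 paste(small, collapse = ", ")))
  }
  chrom_length <- chrom_length %||% attr(h$sites, "chrom_length") %||%
    max(h$sites$pos)
  starts <- seq(1L, as.integer(chrom_length), by = as.integer(window_bp))
  pairs <- if (length(groups) >= 2) utils::combn(groups, 2) else
    matrix(c(groups, NA_character_), nrow = 2)

  out <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    s0 <- starts[w]; e0 <- min(s0 + window_bp, as.integer(chrom_length) + 1L)
    in_w <- which(h$sites$pos >= s0 & h$sites$pos < e0)
    nw <- length(in_w)
    rows <- vector("list", ncol(pairs))
    if (nw >= min_sites) {
      pc <- pair_counts(h$alleles[, in_w, drop = FALSE])
      pis <- vapply(groups, function(g) {
        mean_pair_ratio(pc$diffs, pc$comp, idx[[g]])
      }, 1.0)
      names(pis) <- groups
      for (k in seq_len(ncol(pairs))) {
        g1 <- pairs[1, k]; g2 <- pairs[2, k]
        if (is.na(g2)) {
          rows[[k]] <- tibble(pop1 = g1, pop2 = NA_character_,
                              pi1 = pis[[g1]], pi2 = NA_real_,
                              dxy = NA_real_, da = NA_real_, fst = NA_real_)
        } else {
          dxy <- mean_pair_ratio(pc$diffs, pc$comp, idx[[g1]], idx[[g2]],
                                 within = FALSE)
          da <- dxy - (pis[[g1]] + pis[[g2]]) / 2
          hw1 <- sum_ratio(pc$diffs, pc$comp, idx[[g1]])
          hw2 <- sum_ratio(pc$diffs, pc$comp, idx[[g2]])
          hb <- sum_ratio(pc$diffs, pc$comp, idx[[g1]], idx[[g2]],
                          within = FALSE)
          hw <- mean(c(hw1, hw2), na.rm = TRUE)
          fst <- if (is.na(hb) || hb == 0 || is.na(hw)) NA_real_ else 1 - hw / hb
          rows[[k]] <- tibble(pop1 = g1, pop2 = g2,
                              pi1 = pis[[g1]], pi2 = pis[[g2]],
                              dxy = dxy, da = da, fst = fst)
        }
      }
    } else {
      for (k in seq_len(ncol(pairs))) {
        rows[[k]] <- tibble(pop1 = pairs[1, k], pop2 = pairs[2, k],
                            pi1 = NA_real_, pi2 = NA_real_,
                            dxy = NA_real_, da = NA_real_, fst = NA_real_)
      }
    }
    out[[w]] <- bind_rows(rows) %>%
      mutate(chrom = if (nrow(h$sites)) h$sites$chrom[1] else NA_character_,
             start = s0, end = e0, n_used_sites = nw, .before = 1)
  }
  bind_rows(out)
}

#' Mean pairwise distance matrix between diploid individuals
#'
#' For each pair of diploid individuals the entry is the mean of the four
#' haplotype-pair distances between them; the diagonal holds the distance
#' between an individual's own two haplotypes. This matrix is the standard
#' input for distance-based network methods (e.g. Neighbor-Net). Pairs whose
#' four haplotype distances are all undefined propagate `NA`.
#'
#' @param h a `haplotype_set` with two haplotypes per sample.
#' @return a symmetric numeric matrix with sample ids as dimnames.
#' @export
diploid_distance_matrix <- function(h) {
  samp <- sub("_[AB]$", "", h$haplotype_ids)
  sample_ids <- unique(samp)
  pc <- pair_counts(h$alleles)
  d <- ifelse(pc$comp > 0, pc$diffs / pc$comp, NA_real_)
  n <- length(sample_ids)
  out <- matrix(NA_real_, n, n, dimnames = list(sample_ids, sample_ids))
  hap_idx <- lapply(sample_ids, function(s) which(samp == s))
  for (i in seq_len(n)) {
    hi <- hap_idx[[i]]
    if (length(hi) == 2) out[i, i] <- d[hi[1], hi[2]]
    for (j in seq_len(n)) {
      if (j <= i) next
      hj <- hap_idx[[j]]
      v <- as.vector(d[hi, hj, drop = FALSE])
      out[i, j] <- out[j, i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
  }
  out
}

#' Pairwise linkage disequilibrium r-squared from phased haplotypes
#'
#' Computes `r^2 = D^2 / (p_i (1-p_i) p_j (1-p_j))` with
#' `D = P(11) - p_i p_j` from two-locus haplotype counts. Sites with any
#' missing allele across the used haplotypes are dropped (complete-case), as
#' are sites with minor allele frequency below `maf_min` or monomorphic sites.
#' When `thin_to` is given, surviving sites are thinned by seeded sampling
#' without replacement before pairing.
#'
#' @param h a `haplotype_set`.
#' @param maf_min minimum minor allele frequency.
#' @param thin_to optional number of sites to retain after filtering.
#' @param seed integer seed for the thinning draw.
#' @return a tibble (pos_i, pos_j, r2) with `pos_i < pos_j`.
#' @export
ld_r2 <- function(h, maf_min = 0.2, thin_to = NULL, seed = 1L) {
  complete <- colSums(is.na(h$alleles)) == 0
  A <- h$alleles[, complete, drop = FALSE]
  pos <- h$sites$pos[complete]
  p <- colMeans(A)
  keep <- pmin(p, 1 - p) >= maf_min & p > 0 & p < 1
  A <- A[, keep, drop = FALSE]
  pos <- pos[keep]
  if (!is.null(thin_to) && ncol(A) > thin_to) {
    pick <- withr::with_seed(seed, sort(sample.int(ncol(A), thin_to)))
    A <- A[, pick, drop = FALSE]
    pos <- pos[pick]
  }
  S <- ncol(A)
  if (S < 2) return(tibble(pos_i = integer(0), pos_j = integer(0), r2 = double(0)))
  n <- nrow(A)
  p <- colMeans(A)
  P11 <- crossprod(A) / n
  D <- P11 - tcrossprod(p)
  denom <- outer(p * (1 - p), p * (1 - p))
  r2 <- D^2 / denom
  iu <- which(upper.tri(r2), arr.ind = TRUE)
  tibble(pos_i = pos[iu[, 1]], pos_j = pos[iu[, 2]],
         r2 = r2[iu]) %>% arrange(.data$pos_i, .data$pos_j)
}

#' Convert an effective migration rate to effective migrants per generation
#'
#' `Me = 4 * Ne * me`: the per-generation effective migration rate `me`
#' scaled by four times the effective population size of the chosen
#' population. For gene flux between supergene haplotype groups fitted as
#' isolation-with-migration, `Ne` should be the effective size of the
#' population receiving migrants (but note published tables are not always
#' consistent about which Ne was used; this function simply applies the
#' conversion to the Ne it is given, recording it in the output).
#'
#' @param me effective migration rate(s) per generation, non-negative.
#' @param ne effective population size(s), in individuals.
#' @return a tibble (me, ne, Me).
#' @export
convert_migration_rate <- function(me, ne) {
  if (any(me < 0, na.rm = TRUE) || any(ne < 0, na.rm = TRUE)) {
    abort("me and ne must be non-negative")
  }
  tibble(me = me, ne = ne, Me = 4 * ne * me)
}
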