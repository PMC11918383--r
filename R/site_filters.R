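# Genotype- and site-level filters, applied in the order genotype -> site.

#' Filtering thresholds
#'
#' Thresholds used by [filter_genotype_quality()] and [filter_sites()].
#' Defaults follow common resequencing practice for this kind of data:
#' per-genotype depth >= 7 and genotype quality >= 30 (both inclusive), sites
#' dropped when more than 10% of haplotypes are missing, when more than 75% of
#' called individuals are heterozygous (a mis-mapping signature), or when the
#' minor allele is present fewer than 2 times. Set any threshold to `NA` to
#' disable that rule.
#'
#' @param min_depth,min_gq inclusive per-genotype minima for DP and GQ.
#' @param max_missing_fraction a site is kept only if its called-haplotype
#'   count is at least `floor((1 - max_missing_fraction) * N)` for `N` total
#'   haplotypes.
#' @param max_het_fraction maximum fraction of *called* diploid individuals
#'   heterozygous at a site (0.75 for distance/tree input, 0.60 upstream of
#'   ancestry painting).
#' @param min_minor_allele_count minimum minor-allele count over called
#'   haplotypes.
#' @param min_nonmissing_fraction minimum fraction of individuals with
#'   non-missing data at a site.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_depth = 7L, min_gq = 30L,
                          max_missing_fraction = 0.10,
                          max_het_fraction = 0.75,
                          min_minor_allele_count = 2L,
                          min_nonmissing_fraction = 0.50) {
  for (p in c(max_missing_fraction, max_het_fraction, min_nonmissing_fraction)) {
    if (!is.na(p) && (p < 0 || p > 1)) abort("proportions must be in [0, 1]")
  }
  for (k in c(min_depth, min_gq, min_minor_allele_count)) {
    if (!is.na(k) && k < 0) abort("count thresholds must be non-negative")
  }
  structure(list(min_depth = min_depth, min_gq = min_gq,
                 max_missing_fraction = max_missing_fraction,
                 max_het_fraction = max_het_fraction,
                 min_minor_allele_count = min_minor_allele_count,
                 min_nonmissing_fraction = min_nonmissing_fraction),
            class = "filter_config")
}

#' Minimum called-haplotype count implied by a missing-data ceiling
#'
#' With `n` total haplotypes and at most a fraction `max_missing` missing,
#' the minimum number of called haplotypes at a surviving site is
#' `floor((1 - max_missing) * n)`; e.g. 348 haplotypes at 10% give 313, and
#' 249 give 224.
#'
#' @param n total haplotype count.
#' @param max_missing maximum missing fraction.
#' @return an integer count.
#' @export
min_called_haplotypes <- function(n, max_missing) {
  as.integer(floor((1 - max_missing) * n))
}

#' Mask genotypes failing depth/quality thresholds
#'
#' Genotypes with `DP < min_depth` or `GQ < min_gq` (thresholds inclusive:
#' DP = 7, GQ = 30 pass at the defaults) are set to missing. Genotypes whose
#' DP/GQ annotation is absent are retained. Dimensions are unchanged. If the
#' set carries neither DP nor GQ the call is a no-op with a warning.
#'
#' @param d a `diploid_set`.
#' @param cfg a [filter_config()].
#' @return a `diploid_set` of identical dimensions.
#' @export
filter_genotype_quality <- function(d, cfg = filter_config()) {
  if (is.null(d$dp) && is.null(d$gq)) {
    warn("no DP or GQ annotations present; genotype filter is a no-op")
    return(d)
  }
  fail <- matrix(FALSE, length(d$sample_ids), nrow(d$sites))
  if (!is.null(d$dp) && !is.na(cfg$min_depth)) {
    fail <- fail | (!is.na(d$dp) & d$dp < cfg$min_depth)
  }
  if (!is.null(d$gq) && !is.na(cfg$min_gq)) {
    fail <- fail | (!is.na(d$gq) & d$gq < cfg$min_gq)
  }
  d$a1[fail] <- NA_integer_
  d$a2[fail] <- NA_integer_
  d$phased[fail] <- FALSE
  d
}

#' Drop sites failing missingness, heterozygosity or allele-count rules
#'
#' A site survives when (i) its called-haplotype count is at least
#' `floor((1 - max_missing_fraction) * N)` where `N` is the total haplotype
#' count, (ii) the fraction of individuals with non-missing data is at least
#' `min_nonmissing_fraction`, (iii) at most `max_het_fraction` of called
#' diploid individuals are heterozygous, and (iv) the minor allele is present
#' at least `min_minor_allele_count` times among called haplotypes. The
#' heterozygosity denominator is the number of individuals *called* at the
#' site. Rules with `NA` thresholds are skipped. Applying the same config
#' twice is a no-op (idempotence).
#'
#' @param d a `diploid_set`.
#' @param cfg a [filter_config()].
#' @return a list with elements `genos` (the filtered `diploid_set`) and
#'   `log`, a tibble (chrom, pos, keep, reason) with one row per input site;
#'   `reason` names the first failed rule, or `"pass"`.
#' @export
filter_sites <- function(d, cfg = filter_config()) {
  n_hap_per <- ifelse(d$haploid, 1L, 2L)
  n_total_haps <- sum(n_hap_per)
  called1 <- !is.na(d$a1)
  called2 <- !is.na(d$a2) & !d$haploid   # haploids contribute one allele
  n_called_haps <- colSums(called1) + colSums(called2)
  n_called_ind <- colSums(called1)
  het <- called1 & called2 & (d$a1 != d$a2)
  dip_called <- colSums(called1 & !d$haploid)
  het_frac <- ifelse(dip_called > 0, colSums(het) / dip_called, 0)
  ones <- colSums(d$a1 * called1, na.rm = TRUE) +
    colSums(d$a2 * called2, na.rm = TRUE)
  mac <- pmin(ones, n_called_haps - ones)

  reason <- rep("pass", nrow(d$sites))
  if (!is.na(cfg$min_minor_allele_count)) {
    reason[mac < cfg$min_minor_allele_count] <- "minor_allele_count"
  }
  if (!is.na(cfg$max_het_fraction)) {
    reason[het_frac > cfg$max_het_fraction] <- "heterozygosity"
  }
  if (!is.na(cfg$min_nonmissing_fraction)) {
    reason[n_called_ind < cfg$min_nonmissing_fraction * length(d$sample_ids)] <-
      "nonmissing_fraction"
  }
  if (!is.na(cfg$max_missing_fraction)) {
    min_called <- min_called_haplotypes(n_total_haps, cfg$max_missing_fraction)
    reason[n_called_haps < min_called] <- "missing_fraction"
  }
  keep <- reason == "pass"
  log <- tibble(chrom = d$sites$chrom, pos = d$sites$pos,
                keep = keep, reason = reason)
  if (!all(keep)) {
    d$sites <- new_site_set(d$sites$chrom[keep], d$sites$pos[keep],
                            d$sites$ref[keep], d$sites$alt[keep],
                            chrom_length = attr(d$sites, "chrom_length"))
    for (f in c("a1", "a2", "phased", "dp", "gq")) {
      if (!is.null(d[[f]])) d[[f]] <- d[[f]][, keep, drop = FALSE]
    }
  }
  if (sum(keep) == 0) inform("filter_sites: no sites survived")
  list(genos = d, log = log)
}
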