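# fixture builders shared across tests

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# haplotype_set straight from an allele matrix (rows = haplotypes)
make_hapset <- function(alleles, pos = seq_len(ncol(alleles)) * 10L,
                        ids = NULL, chrom = "chr15", chrom_length = NULL) {
  ids <- ids %||% paste0("s", rep(seq_len(nrow(alleles) / 2), each = 2),
                         c("_A", "_B"))
  sites <- haplopaint:::new_site_set(rep(chrom, length(pos)), pos,
                                     rep("A", length(pos)), rep("T", length(pos)),
                                     chrom_length = chrom_length)
  haplopaint:::new_haplotype_set(sites, ids, alleles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write VCF body lines with a minimal header; returns the path
write_vcf_text <- function(records, samples, path = tempfile(fileext = ".vcf"),
                           format = "GT") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    "##contig=<ID=chr15,length=2000000>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(pos, ref, alt, gts, format = "GT") {
  paste(c("chr15", pos, ".", ref, alt, ".", "PASS", ".", format, gts),
        collapse = "\t")
}

# one-sided rank-sum p-value by full enumeration of C(n1+n2, n1) group
# assignments: P(rank-sum of x <= observed) under the null
enumerate_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n1 + n2, n1)
  stats <- colSums(matrix(r[combos], nrow = n1))
  mean(stats <= obs)
}

# per-window population statistics by naive per-pair looping with
# hap_distance (independent of the matrix implementation)
naive_window_stats <- function(alleles, idx1, idx2) {
  pairs_mean <- function(ii, jj = NULL) {
    vals <- c()
    if (is.null(jj)) {
      cmb <- utils::combn(ii, 2)
      for (k in seq_len(ncol(cmb))) {
        vals <- c(vals, hap_distance(alleles[cmb[1, k], ], alleles[cmb[2, k], ]))
      }
    } else {
      for (i in ii) for (j in jj) {
        vals <- c(vals, hap_distance(alleles[i, ], alleles[j, ]))
      }
    }
    mean(vals, na.rm = TRUE)
  }
  sums <- function(ii, jj = NULL) {
    d <- 0; k <- 0
    sets <- if (is.null(jj)) utils::combn(ii, 2) else
      as.matrix(expand.grid(ii, jj))
    if (is.null(jj)) sets <- t(sets) else sets <- as.matrix(sets)
    for (r in seq_len(nrow(sets))) {
      a <- alleles[sets[r, 1], ]; b <- alleles[sets[r, 2], ]
      ok <- !is.na(a) & !is.na(b)
      d <- d + sum(a[ok] != b[ok]); k <- k + sum(ok)
    }
    c(d, k)
  }
  pi1 <- pairs_mean(idx1); pi2 <- pairs_mean(idx2)
  dxy <- pairs_mean(idx1, idx2)
  w1 <- sums(idx1); w2 <- sums(idx2); b <- sums(idx1, idx2)
  hw <- mean(c(w1[1] / w1[2], w2[1] / w2[2]))
  hb <- b[1] / b[2]
  list(pi1 = pi1, pi2 = pi2, dxy = dxy, da = dxy - (pi1 + pi2) / 2,
       fst = 1 - hw / hb)
}
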