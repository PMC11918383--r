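# Containers and readers/writers for the formats the pipeline touches.
#
# A `site_set` is a tibble (chrom, pos, ref, alt): biallelic SNPs on one
# chromosome, positions strictly increasing, 1-based. A `diploid_set` bundles
# the sites with per-sample allele matrices; a `haplotype_set` holds the split
# phased haplotypes. Matrices are samples/haplotypes x sites, alleles coded
# 0/1 with NA for missing.

new_site_set <- function(chrom, pos, ref, alt, chrom_length = NULL) {
  stopifnot(length(pos) == length(ref), length(ref) == length(alt))
  if (is.unsorted(pos, strictly = TRUE)) {
    abort("site positions must be strictly increasing")
  }
  s <- tibble(chrom = chrom, pos = as.integer(pos),
              ref = as.character(ref), alt = as.character(alt))
  attr(s, "chrom_length") <- chrom_length
  s
}

new_diploid_set <- function(sites, sample_ids, a1, a2, phased,
                            dp = NULL, gq = NULL, haploid = NULL) {
  n <- length(sample_ids)
  m <- nrow(sites)
  for (mm in list(a1, a2, phased)) stopifnot(nrow(mm) == n, ncol(mm) == m)
  if (is.null(haploid)) haploid <- rep(FALSE, n)
  structure(
    list(sites = sites, sample_ids = sample_ids,
         a1 = a1, a2 = a2, phased = phased,
         dp = dp, gq = gq, haploid = haploid),
    class = "diploid_set")
}

#' @export
print.diploid_set <- function(x, ...) {
  cat(sprintf("<diploid_set> %d samples x %d sites on %s\n",
              length(x$sample_ids), nrow(x$sites),
              if (nrow(x$sites)) x$sites$chrom[1] else "?"))
  cat(sprintf("  missing genotypes: %.1f%%; DP/GQ: %s\n",
              100 * mean(is.na(x$a1)),
              if (is.null(x$dp) && is.null(x$gq)) "absent" else "present"))
  invisible(x)
}

new_haplotype_set <- function(sites, haplotype_ids, alleles, haploid = NULL) {
  stopifnot(nrow(alleles) == length(haplotype_ids), ncol(alleles) == nrow(sites))
  rownames(alleles) <- haplotype_ids
  structure(list(sites = sites, haplotype_ids = haplotype_ids,
                 alleles = alleles,
                 haploid = haploid %||% rep(FALSE, length(haplotype_ids))),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes x %d sites\n",
              length(x$haplotype_ids), nrow(x$sites)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read phased genotypes from a VCF file
#'
#' Reads a VCF 4.x file into a `diploid_set`. Only biallelic SNP records are
#' kept; multiallelic or indel records are skipped with a message giving the
#' count. The phased flag is taken from the `|` vs `/` genotype separator,
#' and `DP`/`GQ` FORMAT fields are captured when present. Haploid genotype
#' calls (a single allele, e.g. the W-linked chromosome of a female) are
#' supported and flagged. Half-called genotypes such as `0|.` are treated as
#' fully missing.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file with a GT
#'   FORMAT field.
#' @param region optional `"chrom:start-end"` string; only records with
#'   `start <= POS <= end` (1-based inclusive) on that chromosome are kept.
#'   A region containing no records yields empty sets, not an error.
#' @return a `diploid_set`; its `$sites` element is the site tibble
#'   (chrom, pos, ref, alt).
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(VariantAnnotation::ref(v))
  altl <- VariantAnnotation::alt(v)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  snp <- n_alt == 1 & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1 &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0) {
    inform(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", n_skip))
  }
  keep <- which(snp)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) abort("region must be 'chrom:start-end'")
    keep <- keep[chrom[keep] == m[2] &
                   pos[keep] >= as.integer(m[3]) & pos[keep] <= as.integer(m[4])]
  }
  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) abort("VCF has no GT FORMAT field")
  samples <- colnames(gt)
  gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt1 <- alt1[keep]
  if (length(keep) > 1 && length(unique(chrom)) > 1) {
    abort("read_vcf handles one chromosome per call; use `region`")
  }
  sites <- new_site_set(chrom = if (length(keep)) chrom else character(0),
                        pos = pos, ref = ref, alt = alt1)

  n <- length(samples); m <- length(keep)
  a1 <- matrix(NA_integer_, n, m); a2 <- matrix(NA_integer_, n, m)
  phased <- matrix(FALSE, n, m)
  haploid_gt <- matrix(FALSE, n, m)
  if (m > 0) {
    ok_dip <- grepl("^[01.][|/][01.]$", gt)
    ok_hap <- grepl("^[01.]$", gt)
    bad <- !(ok_dip | ok_hap)
    if (any(bad)) {
      idx <- which(bad)[1]                 # gt is variants x samples
      vi <- (idx - 1L) %% m + 1L
      si <- (idx - 1L) %/% m + 1L
      abort(sprintf(
        "malformed GT '%s' for sample %s at %s:%d (record %d)",
        gt[vi, si], samples[si], chrom[vi], pos[vi], vi),
        class = "haplopaint_parse_error")
    }
    # gt is variants x samples; fill transposed
    left <- substr(gt, 1, 1)
    sep <- substr(gt, 2, 2)
    right <- substr(gt, 3, 3)
    to_allele <- function(ch) ifelse(ch == ".", NA_integer_,
                                     as.integer(ch == "1"))
    l <- to_allele(left); r <- to_allele(right)
    hap <- sep == ""                       # haploid call
    half <- !hap & (is.na(l) != is.na(r))  # half-called -> fully missing
    l[half] <- NA_integer_; r[half] <- NA_integer_
    r[hap] <- NA_integer_
    ph <- !hap & sep == "|" & !is.na(l)
    ph[hap & !is.na(l)] <- TRUE
    a1[] <- t(matrix(l, m, n)); a2[] <- t(matrix(r, m, n))
    phased[] <- t(matrix(ph, m, n))
    haploid_gt[] <- t(matrix(hap, m, n))
  }
  haploid <- apply(haploid_gt, 1, function(z) length(z) > 0 && all(z))
  dp <- VariantAnnotation::geno(v)$DP
  gqm <- VariantAnnotation::geno(v)$GQ
  tr <- function(x) {
    if (is.null(x)) return(NULL)
    x <- x[keep, , drop = FALSE]
    if (all(is.na(x))) return(NULL)   # field declared but never populated
    storage.mode(x) <- "integer"
    unname(t(x))
  }
  new_diploid_set(sites, samples, a1, a2, phased,
                  dp = tr(dp), gq = tr(gqm), haploid = haploid)
}

#' Write a `diploid_set` to a VCF file
#'
#' Emits a minimal, valid VCF 4.2 with GT (and DP/GQ when present). The header
#' records the coordinate convention. `read_vcf(write_vcf(x))` preserves
#' positions, alleles and phased GT exactly.
#'
#' @param d a `diploid_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(d, path) {
  s <- d$sites
  chrom <- if (nrow(s)) s$chrom[1] else "chr"
  clen <- attr(s, "chrom_length") %||% (if (nrow(s)) max(s$pos) else 1L)
  fmt_fields <- c("GT",
                  if (!is.null(d$dp)) "DP",
                  if (!is.null(d$gq)) "GQ")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=haplopaint %s", as.character(utils::packageVersion("haplopaint"))),
    sprintf("##coordinates=%s", coord_convention),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(d$dp)) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (!is.null(d$gq)) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    sprintf("##contig=<ID=%s,length=%d>", chrom, as.integer(clen)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", d$sample_ids), collapse = "\t"))
  code <- function(a) ifelse(is.na(a), ".", as.character(a))
  lines <- character(nrow(s))
  for (j in seq_len(nrow(s))) {
    gts <- character(length(d$sample_ids))
    for (i in seq_along(d$sample_ids)) {
      if (d$haploid[i]) {
        gts[i] <- code(d$a1[i, j])
      } else {
        sep <- if (d$phased[i, j] || is.na(d$a1[i, j])) "|" else "/"
        if (is.na(d$a1[i, j]) && is.na(d$a2[i, j])) sep <- "/"
        gts[i] <- paste0(code(d$a1[i, j]), sep, code(d$a2[i, j]))
      }
      extra <- c(if (!is.null(d$dp)) code(d$dp[i, j]),
                 if (!is.null(d$gq)) code(d$gq[i, j]))
      if (length(extra)) gts[i] <- paste(c(gts[i], extra), collapse = ":")
    }
    lines[j] <- paste(c(s$chrom[j], s$pos[j], ".", s$ref[j], s$alt[j], ".",
                        "PASS", ".", paste(fmt_fields, collapse = ":"), gts),
                      collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Split phased diploid genotypes into haplotypes
#'
#' Haplotype `<sample>_A` takes the left allele of each genotype and
#' `<sample>_B` the right. Missing genotypes become missing in both
#' haplotypes. Haploid samples emit a single `<sample>_A` haplotype, flagged
#' haploid. Any *called* genotype that is unphased is an error.
#'
#' @param d a `diploid_set`.
#' @return a `haplotype_set`.
#' @export
split_haplotypes <- function(d) {
  called <- !is.na(d$a1)
  unph <- called & !d$phased & !matrix(d$haploid, length(d$haploid), ncol(called))
  if (any(unph)) {
    i <- which(unph, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "unphased called genotype: sample %s at %s:%d (phase all genotypes first)",
      d$sample_ids[i[1]], d$sites$chrom[1], d$sites$pos[i[2]]))
  }
  ids <- character(0); rows <- list(); haploid <- logical(0)
  for (i in seq_along(d$sample_ids)) {
    ids <- c(ids, paste0(d$sample_ids[i], "_A"))
    rows <- c(rows, list(d$a1[i, ]))
    haploid <- c(haploid, d$haploid[i])
    if (!d$haploid[i]) {
      ids <- c(ids, paste0(d$sample_ids[i], "_B"))
      rows <- c(rows, list(d$a2[i, ]))
      haploid <- c(haploid, FALSE)
    }
  }
  alleles <- do.call(rbind, rows)
  if (is.null(alleles)) alleles <- matrix(NA_integer_, 0, nrow(d$sites))
  new_haplotype_set(d$sites, ids, alleles, haploid = haploid)
}

#' Re-pair split haplotypes into a diploid set
#'
#' Inverse of [split_haplotypes()] for fully phased data; used mainly to
#' verify round-trips and to apply corrected phase back to genotypes.
#'
#' @param h a `haplotype_set` with `_A`/`_B` haplotype naming.
#' @return a `diploid_set` with all called genotypes phased.
#' @export
pair_haplotypes <- function(h) {
  samp <- sub("_[AB]$", "", h$haplotype_ids)
  sample_ids <- unique(samp)
  n <- length(sample_ids); m <- nrow(h$sites)
  a1 <- matrix(NA_integer_, n, m); a2 <- matrix(NA_integer_, n, m)
  haploid <- logical(n)
  for (i in seq_along(sample_ids)) {
    ia <- match(paste0(sample_ids[i], "_A"), h$haplotype_ids)
    ib <- match(paste0(sample_ids[i], "_B"), h$haplotype_ids)
    a1[i, ] <- h$alleles[ia, ]
    if (!is.na(ib)) a2[i, ] <- h$alleles[ib, ] else haploid[i] <- TRUE
  }
  phased <- !is.na(a1)
  new_diploid_set(h$sites, sample_ids, a1, a2, phased, haploid = haploid)
}

#' Read a populations/panel file
#'
#' Two-column whitespace/tab-delimited text (sample, group); an optional third
#' column restricts a row to one haplotype (`A` or `B`, for haploid cases such
#' as a W-linked haplotype). Samples expand to `<sample>_A` and `<sample>_B`.
#' Duplicate rows within a group are deduplicated silently; a sample listed
#' under two groups is an error.
#'
#' @param path path to the panel file. Lines starting with `#` are ignored.
#' @return a tibble with columns `haplotype_id`, `group`.
#' @export
read_panels <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2 | nf > 3)) {
    abort("panel file must have 2 or 3 columns (sample, group[, haplotype])")
  }
  raw <- tibble(
    sample = vapply(fields, `[`, "", 1),
    group = vapply(fields, `[`, "", 2),
    haplotype = vapply(fields, function(f) {
      if (length(f) >= 3) f[3] else NA_character_
    }, ""))
  dup <- raw %>% distinct(.data$sample, .data$group) %>%
    dplyr::count(.data$sample) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("sample(s) assigned to more than one group: ",
                 paste(dup$sample, collapse = ", ")))
  }
  out <- raw %>%
    distinct() %>%
    mutate(haps = purrr::map2(.data$sample, .data$haplotype, function(s, hp) {
      if (is.na(hp)) paste0(s, c("_A", "_B")) else paste0(s, "_", hp)
    })) %>%
    select("group", "haps") %>%
    tidyr::unnest("haps") %>%
    rename(haplotype_id = "haps") %>%
    distinct() %>%
    select("haplotype_id", "group")
  out
}

#' Bind a panel table to a haplotype set
#'
#' Validates that every panel haplotype exists in `h` and that panels are
#' disjoint; errors otherwise.
#' @param panels tibble (haplotype_id, group), e.g. from [read_panels()].
#' @param h a `haplotype_set`.
#' @return `panels`, invisibly, after validation.
#' @export
bind_panels <- function(panels, h) {
  missing_ids <- setdiff(panels$haplotype_id, h$haplotype_ids)
  if (length(missing_ids) > 0) {
    abort(paste0("panel haplotype(s) not in haplotype set: ",
                 paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  if (anyDuplicated(panels$haplotype_id)) {
    abort("panel haplotype lists must be disjoint")
  }
  invisible(panels)
}

#' Write ancestry tracts to a TSV file
#'
#' Five columns (haplotype_id, chrom, start, end, label), 1-based inclusive
#' coordinates; a header comment records the convention and tool version.
#'
#' @param tracts tibble with those five columns; per-haplotype tracts must be
#'   sorted and non-overlapping.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracts <- function(tracts, path) {
  validate_tracts(tracts)
  writeLines(c(
    sprintf("# haplopaint %s ancestry tracts",
            as.character(utils::packageVersion("haplopaint"))),
    sprintf("# %s", coord_convention),
    paste(c("haplotype_id", "chrom", "start", "end", "label"), collapse = "\t")),
    path)
  readr::write_tsv(tracts[, c("haplotype_id", "chrom", "start", "end", "label")],
                   path, col_names = FALSE, append = TRUE, progress = FALSE)
  invisible(path)
}

#' Read ancestry tracts from a TSV file written by [write_tracts()]
#' @param path input path.
#' @return a tract tibble (haplotype_id, chrom, start, end, label).
#' @export
read_tracts <- function(path) {
  x <- readr::read_tsv(path, comment = "#", col_names = TRUE,
                       col_types = readr::cols(
                         haplotype_id = "c", chrom = "c",
                         start = "i", end = "i", label = "c"),
                       progress = FALSE)
  validate_tracts(x)
  x
}

validate_tracts <- function(tracts) {
  stopifnot(all(c("haplotype_id", "chrom", "start", "end", "label") %in% names(tracts)))
  if (any(tracts$start > tracts$end)) abort("tract with start > end")
  bad <- tracts %>%
    arrange(.data$haplotype_id, .data$start) %>%
    group_by(.data$haplotype_id) %>%
    summarise(ov = any(.data$start[-1] <= .data$end[-dplyr::n()]),
              .groups = "drop") %>%
    filter(!is.na(.data$ov), .data$ov)
  if (nrow(bad) > 0) {
    abort(paste0("overlapping tracts for haplotype(s): ",
                 paste(bad$haplotype_id, collapse = ", ")))
  }
  invisible(tracts)
}

#' Construct a supergene module map
#'
#' Named, non-overlapping 1-based inclusive intervals describing the
#' rearranged modules of a supergene, with `masked = TRUE` marking regions
#' (such as a copy-number-variable tract) that cannot be genotyped and carry
#' no SNPs.
#'
#' @param module character labels.
#' @param start,end 1-based inclusive bounds, `start < end`.
#' @param masked logical, default all `FALSE`.
#' @return a tibble (module, start, end, masked).
#' @export
module_map <- function(module, start, end, masked = FALSE) {
  m <- tibble(module = as.character(module), start = as.integer(start),
              end = as.integer(end),
              masked = rep_len(masked, length(module))) %>%
    arrange(.data$start)
  if (any(m$start >= m$end)) abort("module intervals need start < end")
  if (nrow(m) > 1 && any(m$start[-1] <= m$end[-nrow(m)])) {
    abort("module intervals must not overlap")
  }
  m
}

#' Default synthetic supergene module map
#'
#' A stand-in layout on a 6 Mb chromosome mirroring a modular supergene:
#' four single-copy rearranged modules of 1.3, 0.9, 1.6 and 0.5 Mb named
#' `"1.1"`, `"1.2"`, `"2"` and `"4"`, separated by 100 kb collinear gaps, plus
#' a masked 0.8 Mb copy-number-variable region between modules 2 and 4 that
#' carries no usable SNPs.
#'
#' @return a module map tibble (see [module_map()]).
#' @export
default_module_map <- function() {
  module_map(
    module = c("1.1", "1.2", "2", "CNV", "4"),
    start = c(200001L, 1600001L, 2600001L, 4200001L, 5000001L),
    end   = c(1500000L, 2500000L, 4200000L, 5000000L, 5500000L),
    masked = c(FALSE, FALSE, FALSE, TRUE, FALSE))
}

#' Read / write a module map as JSON
#' @param path file path.
#' @rdname module_map_io
#' @return `read_module_map()` returns the module map tibble;
#'   `write_module_map()` returns `path` invisibly.
#' @export
read_module_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  module_map(x$modules$module, x$modules$start, x$modules$end, x$modules$masked)
}

#' @param m a module map tibble.
#' @rdname module_map_io
#' @export
write_module_map <- function(m, path) {
  jsonlite::write_json(
    list(coordinates = coord_convention, modules = m),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
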