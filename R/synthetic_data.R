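# Balding-Nichols style cohort simulator. Divergent haplotype groups are
# modelled as populations with beta-distributed allele frequencies around a
# shared ancestral frequency; the differentiation parameter F of each group
# equals the expected FST between groups (Hudson's estimator). Recombinant
# mosaic haplotypes draw each site from the frequency of the group owning its
# tract, so planted breakpoints are exact. This frequency model (rather than
# a coalescent) gives closed-form expectations and exact truth tables for the
# painter, phase corrector and statistics under test.

#' Specify a recombinant mosaic haplotype
#'
#' @param labels group labels, left to right along the chromosome.
#' @param ends 1-based inclusive end position of each tract; increasing, the
#'   last equal to the chromosome length.
#' @return a mosaic spec tibble (label, end) for use in a
#'   [sim_config()] cohort.
#' @export
mosaic <- function(labels, ends) {
  stopifnot(length(labels) == length(ends))
  if (is.unsorted(ends, strictly = TRUE)) abort("mosaic ends must be increasing")
  tibble(label = as.character(labels), end = as.integer(ends))
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale stand-in for one supergene-bearing
#' chromosome arm: 2 Mb, 20,000 SNPs, two haplotype groups at moderate
#' differentiation (F = 0.2) with 20 reference-panel haplotypes each, no
#' recombinants, no masked region, and clean data (no missing genotypes or
#' switch errors). Tune `groups`, `cohort`, `switch_errors`, `missing_rate`
#' and `modules` to plant structure.
#'
#' @param seed integer seed; the whole run uses one stream, so identical
#'   seed and config give byte-identical output.
#' @param chrom_length chromosome length in bp.
#' @param n_sites number of SNP sites to place (uniformly, excluding masked
#'   module intervals).
#' @param groups tibble (label, f, n_panel): per group, the Balding-Nichols
#'   differentiation parameter `f` in \[0, 1) and an even number of pure
#'   panel haplotypes.
#' @param cohort tibble (sample, hap_a, hap_b); `hap_a`/`hap_b` are
#'   list-columns whose elements are either a group label (pure haplotype)
#'   or a [mosaic()] spec. `NULL` for no cohort samples.
#' @param switch_errors tibble (sample, pos): planted phase-switch positions,
#'   or `NULL`.
#' @param missing_rate per-genotype missingness probability.
#' @param modules optional module map; masked intervals carry no sites.
#' @param chrom chromosome name.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, chrom_length = 2e6, n_sites = 20000L,
                       groups = tibble(label = c("grpA", "grpB"),
                                       f = 0.2, n_panel = 20L),
                       cohort = NULL, switch_errors = NULL,
                       missing_rate = 0, modules = NULL, chrom = "chr15") {
  stopifnot(all(groups$f >= 0), all(groups$f < 1))
  if (any(groups$n_panel %% 2 != 0)) {
    abort("n_panel must be even (panel haplotypes are emitted as diploids)")
  }
  structure(list(seed = as.integer(seed), chrom_length = as.integer(chrom_length),
                 n_sites = as.integer(n_sites), groups = groups,
                 cohort = cohort, switch_errors = switch_errors,
                 missing_rate = missing_rate, modules = modules,
                 chrom = chrom),
            class = "sim_config")
}

# draw n distinct sorted positions uniformly from [1, L] excluding masked
# module intervals
draw_positions <- function(n, L, modules) {
  masked <- if (!is.null(modules)) modules[modules$masked, , drop = FALSE] else NULL
  if (is.null(masked) || nrow(masked) == 0) {
    if (n > L) abort("n_sites exceeds available positions")
    return(sort(sample.int(L, n)))
  }
  gap_len <- masked$end - masked$start + 1L
  avail <- L - sum(gap_len)
  if (n > avail) abort("n_sites exceeds available positions")
  raw <- sort(sample.int(avail, n))
  # shift draws past each gap
  for (g in order(masked$start)) {
    at_or_after <- raw >= masked$start[order(masked$start)][g]
    raw[at_or_after] <- raw[at_or_after] + gap_len[order(masked$start)][g]
  }
  raw
}

#' Simulate a phased cohort with planted ancestry structure
#'
#' Site positions are sorted distinct uniform draws over the chromosome,
#' excluding masked module intervals (e.g. a copy-number-variable region that
#' cannot be genotyped). Each site gets an ancestral frequency
#' `p ~ Uniform(0.05, 0.95)`; each group's frequency is
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` (exactly `p` when `F = 0`). Panel
#' haplotypes are pure-group Bernoulli draws; cohort haplotypes draw each
#' site from the frequency of the group owning its tract. Phase-switch
#' errors and missing genotypes are then injected per config. Truth tables
#' record every planted tract, switch position and group frequency.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_cohort` list: `genos` (a phased `diploid_set` of panel +
#'   cohort samples), `sites`, `panels` (tibble haplotype_id, group covering
#'   the panel haplotypes), and `truth` (list: `tracts` per-haplotype true
#'   ancestry tibble, `switches` tibble (sample, pos), `freqs` group x site
#'   frequency matrix).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$chrom_length
  pos <- draw_positions(cfg$n_sites, L, cfg$modules)
  m <- length(pos)
  p_anc <- runif(m, 0.05, 0.95)
  glabs <- cfg$groups$label
  freqs <- matrix(NA_real_, length(glabs), m, dimnames = list(glabs, NULL))
  for (i in seq_along(glabs)) {
    f <- cfg$groups$f[i]
    freqs[i, ] <- if (f == 0) p_anc else
      rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }

  hap_rows <- list(); hap_ids <- character(0); truth_rows <- list()
  draw_pure <- function(g) rbinom(m, 1L, freqs[g, ])
  draw_spec <- function(spec) {
    if (is.character(spec)) {
      list(alleles = draw_pure(spec),
           tracts = tibble(start = 1L, end = L, label = spec))
    } else {
      starts <- c(1L, utils::head(spec$end, -1) + 1L)
      if (spec$end[nrow(spec)] != L) {
        abort("mosaic spec must end at chrom_length")
      }
      owner <- spec$label[findInterval(pos, c(0L, spec$end), left.open = TRUE)]
      al <- integer(m)
      for (g in unique(spec$label)) {
        sel <- owner == g
        al[sel] <- rbinom(sum(sel), 1L, freqs[g, sel])
      }
      list(alleles = al,
           tracts = tibble(start = starts, end = spec$end, label = spec$label))
    }
  }

  # panel samples first, in group order
  panel_rows <- list()
  for (i in seq_along(glabs)) {
    g <- glabs[i]
    n_samp <- cfg$groups$n_panel[i] / 2
    for (k in seq_len(n_samp)) {
      sid <- sprintf("%s_p%02d", g, k)
      for (suffix in c("_A", "_B")) {
        hid <- paste0(sid, suffix)
        hap_ids <- c(hap_ids, hid)
        hap_rows[[hid]] <- draw_pure(g)
        truth_rows[[hid]] <- tibble(haplotype_id = hid, chrom = cfg$chrom,
                                    start = 1L, end = L, label = g)
        panel_rows[[hid]] <- tibble(haplotype_id = hid, group = g)
      }
    }
  }
  # cohort samples
  if (!is.null(cfg$cohort)) {
    for (r in seq_len(nrow(cfg$cohort))) {
      sid <- cfg$cohort$sample[r]
      for (side in c("a", "b")) {
        spec <- cfg$cohort[[paste0("hap_", side)]][[r]]
        hid <- paste0(sid, if (side == "a") "_A" else "_B")
        d <- draw_spec(spec)
        hap_ids <- c(hap_ids, hid)
        hap_rows[[hid]] <- d$alleles
        truth_rows[[hid]] <- d$tracts %>%
          mutate(haplotype_id = hid, chrom = cfg$chrom, .before = 1)
      }
    }
  }

  alleles <- do.call(rbind, hap_rows[hap_ids])
  sites <- new_site_set(rep(cfg$chrom, m), pos,
                        ref = rep("A", m), alt = rep("T", m),
                        chrom_length = L)
  h <- new_haplotype_set(sites, hap_ids, alleles)
  genos <- pair_haplotypes(h)

  switches <- tibble(sample = character(0), pos = integer(0))
  if (!is.null(cfg$switch_errors) && nrow(cfg$switch_errors) > 0) {
    sw <- inject_phase_switch_errors(genos, cfg$switch_errors, seed = NULL)
    genos <- sw$genos
    switches <- sw$switches
  }
  if (cfg$missing_rate > 0) {
    genos <- inject_missing(genos, cfg$missing_rate, seed = NULL)
  }

  structure(list(
    genos = genos, sites = sites,
    panels = bind_rows(panel_rows),
    truth = list(tracts = bind_rows(truth_rows), switches = switches,
                 freqs = freqs),
    config = cfg),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d samples x %d sites; groups: %s; %d planted switch(es)\n",
              length(x$genos$sample_ids), nrow(x$sites),
              paste(x$config$groups$label, collapse = ", "),
              nrow(x$truth$switches)))
  invisible(x)
}

#' Inject classic phase-switch errors
#'
#' A switch at position `p` exchanges the A/B assignment of all alleles at
#' sites with position `> p`; two switches in one sample restore the original
#' phase downstream of the second.
#'
#' @param d a phased `diploid_set`.
#' @param plan tibble (sample, pos) of switch positions; positions must lie
#'   within the chromosome.
#' @param seed optional seed (the operation itself is deterministic; the
#'   argument exists so callers can pin a stream before related draws).
#'   `NULL` leaves the RNG state untouched.
#' @return list with `genos` (the modified `diploid_set`) and `switches`
#'   (the plan, sorted per sample).
#' @export
inject_phase_switch_errors <- function(d, plan, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- attr(d$sites, "chrom_length") %||% max(d$sites$pos)
  if (any(plan$pos < 1 | plan$pos > L)) {
    abort("switch position outside chromosome")
  }
  unknown <- setdiff(plan$sample, d$sample_ids)
  if (length(unknown)) {
    abort(paste0("switch plan names unknown sample(s): ",
                 paste(unknown, collapse = ", ")))
  }
  plan <- plan %>% arrange(.data$sample, .data$pos)
  for (r in seq_len(nrow(plan))) {
    i <- match(plan$sample[r], d$sample_ids)
    sel <- d$sites$pos > plan$pos[r]
    tmp <- d$a1[i, sel]
    d$a1[i, sel] <- d$a2[i, sel]
    d$a2[i, sel] <- tmp
  }
  list(genos = d, switches = plan)
}

#' Set genotypes missing at random
#'
#' Each genotype is independently set to missing with probability `rate`.
#'
#' @param d a `diploid_set`.
#' @param rate missingness probability in \[0, 1\].
#' @param seed optional seed; `NULL` continues the current stream.
#' @return the modified `diploid_set`.
#' @export
inject_missing <- function(d, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(d)
  drop <- matrix(runif(length(d$a1)) < rate,
                 nrow(d$a1), ncol(d$a1))
  d$a1[drop] <- NA_integer_
  d$a2[drop] <- NA_integer_
  d$phased[drop] <- FALSE
  d
}
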