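# Heuristic repair of statistical-phasing switch errors at the level of
# ancestry labels. A switch error exchanges the maternal/paternal assignment
# of everything downstream of a point, so a heterozygous individual carrying
# two common intact haplotypes can be painted as two reciprocal mosaics
# (e.g. c-c-c-k / k-k-k-c). The corrector greedily swaps tract labels between
# an individual's two haplotypes wherever doing so makes them more similar to
# the most similar haplotypes in the rest of the cohort, thereby minimising
# spurious inferred recombination.

#' Build the atomic interval partition and label matrix for a painted set
#'
#' The atomic partition is the union of all tract boundaries across all
#' haplotypes: ordered intervals covering the painted span within which every
#' haplotype's label is constant. Regions of a haplotype not covered by any
#' tract are labelled `UNDEFINED`.
#'
#' @param p a `painted_set`, or a tract tibble
#'   (haplotype_id, chrom, start, end, label).
#' @return a `label_matrix`: list with `labels` (character matrix,
#'   haplotypes x intervals), `intervals` (tibble start, end, length),
#'   `sample_of` (sample id per haplotype row) and `chrom`.
#' @export
build_label_matrix <- function(p) {
  tracts <- if (inherits(p, "painted_set")) p$tracts else p
  validate_tracts(tracts)
  haps <- unique(tracts$haplotype_id)
  cuts <- sort(unique(c(tracts$start, tracts$end + 1L)))
  span_lo <- min(tracts$start); span_hi <- max(tracts$end)
  cuts <- cuts[cuts >= span_lo & cuts <= span_hi + 1L]
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1] - 1L
  keep <- ends >= starts
  starts <- starts[keep]; ends <- ends[keep]
  intervals <- tibble(start = starts, end = ends,
                      length = ends - starts + 1)
  labels <- matrix(UNDEFINED_LABEL, length(haps), nrow(intervals),
                   dimnames = list(haps, NULL))
  for (r in seq_len(nrow(tracts))) {
    cover <- starts >= tracts$start[r] & ends <= tracts$end[r]
    labels[tracts$haplotype_id[r], cover] <- tracts$label[r]
  }
  structure(list(labels = labels, intervals = intervals,
                 sample_of = sub("_[AB]$", "", haps),
                 chrom = tracts$chrom[1]),
            class = "label_matrix")
}

#' Length-weighted similarity of two label vectors
#'
#' The fraction of interval length on which the labels agree, over intervals
#' where both labels are defined (not `UNDEFINED`), restricted to
#' `interval_range`. Returns 0 when no such interval exists.
#'
#' @param a,b character label vectors over the atomic partition.
#' @param lengths interval lengths in bp.
#' @param interval_range indices of the intervals to consider (default all).
#' @return a proportion in \[0, 1\].
#' @export
pair_similarity <- function(a, b, lengths, interval_range = seq_along(a)) {
  a <- a[interval_range]; b <- b[interval_range]
  w <- lengths[interval_range]
  ok <- a != UNDEFINED_LABEL & b != UNDEFINED_LABEL
  denom <- sum(w[ok])
  if (denom == 0) return(0)
  sum(w[ok & a == b]) / denom
}

# mean of the top-3 similarities of haplotype row `i` against all rows except
# `exclude`, over the given interval range
top3_similarity <- function(labels, lengths, i, exclude, interval_range) {
  others <- setdiff(seq_len(nrow(labels)), exclude)
  a <- labels[i, interval_range, drop = TRUE]
  w <- lengths[interval_range]
  a_def <- a != UNDEFINED_LABEL
  O <- labels[others, interval_range, drop = FALSE]
  def <- O != UNDEFINED_LABEL
  def <- sweep(def, 2, a_def, `&`)
  eq <- def & sweep(O, 2, a, `==`)
  denom <- as.vector(def %*% w)
  num <- as.vector(eq %*% w)
  sims <- ifelse(denom > 0, num / denom, 0)
  k <- min(3L, length(sims))
  mean(sort(sims, decreasing = TRUE)[seq_len(k)])
}

#' Correct phase-switch errors by greedy tract-label swapping
#'
#' For each individual in input order, each atomic interval is visited
#' left-to-right and the labels of the individual's two haplotypes at that
#' interval are tentatively exchanged. The objective is the sum, over the two
#' haplotypes, of the mean similarity to the three most similar other
#' haplotypes in the cohort (the individual's own partner haplotype
#' excluded), evaluated over all intervals up to and including the focal one.
#' The swap is kept only if the objective strictly increases. A right-to-left
#' pass follows, with the objective evaluated from the focal interval to the
#' end. One iteration is both passes over all individuals; iteration stops
#' after `max_iter` rounds or as soon as a full iteration accepts no swap.
#' Comparisons always use the current (already partially corrected) state of
#' the cohort, so the procedure is deterministic for a fixed input order.
#'
#' @param m a `label_matrix` from [build_label_matrix()].
#' @param max_iter maximum number of full iterations. 500 suits the coarse
#'   window painter (few intervals); 20 is typical for denser HMM paintings.
#' @return a `phase_correction` object: list with `labels` (the corrected
#'   `label_matrix`), `log` (tibble iteration, pass, sample, interval, start,
#'   end — replaying it on the input reproduces the output), `iterations`
#'   performed, and `converged`.
#' @export
phasepaint_correct <- function(m, max_iter = 500L) {
  stopifnot(inherits(m, "label_matrix"))
  labels <- m$labels
  if (nrow(labels) < 4) {
    abort("phasepaint_correct needs at least 4 haplotypes (top-3 similarity)")
  }
  lengths <- m$intervals$length
  K <- ncol(labels)
  samples <- unique(m$sample_of)
  pair_rows <- lapply(samples, function(s) which(m$sample_of == s))
  names(pair_rows) <- samples
  log_rows <- list()
  iterations <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    any_swap <- FALSE
    for (pass in c("left_to_right", "right_to_left")) {
      focal_order <- if (pass == "left_to_right") seq_len(K) else rev(seq_len(K))
      for (s in samples) {
        rows <- pair_rows[[s]]
        if (length(rows) != 2) next   # haploid samples carry no phase
        for (j in focal_order) {
          region <- if (pass == "left_to_right") 1:j else j:K
          if (labels[rows[1], j] == labels[rows[2], j]) next  # swap is a no-op
          obj0 <- top3_similarity(labels, lengths, rows[1], rows, region) +
            top3_similarity(labels, lengths, rows[2], rows, region)
          tmp <- labels[rows[1], j]
          labels[rows[1], j] <- labels[rows[2], j]
          labels[rows[2], j] <- tmp
          obj1 <- top3_similarity(labels, lengths, rows[1], rows, region) +
            top3_similarity(labels, lengths, rows[2], rows, region)
          if (obj1 > obj0) {
            any_swap <- TRUE
            log_rows[[length(log_rows) + 1L]] <- tibble(
              iteration = iter, pass = pass, sample = s, interval = j,
              start = m$intervals$start[j], end = m$intervals$end[j])
          } else {
            tmp <- labels[rows[1], j]
            labels[rows[1], j] <- labels[rows[2], j]
            labels[rows[2], j] <- tmp
          }
        }
      }
    }
    if (!any_swap) { converged <- TRUE; break }
  }
  out <- m
  out$labels <- labels
  structure(list(labels = out,
                 log = if (length(log_rows)) bind_rows(log_rows) else
                   tibble(iteration = integer(0), pass = character(0),
                          sample = character(0), interval = integer(0),
                          start = integer(0), end = integer(0)),
                 iterations = iterations, converged = converged),
            class = "phase_correction")
}

#' Replay a switch log on a label matrix
#'
#' Applies the recorded swaps in order; replaying the log of a
#' [phasepaint_correct()] run on its input reproduces its output exactly.
#'
#' @param m a `label_matrix`.
#' @param log a switch-log tibble as produced by [phasepaint_correct()].
#' @return the `label_matrix` after all swaps.
#' @export
apply_switch_log <- function(m, log) {
  for (r in seq_len(nrow(log))) {
    rows <- which(m$sample_of == log$sample[r])
    j <- log$interval[r]
    tmp <- m$labels[rows[1], j]
    m$labels[rows[1], j] <- m$labels[rows[2], j]
    m$labels[rows[2], j] <- tmp
  }
  m
}

#' Convert a label matrix back to a tract tibble
#'
#' Merges runs of equal labels per haplotype into 1-based inclusive tracts.
#'
#' @param m a `label_matrix`.
#' @return a tract tibble (haplotype_id, chrom, start, end, label).
#' @export
label_matrix_to_tracts <- function(m) {
  haps <- rownames(m$labels)
  out <- lapply(haps, function(h) {
    lab <- m$labels[h, ]
    r <- rle(lab)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    tibble(haplotype_id = h, chrom = m$chrom,
           start = m$intervals$start[idx_start],
           end = m$intervals$end[idx_end],
           label = r$values)
  })
  bind_rows(out)
}

#' @export
print.phase_correction <- function(x, ...) {
  cat(sprintf("<phase_correction> %d swap(s) in %d iteration(s); %s\n",
              nrow(x$log), x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @describeIn phasepaint_correct tidy method: the switch log.
#' @param x a `phase_correction`.
#' @param ... unused.
#' @export
tidy.phase_correction <- function(x, ...) x$log

#' @describeIn phasepaint_correct glance method: one-row summary.
#' @export
glance.phase_correction <- function(x, ...) {
  tibble(n_swaps = nrow(x$log), iterations = x$iterations,
         converged = x$converged)
}
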