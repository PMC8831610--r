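# Intron-retention (PIR) and detained-intron statistics across cellular
# fractions, plus U(T)-rich / G-rich intronic-splicing-enhancer window
# counting and a chi-squared enrichment contrast.

#' Boundary-spanning and spliced read counts for one intron
#'
#' `i1`/`i2` count continuous (match-block) reads crossing the 5'/3' intron
#' boundary by at least `min_overhang` nt on each side (strand-aware: on the
#' minus strand the 5' boundary is the right-hand one); `e` counts gapped
#' reads whose skip equals the intron exactly; `o` counts gapped reads whose
#' skip overlaps the intron with different coordinates.
#'
#' @param alns data.frame from [read_sam()] (one sample).
#' @param chrom,start,end,strand the intron (1-based closed).
#' @param min_overhang nt required on each side of a boundary.
#' @return named integer vector `c(i1, i2, e, o)`.
#' @export
intron_boundary_counts <- function(alns, chrom, start, end, strand = "+",
                                   min_overhang = 4L) {
  i1 <- i2 <- e <- o <- 0L
  alns <- alns[alns$chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(alns))) {
    ops <- parse_cigar(alns$cigar[r])
    blocks <- cigar_ref_blocks(alns$pos[r], ops)
    if (nrow(blocks) == 0L) next
    # boundary crossings by a continuous block
    left_cross <- any(blocks[, "start"] <= start - min_overhang &
                        blocks[, "end"] >= start + min_overhang - 1L)
    right_cross <- any(blocks[, "start"] <= end - min_overhang + 1L &
                         blocks[, "end"] >= end + min_overhang)
    if (left_cross) { if (strand == "-") i2 <- i2 + 1L else i1 <- i1 + 1L }
    if (right_cross) { if (strand == "-") i1 <- i1 + 1L else i2 <- i2 + 1L }
    # gapped reads: N skips between consecutive blocks; the 4-nt rule
    # applies to these junction reads too (blocks adjoining the gap)
    if (nrow(blocks) >= 2L) {
      gs <- blocks[-nrow(blocks), "end"] + 1L
      ge <- blocks[-1L, "start"] - 1L
      bw <- blocks[, "end"] - blocks[, "start"] + 1L
      for (k in seq_along(gs)) {
        if (bw[k] < min_overhang || bw[k + 1L] < min_overhang) next
        if (gs[k] == start && ge[k] == end) e <- e + 1L
        else if (gs[k] <= end && ge[k] >= start) o <- o + 1L
      }
    }
  }
  c(i1 = i1, i2 = i2, e = e, o = o)
}

#' Percentage of intron retention
#'
#' PIR = 100 (i1 + i2) / (i1 + i2 + 2e + 2o); `NA` when the total junction
#' read count is below `min_reads`. By default the total is i1 + i2 + e + o
#' (single-count); set `double_count_spliced = TRUE` to count e and o twice
#' in the NA rule.
#'
#' @param i1,i2,e,o read counts (see [intron_boundary_counts()]).
#' @param min_reads NA threshold on the total junction reads.
#' @param double_count_spliced count e/o doubly in the NA-rule total.
#' @return PIR in `[0, 100]`, or `NA`.
#' @export
compute_pir <- function(i1, i2, e, o, min_reads = 10L,
                        double_count_spliced = FALSE) {
  stopifnot(i1 >= 0, i2 >= 0, e >= 0, o >= 0)
  total <- if (double_count_spliced) i1 + i2 + 2 * e + 2 * o else i1 + i2 + e + o
  if (total < min_reads) return(NA_real_)
  100 * (i1 + i2) / (i1 + i2 + 2 * e + 2 * o)
}

#' Unspliced ratio from PIR
#'
#' @param pir PIR value(s) in `[0, 100]`.
#' @return ratio(s) in `[0, 1]`.
#' @export
unspliced_ratio <- function(pir) pir / 100

#' Classify an intron as detained (PTS) or constitutive (CTS)
#'
#' Replicate unspliced ratios are averaged per fraction. Introns with mean
#' cytoplasmic ratio >= `cyto_max` are excluded (not constitutively
#' spliced); otherwise a mean chromatin-bound (CB) ratio > `cb_detained`
#' marks a detained intron requiring post-transcriptional splicing.
#'
#' @param cb_ratios,cyto_ratios numeric vectors of replicate unspliced
#'   ratios (NA replicates dropped).
#' @param cb_detained CB threshold for detention.
#' @param cyto_max constitutive-splicing ceiling in the cytoplasm.
#' @return `"detained_PTS"`, `"constitutive_CTS"` or `"excluded"`.
#' @export
classify_detained <- function(cb_ratios, cyto_ratios,
                              cb_detained = 0.1, cyto_max = 0.2) {
  cyto <- mean(cyto_ratios, na.rm = TRUE)
  cb <- mean(cb_ratios, na.rm = TRUE)
  if (!is.finite(cyto) || cyto >= cyto_max) return("excluded")
  if (is.finite(cb) && cb > cb_detained) "detained_PTS" else "constitutive_CTS"
}

#' U-rich / G-rich window scan of an intron interior
#'
#' The interior excludes 10 nt after the 5' splice site and 10 nt before the
#' 3' splice site. A T-rich (U-rich in RNA) motif is present when some 20-nt
#' window (step 1) has strictly more than 80% T; a G-rich motif when some
#' 10-nt window has strictly more than 80% G.
#'
#' @param intron_seq intron sequence in sense orientation.
#' @return list with `has_t_rich`, `has_g_rich` (both `FALSE`, with a
#'   warning, for introns of 40 nt or less).
#' @export
motif_window_scan <- function(intron_seq) {
  intron_seq <- toupper(intron_seq)
  L <- nchar(intron_seq)
  if (L <= 40L) {
    warning("intron of length ", L, " <= 40 nt; window scan skipped")
    return(list(has_t_rich = FALSE, has_g_rich = FALSE))
  }
  interior <- substr(intron_seq, 11L, L - 10L)
  ch <- strsplit(interior, "")[[1L]]
  has_rich <- function(base, w) {
    n <- length(ch)
    if (n < w) return(FALSE)
    cs <- cumsum(ch == base)
    counts <- cs[w:n] - c(0L, cs)[seq_len(n - w + 1L)]
    any(counts > 0.8 * w)
  }
  list(has_t_rich = has_rich("T", 20L), has_g_rich = has_rich("G", 10L))
}

#' Chi-squared enrichment of a motif between two intron sets
#'
#' Pearson's chi-squared without continuity correction on the 2 x 2
#' presence/absence table (microexon-flanking vs control introns).
#' Degenerate tables (a zero row or column margin) return `NA` statistics.
#'
#' @param me_flags,control_flags logical vectors of motif presence.
#' @return list with `statistic`, `p_value` and `table`.
#' @export
motif_enrichment <- function(me_flags, control_flags) {
  tab <- rbind(me = c(yes = sum(me_flags), no = sum(!me_flags)),
               control = c(yes = sum(control_flags), no = sum(!control_flags)))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(list(statistic = NA_real_, p_value = NA_real_, table = tab))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       table = tab)
}

#' Seeded sampler of control introns
#'
#' Draws `n` introns (rows) from a pool of constitutively spliced introns,
#' for use as the control set in [motif_enrichment()].
#'
#' @param introns data.frame of candidate introns.
#' @param n number to draw (capped at the pool size).
#' @param seed RNG seed.
#' @return row subset of `introns`.
#' @export
sample_control_introns <- function(introns, n = 1000L, seed = 1L) {
  withr::with_seed(seed, {
    idx <- sample.int(nrow(introns), min(n, nrow(introns)))
  })
  introns[sort(idx), , drop = FALSE]
}
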