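# Independent brute-force oracles used across the suite. These re-derive
# expected results from first principles (position vectors, all-substrings
# enumeration, textbook formulas) and deliberately share no code with the
# implementation paths they check.

# Genomic positions covered by a read of length rl starting at spliced
# offset s of an isoform given as an ascending block matrix. Returns the
# maximal runs of consecutive genomic positions (the read's aligned parts).
oracle_read_segments <- function(blocks, s, rl) {
  pos <- unlist(lapply(seq_len(nrow(blocks)), function(k)
    seq.int(blocks[k, "start"], blocks[k, "end"])))
  covered <- pos[s:(s + rl - 1L)]
  runs <- cumsum(c(1L, diff(covered) != 1L))
  lapply(split(covered, runs), range)
}

# TRUE iff the true layout places a 1-15 nt exon fully inside the read with
# >= min_anchor nt on each side and both surrounding gaps within
# intron_range (the semantic definition of a microexon-spanning read).
oracle_is_spanning <- function(blocks, s, rl, min_anchor = 6L,
                               me_range = c(1L, 15L),
                               intron_range = c(20L, 20000L)) {
  segs <- oracle_read_segments(blocks, s, rl)
  n <- length(segs)
  if (n < 3L) return(FALSE)
  for (k in 2L:(n - 1L)) {
    mid <- segs[[k]][2L] - segs[[k]][1L] + 1L
    if (mid < me_range[1L] || mid > me_range[2L]) next
    gap_l <- segs[[k]][1L] - segs[[k - 1L]][2L] - 1L
    gap_r <- segs[[k + 1L]][1L] - segs[[k]][2L] - 1L
    if (gap_l < intron_range[1L] || gap_l > intron_range[2L]) next
    if (gap_r < intron_range[1L] || gap_r > intron_range[2L]) next
    left <- segs[[k - 1L]][2L] - segs[[k - 1L]][1L] + 1L
    right <- segs[[k + 1L]][2L] - segs[[k + 1L]][1L] + 1L
    if (left >= min_anchor && right >= min_anchor) return(TRUE)
  }
  FALSE
}

# all-substrings window oracle for the U-rich / G-rich scan
oracle_window_scan <- function(seq) {
  L <- nchar(seq)
  if (L <= 40L) return(list(has_t_rich = FALSE, has_g_rich = FALSE))
  interior <- substr(seq, 11L, L - 10L)
  count_hit <- function(base, w) {
    n <- nchar(interior)
    if (n < w) return(FALSE)
    for (i in seq_len(n - w + 1L)) {
      win <- substr(interior, i, i + w - 1L)
      cnt <- sum(strsplit(win, "")[[1L]] == base)
      if (cnt / w > 0.8) return(TRUE)
    }
    FALSE
  }
  list(has_t_rich = count_hit("T", 20L), has_g_rich = count_hit("G", 10L))
}

# textbook Pearson chi-squared on a 2x2 table of counts
oracle_pearson_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# brute-force longest ATG-initiated ORF: walk codons from every ATG
oracle_longest_orf <- function(seq, min_len = 30L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- NULL
  atg <- gregexpr("ATG", seq)[[1L]]
  if (atg[1L] == -1L) return(NULL)
  for (a in atg) {
    e <- a - 1L
    repeat {
      if (e + 3L > n) break
      cod <- substr(seq, e + 1L, e + 3L)
      e <- e + 3L
      if (cod %in% c("TAA", "TAG", "TGA")) break
    }
    len <- e - a + 1L
    if (len < min_len) next
    if (is.null(best) || len > best$len) best <- list(start = a, end = e, len = len)
  }
  if (is.null(best)) NULL else list(start = best$start, end = best$end)
}

# independent per-window PWM score via Biostrings (never used in the package
# scanner itself)
oracle_pwm_score <- function(logodds, seq, starts) {
  Biostrings::PWMscoreStartingAt(logodds, Biostrings::DNAString(seq), starts)
}

# small helper: run the read-level discovery pipeline on a fixture
run_discovery <- function(fx, sim = NULL, min_support = 5L) {
  if (is.null(sim)) sim <- simulate_reads(fx)
  tf <- tempfile(fileext = ".sam")
  on.exit(unlink(tf))
  writeLines(sim$sam, tf)
  alns <- read_sam(tf)
  jt <- count_junctions(alns, fx$genome, sample_id = "s1")
  calls <- call_microexons(list(s1 = jt), fx$genome, min_support = min_support)
  compute_psi(calls, list(s1 = jt))
}

# SAM line constructor for hand-built reads
sam_line <- function(qname, chrom, pos, cigar, flag = 0L, mapq = 255L,
                     seq = "*", nh = 1L) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNH:i:%d",
          qname, flag, chrom, pos, mapq, cigar, seq, nh)
}

sam_header <- function(chroms, lens) {
  c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", chroms, lens))
}

read_sam_lines <- function(lines) {
  tf <- tempfile(fileext = ".sam")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  read_sam(tf)
}
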