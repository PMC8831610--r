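# Microexon-spanning read detection from CIGAR strings and per-sample
# junction counting. A spanning read is a uniquely mapped gapped read with at
# least five mapped parts M,N,M,N,M whose middle match block (1-15 nt) lies
# fully on the microexon and extends >= 6 nt into each flanking exon.

#' Parse a CIGAR string
#'
#' `=`/`X` are normalized to `M` and adjacent same-op runs merged.
#'
#' @param cigar CIGAR string, e.g. `"20M100N9M150N21M"`.
#' @return data.frame with columns `op` (character) and `len` (integer).
#' @export
parse_cigar <- function(cigar) {
  stopifnot(is_string(cigar), nzchar(cigar), cigar != "*")
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1L]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("invalid CIGAR: ", cigar)
  len <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  if (any(len == 0L)) stop("zero-length CIGAR op in ", cigar)
  bad <- setdiff(op, c("M", "I", "D", "N", "S", "H", "P", "=", "X"))
  if (length(bad)) stop("unknown CIGAR op '", bad[1L], "' in ", cigar)
  op[op %in% c("=", "X")] <- "M"
  # merge adjacent identical ops after normalization
  r <- rle(op)
  if (any(r$lengths > 1L)) {
    grp <- rep(seq_along(r$lengths), r$lengths)
    len <- as.integer(tapply(len, grp, sum))
    op <- r$values
  }
  data.frame(op = op, len = len, stringsAsFactors = FALSE)
}

# Reference-consuming blocks of an alignment: M runs (D merged into the
# surrounding block, N splits blocks). Returns matrix [start,end] 1-based.
cigar_ref_blocks <- function(pos, ops) {
  starts <- integer(); ends <- integer()
  ref <- pos
  open_start <- NA_integer_
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "D")) {
      if (is.na(open_start)) open_start <- ref
      ref <- ref + len
    } else if (op == "N") {
      if (!is.na(open_start)) { starts <- c(starts, open_start); ends <- c(ends, ref - 1L) }
      open_start <- NA_integer_
      ref <- ref + len
    }
    # I, S, H, P consume no reference
  }
  if (!is.na(open_start)) { starts <- c(starts, open_start); ends <- c(ends, ref - 1L) }
  cbind(start = starts, end = ends)
}

#' Detect microexon-spanning evidence in one alignment
#'
#' Scans the (normalized) op list for consecutive `M,N,M,N,M` windows whose
#' middle match block has length within `me_len_range`, whose two skips are
#' within `intron_range`, and whose outer match blocks adjoining the
#' junctions are at least `min_anchor` nt. Insertions or deletions adjoining
#' a junction break the pattern and disqualify that window. Reads with more
#' than five parts are scanned for every embedded qualifying window.
#'
#' @param chrom,pos,cigar alignment fields (`pos` 1-based leftmost).
#' @param min_anchor minimum match length on each flanking exon (nt).
#' @param me_len_range allowed microexon lengths, inclusive.
#' @param intron_range allowed intron (N) lengths, inclusive.
#' @return data.frame of evidence rows (possibly 0 rows) with the genomic
#'   intervals of the left anchor, upstream intron, microexon, downstream
#'   intron and right anchor, plus `me_len`.
#' @export
detect_spanning <- function(chrom, pos, cigar, min_anchor = 6L,
                            me_len_range = c(1L, 15L),
                            intron_range = c(20L, 20000L)) {
  pos <- as.integer(pos)
  ops <- parse_cigar(cigar)
  # soft/hard clips allowed only at termini
  inner <- ops$op[ops$op != "H"]
  s_idx <- which(inner == "S")
  if (length(s_idx) && any(s_idx != 1L & s_idx != length(inner)))
    stop("internal soft clip in CIGAR ", cigar)
  # genomic start of each op
  ref_start <- integer(nrow(ops))
  ref <- pos
  for (i in seq_len(nrow(ops))) {
    ref_start[i] <- ref
    if (ops$op[i] %in% c("M", "D", "N")) ref <- ref + ops$len[i]
  }
  empty <- data.frame(chrom = character(), left_start = integer(), left_end = integer(),
                      up_start = integer(), up_end = integer(),
                      me_start = integer(), me_end = integer(),
                      dn_start = integer(), dn_end = integer(),
                      right_start = integer(), right_end = integer(),
                      me_len = integer(), stringsAsFactors = FALSE)
  n <- nrow(ops)
  if (n < 5L) return(empty)
  out <- empty
  for (i in seq_len(n - 4L)) {
    o <- ops$op[i:(i + 4L)]
    if (!identical(o, c("M", "N", "M", "N", "M"))) next
    l <- ops$len[i:(i + 4L)]
    if (l[3L] < me_len_range[1L] || l[3L] > me_len_range[2L]) next
    if (l[2L] < intron_range[1L] || l[2L] > intron_range[2L]) next
    if (l[4L] < intron_range[1L] || l[4L] > intron_range[2L]) next
    if (l[1L] < min_anchor || l[5L] < min_anchor) next
    rs <- ref_start[i:(i + 4L)]
    out <- rbind(out, data.frame(
      chrom = chrom,
      left_start = rs[1L], left_end = rs[1L] + l[1L] - 1L,
      up_start = rs[2L], up_end = rs[2L] + l[2L] - 1L,
      me_start = rs[3L], me_end = rs[3L] + l[3L] - 1L,
      dn_start = rs[4L], dn_end = rs[4L] + l[4L] - 1L,
      right_start = rs[5L], right_end = rs[5L] + l[5L] - 1L,
      me_len = l[3L], stringsAsFactors = FALSE))
  }
  out
}

# intron motif from genome dinucleotides; returns list(motif, strand)
intron_motif <- function(genome, chrom, start, end) {
  n <- nchar(genome[[chrom]])
  if (start < 1L || end > n) return(NULL)
  donor <- substr(genome[[chrom]], start, start + 1L)
  accep <- substr(genome[[chrom]], end - 1L, end)
  if (accep == "AG" && donor %in% c("GT", "GC"))
    return(list(motif = paste0(donor, "-AG"), strand = "+"))
  # minus-strand canonical introns read CT..AC / CT..GC on the plus strand
  if (donor == "CT" && accep %in% c("AC", "GC"))
    return(list(motif = paste0(revcomp(accep), "-AG"), strand = "-"))
  list(motif = "other", strand = ".")
}

#' Count splice junctions for one sample
#'
#' Every `N` op of a uniquely mapped read contributes one count to its intron
#' provided both adjoining match blocks are at least `min_anchor` nt. The
#' splice motif is read from the genome (donor GT/GC, acceptor AG) and the
#' strand inferred from the motif orientation.
#'
#' @param alns data.frame from [read_sam()] (one sample).
#' @param genome named character vector from [read_fasta()].
#' @param min_anchor minimum adjoining match block length.
#' @param sample_id sample label stored as an attribute.
#' @return junction table data.frame (`chrom`, `start`, `end`, `strand`,
#'   `motif`, `count`), sorted by position, with attribute `sample_id`.
#' @export
count_junctions <- function(alns, genome, min_anchor = 6L, sample_id = "sample1") {
  alns <- alns[is_unique_mapping(alns), , drop = FALSE]
  cc <- ss <- ee <- character(0)
  key <- character(0)
  rec <- list()
  for (i in seq_len(nrow(alns))) {
    ops <- parse_cigar(alns$cigar[i])
    if (nrow(ops) < 3L) next
    ref <- alns$pos[i]
    ref_start <- integer(nrow(ops))
    for (k in seq_len(nrow(ops))) {
      ref_start[k] <- ref
      if (ops$op[k] %in% c("M", "D", "N")) ref <- ref + ops$len[k]
    }
    for (k in which(ops$op == "N")) {
      if (k == 1L || k == nrow(ops)) next
      if (ops$op[k - 1L] != "M" || ops$op[k + 1L] != "M") next
      # an M block that is itself bounded by a further N (a microexon part of
      # a spanning read) is exempt from the anchor minimum: its anchor
      # continues across the next junction into the true flanking exon
      left_ok <- ops$len[k - 1L] >= min_anchor ||
        (k - 2L >= 1L && ops$op[k - 2L] == "N")
      right_ok <- ops$len[k + 1L] >= min_anchor ||
        (k + 2L <= nrow(ops) && ops$op[k + 2L] == "N")
      if (!left_ok || !right_ok) next
      s <- ref_start[k]; e <- s + ops$len[k] - 1L
      rec[[length(rec) + 1L]] <- c(alns$chrom[i], s, e)
    }
  }
  if (length(rec) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), motif = character(), count = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  m <- do.call(rbind, rec)
  df <- data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]),
                   end = as.integer(m[, 3L]), stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = df[c("chrom", "start", "end")], FUN = sum)
  motif <- character(nrow(agg)); strand <- character(nrow(agg))
  drop <- logical(nrow(agg))
  for (i in seq_len(nrow(agg))) {
    mt <- intron_motif(genome, agg$chrom[i], agg$start[i], agg$end[i])
    if (is.null(mt)) { drop[i] <- TRUE; next }
    motif[i] <- mt$motif; strand[i] <- mt$strand
  }
  if (any(drop)) warning(sum(drop), " intron(s) outside chromosome bounds dropped")
  agg <- agg[!drop, , drop = FALSE]
  out <- data.frame(chrom = agg$chrom, start = agg$start, end = agg$end,
                    strand = strand[!drop], motif = motif[!drop],
                    count = as.integer(agg$count), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  out
}
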