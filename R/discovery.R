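# Call internal microexons from multi-sample junction tables, estimate PSI,
# and compare calls against an existing annotation.

# pool junction tables: unique introns with per-sample count matrix
pool_junctions <- function(junction_tables) {
  stopifnot(length(junction_tables) >= 1L)
  if (is.null(names(junction_tables)) || any(!nzchar(names(junction_tables))))
    names(junction_tables) <- paste0("sample", seq_along(junction_tables))
  all <- do.call(rbind, lapply(names(junction_tables), function(s) {
    jt <- junction_tables[[s]]
    if (nrow(jt) == 0L) return(NULL)
    cbind(jt, sample = s, stringsAsFactors = FALSE)
  }))
  if (is.null(all)) stop("all junction tables are empty")
  key <- paste(all$chrom, all$start, all$end, sep = ":")
  uk <- !duplicated(key)
  introns <- all[uk, c("chrom", "start", "end", "strand", "motif")]
  rownames(introns) <- key[uk]
  counts <- matrix(0L, nrow(introns), length(junction_tables),
                   dimnames = list(rownames(introns), names(junction_tables)))
  counts[cbind(key, all$sample)] <- all$count
  list(introns = introns, counts = counts)
}

#' Call 1-15 nt internal microexons from junction evidence
#'
#' Candidate microexons are the genomic gaps between a same-chrom, same-strand
#' intron pair both having canonical splice motifs (GT-AG or GC-AG) with gap
#' length within `me_len_range`. A candidate is called when at least one
#' single sample has `min_support` or more reads on *both* flanking introns.
#' When alternative introns compete on one side of a candidate exon, the
#' intron with the highest mean junction count across samples is used; ties
#' are broken by shorter intron, then leftmost.
#'
#' @param junction_tables named list of per-sample junction tables
#'   (see [count_junctions()]).
#' @param genome genome (used only for sanity checks; motifs come from the
#'   tables). May be `NULL`.
#' @param min_support per-sample read support required on each side.
#' @param me_len_range allowed microexon sizes.
#' @return data.frame of calls: `chrom`, `strand`, `start`, `end`, `size`,
#'   flanking intron coordinates/motifs, per-sample support matrices in
#'   attributes `left_counts`/`right_counts`, and `psi` (filled by
#'   [compute_psi()]).
#' @export
call_microexons <- function(junction_tables, genome = NULL, min_support = 5L,
                            me_len_range = c(1L, 15L)) {
  pool <- pool_junctions(junction_tables)
  ji <- pool$introns
  cnt <- pool$counts
  canon <- ji$motif %in% c("GT-AG", "GC-AG")
  ji <- ji[canon, , drop = FALSE]
  cnt <- cnt[canon, , drop = FALSE]
  if (nrow(ji) == 0L) return(empty_calls())
  mean_cnt <- rowMeans(cnt)
  calls <- list()
  for (cs in unique(paste(ji$chrom, ji$strand))) {
    sel <- paste(ji$chrom, ji$strand) == cs
    sub <- ji[sel, , drop = FALSE]
    scnt <- cnt[sel, , drop = FALSE]
    smean <- mean_cnt[sel]
    o <- order(sub$start, sub$end)
    sub <- sub[o, , drop = FALSE]; scnt <- scnt[o, , drop = FALSE]; smean <- smean[o]
    # candidate exon intervals: gap between left intron end and right intron start
    n <- nrow(sub)
    if (n < 2L) next
    # group left introns by their 3' end (exon start - 1), right by 5' start
    cand <- list()
    for (i in seq_len(n)) {
      gap_start <- sub$end[i] + 1L
      js <- which(sub$start > sub$end[i] &
                    sub$start - 1L - sub$end[i] >= me_len_range[1L] &
                    sub$start - 1L - sub$end[i] <= me_len_range[2L])
      for (j in js) {
        cand[[length(cand) + 1L]] <- c(i, j, gap_start, sub$start[j] - 1L)
      }
    }
    if (length(cand) == 0L) next
    cm <- do.call(rbind, cand)
    exon_key <- paste(cm[, 3L], cm[, 4L])
    for (ek in unique(exon_key)) {
      rows <- cm[exon_key == ek, , drop = FALSE]
      lefts <- unique(rows[, 1L]); rights <- unique(rows[, 2L])
      pick <- function(idx) {
        # most average junction reads in the population; ties: shorter, leftmost
        mu <- smean[idx]
        len <- sub$end[idx] - sub$start[idx] + 1L
        idx[order(-mu, len, sub$start[idx])][1L]
      }
      li <- pick(lefts); ri <- pick(rights)
      support <- pmin(scnt[li, ], scnt[ri, ])
      if (max(support) < min_support) next
      calls[[length(calls) + 1L]] <- list(
        chrom = sub$chrom[li], strand = sub$strand[li],
        start = rows[1L, 3L], end = rows[1L, 4L],
        up_start = sub$start[li], up_end = sub$end[li], up_motif = sub$motif[li],
        dn_start = sub$start[ri], dn_end = sub$end[ri], dn_motif = sub$motif[ri],
        left_counts = scnt[li, ], right_counts = scnt[ri, ])
    }
  }
  if (length(calls) == 0L) return(empty_calls())
  df <- do.call(rbind, lapply(calls, function(x)
    data.frame(chrom = x$chrom, strand = x$strand, start = x$start, end = x$end,
               size = x$end - x$start + 1L,
               up_start = x$up_start, up_end = x$up_end, up_motif = x$up_motif,
               dn_start = x$dn_start, dn_end = x$dn_end, dn_motif = x$dn_motif,
               psi = NA_real_, stringsAsFactors = FALSE)))
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "left_counts") <- do.call(rbind, lapply(calls, `[[`, "left_counts"))[o, , drop = FALSE]
  attr(df, "right_counts") <- do.call(rbind, lapply(calls, `[[`, "right_counts"))[o, , drop = FALSE]
  df
}

empty_calls <- function() {
  data.frame(chrom = character(), strand = character(), start = integer(),
             end = integer(), size = integer(), up_start = integer(),
             up_end = integer(), up_motif = character(), dn_start = integer(),
             dn_end = integer(), dn_motif = character(), psi = numeric(),
             stringsAsFactors = FALSE)
}

#' Percent spliced-in for microexon calls
#'
#' PSI = I / (I + E): I is the mean of the two inclusion-junction counts
#' (each summed over samples); E is the summed count of the exclusion
#' junction joining the two flanking exons directly, i.e. the intron running
#' from the upstream intron's donor to the downstream intron's acceptor.
#' Only a canonical exclusion junction contributes to E. `NA` when I + E = 0.
#'
#' @param calls data.frame from [call_microexons()].
#' @param junction_tables the same per-sample junction tables.
#' @return `calls` with the `psi` column filled (values in `[0, 1]` or `NA`).
#' @export
compute_psi <- function(calls, junction_tables) {
  if (nrow(calls) == 0L) return(calls)
  pool <- pool_junctions(junction_tables)
  key <- rownames(pool$introns)
  tot <- rowSums(pool$counts)
  canon <- pool$introns$motif %in% c("GT-AG", "GC-AG")
  lc <- attr(calls, "left_counts"); rc <- attr(calls, "right_counts")
  for (i in seq_len(nrow(calls))) {
    I <- mean(c(sum(lc[i, ]), sum(rc[i, ])))
    ex_key <- paste(calls$chrom[i], calls$up_start[i], calls$dn_end[i], sep = ":")
    j <- match(ex_key, key)
    E <- if (!is.na(j) && canon[j]) tot[j] else 0
    calls$psi[i] <- if (I + E == 0) NA_real_ else I / (I + E)
  }
  calls
}

# introns implied by a transcript's exon chain; matrix [start,end] (possibly 0 rows)
transcript_introns <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(cbind(start = integer(), end = integer()))
  cbind(start = ex[-nrow(ex), "end"] + 1L, end = ex[-1L, "start"] - 1L)
}

#' Classify calls against an annotation
#'
#' For each call: `annotated_exact` when an annotated internal exon equals
#' the call interval and its flanking introns match the call's;
#' `within_larger_exon` when the call overlaps a longer annotated exon;
#' `intronic` when it lies strictly inside an annotated intron;
#' `unannotated_gene` otherwise.
#'
#' @param calls data.frame from [call_microexons()].
#' @param transcripts `mek_transcripts` from [read_gtf()].
#' @return `calls` with an `annotation_status` column appended.
#' @export
classify_vs_annotation <- function(calls, transcripts) {
  status <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    st <- "unannotated_gene"
    for (tx in transcripts) {
      if (tx$chrom != calls$chrom[i]) next
      ex <- tx$exons
      ni <- transcript_introns(tx)
      nex <- nrow(ex)
      # exact internal exon with matching introns
      for (k in seq_len(nex)) {
        if (k == 1L || k == nex) next
        if (ex[k, "start"] == calls$start[i] && ex[k, "end"] == calls$end[i] &&
            ni[k - 1L, "start"] == calls$up_start[i] && ni[k - 1L, "end"] == calls$up_end[i] &&
            ni[k, "start"] == calls$dn_start[i] && ni[k, "end"] == calls$dn_end[i]) {
          st <- "annotated_exact"
          break
        }
      }
      if (st == "annotated_exact") break
      lens <- ex[, "end"] - ex[, "start"] + 1L
      ov <- ex[, "start"] <= calls$end[i] & ex[, "end"] >= calls$start[i]
      if (any(ov & lens > calls$size[i])) { st <- "within_larger_exon"; next }
      if (nrow(ni) > 0L &&
          any(ni[, "start"] < calls$start[i] & ni[, "end"] > calls$end[i]) &&
          st == "unannotated_gene")
        st <- "intronic"
    }
    status[i] <- st
  }
  calls$annotation_status <- status
  calls
}

#' Junction support for microexons already present in an annotation
#'
#' Annotated *internal* exons of at most `max_size` nt are checked for
#' junction support: an exon is supported when some single sample has
#' `min_support` or more reads on both of its flanking introns. First and
#' last exons are excluded.
#'
#' @param transcripts `mek_transcripts` from [read_gtf()].
#' @param junction_tables named list of per-sample junction tables.
#' @param min_support per-sample support threshold.
#' @param max_size microexon size cutoff (nt).
#' @return data.frame: `transcript_id`, `chrom`, `strand`, `start`, `end`,
#'   `size`, `supported`.
#' @export
validate_annotated_microexons <- function(transcripts, junction_tables,
                                          min_support = 5L, max_size = 15L) {
  pool <- pool_junctions(junction_tables)
  key <- rownames(pool$introns)
  out <- list()
  for (tx in transcripts) {
    ex <- tx$exons
    nex <- nrow(ex)
    if (nex < 3L) next
    ni <- transcript_introns(tx)
    for (k in 2L:(nex - 1L)) {
      sz <- ex[k, "end"] - ex[k, "start"] + 1L
      if (sz > max_size) next
      k_up <- paste(tx$chrom, ni[k - 1L, "start"], ni[k - 1L, "end"], sep = ":")
      k_dn <- paste(tx$chrom, ni[k, "start"], ni[k, "end"], sep = ":")
      iu <- match(k_up, key); id <- match(k_dn, key)
      supported <- FALSE
      if (!is.na(iu) && !is.na(id))
        supported <- max(pmin(pool$counts[iu, ], pool$counts[id, ])) >= min_support
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tx$transcript_id, chrom = tx$chrom, strand = tx$strand,
        start = ex[k, "start"], end = ex[k, "end"], size = sz,
        supported = supported, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(transcript_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      size = integer(), supported = logical(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
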