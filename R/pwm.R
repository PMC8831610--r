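# Per-cluster position weight matrices, split at exon boundaries, and the
# genome scanner that chains part matches across intron gaps with canonical
# splice sites — homology-based microexon modeling without RNA-seq data.

#' Build a position weight matrix from equal-length coding sequences
#'
#' Column probabilities are (n_b + alpha) / (N + 4 alpha); log-odds are base-2
#' against a uniform 0.25 background. Sequences containing N are dropped with
#' a warning.
#'
#' @param seqs character vector of equal-length A/C/G/T sequences.
#' @param pseudocount alpha added per base per column.
#' @return list with `prob` and `logodds` (4 x width matrices, rows A/C/G/T),
#'   and `n` (number of sequences used).
#' @export
build_pwm <- function(seqs, pseudocount = 0.25) {
  seqs <- toupper(seqs)
  hasN <- grepl("[^ACGT]", seqs)
  if (any(hasN)) {
    warning(sum(hasN), " sequence(s) with non-ACGT characters dropped")
    seqs <- seqs[!hasN]
  }
  if (length(seqs) < 2L) stop("need at least 2 sequences to build a PWM")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must have equal length")
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  counts <- vapply(seq_len(w), function(j)
    tabulate(match(chars[, j], DNA_BASES4), 4L), integer(4L))
  prob <- (counts + pseudocount) / (length(seqs) + 4 * pseudocount)
  dimnames(prob) <- list(DNA_BASES4, NULL)
  list(prob = prob, logodds = log2(prob / 0.25), n = length(seqs))
}

#' Split a PWM at exon boundaries
#'
#' The matrix is sliced at every boundary offset; the part covering the
#' microexon window is labelled `microexon`, parts 5' of it `flank5`, parts
#' 3' of it `flank3`.
#'
#' @param pwm list from [build_pwm()].
#' @param boundaries integer offsets (nt before each junction), strictly
#'   inside the tag.
#' @param me_offset nt before the microexon within the tag.
#' @param me_size microexon width; must be delimited by two boundaries (or a
#'   tag end for truncated clusters).
#' @param cluster_id,me_phase identifiers carried through to hits.
#' @return a `mek_split_pwm`: list with `parts` (each `prob`, `logodds`,
#'   `width`, `role`), `me_part`, `me_size`, `me_phase` (optional),
#'   `cluster_id`.
#' @export
split_pwm <- function(pwm, boundaries, me_offset, me_size,
                      cluster_id = NA, me_phase = NA_integer_) {
  w <- ncol(pwm$prob)
  boundaries <- sort(unique(as.integer(boundaries)))
  if (any(boundaries <= 0L | boundaries >= w))
    stop("boundary offsets must lie strictly inside the tag")
  cuts <- c(0L, boundaries, w)
  me_lo <- me_offset; me_hi <- me_offset + me_size
  if (!(me_lo %in% cuts) || !(me_hi %in% cuts))
    stop("microexon must be delimited by exon boundaries (or tag ends)")
  parts <- list()
  me_part <- NA_integer_
  for (k in seq_len(length(cuts) - 1L)) {
    lo <- cuts[k]; hi <- cuts[k + 1L]
    role <- if (lo == me_lo && hi == me_hi) "microexon"
            else if (hi <= me_lo) "flank5" else "flank3"
    if (role == "microexon") me_part <- k
    parts[[k]] <- list(prob = pwm$prob[, (lo + 1L):hi, drop = FALSE],
                       logodds = pwm$logodds[, (lo + 1L):hi, drop = FALSE],
                       width = hi - lo, role = role)
  }
  if (is.na(me_part)) stop("no part matches the microexon window")
  structure(list(cluster_id = cluster_id, parts = parts, me_part = me_part,
                 me_size = as.integer(me_size), me_phase = me_phase,
                 tag_len = w),
            class = "mek_split_pwm")
}

#' Build the split PWM for a tag cluster
#'
#' Convenience wrapper: filter homolog/member sequences, build the PWM and
#' split it at the cluster's canonical boundaries.
#'
#' @param cluster `mek_tag_cluster`.
#' @param candidates optional extra coding fragments (see
#'   [filter_homolog_sequences()]).
#' @param pseudocount passed to [build_pwm()].
#' @return `mek_split_pwm`.
#' @export
cluster_split_pwm <- function(cluster, candidates = character(0), pseudocount = 0.25) {
  seqs <- filter_homolog_sequences(candidates, cluster)
  if (length(seqs) == 0L) stop("cluster is un-modelable (no usable sequences)")
  pwm <- build_pwm(seqs, pseudocount)
  split_pwm(pwm, cluster$canonical_boundaries, cluster$canonical_me_offset,
            cluster$me_size, cluster_id = cluster$cluster_id,
            me_phase = cluster$me_phase)
}

#' @export
print.mek_split_pwm <- function(x, ...) {
  cat(sprintf("split PWM (cluster %s): %d part(s) [%s], microexon width %d\n",
              x$cluster_id, length(x$parts),
              paste(vapply(x$parts, `[[`, 1L, "width"), collapse = ","),
              x$me_size))
  invisible(x)
}

# sliding log-odds scores of one part over an encoded sequence;
# returns numeric vector over start positions (NA bases score -Inf)
part_scores <- function(code, logodds) {
  w <- ncol(logodds)
  L <- length(code)
  if (L < w) return(numeric(0))
  ns <- L - w + 1L
  sc <- numeric(ns)
  for (j in seq_len(w)) {
    v <- logodds[cbind(code[j:(ns + j - 1L)], j)]
    v[is.na(v)] <- -Inf
    sc <- sc + v
  }
  sc
}

part_score_range <- function(logodds) {
  c(min = sum(apply(logodds, 2L, min)), max = sum(apply(logodds, 2L, max)))
}

#' Scan a genome with a split PWM and assemble microexon-tag loci
#'
#' Each part is scanned independently on both strands; windows scoring at
#' least `min_score_frac` of the way from the part's minimum to its maximum
#' achievable score are kept. Part hits are chained in order with inter-part
#' gaps of exactly 0 (intron absent) or within `gap_range` (intron present);
#' a nonzero gap must begin GT or GC and end AG in the strand's reading
#' sense. Overlapping chains are resolved by total score, then leftmost.
#' A chain is classified `microexon` when both gaps flanking the microexon
#' part are introns, `merged` when at least one is 0, and `partial` when an
#' outer flank part is missing (reported, excluded from rates).
#'
#' @param genome named character vector from [read_fasta()].
#' @param spwm `mek_split_pwm`.
#' @param min_score_frac per-part threshold as a fraction of the min-max
#'   score range.
#' @param gap_range allowed intron lengths, inclusive.
#' @param allow_partial also search chains missing outer flank parts.
#' @return data.frame of hits: `cluster_id`, `chrom`, `strand`, `start`,
#'   `end`, `score`, `classification`, `n_parts`, plus list columns `parts`
#'   (matrix of plus-strand part intervals) and `gaps` (intron lengths
#'   between consecutive parts).
#' @export
scan_and_assemble <- function(genome, spwm, min_score_frac = 0.8,
                              gap_range = c(20L, 10000L), allow_partial = TRUE) {
  K <- length(spwm$parts)
  im <- spwm$me_part
  widths <- vapply(spwm$parts, `[[`, 1L, "width")
  thr <- lapply(spwm$parts, function(p) {
    r <- part_score_range(p$logodds)
    r["min"] + min_score_frac * (r["max"] - r["min"])
  })
  runs <- list(c(1L, K))
  if (allow_partial && K > 2L) {
    for (a in 1L:im) for (b in im:K) {
      if (a == 1L && b == K) next
      if (b - a + 1L < 2L) next
      runs[[length(runs) + 1L]] <- c(a, b)
    }
  }
  hits <- list()
  for (chrom in names(genome)) {
    plus <- genome[[chrom]]
    L <- nchar(plus)
    for (strand in c("+", "-")) {
      seqc <- if (strand == "+") plus else revcomp(plus)
      code <- match(strsplit(seqc, "")[[1L]], DNA_BASES4)
      # per-part qualifying start positions and scores
      ph <- vector("list", K)
      for (k in seq_len(K)) {
        sc <- part_scores(code, spwm$parts[[k]]$logodds)
        ok <- which(sc >= thr[[k]])
        ph[[k]] <- list(start = ok, score = sc[ok])
      }
      chars <- strsplit(seqc, "")[[1L]]
      dinu <- function(i) paste0(chars[i], chars[i + 1L])
      for (run in runs) {
        a <- run[1L]; b <- run[2L]
        if (length(ph[[a]]$start) == 0L) next
        chains <- lapply(seq_along(ph[[a]]$start), function(i)
          list(starts = ph[[a]]$start[i], score = ph[[a]]$score[i]))
        ok_run <- TRUE
        for (k in seq.int(a + 1L, length.out = b - a)) {
          if (length(ph[[k]]$start) == 0L) { ok_run <- FALSE; break }
          nxt <- list()
          for (ch in chains) {
            prev_end <- ch$starts[length(ch$starts)] + widths[k - 1L] - 1L
            gap <- ph[[k]]$start - prev_end - 1L
            sel <- which(gap == 0L | (gap >= gap_range[1L] & gap <= gap_range[2L]))
            for (s in sel) {
              g <- gap[s]
              if (g > 0L) {
                don <- dinu(prev_end + 1L)
                acc <- dinu(ph[[k]]$start[s] - 2L)
                if (!(don %in% c("GT", "GC")) || acc != "AG") next
              }
              nxt[[length(nxt) + 1L]] <- list(
                starts = c(ch$starts, ph[[k]]$start[s]),
                score = ch$score + ph[[k]]$score[s])
            }
          }
          chains <- nxt
          if (length(chains) == 0L) { ok_run <- FALSE; break }
        }
        if (!ok_run || length(chains) == 0L) next
        for (ch in chains) {
          ends <- ch$starts + widths[a:b] - 1L
          gaps <- if (length(ch$starts) > 1L)
            ch$starts[-1L] - ends[-length(ends)] - 1L else integer(0)
          cls <- classify_chain(a, b, im, K, gaps)
          # map working coords back to plus strand
          ps <- ch$starts; pe <- ends
          if (strand == "-") {
            tmp <- L - pe + 1L
            pe <- L - ps + 1L
            ps <- tmp
            ps <- rev(ps); pe <- rev(pe)
          }
          hits[[length(hits) + 1L]] <- data.frame(
            cluster_id = spwm$cluster_id, chrom = chrom, strand = strand,
            start = min(ps), end = max(pe), score = ch$score,
            classification = cls, n_parts = b - a + 1L,
            parts = I(list(cbind(start = ps, end = pe))),
            gaps = I(list(gaps)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(cluster_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      score = numeric(), classification = character(),
                      n_parts = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, hits)
  # resolve overlaps: highest total score, then leftmost
  df <- df[order(-df$score, df$chrom, df$start), , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    sel <- which(keep)
    clash <- any(df$chrom[sel] == df$chrom[i] &
                   df$start[sel] <= df$end[i] & df$end[sel] >= df$start[i])
    keep[i] <- !clash
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

classify_chain <- function(a, b, im, K, gaps) {
  if (a > 1L || b < K) return("partial")   # outer flank part missing
  g_up <- gaps[im - a]                     # gap between parts im-1 and im
  g_dn <- gaps[im - a + 1L]                # gap between parts im and im+1
  if (g_up > 0L && g_dn > 0L) "microexon" else "merged"
}

#' Per-cluster per-species microexon rates
#'
#' rate = microexon hits / (microexon + merged hits); `partial` hits are
#' excluded; `NA` where a cluster has no microexon or merged hit in a
#' species (tag not found).
#'
#' @param hits data.frame with columns `cluster_id`, `species`,
#'   `classification` (rbind of [scan_and_assemble()] results over species,
#'   with a `species` column added).
#' @return numeric matrix, clusters x species, values in `[0, 1]` or `NA`.
#' @export
summarize_rates <- function(hits) {
  stopifnot(all(c("cluster_id", "species", "classification") %in% names(hits)))
  clusters <- sort(unique(hits$cluster_id))
  species <- sort(unique(hits$species))
  rates <- matrix(NA_real_, length(clusters), length(species),
                  dimnames = list(as.character(clusters), species))
  for (ci in seq_along(clusters)) for (si in seq_along(species)) {
    cls <- hits$classification[hits$cluster_id == clusters[ci] &
                                 hits$species == species[si]]
    n_me <- sum(cls == "microexon"); n_mg <- sum(cls == "merged")
    if (n_me + n_mg > 0L) rates[ci, si] <- n_me / (n_me + n_mg)
  }
  rates
}
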