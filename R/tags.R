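# Microexon-tags: fixed-length (default 108 nt) in-frame coding windows
# centred on a microexon, translated to peptides (36 aa at full length),
# grouped by microexon size and phase, and clustered by BLOSUM62 similarity.
# Tags are the homology unit for genome-wide microexon modeling.

#' Find the longest ATG-initiated open reading frame
#'
#' Forward strand of the transcript only. The ORF runs from an ATG to the
#' first in-frame stop (inclusive) or the last complete codon of the
#' sequence. Length ties are broken 5'-most.
#'
#' @param seq transcript sequence (sense orientation).
#' @param min_len minimum ORF length in nt (shorter ORFs return `NULL`).
#' @return list with `start`, `end` (1-based closed, length divisible by 3)
#'   or `NULL` when no qualifying ORF exists.
#' @export
find_longest_orf <- function(seq, min_len = 30L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- NULL
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    codons <- substring(seq, f + 1L + 3L * (seq_len(ncod) - 1L), f + 3L * seq_len(ncod))
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    # segment index between stops
    seg <- cumsum(c(FALSE, head(is_stop, -1L)))
    for (s in unique(seg)) {
      idx <- which(seg == s)
      atg <- idx[is_atg[idx]]
      if (length(atg) == 0L) next
      a <- atg[1L]
      last <- idx[length(idx)]
      # include terminal stop codon if present
      end_cod <- if (is_stop[last]) last else last
      len <- (end_cod - a + 1L) * 3L
      if (len < min_len) next
      if (is.null(best) || len > best$len ||
          (len == best$len && (f + 1L + 3L * (a - 1L)) < best$start)) {
        best <- list(start = f + 1L + 3L * (a - 1L),
                     end = f + 3L * end_cod, len = len)
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(start = best$start, end = best$end)
}

#' Reading-frame phase of a microexon
#'
#' Number of CDS nucleotides 5' of the microexon, modulo 3. Phase 0 means
#' the microexon starts on a codon boundary.
#'
#' @param me_cds_start 1-based start of the microexon within the CDS.
#' @return integer 0, 1 or 2.
#' @export
microexon_phase <- function(me_cds_start) {
  stopifnot(is_count(me_cds_start), me_cds_start >= 1L)
  as.integer((me_cds_start - 1L) %% 3L)
}

#' Extract a microexon-tag from CDS coordinates
#'
#' A window of `tag_len` nt is centred on the microexon within the CDS (the
#' odd spare nucleotide goes 3'), shifted by at most one nucleotide so the
#' window starts on a codon boundary, and truncated in frame where it would
#' run past either end of the ORF. Exon junctions falling inside the window
#' are recorded as offsets (nt counts from the window start).
#'
#' @param cds_seq spliced CDS sequence (ATG..stop).
#' @param me_cds_start 1-based microexon start within the CDS.
#' @param me_size microexon length (1-15 nt).
#' @param exon_boundaries integer offsets of exon junctions within the CDS
#'   (a junction after CDS position k is recorded as k).
#' @param tag_len window length, default 108 nt.
#' @param species,gene_id,transcript_id identifiers carried on the tag.
#' @return one-row data.frame: `species`, `gene_id`, `transcript_id`, `dna`,
#'   `peptide`, `me_size`, `me_phase`, `me_offset` (nt before the microexon
#'   within `dna`) and list column `boundaries`; or `NULL` when the window
#'   truncates below one codon.
#' @export
extract_microexon_tag <- function(cds_seq, me_cds_start, me_size,
                                  exon_boundaries = integer(0), tag_len = 108L,
                                  species = "sp", gene_id = "g", transcript_id = "t") {
  cds_len <- nchar(cds_seq)
  me_cds_start <- as.integer(me_cds_start)
  me_size <- as.integer(me_size)
  tag_len <- as.integer(tag_len)
  exon_boundaries <- as.integer(exon_boundaries)
  stopifnot(cds_len %% 3L == 0L, me_cds_start + me_size - 1L <= cds_len)
  me0 <- me_cds_start - 1L                     # nt before the microexon
  start0 <- me0 - (tag_len - me_size) %/% 2L   # 0-based window start
  r <- start0 %% 3L
  if (r == 1L) start0 <- start0 - 1L
  if (r == 2L) start0 <- start0 + 1L
  end0 <- start0 + tag_len
  if (start0 < 0L) start0 <- 0L
  if (end0 > cds_len) end0 <- cds_len
  end0 <- start0 + ((end0 - start0) %/% 3L) * 3L
  if (end0 - start0 < 3L) {
    warning("tag window shorter than one codon; skipped")
    return(NULL)
  }
  stopifnot(me0 >= start0, me0 + me_size <= end0)
  dna <- substr(cds_seq, start0 + 1L, end0)
  pep <- translate_dna(dna)
  bnd <- sort(exon_boundaries[exon_boundaries > start0 & exon_boundaries < end0]) - start0
  data.frame(species = species, gene_id = gene_id, transcript_id = transcript_id,
             dna = dna, peptide = pep, me_size = as.integer(me_size),
             me_phase = microexon_phase(me_cds_start),
             me_offset = me0 - start0,
             boundaries = I(list(as.integer(bnd))),
             stringsAsFactors = FALSE)
}

#' Extract microexon-tags from gene models
#'
#' For each transcript containing a given microexon, the spliced transcript
#' sequence is assembled, the longest ORF located, the microexon mapped to
#' CDS coordinates, and the tag extracted with [extract_microexon_tag()].
#' Transcripts whose ORF does not contain the microexon are skipped.
#'
#' @param transcripts `mek_transcripts`.
#' @param genome named character vector from [read_fasta()].
#' @param microexons data.frame with `chrom`, `start`, `end` (one row per
#'   microexon) — typically calls or ground truth.
#' @param tag_len tag window length.
#' @param species species label.
#' @return data.frame of tags (see [extract_microexon_tag()]).
#' @export
tags_from_gene_models <- function(transcripts, genome, microexons,
                                  tag_len = 108L, species = "sp") {
  out <- list()
  for (tx in transcripts) {
    ex <- tx$exons
    widths <- ex[, "end"] - ex[, "start"] + 1L
    # spliced sequence in sense orientation
    pieces <- vapply(seq_len(nrow(ex)), function(k)
      substr(genome[[tx$chrom]], ex[k, "start"], ex[k, "end"]), "")
    txseq <- paste(pieces, collapse = "")
    if (identical(tx$strand, "-")) txseq <- revcomp(txseq)
    orf <- find_longest_orf(txseq)
    if (is.null(orf)) next
    # transcript coordinate of each genomic position, sense orientation
    cum <- cumsum(c(0L, widths))
    tx_len <- sum(widths)
    g2t <- function(gpos) {
      k <- which(ex[, "start"] <= gpos & ex[, "end"] >= gpos)
      if (length(k) != 1L) return(NA_integer_)
      p <- cum[k] + (gpos - ex[k, "start"] + 1L)
      if (identical(tx$strand, "-")) p <- tx_len - p + 1L
      p
    }
    # exon junction offsets in transcript coordinates
    jb <- cum[-c(1L, length(cum))]
    if (identical(tx$strand, "-")) jb <- sort(tx_len - jb)
    for (m in seq_len(nrow(microexons))) {
      if (microexons$chrom[m] != tx$chrom) next
      a <- g2t(microexons$start[m]); b <- g2t(microexons$end[m])
      if (is.na(a) || is.na(b)) next
      me_t_start <- min(a, b)
      me_size <- microexons$end[m] - microexons$start[m] + 1L
      if (me_t_start < orf$start || me_t_start + me_size - 1L > orf$end) next
      cds_seq <- substr(txseq, orf$start, orf$end)
      tag <- extract_microexon_tag(
        cds_seq, me_t_start - orf$start + 1L, me_size,
        exon_boundaries = jb[jb > orf$start - 1L & jb < orf$end] - (orf$start - 1L),
        tag_len = tag_len, species = species,
        gene_id = tx$gene_id, transcript_id = tx$transcript_id)
      if (!is.null(tag)) out[[length(out) + 1L]] <- tag
    }
  }
  if (length(out) == 0L) return(NULL)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# pairwise global BLOSUM62 alignment scores for a character vector of peptides
peptide_score_matrix <- function(peps, gap_open = 10, gap_ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  n <- length(peps)
  s <- matrix(NA_real_, n, n)
  aa <- Biostrings::AAStringSet(peps)
  for (i in seq_len(n)) {
    if (i < n) {
      sc <- Biostrings::pairwiseAlignment(
        aa[(i + 1L):n], aa[[i]], type = "global",
        substitutionMatrix = get("BLOSUM62", envir = environment()),
        gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE)
      s[i, (i + 1L):n] <- sc
      s[(i + 1L):n, i] <- sc
    }
  }
  diag(s) <- NA_real_
  s
}

#' Cluster microexon-tags by peptide similarity
#'
#' Tags are grouped by (microexon size, phase). Within each group, peptides
#' are aligned globally under BLOSUM62 (gap opening `gap_open`, extension
#' `gap_ext`); scores become distances d = s_max - s and the complete-linkage
#' tree is cut at height s_max - `score_cutoff`, so every within-cluster pair
#' aligns with score >= `score_cutoff`. Clusters represented by fewer than
#' `min_species` distinct species are discarded.
#'
#' @param tags data.frame of tags.
#' @param score_cutoff minimum pairwise alignment score inside a cluster.
#' @param min_species minimum number of distinct species per cluster.
#' @param gap_open,gap_ext gap penalties (positive costs).
#' @return list of clusters; each is a list with `cluster_id`, `me_size`,
#'   `me_phase`, `tags` (member rows), `species`, `tag_len`,
#'   `canonical_boundaries` and `canonical_me_offset` (modal over members).
#' @export
cluster_tags <- function(tags, score_cutoff = 50, min_species = 3L,
                         gap_open = 10, gap_ext = 0.5) {
  stopifnot(nrow(tags) >= 2L)
  # deterministic order regardless of input order
  tags <- tags[order(tags$species, tags$gene_id, tags$transcript_id, tags$dna), ,
               drop = FALSE]
  clusters <- list()
  groups <- split(seq_len(nrow(tags)), paste(tags$me_size, tags$me_phase))
  for (g in groups[order(names(groups))]) {
    if (length(g) < 2L) next
    sub <- tags[g, , drop = FALSE]
    s <- peptide_score_matrix(sub$peptide, gap_open, gap_ext)
    s_max <- max(s, na.rm = TRUE)
    h <- s_max - score_cutoff
    if (h < 0) next
    d <- s_max - s
    diag(d) <- 0
    memb <- stats::cutree(stats::hclust(stats::as.dist(d), method = "complete"),
                          h = h)
    for (cl in sort(unique(memb))) {
      rows <- sub[memb == cl, , drop = FALSE]
      if (length(unique(rows$species)) < min_species) next
      clusters[[length(clusters) + 1L]] <- new_tag_cluster(rows)
    }
  }
  for (i in seq_along(clusters)) clusters[[i]]$cluster_id <- i
  clusters
}

# build one cluster record from member tag rows
new_tag_cluster <- function(rows) {
  lens <- nchar(rows$dna)
  tag_len <- modal_value(lens)
  full <- rows[lens == tag_len, , drop = FALSE]
  bkey <- vapply(full$boundaries, paste, "", collapse = ",")
  canon_b <- full$boundaries[[which(bkey == modal_value(bkey))[1L]]]
  canon_off <- modal_value(full$me_offset)
  structure(list(cluster_id = NA_integer_,
                 me_size = as.integer(rows$me_size[1L]),
                 me_phase = as.integer(rows$me_phase[1L]),
                 tags = rows, species = sort(unique(rows$species)),
                 tag_len = tag_len,
                 canonical_boundaries = canon_b,
                 canonical_me_offset = canon_off,
                 motif = NULL),
            class = "mek_tag_cluster")
}

modal_value <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  v <- names(tb)[1L]
  if (is.numeric(x)) as.integer(v) else v
}

#' @export
print.mek_tag_cluster <- function(x, ...) {
  cat(sprintf("microexon-tag cluster %s: size %d, phase %d, %d tag(s), %d species\n",
              x$cluster_id, x$me_size, x$me_phase, nrow(x$tags), length(x$species)))
  invisible(x)
}

#' Filter homolog coding fragments for PWM construction
#'
#' Candidates (e.g. EST-derived 108-nt fragments already laid onto the
#' cluster frame) are combined with the member tag sequences; sequences with
#' an in-frame stop codon, sequences shorter than the cluster tag length,
#' and exact duplicates are removed. Sequences longer than the tag length
#' are dropped with a warning (the PWM needs equal widths).
#'
#' @param candidates character vector of DNA fragments.
#' @param cluster a `mek_tag_cluster`.
#' @return character vector of unique tag-length coding sequences.
#' @export
filter_homolog_sequences <- function(candidates, cluster) {
  pool <- c(cluster$tags$dna[nchar(cluster$tags$dna) == cluster$tag_len],
            toupper(candidates))
  short <- nchar(pool) < cluster$tag_len
  long <- nchar(pool) > cluster$tag_len
  if (any(long)) warning(sum(long), " sequence(s) longer than the cluster tag length dropped")
  pool <- pool[!short & !long]
  has_stop <- vapply(pool, function(x) grepl("\\*", translate_dna(x)), TRUE,
                     USE.NAMES = FALSE)
  pool <- pool[!has_stop]
  pool <- unique(pool)
  if (length(pool) == 0L) {
    warning("cluster ", cluster$cluster_id, " has no usable sequences; un-modelable")
    return(character(0))
  }
  pool
}

#' Assign a protein motif to microexon-encoded residues
#'
#' The residues are assigned to a motif when they lie entirely within the
#' motif's peptide interval extended by `flank` amino acids on each side;
#' among several qualifying motifs the smallest E-value wins.
#'
#' @param me_aa_start,me_aa_end 1-based residue interval encoded by the
#'   microexon within the protein.
#' @param motif_hits data.frame with `motif`, `start`, `end`, `evalue`
#'   (externally produced motif-search table).
#' @param flank extension in aa on each side of a motif.
#' @return the selected row of `motif_hits`, or `NULL` when none qualifies.
#' @export
assign_protein_motif <- function(me_aa_start, me_aa_end, motif_hits, flank = 5L) {
  if (is.null(motif_hits) || nrow(motif_hits) == 0L) return(NULL)
  ok <- me_aa_start >= motif_hits$start - flank & me_aa_end <= motif_hits$end + flank
  if (!any(ok)) return(NULL)
  hits <- motif_hits[ok, , drop = FALSE]
  hits[order(hits$evalue, hits$motif), , drop = FALSE][1L, , drop = FALSE]
}
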