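# Readers/writers for FASTA, GTF/GFF3, SAM text and the junction/call tables,
# plus the in-memory gene model used throughout the package.

#' Read a (multi-)FASTA file of genome sequences
#'
#' Sequences are uppercased; IUPAC ambiguity characters outside A/C/G/T/N are
#' mapped to N with a warning. Duplicate record names and empty files are hard
#' errors.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate sequence names in ", path)
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contain non-ACGTN characters; mapped to N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  stats::setNames(seqs, nm)
}

#' Write genome sequences to FASTA
#'
#' @param genome named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene models from GTF or GFF3
#'
#' Exon and CDS features are grouped by transcript (GTF `transcript_id`, with
#' GFF3 `Parent` fallback) into a list of transcript models. Transcripts with
#' zero exons are skipped with a warning. File coordinates (1-based closed)
#' are kept as-is; minus-strand exon lists are stored in ascending genomic
#' order with a strand flag.
#'
#' @param path path to a GTF or GFF3 file.
#' @return a `mek_transcripts` object: a list of transcript models, each a
#'   list with `transcript_id`, `gene_id`, `chrom`, `strand`, `exons` (2-column
#'   matrix start/end) and `cds` (matrix or `NULL`).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  keep <- df$type %in% c("exon", "CDS")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no exon/CDS features in ", path)
  tid <- if ("transcript_id" %in% names(df)) as.character(df$transcript_id) else rep(NA_character_, nrow(df))
  if ("Parent" %in% names(df)) {
    par <- vapply(df$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_, "")
    tid[is.na(tid)] <- par[is.na(tid)]
  }
  if (anyNA(tid)) stop("features without transcript_id/Parent in ", path)
  gid <- if ("gene_id" %in% names(df)) as.character(df$gene_id) else tid
  out <- list()
  for (t in unique(tid)) {
    rows <- df[tid == t, , drop = FALSE]
    ex <- rows[rows$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) {
      # annotation dialects that give only CDS lines: use CDS as exons
      ex <- rows[rows$type == "CDS", , drop = FALSE]
    }
    if (nrow(ex) == 0L) {
      warning("transcript ", t, " has zero exons; skipped")
      next
    }
    cds <- rows[rows$type == "CDS", , drop = FALSE]
    o <- order(ex$start)
    exm <- cbind(start = ex$start[o], end = ex$end[o])
    cdm <- NULL
    if (nrow(cds) > 0L) {
      o2 <- order(cds$start)
      cdm <- cbind(start = cds$start[o2], end = cds$end[o2])
    }
    out[[t]] <- list(transcript_id = t,
                     gene_id = gid[tid == t][1L],
                     chrom = as.character(rows$seqnames[1L]),
                     strand = as.character(rows$strand[1L]),
                     exons = exm, cds = cdm)
  }
  if (length(out) == 0L) stop("no usable transcripts in ", path)
  structure(unname(out), class = "mek_transcripts")
}

#' @export
print.mek_transcripts <- function(x, ...) {
  cat("mek_transcripts:", length(x), "transcript model(s)\n")
  invisible(x)
}

#' Read spliced alignments from SAM text
#'
#' Keeps the columns needed for spanning-read detection. Unmapped (FLAG 0x4)
#' and secondary/supplementary (0x100/0x800) records are dropped, as are
#' mapped records with CIGAR `*` (with a warning).
#'
#' @param path path to a SAM text file (header optional).
#' @return data.frame with columns `qname`, `flag`, `chrom`, `pos` (1-based),
#'   `mapq`, `cigar`, `nh` (NA when the NH tag is absent).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(qname = character(), flag = integer(), chrom = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      nh = integer(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stop("malformed SAM line (fewer than 11 fields) at line ",
                          which(nf < 11L)[1L])
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  keep <- bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
    bitwAnd(flag, 0x800L) == 0L
  f <- f[keep]; flag <- flag[keep]
  cig <- vapply(f, `[[`, "", 6L)
  star <- cig == "*"
  if (any(star)) {
    warning(sum(star), " mapped record(s) with CIGAR '*' dropped")
    f <- f[!star]; flag <- flag[!star]; cig <- cig[!star]
  }
  nh <- vapply(f, function(x) {
    m <- grep("^NH:i:", x[-(1:11)], value = TRUE)
    if (length(m)) as.integer(sub("^NH:i:", "", m[1L])) else NA_integer_
  }, 1L)
  data.frame(qname = vapply(f, `[[`, "", 1L),
             flag = flag,
             chrom = vapply(f, `[[`, "", 3L),
             pos = as.integer(vapply(f, `[[`, "", 4L)),
             mapq = as.integer(vapply(f, `[[`, "", 5L)),
             cigar = cig,
             nh = nh,
             stringsAsFactors = FALSE)
}

#' Is an alignment record uniquely mapped?
#'
#' NH tag equal to 1 when present, otherwise MAPQ >= `min_mapq`.
#'
#' @param alns data.frame from [read_sam()].
#' @param min_mapq MAPQ fallback threshold.
#' @return logical vector.
#' @export
is_unique_mapping <- function(alns, min_mapq = 20L) {
  ifelse(!is.na(alns$nh), alns$nh == 1L, alns$mapq >= min_mapq)
}

#' Write / read a per-sample junction table
#'
#' Tab-separated, 1-based closed intron coordinates, column order
#' `chrom, start, end, strand, motif, count` (the de-facto spliced-aligner
#' junction-table layout).
#'
#' @param junctions data.frame with those columns.
#' @param path output path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
write_junction_table <- function(junctions, path) {
  cols <- c("chrom", "start", "end", "strand", "motif", "count")
  stopifnot(all(cols %in% names(junctions)))
  utils::write.table(junctions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_junction_table
#' @export
read_junction_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "character", "integer"),
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "strand", "motif", "count")
  df
}

#' Write microexon calls as GTF exon features
#'
#' Attributes carry `microexon_id`, `size`, `phase` (when known) and `psi`,
#' so the output drops into standard annotation tooling. An empty call set
#' yields a header-only file.
#'
#' @param calls data.frame of calls from [call_microexons()].
#' @param path output path.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_calls_gtf <- function(calls, path, source = "mekit") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 2", con)
  if (nrow(calls) == 0L) return(invisible(path))
  for (i in seq_len(nrow(calls))) {
    id <- sprintf("me%04d", i)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; microexon_id "%s"; size "%d";',
                     id, id, id, calls$size[i])
    if (!is.null(calls$phase) && !is.na(calls$phase[i]))
      attrs <- paste(attrs, sprintf('phase "%d";', calls$phase[i]))
    if (!is.null(calls$psi) && !is.na(calls$psi[i]))
      attrs <- paste(attrs, sprintf('psi "%.4f";', calls$psi[i]))
    writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                       calls$chrom[i], source, calls$start[i], calls$end[i],
                       calls$strand[i], attrs), con)
  }
  invisible(path)
}
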