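# Seeded generators for genomes with planted microexon genes, exact-CIGAR
# spliced reads, and mutated cross-species tag families. These fixtures
# emulate the study conditions the rest of the package is tested under:
# multi-exon coding genes with a 1-15 nt internal microexon of known phase,
# GT..AG (or GC..AG) introns, configurable inclusion level (PSI), intron
# retention fractions, and error-free reads with exactly known layouts.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n, gc = 0.36) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_coding <- function(n_codons) {
  codons <- as.vector(outer(outer(DNA_BASES4, DNA_BASES4, paste0), DNA_BASES4, paste0))
  codons <- setdiff(codons, STOP_CODONS)
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

random_intron <- function(len, gc = 0.36, donor = "GT") {
  stopifnot(len >= 20L)
  paste0(donor, random_dna(len - 4L, gc), "AG")
}

#' Specification of a synthetic microexon fixture
#'
#' Defaults describe a typical plant-like test bed: background GC 0.36,
#' introns of 80-500 nt, 100-nt reads, constitutive inclusion (PSI 1) and no
#' retention; microexon sizes drawn uniformly from 1-15 and phases from
#' 0-2 unless given explicitly.
#'
#' @param seed RNG seed; every generator derived from this spec is
#'   deterministic given the seed.
#' @param n_genes number of planted microexon genes.
#' @param me_sizes vector of sizes to draw from (recycled if length
#'   `n_genes`).
#' @param me_phases vector of phases to draw from (recycled likewise).
#' @param psi per-gene inclusion level(s) in `[0, 1]`.
#' @param retention per-gene flanking-intron retention fraction(s).
#' @param intron_range intron length range (within 20-20000).
#' @param read_len simulated read length.
#' @param reads_per_gene simulated depth per gene.
#' @param gc background GC content.
#' @param donor `"GT"` or `"GC"` splice donor for planted introns.
#' @param strands strand(s) to draw per gene.
#' @param error_rate per-base substitution error rate in reads.
#' @return list of class `mek_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 10L, me_sizes = 1:15,
                         me_phases = 0:2, psi = 1, retention = 0,
                         intron_range = c(80L, 500L), read_len = 100L,
                         reads_per_gene = 60L, gc = 0.36, donor = "GT",
                         strands = "+", error_rate = 0) {
  stopifnot(all(me_sizes >= 1L & me_sizes <= 15L),
            all(psi >= 0 & psi <= 1), all(retention >= 0 & retention <= 1),
            intron_range[1L] >= 20L, intron_range[2L] <= 20000L,
            donor %in% c("GT", "GC"))
  structure(list(seed = seed, n_genes = n_genes, me_sizes = me_sizes,
                 me_phases = me_phases, psi = psi, retention = retention,
                 intron_range = intron_range, read_len = read_len,
                 reads_per_gene = reads_per_gene, gc = gc, donor = donor,
                 strands = strands, error_rate = error_rate),
            class = "mek_fixture_spec")
}

# UTR cap with stop codons in all three frames, so no upstream ORF can run
# through into the planted CDS
utr_cap <- function(gc) paste0(random_dna(20L, gc), "CTAACTAACTAAC")

#' Generate a genome with planted microexon genes
#'
#' Each gene has five exons; the middle one is the planted microexon flanked
#' by canonical introns, and the spliced transcript carries a single
#' ATG..stop ORF (the longest in the transcript) containing the microexon at
#' the requested phase. The ground-truth table records exact coordinates,
#' sizes and phases.
#'
#' @param spec `mek_fixture_spec`.
#' @return list of class `mek_fixture`: `genome` (named character),
#'   `transcripts` (`mek_transcripts`, one inclusion transcript per gene),
#'   `truth` (data.frame) and `spec`.
#' @export
generate_genome <- function(spec) {
  withr::with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  n <- spec$n_genes
  sizes <- if (length(spec$me_sizes) == n) as.integer(spec$me_sizes) else
    sample(rep(as.integer(spec$me_sizes), 2L), n, replace = TRUE)
  phases <- if (length(spec$me_phases) == n) as.integer(spec$me_phases) else
    sample(rep(as.integer(spec$me_phases), 2L), n, replace = TRUE)
  psi <- rep_len(spec$psi, n)
  reten <- rep_len(spec$retention, n)
  strands <- rep_len(spec$strands, n)
  chrom_seq <- character(0)
  txs <- list()
  truth <- list()
  pos <- 1L
  pieces <- character(0)
  chrom <- "chr1"
  rint <- function() sample(seq(spec$intron_range[1L], spec$intron_range[2L]), 1L)
  for (g in seq_len(n)) {
    gid <- sprintf("gene%03d", g)
    me <- sizes[g]; ph <- phases[g]
    c1 <- 150L
    c2 <- 90L + ((ph - (150L + 90L)) %% 3L)
    c3 <- 90L
    c4 <- 150L
    c4 <- c4 + ((3L - (c1 + c2 + me + c3 + c4) %% 3L) %% 3L)
    cds_len <- c1 + c2 + me + c3 + c4 + 3L   # with stop codon
    cds <- paste0("ATG", random_coding((cds_len - 6L) %/% 3L))
    cds <- paste0(cds, sample(STOP_CODONS, 1L))
    stopifnot(nchar(cds) == cds_len)
    # slice CDS into the coding parts of the five exons
    co <- cumsum(c(c1, c2, me, c3, c4 + 3L))
    parts <- substring(cds, c(1L, head(co, -1L) + 1L), co)
    utr5 <- utr_cap(spec$gc)
    utr3 <- random_dna(25L, spec$gc)
    il <- c(rint(), rint(), rint(), rint())
    exon_seqs <- c(paste0(utr5, parts[1L]), parts[2L], parts[3L], parts[4L],
                   paste0(parts[5L], utr3))
    cassette <- paste0(exon_seqs[1L], random_intron(il[1L], spec$gc, spec$donor),
                       exon_seqs[2L], random_intron(il[2L], spec$gc, spec$donor),
                       exon_seqs[3L], random_intron(il[3L], spec$gc, spec$donor),
                       exon_seqs[4L], random_intron(il[4L], spec$gc, spec$donor),
                       exon_seqs[5L])
    # relative exon coordinates (plus orientation)
    ew <- nchar(exon_seqs)
    rel_start <- cumsum(c(1L, head(ew, -1L) + il))
    rel_end <- rel_start + ew - 1L
    cass_len <- nchar(cassette)
    strand <- strands[g]
    if (strand == "-") {
      cassette <- revcomp(cassette)
      tmp <- cass_len - rel_end + 1L
      rel_end <- cass_len - rel_start + 1L
      rel_start <- tmp
      o <- order(rel_start)
      rel_start <- rel_start[o]; rel_end <- rel_end[o]
      me_idx <- 3L   # symmetric layout: microexon stays the middle exon
    } else me_idx <- 3L
    spacer <- random_dna(300L, spec$gc)
    pieces <- c(pieces, spacer, cassette)
    offset <- pos + nchar(spacer)
    pos <- offset + cass_len
    ex <- cbind(start = rel_start + offset - 1L, end = rel_end + offset - 1L)
    # CDS genomic segments: exon 1 minus 5' UTR, exon 5 minus 3' UTR (strand-aware)
    cdsm <- ex
    if (strand == "+") {
      cdsm[1L, "start"] <- cdsm[1L, "start"] + nchar(utr5)
      cdsm[5L, "end"] <- cdsm[5L, "end"] - nchar(utr3)
    } else {
      cdsm[5L, "end"] <- cdsm[5L, "end"] - nchar(utr5)
      cdsm[1L, "start"] <- cdsm[1L, "start"] + nchar(utr3)
    }
    tid <- paste0(gid, ".1")
    txs[[length(txs) + 1L]] <- list(transcript_id = tid, gene_id = gid,
                                    chrom = chrom, strand = strand,
                                    exons = ex, cds = cdsm)
    introns <- cbind(start = ex[-nrow(ex), "end"] + 1L, end = ex[-1L, "start"] - 1L)
    up <- if (strand == "+") 2L else 3L    # intron row 5' of the microexon in sense
    dn <- if (strand == "+") 3L else 2L
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = gid, transcript_id = tid, chrom = chrom, strand = strand,
      me_start = ex[me_idx, "start"], me_end = ex[me_idx, "end"],
      me_size = me, me_phase = ph, psi = psi[g], retention = reten[g],
      up_start = introns[up, "start"], up_end = introns[up, "end"],
      dn_start = introns[dn, "start"], dn_end = introns[dn, "end"],
      stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, random_dna(300L, spec$gc))
  genome <- stats::setNames(paste(pieces, collapse = ""), chrom)
  structure(list(genome = genome,
                 transcripts = structure(txs, class = "mek_transcripts"),
                 truth = do.call(rbind, truth), spec = spec),
            class = "mek_fixture")
}

#' @export
print.mek_fixture <- function(x, ...) {
  cat(sprintf("mek_fixture: %d gene(s) on %d chromosome(s), genome %d nt\n",
              nrow(x$truth), length(x$genome), sum(nchar(x$genome))))
  invisible(x)
}

# spliced-isoform block sets for one gene: inclusion, exclusion, and
# retention variants of the inclusion form
gene_isoforms <- function(ex, me_idx) {
  introns <- cbind(start = ex[-nrow(ex), "end"] + 1L, end = ex[-1L, "start"] - 1L)
  fuse <- function(blocks, k) {  # retain intron k: fuse exons k and k+1
    b <- blocks
    b[k, "end"] <- b[k + 1L, "end"]
    b[-(k + 1L), , drop = FALSE]
  }
  list(incl = ex,
       excl = ex[-me_idx, , drop = FALSE],
       ret_up = fuse(ex, me_idx - 1L),
       ret_dn = fuse(ex, me_idx),
       ret_both = fuse(fuse(ex, me_idx), me_idx - 1L))
}

# CIGAR + leftmost position for a read covering spliced interval
# [s, s + rl - 1] of an isoform with the given (ascending) blocks
read_layout_to_cigar <- function(blocks, s, rl) {
  widths <- blocks[, "end"] - blocks[, "start"] + 1L
  cum <- cumsum(c(0L, widths))
  e <- s + rl - 1L
  stopifnot(e <= sum(widths))
  ops <- character(0); lens <- integer(0)
  pos <- NA_integer_
  for (k in seq_len(nrow(blocks))) {
    lo <- max(s, cum[k] + 1L); hi <- min(e, cum[k + 1L])
    if (lo > hi) next
    gstart <- blocks[k, "start"] + (lo - cum[k] - 1L)
    if (is.na(pos)) pos <- gstart
    if (length(ops) > 0L) {
      prev_gend <- blocks[k - 1L, "end"]
      ops <- c(ops, "N"); lens <- c(lens, blocks[k, "start"] - prev_gend - 1L)
    }
    ops <- c(ops, "M"); lens <- c(lens, hi - lo + 1L)
  }
  list(pos = pos, cigar = paste0(lens, ops, collapse = ""))
}

#' Simulate error-free spliced reads from a fixture
#'
#' Reads of the spec's length are drawn uniformly along each gene's
#' isoforms: the microexon is included with probability `psi`, and each
#' flanking intron is independently retained with probability `retention`
#' (retention takes precedence over exclusion for the affected intron).
#' CIGARs are computed exactly from the isoform layout; all records carry
#' `NH:i:1`.
#'
#' @param fixture `mek_fixture` from [generate_genome()].
#' @param seed RNG seed (defaults to the fixture spec's seed + 1).
#' @return list with `sam` (character vector of SAM lines, header included),
#'   `reads` (per-read truth: gene, isoform key, spliced offset) and
#'   `isoforms` (named list of block matrices keyed `gene|iso`).
#' @export
simulate_reads <- function(fixture, seed = NULL) {
  spec <- fixture$spec
  if (is.null(seed)) seed <- spec$seed + 1L
  withr::with_seed(seed, simulate_reads_impl(fixture))
}

simulate_reads_impl <- function(fixture) {
  spec <- fixture$spec
  rl <- spec$read_len
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(fixture$genome),
                      nchar(fixture$genome)))
  sam <- character(0)
  reads <- list()
  isoforms <- list()
  for (g in seq_len(nrow(fixture$truth))) {
    tr <- fixture$truth[g, ]
    tx <- fixture$transcripts[[g]]
    me_idx <- which(tx$exons[, "start"] == tr$me_start)
    iso <- gene_isoforms(tx$exons, me_idx)
    for (nm in names(iso)) isoforms[[paste0(tr$gene_id, "|", nm)]] <- iso[[nm]]
    # molecule-type probabilities; reads are drawn proportional to
    # molecular abundance x isoform length (standard RNA-seq sampling)
    r <- tr$retention; p <- tr$psi
    mp <- c(incl = (1 - r)^2 * p, excl = (1 - r)^2 * (1 - p),
            ret_up = r * (1 - r), ret_dn = (1 - r) * r, ret_both = r^2)
    ilen <- vapply(iso, function(b) sum(b[, "end"] - b[, "start"] + 1L), 1)
    # reads ~ abundance x number of valid start positions (uniform fragments)
    wt <- mp[names(iso)] * pmax(ilen - rl + 1, 0)
    for (i in seq_len(spec$reads_per_gene)) {
      key <- sample(names(iso), 1L, prob = wt)
      blocks <- iso[[key]]
      iso_len <- sum(blocks[, "end"] - blocks[, "start"] + 1L)
      if (iso_len < rl) next
      s <- sample.int(iso_len - rl + 1L, 1L)
      lay <- read_layout_to_cigar(blocks, s, rl)
      qname <- sprintf("%s_r%04d", tr$gene_id, i)
      seq_read <- spliced_read_seq(fixture$genome[[tr$chrom]], blocks, s, rl)
      if (spec$error_rate > 0) seq_read <- mutate_bases(seq_read, spec$error_rate)
      sam <- c(sam, sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNH:i:1",
                            qname, tr$chrom, lay$pos, lay$cigar, seq_read))
      reads[[length(reads) + 1L]] <- data.frame(
        qname = qname, gene_id = tr$gene_id, chrom = tr$chrom,
        isoform = paste0(tr$gene_id, "|", key), offset = s,
        read_len = rl, stringsAsFactors = FALSE)
    }
  }
  list(sam = c(header, sam),
       reads = if (length(reads)) do.call(rbind, reads) else NULL,
       isoforms = isoforms)
}

spliced_read_seq <- function(chrom_seq, blocks, s, rl) {
  widths <- blocks[, "end"] - blocks[, "start"] + 1L
  cum <- cumsum(c(0L, widths))
  e <- s + rl - 1L
  out <- character(0)
  for (k in seq_len(nrow(blocks))) {
    lo <- max(s, cum[k] + 1L); hi <- min(e, cum[k + 1L])
    if (lo > hi) next
    out <- c(out, substr(chrom_seq, blocks[k, "start"] + (lo - cum[k] - 1L),
                         blocks[k, "start"] + (hi - cum[k] - 1L)))
  }
  paste(out, collapse = "")
}

mutate_bases <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES4, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Mutate a microexon-tag into a cross-species homolog family
#'
#' Synonymous-biased point mutations (third codon positions are hit four
#' times as often as first/second) at mean per-site rate `rate`; mutations
#' creating an in-frame stop codon are reverted, so frame, length and
#' microexon size are always preserved.
#'
#' @param tag one-row tag data.frame (see [extract_microexon_tag()]).
#' @param n_species number of homolog copies to derive.
#' @param rate mean per-site mutation rate in `[0, 0.3]`.
#' @param seed RNG seed.
#' @param species_names optional names (default `sp01..`).
#' @return data.frame of `n_species` tags.
#' @export
mutate_homologs <- function(tag, n_species, rate, seed = 1L,
                            species_names = NULL) {
  stopifnot(rate >= 0, rate <= 0.3, nrow(tag) == 1L)
  if (is.null(species_names)) species_names <- sprintf("sp%02d", seq_len(n_species))
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_species), function(s) {
      ch <- strsplit(tag$dna, "")[[1L]]
      w <- rep(c(0.5, 0.5, 2), length.out = length(ch)) * rate
      hit <- which(stats::runif(length(ch)) < w)
      for (i in hit) {
        old <- ch[i]
        ch[i] <- sample(setdiff(DNA_BASES4, old), 1L)
        cod <- (i - 1L) %/% 3L
        codon <- paste(ch[(3L * cod + 1L):(3L * cod + 3L)], collapse = "")
        if (codon %in% STOP_CODONS) ch[i] <- old
      }
      dna <- paste(ch, collapse = "")
      data.frame(species = species_names[s], gene_id = tag$gene_id,
                 transcript_id = tag$transcript_id, dna = dna,
                 peptide = translate_dna(dna), me_size = tag$me_size,
                 me_phase = tag$me_phase, me_offset = tag$me_offset,
                 boundaries = I(tag$boundaries), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Embed tag sequences as genomic loci
#'
#' Plants each tag into a random background chromosome, either with
#' canonical introns around the microexon part (a true microexon locus) or
#' contiguously (introns lost, merged into one long exon). One chromosome
#' per tag.
#'
#' @param dnas character vector of tag DNA sequences (equal length).
#' @param me_offset,me_size microexon window within the tags (nt before /
#'   width).
#' @param intron_len length of the inserted introns.
#' @param merged logical (recycled): embed without introns.
#' @param flank_bg background length on each side.
#' @param gc background GC content.
#' @param seed RNG seed.
#' @param donor splice donor dinucleotide.
#' @return list with `genome` (named character) and `truth` (data.frame of
#'   the embedded microexon coordinates; NA for merged loci).
#' @export
embed_tag_loci <- function(dnas, me_offset, me_size, intron_len = 100L,
                           merged = FALSE, flank_bg = 1500L, gc = 0.36,
                           seed = 1L, donor = "GT") {
  merged <- rep_len(merged, length(dnas))
  me_offset <- as.integer(me_offset); me_size <- as.integer(me_size)
  intron_len <- as.integer(intron_len); flank_bg <- as.integer(flank_bg)
  withr::with_seed(seed, {
    genome <- character(0)
    truth <- list()
    for (i in seq_along(dnas)) {
      p5 <- substr(dnas[i], 1L, me_offset)
      me <- substr(dnas[i], me_offset + 1L, me_offset + me_size)
      p3 <- substr(dnas[i], me_offset + me_size + 1L, nchar(dnas[i]))
      bg1 <- random_dna(flank_bg, gc); bg2 <- random_dna(flank_bg, gc)
      if (merged[i]) {
        seqs <- paste0(bg1, dnas[i], bg2)
        me_start <- NA_integer_
      } else {
        seqs <- paste0(bg1, p5, random_intron(intron_len, gc, donor), me,
                       random_intron(intron_len, gc, donor), p3, bg2)
        me_start <- flank_bg + me_offset + intron_len + 1L
      }
      nm <- sprintf("tig%02d", i)
      genome[nm] <- seqs
      truth[[i]] <- data.frame(chrom = nm, merged = merged[i],
                               me_start = me_start,
                               me_end = if (is.na(me_start)) NA_integer_ else
                                 me_start + me_size - 1L,
                               stringsAsFactors = FALSE)
    }
    list(genome = genome, truth = do.call(rbind, truth))
  })
}
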