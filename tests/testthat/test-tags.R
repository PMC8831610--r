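test_that("longest-ORF finding matches a brute-force scan and applies the tie rule", {
  orf <- find_longest_orf("AAATGGCCTAAGG", min_len = 9L)
  expect_identical(orf, list(start = 3L, end = 11L))

  # two equal-length ORFs: 5'-most kept
  seq2 <- "ATGAAATAACCCATGCCCTAA"
  orf2 <- find_longest_orf(seq2, min_len = 9L)
  expect_identical(orf2$start, 1L)

  expect_null(find_longest_orf("CCCCCCCCCCCC"))

  set.seed(71)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    got <- find_longest_orf(s)
    want <- oracle_longest_orf(s)
    if (is.null(want)) expect_null(got)
    else {
      expect_identical(got$start, want$start)
      expect_identical(got$end, want$end)
    }
  }
})

test_that("phase is the CDS offset mod 3, validated on the AP2 VYLG worked case", {
  expect_identical(microexon_phase(1), 0L)    # codon boundary
  expect_identical(microexon_phase(4), 0L)
  expect_identical(microexon_phase(5), 1L)
  expect_identical(microexon_phase(6), 2L)

  # AP2-type 9-nt phase-1 microexon: with one nt 5' and two nt 3' it reads VYLG
  cds <- paste0("ATG", "GTTTACCTTGGC", "GATTGA")
  expect_identical(microexon_phase(5), 1L)
  expect_identical(translate_dna(substr(cds, 4, 15)), "VYLG")
  tag <- extract_microexon_tag(cds, 5, 9, tag_len = 12L)
  expect_identical(tag$me_phase, 1L)
  expect_true(grepl("VYLG", tag$peptide))

  # invertase-type 9-nt phase-1 microexon encodes D-P-N/D-G/A
  cds2 <- paste0("ATG", "GATCCAAATGCA", "AAATAA")
  tag2 <- extract_microexon_tag(cds2, 5, 9, tag_len = 12L)
  expect_identical(tag2$me_phase, 1L)
  expect_true(grepl("DP[ND][GA]", tag2$peptide))
})

test_that("tag windows are centred, in frame, and truncated at ORF ends", {
  set.seed(72)
  long_cds <- paste0("ATG", paste(sample(c("GCA", "GAA", "TGG", "CCT"), 120,
                                         replace = TRUE), collapse = ""), "TAA")
  # 9-nt microexon at a deep phase-0 position
  tag <- extract_microexon_tag(long_cds, 181, 9, exon_boundaries = c(180L, 189L))
  expect_identical(nchar(tag$dna), 108L)
  expect_identical(nchar(tag$peptide), 36L)
  expect_identical(nchar(tag$dna) %% 3L, 0L)
  expect_false(grepl("\\*", substr(tag$peptide, 1, 35)))
  expect_identical(tag$boundaries[[1]],
                   c(180L, 189L) - (181L - 1L - tag$me_offset))

  # microexon 30 nt after the start codon: truncated but in frame
  tag2 <- extract_microexon_tag(long_cds, 31, 9)
  expect_lt(nchar(tag2$dna), 108L)
  expect_identical(nchar(tag2$dna) %% 3L, 0L)
  expect_identical(substr(tag2$dna, tag2$me_offset + 1, tag2$me_offset + 9),
                   substr(long_cds, 31, 39))

  # short flanking exons: four junctions recorded inside the window
  tag3 <- extract_microexon_tag(long_cds, 181, 9,
                                exon_boundaries = c(150L, 180L, 190L, 220L))
  expect_identical(length(tag3$boundaries[[1]]), 4L)
})

test_that("phase 1 and 2 windows shift by one nucleotide to stay in frame", {
  set.seed(73)
  cds <- paste0("ATG", paste(sample(c("GCA", "GAA", "TGG", "CCT"), 120,
                                    replace = TRUE), collapse = ""), "TAA")
  for (start in c(181L, 182L, 183L)) {
    tag <- extract_microexon_tag(cds, start, 9)
    expect_identical(nchar(tag$dna) %% 3L, 0L)
    expect_identical(tag$me_phase, (start - 1L) %% 3L)
    # the window lands on a codon boundary of the CDS
    win_start0 <- (start - 1L) - tag$me_offset
    expect_identical(win_start0 %% 3L, 0L)
    # microexon content is preserved verbatim
    expect_identical(substr(tag$dna, tag$me_offset + 1, tag$me_offset + 9),
                     substr(cds, start, start + 8))
  }
})

test_that("clustering groups by size and phase, enforces the score cutoff and species minimum", {
  base <- "MSTELLARVYLGHQWKDENPFRAGILKVMSTQRCDE"
  other <- "WWWWPPPPGGGGCCCCHHHHKKKKDDDDEEEEFFFF"
  mk <- function(pep, sp, size, phase, id) {
    data.frame(species = sp, gene_id = id, transcript_id = id,
               dna = strrep("ACG", nchar(pep)), peptide = pep,
               me_size = size, me_phase = phase, me_offset = 49L,
               boundaries = I(list(c(49L, 58L))), stringsAsFactors = FALSE)
  }
  tags <- rbind(mk(base, "sp1", 9, 1, "a"), mk(base, "sp2", 9, 1, "b"),
                mk(base, "sp3", 9, 1, "c"), mk(base, "sp4", 9, 1, "d"),
                mk(other, "sp1", 9, 1, "e"), mk(other, "sp2", 9, 1, "f"),
                mk(other, "sp3", 9, 1, "g"),
                mk(base, "sp1", 4, 0, "h"), mk(base, "sp2", 4, 0, "i"))
  cl <- cluster_tags(tags)
  # the two unrelated 9/1 peptide sets separate; the 4/0 pair fails min_species
  expect_length(cl, 2L)
  peps <- lapply(cl, function(x) unique(x$tags$peptide))
  expect_true(all(lengths(peps) == 1L))
  expect_setequal(unlist(peps), c(base, other))
  for (x in cl) {
    expect_identical(x$me_size, 9L)
    expect_identical(x$me_phase, 1L)
    expect_gte(length(x$species), 3L)
  }

  # independent check: between-set alignment scores sit below the cutoff
  data("BLOSUM62", package = "Biostrings", envir = environment())
  cross <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(base), Biostrings::AAString(other), type = "global",
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
  expect_lt(cross, 50)
})

test_that("clustering is invariant to input order and homogeneous in size/phase", {
  fx <- generate_genome(fixture_spec(seed = 51, n_genes = 2, me_sizes = c(9, 4),
                                     me_phases = c(1, 2)))
  tags <- tags_from_gene_models(fx$transcripts, fx$genome,
                                data.frame(chrom = fx$truth$chrom,
                                           start = fx$truth$me_start,
                                           end = fx$truth$me_end))
  fam <- rbind(mutate_homologs(tags[1, ], 4, 0.1, seed = 52),
               mutate_homologs(tags[2, ], 4, 0.1, seed = 53))
  cl1 <- cluster_tags(fam)
  cl2 <- cluster_tags(fam[rev(seq_len(nrow(fam))), ])
  expect_identical(length(cl1), length(cl2))
  key <- function(cl) sort(vapply(cl, function(x) paste(sort(x$tags$dna), collapse = "|"), ""))
  expect_identical(key(cl1), key(cl2))
})

test_that("mutated tag families re-cluster into their planted families exactly", {
  fx <- generate_genome(fixture_spec(seed = 55, n_genes = 3, me_sizes = c(9, 9, 5),
                                     me_phases = c(1, 1, 0)))
  tags <- tags_from_gene_models(fx$transcripts, fx$genome,
                                data.frame(chrom = fx$truth$chrom,
                                           start = fx$truth$me_start,
                                           end = fx$truth$me_end))
  fams <- lapply(1:3, function(i) {
    f <- mutate_homologs(tags[i, ], 5, 0.15, seed = 60 + i)
    f$gene_id <- paste0("fam", i)
    f
  })
  cl <- cluster_tags(do.call(rbind, fams))
  expect_length(cl, 3L)
  for (x in cl) expect_length(unique(x$tags$gene_id), 1L)
})

test_that("homolog filtering removes in-frame stops, short fragments and duplicates", {
  fx <- generate_genome(fixture_spec(seed = 57, n_genes = 1, me_sizes = 9, me_phases = 0))
  tags <- tags_from_gene_models(fx$transcripts, fx$genome,
                                data.frame(chrom = fx$truth$chrom,
                                           start = fx$truth$me_start,
                                           end = fx$truth$me_end))
  fam <- mutate_homologs(tags, 4, 0.05, seed = 58)
  cl <- cluster_tags(fam)[[1]]
  good <- fam$dna[1]
  stopper <- paste0("TAA", substr(good, 4, 108))
  short <- substr(good, 1, 90)
  out <- filter_homolog_sequences(c(stopper, short, good, good), cl)
  expect_false(stopper %in% out)
  expect_false(short %in% out)
  expect_identical(sum(out == good), 1L)
  expect_identical(anyDuplicated(out), 0L)
})

test_that("motif assignment honors the 5-aa window and the smallest E-value", {
  hits <- data.frame(motif = c("AP2", "Gelsolin"), start = c(20L, 18L),
                     end = c(60L, 70L), evalue = c(1e-30, 1e-5),
                     stringsAsFactors = FALSE)
  # residues 3 aa upstream of the AP2 start: assigned
  got <- assign_protein_motif(17, 19, hits[1, , drop = FALSE])
  expect_identical(got$motif, "AP2")
  # residues 6 aa away: not assigned
  expect_null(assign_protein_motif(10, 14, hits[1, , drop = FALSE]))
  # overlap with both: smallest E-value wins
  both <- assign_protein_motif(30, 33, hits)
  expect_identical(both$motif, "AP2")
})
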