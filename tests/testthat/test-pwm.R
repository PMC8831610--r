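test_that("PWM probabilities use the 0.25 pseudocount and log-odds a uniform background", {
  pwm <- build_pwm(c("AAG", "AAT", "ACG", "AAT"))
  # column 1: A count 4 -> (4 + 0.25) / (4 + 1) = 0.85
  expect_equal(unname(pwm$prob["A", 1]), 0.85)
  expect_equal(unname(colSums(pwm$prob)), rep(1, 3))
  # column 2: A 3, C 1 -> checks the general formula
  expect_equal(unname(pwm$prob["C", 2]), 1.25 / 5)
  expect_equal(unname(pwm$logodds["A", 1]), log2(0.85 / 0.25))

  # perfectly uniform column scores 0 for every base
  u <- build_pwm(c("A", "C", "G", "T"))
  expect_equal(unname(u$logodds[, 1]), rep(0, 4))

  expect_error(build_pwm("ACGT"), "at least 2")
  expect_warning(build_pwm(c("AN", "AC", "AG")), "dropped")
})

test_that("splitting slices the matrix at boundaries and locates the microexon part", {
  seqs <- replicate(3, paste(sample(c("A", "C", "G", "T"), 108, replace = TRUE),
                             collapse = ""))
  pwm <- build_pwm(seqs)
  sp <- split_pwm(pwm, boundaries = c(50L, 59L), me_offset = 50L, me_size = 9L)
  expect_identical(vapply(sp$parts, `[[`, 1L, "width"), c(50L, 9L, 49L))
  expect_identical(vapply(sp$parts, `[[`, "", "role"),
                   c("flank5", "microexon", "flank3"))
  expect_identical(sp$me_part, 2L)

  # five-exon tag structure -> five parts
  sp5 <- split_pwm(pwm, boundaries = c(20L, 50L, 59L, 90L), me_offset = 50L,
                   me_size = 9L)
  expect_length(sp5$parts, 5L)

  expect_error(split_pwm(pwm, boundaries = c(0L, 59L), me_offset = 0L,
                         me_size = 59L), "strictly inside")
  expect_error(split_pwm(pwm, boundaries = c(40L, 59L), me_offset = 50L,
                         me_size = 9L), "delimited")
})

test_that("sliding part scores agree with the Biostrings per-window oracle", {
  set.seed(81)
  seqs <- replicate(6, paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                             collapse = ""))
  pwm <- build_pwm(seqs)
  target <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  code <- match(strsplit(target, "")[[1]], c("A", "C", "G", "T"))
  got <- mekit:::part_scores(code, pwm$logodds)
  want <- oracle_pwm_score(pwm$logodds, target, seq_along(got))
  expect_equal(got, unname(want), tolerance = 1e-8)
})

# shared scan fixture: a mutated 9-nt phase-1 family embedded as loci
make_scan_cluster <- function(seed = 91, n_species = 6, rate = 0.08) {
  fx <- generate_genome(fixture_spec(seed = seed, n_genes = 1, me_sizes = 9,
                                     me_phases = 1))
  tags <- tags_from_gene_models(fx$transcripts, fx$genome,
                                data.frame(chrom = fx$truth$chrom,
                                           start = fx$truth$me_start,
                                           end = fx$truth$me_end))
  fam <- mutate_homologs(tags, n_species, rate, seed = seed + 1)
  cl <- cluster_tags(fam)[[1]]
  list(cluster = cl, spwm = cluster_split_pwm(cl), fam = fam)
}

test_that("scanning recovers embedded training loci and classifies intron presence", {
  sc <- make_scan_cluster()
  cl <- sc$cluster
  emb <- embed_tag_loci(cl$tags$dna, cl$canonical_me_offset, cl$me_size,
                        intron_len = 100, merged = FALSE, seed = 92)
  hits <- scan_and_assemble(emb$genome, sc$spwm)
  expect_gte(nrow(hits), length(cl$tags$dna) * 0.9)
  expect_true(all(hits$classification == "microexon"))
  # microexon part width preserved at every hit
  for (i in seq_len(nrow(hits))) {
    p <- hits$parts[[i]][sc$spwm$me_part, , drop = FALSE]
    expect_identical(unname(p[, "end"] - p[, "start"] + 1L), cl$me_size)
  }
  # predicted microexon matches the embedded coordinates
  idx <- match(hits$chrom, emb$truth$chrom)
  for (i in seq_len(nrow(hits))) {
    p <- hits$parts[[i]][sc$spwm$me_part, , drop = FALSE]
    expect_identical(unname(p[, "start"]), as.integer(emb$truth$me_start[idx[i]]))
  }

  # intron-deleted (contiguous) variants are merged, not microexons
  emb2 <- embed_tag_loci(cl$tags$dna, cl$canonical_me_offset, cl$me_size,
                         merged = TRUE, seed = 93)
  hits2 <- scan_and_assemble(emb2$genome, sc$spwm)
  expect_gte(nrow(hits2), 1L)
  expect_true(all(hits2$classification == "merged"))
})

test_that("intron gaps must be canonical and within bounds", {
  sc <- make_scan_cluster(seed = 95)
  cl <- sc$cluster
  dna <- cl$tags$dna[1]
  off <- cl$canonical_me_offset
  p5 <- substr(dna, 1, off)
  me <- substr(dna, off + 1, off + cl$me_size)
  p3 <- substr(dna, off + cl$me_size + 1, nchar(dna))
  bad_intron <- function(len, donor = "GT", acceptor = "AG")
    paste0(donor, strrep("C", len - 4), acceptor)
  mk_genome <- function(i1, i2)
    c(t1 = paste0(strrep("A", 800), p5, i1, me, i2, p3, strrep("A", 800)))
  # 19-nt intron: below the floor -> no full-model microexon call
  h <- scan_and_assemble(mk_genome(bad_intron(19), bad_intron(100)), sc$spwm,
                         allow_partial = FALSE)
  expect_false(any(h$classification == "microexon"))
  # non-canonical donor AT: rejected
  h2 <- scan_and_assemble(mk_genome(bad_intron(100, donor = "AT"), bad_intron(100)),
                          sc$spwm, allow_partial = FALSE)
  expect_false(any(h2$classification == "microexon"))
  # control: both canonical and in range
  h3 <- scan_and_assemble(mk_genome(bad_intron(100), bad_intron(100)), sc$spwm,
                          allow_partial = FALSE)
  expect_true(any(h3$classification == "microexon"))
})

test_that("scanning is strand symmetric and score-threshold monotone", {
  sc <- make_scan_cluster(seed = 97, n_species = 4)
  cl <- sc$cluster
  emb <- embed_tag_loci(cl$tags$dna[1:2], cl$canonical_me_offset, cl$me_size,
                        intron_len = 80, seed = 98)
  fwd <- scan_and_assemble(emb$genome, sc$spwm)
  rcg <- vapply(emb$genome, revcomp, "")
  rev <- scan_and_assemble(rcg, sc$spwm)
  expect_identical(nrow(fwd), nrow(rev))
  expect_true(all(fwd$strand == "+"))
  expect_true(all(rev$strand == "-"))
  L <- nchar(emb$genome)[match(rev$chrom, names(emb$genome))]
  expect_identical(sort(unname(L) - rev$end + 1L), sort(fwd$start))
  expect_equal(sort(rev$score), sort(fwd$score))

  # lowering the threshold never removes a hit locus
  lo <- scan_and_assemble(emb$genome, sc$spwm, min_score_frac = 0.7)
  key <- function(h) paste(h$chrom, h$strand, h$start)
  expect_true(all(key(fwd) %in% key(lo)))
})

test_that("microexon rates are the microexon fraction of informative hits", {
  hits <- data.frame(
    cluster_id = c(1, 1, 1, 1, 2, 2, 3),
    species = c("pper", "pper", "atha", "atha", "pper", "pper", "pper"),
    classification = c("microexon", "merged", "microexon", "microexon",
                       "merged", "merged", "partial"))
  r <- summarize_rates(hits)
  expect_equal(r["1", "pper"], 0.5)
  expect_equal(r["1", "atha"], 1.0)
  expect_equal(r["2", "pper"], 0.0)
  expect_true(is.na(r["3", "pper"]))     # only a partial hit: tag not found
  expect_true(is.na(r["2", "atha"]))
})
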