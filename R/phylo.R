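# Consensus strings per cluster per species and the concatenated supermatrix
# (with '-' for missing clusters) used as input for tree inference.

#' Per-site majority consensus of equal-length DNA strings
#'
#' Ties are broken in fixed base order A < C < G < T; N is ignored for
#' frequency counting (an all-N column yields N).
#'
#' @param seqs character vector of equal-length DNA strings.
#' @return single consensus string.
#' @export
consensus_string <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must have equal length")
  if (length(seqs) == 1L) return(toupper(seqs))
  chars <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(seqs),
                  byrow = TRUE)
  out <- vapply(seq_len(w), function(j) {
    cnt <- tabulate(match(chars[, j], DNA_BASES4), 4L)
    if (all(cnt == 0L)) return("N")
    DNA_BASES4[which.max(cnt)]
  }, "")
  paste(out, collapse = "")
}

#' Build a concatenated consensus supermatrix
#'
#' Per-cluster consensus strings are concatenated end-to-end in ascending
#' cluster id order; a species missing a cluster receives `-` across that
#' block, so all rows have equal length.
#'
#' @param consensus_by_cluster named list (cluster id -> named character
#'   vector of per-species consensus strings).
#' @return a `mek_supermatrix`: list with `species`, `cluster_ids`, `widths`
#'   and `alignment` (named character vector).
#' @export
build_supermatrix <- function(consensus_by_cluster) {
  if (length(consensus_by_cluster) == 0L) stop("no clusters provided")
  ids <- names(consensus_by_cluster)
  if (is.null(ids)) ids <- as.character(seq_along(consensus_by_cluster))
  num <- suppressWarnings(as.numeric(ids))
  ord <- if (!anyNA(num)) order(num) else order(ids)
  consensus_by_cluster <- consensus_by_cluster[ord]
  ids <- ids[ord]
  widths <- vapply(consensus_by_cluster, function(x) {
    w <- unique(nchar(x))
    if (length(w) != 1L) stop("unequal consensus lengths within a cluster")
    w
  }, 1L)
  species <- sort(unique(unlist(lapply(consensus_by_cluster, names))))
  if (length(species) == 0L) stop("consensus vectors must be named by species")
  rows <- vapply(species, function(sp) {
    paste(vapply(seq_along(ids), function(k) {
      blk <- consensus_by_cluster[[k]]
      if (sp %in% names(blk)) blk[[sp]] else strrep("-", widths[k])
    }, ""), collapse = "")
  }, "")
  structure(list(species = species, cluster_ids = ids,
                 widths = unname(widths), alignment = rows),
            class = "mek_supermatrix")
}

#' @export
print.mek_supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d species x %d sites (%d cluster blocks)\n",
              length(x$species), nchar(x$alignment[[1L]]), length(x$widths)))
  invisible(x)
}

#' Write a supermatrix as FASTA, relaxed PHYLIP, or a partition file
#'
#' @param sm `mek_supermatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_supermatrix_fasta <- function(sm, path) {
  write_fasta(sm$alignment, path)
}

#' @rdname write_supermatrix_fasta
#' @export
write_supermatrix_phylip <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$species), nchar(sm$alignment[[1L]])), con)
  writeLines(sprintf("%s  %s", sm$species, sm$alignment), con)
  invisible(path)
}

#' @rdname write_supermatrix_fasta
#' @export
write_supermatrix_partitions <- function(sm, path) {
  ends <- cumsum(sm$widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  writeLines(sprintf("DNA, cluster%s = %d-%d", sm$cluster_ids, starts, ends),
             path)
  invisible(path)
}

#' Read a relaxed-PHYLIP alignment back into a supermatrix row set
#'
#' @param path relaxed PHYLIP file written by [write_supermatrix_phylip()].
#' @return named character vector of aligned rows.
#' @export
read_phylip_rows <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  body <- lines[-1L][nzchar(lines[-1L])]
  parts <- strsplit(trimws(body), "\\s+")
  rows <- vapply(parts, `[[`, "", 2L)
  names(rows) <- vapply(parts, `[[`, "", 1L)
  stopifnot(length(rows) == hdr[1L], all(nchar(rows) == hdr[2L]))
  rows
}
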