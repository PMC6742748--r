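## genome_io: file formats and the shared coordinate / profile data model.
##
## Everything downstream reasons in 1-based inclusive genomic positions on a
## single replicon. bedGraph (0-based half-open) and BED (0-based half-open)
## conventions are converted here and nowhere else. Standard formats are read
## and written through rtracklayer / Biostrings.

PROFILE_LABELS <- c("TAP_PLUS", "TAP_MINUS", "TERMSEQ_R1", "TERMSEQ_R2",
                    "RNASEQ", "RIBOSEQ")

#' Construct a genome object
#'
#' @param sequence nucleotide string over A/C/G/T.
#' @param seqname replicon name (default "chr").
#' @return object of class `tu_genome` with fields `seqname`, `sequence`,
#'   `length`.
#' @export
genome <- function(sequence, seqname = "chr") {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("empty genome sequence", call. = FALSE)
  if (grepl("[^ACGT]", sequence)) {
    stop("genome sequence must contain only A/C/G/T", call. = FALSE)
  }
  structure(
    list(seqname = seqname, sequence = sequence, length = nchar(sequence)),
    class = "tu_genome"
  )
}

#' @export
print.tu_genome <- function(x, ...) {
  cat(sprintf("<tu_genome> %s: %s nt, GC %.1f%%\n", x$seqname, x$length,
              100 * gc_fraction_of(x$sequence)))
  invisible(x)
}

gc_fraction_of <- function(seq) {
  n <- nchar(seq)
  gc <- n - nchar(gsub("[GC]", "", seq))
  gc / n
}

#' Read a genome from FASTA
#'
#' @param path FASTA file with exactly one sequence (single replicon).
#' @return `tu_genome`.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) {
    stop("expected a single-replicon FASTA; got ", length(ss), " sequences",
         call. = FALSE)
  }
  genome(as.character(ss[[1]]), seqname = sub("\\s.*$", "", names(ss)[1]))
}

#' Write a genome to FASTA
#' @param g `tu_genome`.
#' @param path output path.
#' @export
write_genome_fasta <- function(g, path) {
  ss <- Biostrings::DNAStringSet(g$sequence)
  names(ss) <- g$seqname
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' One row per feature of the requested type(s); coordinates are kept 1-based
#' inclusive as in GFF3. Rows are ordered deterministically by
#' (start, gene_id). The gene id is taken from the `ID`, `gene_id` or `Name`
#' attribute, in that order.
#'
#' @param path GFF3 file.
#' @param feature_types GFF3 `type` values to keep (default gene/CDS).
#' @return data.frame with columns `gene_id`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path, feature_types = c("gene", "CDS")) {
  check_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(unique(as.character(GenomicRanges::seqnames(gr)))) > 1L) {
    stop("annotation spans multiple replicons; one replicon per run",
         call. = FALSE)
  }
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L) {
    stop("no features of type ", paste(feature_types, collapse = "/"),
         " in ", path, call. = FALSE)
  }
  meta <- S4Vectors::mcols(gr)
  ids <- NULL
  for (field in c("ID", "gene_id", "Name")) {
    if (field %in% names(meta) && !all(is.na(meta[[field]]))) {
      ids <- as.character(meta[[field]])
      break
    }
  }
  if (is.null(ids)) ids <- paste0("feature_", seq_along(gr))
  genes <- data.frame(
    gene_id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  validate_genes(genes)
}

## Cheap structural pre-check so malformed lines are reported by number;
## rtracklayer's own messages do not always carry the line.
check_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L || is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      stop("malformed GFF3 line ", i, " in ", path, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a gene annotation to GFF3
#'
#' @param genes gene table (`gene_id`, `start`, `end`, `strand`).
#' @param path output path.
#' @param seqname replicon name.
#' @param type feature type to write (default "gene").
#' @export
write_annotation <- function(genes, path, seqname = "chr", type = "gene") {
  genes <- validate_genes(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$source <- "tuarch"
  gr$type <- type
  gr$ID <- genes$gene_id
  gr$Name <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Construct an end profile
#'
#' An end profile is a per-position count vector for one library on one
#' strand of one replicon: position p carries the number of read 5'-ends
#' (dRNA-Seq), read 3'-ends (Term-Seq) or the coverage depth (RNA-Seq /
#' Ribo-Seq) mapped there. Absent positions are zero.
#'
#' @param genome_length replicon length in nt.
#' @param strand "+" or "-".
#' @param label library label, one of `TAP_PLUS`, `TAP_MINUS`, `TERMSEQ_R1`,
#'   `TERMSEQ_R2`, `RNASEQ`, `RIBOSEQ`.
#' @param positions,counts parallel vectors of 1-based positions and
#'   non-negative integer counts (repeated positions accumulate).
#' @param seqname replicon name.
#' @return object of class `end_profile`.
#' @export
end_profile <- function(genome_length, strand, label,
                        positions = integer(0), counts = integer(0),
                        seqname = "chr") {
  assert_strand(strand)
  label <- match.arg(label, PROFILE_LABELS)
  stopifnot(genome_length >= 1, length(positions) == length(counts))
  if (length(positions) && (min(positions) < 1 ||
                            max(positions) > genome_length)) {
    stop("positions outside [1, genome_length]", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  x <- numeric(genome_length)
  if (length(positions)) {
    acc <- rowsum(as.numeric(counts), positions)
    x[as.integer(rownames(acc))] <- acc[, 1]
  }
  structure(
    list(seqname = seqname, strand = strand, label = label,
         genome_length = as.integer(genome_length), counts = x),
    class = "end_profile"
  )
}

#' @export
print.end_profile <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat(sprintf("<end_profile> %s %s strand %s: %d nt, %d non-zero positions, %g reads\n",
              x$label, x$seqname, x$strand, x$genome_length, nz,
              sum(x$counts)))
  invisible(x)
}

## Positions with count >= 1, as a data.frame(pos, count), ascending.
profile_nonzero <- function(profile) {
  idx <- which(profile$counts > 0)
  data.frame(pos = idx, count = profile$counts[idx])
}

#' Read an end profile from bedGraph
#'
#' bedGraph intervals are 0-based half-open: a line `chr a b v` assigns count
#' `v` to 1-based positions `a+1 .. b`. Values must be non-negative integers,
#' intervals must not overlap and must lie within the replicon. bedGraph
#' carries no strand, so the strand is supplied by the caller (profiles are
#' conventionally stored as a `.plus` / `.minus` file pair).
#'
#' @param path bedGraph file.
#' @param strand "+" or "-".
#' @param label library label (see [end_profile()]).
#' @param genome_length replicon length in nt.
#' @param seqname expected replicon name (checked when the file is non-empty).
#' @return `end_profile`.
#' @export
read_end_profile <- function(path, strand, label, genome_length,
                             seqname = "chr") {
  assert_strand(strand)
  info <- file.info(path)
  if (is.na(info$size)) stop("no such file: ", path, call. = FALSE)
  if (info$size == 0L) {
    return(end_profile(genome_length, strand, label, seqname = seqname))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) {
    return(end_profile(genome_length, strand, label, seqname = seqname))
  }
  sn <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(sn) > 1L) {
    stop("bedGraph spans multiple replicons; one replicon per run",
         call. = FALSE)
  }
  v <- gr$score
  if (any(v < 0)) stop("negative bedGraph value in ", path, call. = FALSE)
  if (any(v != round(v))) {
    stop("non-integer bedGraph value in ", path, call. = FALSE)
  }
  if (max(GenomicRanges::end(gr)) > genome_length) {
    stop("bedGraph interval beyond genome length in ", path, call. = FALSE)
  }
  if (!IRanges::isDisjoint(GenomicRanges::ranges(gr))) {
    stop("overlapping bedGraph intervals in ", path, call. = FALSE)
  }
  x <- numeric(genome_length)
  s <- GenomicRanges::start(gr)  # already converted to 1-based by import
  e <- GenomicRanges::end(gr)
  for (i in seq_along(gr)) x[s[i]:e[i]] <- v[i]
  structure(
    list(seqname = sn, strand = strand, label = label,
         genome_length = as.integer(genome_length), counts = x),
    class = "end_profile"
  )
}

#' Write an end profile to bedGraph
#'
#' Inverse of [read_end_profile()]: maximal runs of equal non-zero counts
#' become 0-based half-open intervals. Zero positions are omitted, so a
#' write/read round trip reproduces the position-to-count map exactly.
#'
#' @param profile `end_profile`.
#' @param path output path.
#' @export
write_end_profile <- function(profile, path) {
  r <- rle(profile$counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0
  if (!any(keep)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = profile$seqname,
    ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
    score = r$values[keep]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write called sites as BED6 + TSV
#'
#' Emits a BED6 file (0-based half-open single-nucleotide intervals, score =
#' read count, strand column) and a companion TSV carrying every record field
#' (category, z-scores, assigned gene, ...). Records must be classified.
#'
#' @param records TSS or TEP record data.frame; must have `pos`, `strand`,
#'   `category` columns. The BED score is `tap_plus` for TSS records and
#'   `count_r1 + count_r2` for TEP records.
#' @param prefix output path prefix; writes `<prefix>.bed` and `<prefix>.tsv`.
#' @param seqname replicon name.
#' @return invisibly, the two paths written.
#' @export
write_sites <- function(records, prefix, seqname = "chr") {
  if (nrow(records) > 0 && ("category" %in% names(records)) &&
      any(is.na(records$category))) {
    stop("refusing to write unclassified records: run classify_tss()/",
         "classify_tep() first", call. = FALSE)
  }
  if (!"category" %in% names(records) && nrow(records) > 0) {
    stop("refusing to write unclassified records (no category column)",
         call. = FALSE)
  }
  score <- if ("tap_plus" %in% names(records)) {
    records$tap_plus
  } else if (all(c("count_r1", "count_r2") %in% names(records))) {
    records$count_r1 + records$count_r2
  } else {
    rep(0, nrow(records))
  }
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  bed <- data.frame(
    chrom = rep(seqname, nrow(records)),
    start = records$pos - 1L,            # 0-based half-open single nt
    end = records$pos,
    name = if (nrow(records)) {
      sprintf("site_%05d", seq_len(nrow(records)))
    } else character(0),
    score = score,
    strand = records$strand,
    stringsAsFactors = FALSE
  )
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (nrow(records) == 0L) {
    # header-only outputs
    writeLines(paste(c("chrom", "start", "end", "name", "score", "strand"),
                     collapse = "\t"), bed_path)
  }
  write.table(records, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Write assembled TUs to GFF3
#'
#' Each TU becomes one `transcription_unit` feature spanning TSS..TEP with
#' `ID`, `category` and comma-joined `genes` attributes.
#'
#' @param tus TU table from [assemble_tus()] / [categorize_tus()].
#' @param path output path.
#' @param seqname replicon name.
#' @export
write_tus <- function(tus, path, seqname = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = tus$start, end = tus$end),
    strand = tus$strand
  )
  gr$source <- "tuarch"
  gr$type <- "transcription_unit"
  gr$ID <- tus$tu_id
  if ("category" %in% names(tus)) gr$category <- tus$category
  if ("genes" %in% names(tus)) {
    gr$genes <- vapply(tus$genes, paste, character(1), collapse = ",")
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
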