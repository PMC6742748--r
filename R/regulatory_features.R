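## regulatory_features: sequence- and expression-level features derived
## from called sites: 5'-UTR lengths and leaderless transcripts, start-codon
## usage, promoter/RBS/terminator sequence windows for external motif and
## folding tools, promoter spacer lengths, nucleotide frequency/enrichment,
## RPKM and translation efficiency.

## Relative window spans (offsets from the site, negative = upstream,
## the site itself = 0), inclusive on both ends.
WINDOW_SPANS <- list(
  minus10      = c(-20L, 1L),    # 22 nt: -10 promoter element search space
  minus35      = c(-40L, -25L),  # 16 nt: -35 promoter element search space
  tep_context  = c(-41L, 20L),   # 62 nt: terminator alignment window
  tep_upstream = c(-41L, -1L)    # 41 nt: folding / stem-structure window
)

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

subseq_at <- function(g, from, to) substr(g$sequence, from, to)

## Oriented window sequence around one site: relative offsets [lo, hi] map
## to genomic [pos+lo, pos+hi] on "+", and to the mirrored, reverse-
## complemented [pos-hi, pos-lo] on "-". NA when truncated by a replicon
## edge.
window_seq <- function(g, pos, strand, lo, hi) {
  if (strand == "+") {
    from <- pos + lo; to <- pos + hi
  } else {
    from <- pos - hi; to <- pos - lo
  }
  if (from < 1L || to > g$length) return(NA_character_)
  s <- subseq_at(g, from, to)
  if (strand == "-") revcomp(s) else s
}

#' Extract sequence windows around called sites
#'
#' Window kinds (relative to the site, inclusive): `minus10` spans -20..+1
#' (22 nt, the -10 element search space), `minus35` spans -40..-25 (16 nt),
#' `tep_context` spans -41..+20 (62 nt, terminator alignment), and
#' `tep_upstream` spans -41..-1 (41 nt, the folding input). Windows are
#' strand-mirrored and reverse-complemented on "-". Sites whose window
#' would be truncated by a replicon edge are dropped with a warning.
#'
#' @param sites data.frame with `pos` and `strand`.
#' @param g [genome()].
#' @param kind one of `"minus10"`, `"minus35"`, `"tep_context"`,
#'   `"tep_upstream"`.
#' @return named [Biostrings::DNAStringSet] (names `<kind>_<pos>_<strand>`).
#' @export
extract_windows <- function(sites, g, kind = names(WINDOW_SPANS)) {
  kind <- match.arg(kind)
  span <- WINDOW_SPANS[[kind]]
  seqs <- vapply(seq_len(nrow(sites)), function(i) {
    window_seq(g, sites$pos[i], sites$strand[i], span[1], span[2])
  }, character(1))
  drop <- is.na(seqs)
  if (any(drop)) {
    warning(sum(drop), " ", kind, " window(s) truncated at genome edge; ",
            "dropped")
  }
  out <- Biostrings::DNAStringSet(seqs[!drop])
  names(out) <- sprintf("%s_%d_%s", kind, sites$pos[!drop],
                        sites$strand[!drop])
  out
}

#' 5'-UTR lengths from primary TSSs
#'
#' The 5'-UTR is the stretch between a gene's primary TSS and its start
#' codon: `utr_length = start_codon_pos - tss_pos` on "+", mirrored on "-".
#' Transcripts with a 5'-UTR of 0-9 nt are leaderless. A TSS downstream of
#' the start codon (possible through the +100 assignment window) records
#' length 0 with `tss_internal = TRUE`.
#'
#' @param primary_tss data.frame `gene_id`, `pos`, `strand` of primary TSSs.
#' @param genes gene table.
#' @param g [genome()], used to report each gene's start codon; `NULL` for
#'   `NA` codons.
#' @param leaderless_max maximum leaderless 5'-UTR length (default 9 nt).
#' @return data.frame `gene_id`, `utr_length`, `leaderless`, `tss_internal`,
#'   `start_codon`.
#' @export
utr_lengths <- function(primary_tss, genes, g = NULL, leaderless_max = 9) {
  genes <- validate_genes(genes)
  idx <- match(primary_tss$gene_id, genes$gene_id)
  if (any(is.na(idx))) stop("primary TSS for unknown gene", call. = FALSE)
  g5 <- gene_5p(genes)[idx]
  raw <- ifelse(primary_tss$strand == "+", g5 - primary_tss$pos,
                primary_tss$pos - g5)
  internal <- raw < 0
  utr <- pmax(raw, 0L)
  codon <- rep(NA_character_, length(idx))
  if (!is.null(g)) {
    codon <- vapply(idx, function(j) {
      if (genes$strand[j] == "+") {
        subseq_at(g, genes$start[j], genes$start[j] + 2L)
      } else {
        revcomp(subseq_at(g, genes$end[j] - 2L, genes$end[j]))
      }
    }, character(1))
  }
  data.frame(gene_id = primary_tss$gene_id, utr_length = as.integer(utr),
             leaderless = utr <= leaderless_max, tss_internal = internal,
             start_codon = codon, stringsAsFactors = FALSE)
}

#' Start-codon usage by 5'-UTR class
#'
#' Tallies each gene's start trinucleotide into leaderless / leadered / all
#' columns. Codons outside the watch list count as "other".
#'
#' @param utr_records [utr_lengths()] output (needs `start_codon`).
#' @param watch codons tallied individually (default ATG/GTG/TTG/CTG).
#' @return data.frame `codon` x columns `leaderless`, `leadered`, `all`.
#' @export
start_codon_tally <- function(utr_records,
                              watch = c("ATG", "GTG", "TTG", "CTG")) {
  stopifnot("start_codon" %in% names(utr_records))
  codon <- ifelse(utr_records$start_codon %in% watch,
                  utr_records$start_codon, "other")
  lvls <- c(watch, "other")
  tally <- function(sel) {
    vapply(lvls, function(cd) sum(codon[sel] == cd), numeric(1))
  }
  out <- data.frame(
    codon = lvls,
    leaderless = tally(utr_records$leaderless),
    leadered = tally(!utr_records$leaderless),
    all = tally(rep(TRUE, nrow(utr_records))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Ribosome-binding-site windows
#'
#' For each gene whose 5'-UTR is longer than `min_utr - 1` nt, extracts the
#' `min(max_len, utr_length)` nt immediately upstream of the start codon
#' (reverse-complemented on "-"), the search space for the RBS motif.
#'
#' @param utr_records [utr_lengths()] output.
#' @param genes gene table.
#' @param g [genome()].
#' @param max_len maximum window length (default 25 nt).
#' @param min_utr minimum 5'-UTR length to qualify (default 11 nt, i.e.
#'   "longer than 10").
#' @return named [Biostrings::DNAStringSet].
#' @export
rbs_windows <- function(utr_records, genes, g, max_len = 25, min_utr = 11) {
  genes <- validate_genes(genes)
  keep <- utr_records$utr_length >= min_utr
  rec <- utr_records[keep, , drop = FALSE]
  idx <- match(rec$gene_id, genes$gene_id)
  seqs <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    j <- idx[i]
    len <- min(max_len, rec$utr_length[i])
    if (genes$strand[j] == "+") {
      seqs[i] <- subseq_at(g, genes$start[j] - len, genes$start[j] - 1L)
    } else {
      seqs[i] <- revcomp(subseq_at(g, genes$end[j] + 1L, genes$end[j] + len))
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- rec$gene_id
  out
}

#' Spacer length between promoter elements
#'
#' Number of nucleotides strictly between the 3' end of the -35 element and
#' the 5' end of the -10 element, given their genomic occurrence intervals
#' on the TSS strand. Overlapping or abutting elements give spacer 0 (with
#' a warning when they overlap).
#'
#' @param minus35,minus10 length-2 vectors `c(start, end)` of genomic
#'   occurrence intervals (start <= end).
#' @param strand "+" or "-".
#' @return integer spacer length (nt).
#' @export
#' @examples
#' # TSS-relative -35 at [-34,-31], -10 at [-12,-7] on "+" at TSS 1000:
#' spacer_length(c(966, 969), c(988, 993), "+")  # 18
spacer_length <- function(minus35, minus10, strand) {
  assert_strand(strand)
  stopifnot(minus35[1] <= minus35[2], minus10[1] <= minus10[2])
  sp <- if (strand == "+") minus10[1] - minus35[2] - 1L
        else minus35[1] - minus10[2] - 1L
  if (sp < 0L) {
    warning("overlapping promoter elements; spacer reported as 0")
    sp <- 0L
  }
  as.integer(sp)
}

#' Per-position nucleotide frequency and enrichment around sites
#'
#' Computes the base frequency at each relative offset around a site set,
#' and the enrichment of those frequencies over a seeded random draw of
#' intergenic background positions (positions inside no gene on either
#' strand), matched offset for offset:
#' `enrichment = site_frequency / background_frequency`.
#'
#' @param sites data.frame `pos`, `strand`.
#' @param g [genome()].
#' @param genes gene table (defines intergenic space for the background).
#' @param offsets `c(lo, hi)` relative window (default -20..+10).
#' @param n_background background sample size (default 1000).
#' @param seed RNG seed for the background draw.
#' @return list with matrices `frequency`, `background` and `enrichment`
#'   (rows = offsets, columns = A/C/G/T).
#' @export
nucleotide_stats <- function(sites, g, genes, offsets = c(-20L, 10L),
                             n_background = 1000L, seed = 1L) {
  genes <- validate_genes(genes)
  freq_matrix <- function(df) {
    mats <- lapply(seq_len(nrow(df)), function(i) {
      s <- window_seq(g, df$pos[i], df$strand[i], offsets[1], offsets[2])
      if (is.na(s)) return(NULL)
      strsplit(s, "")[[1]]
    })
    mats <- Filter(Negate(is.null), mats)
    if (length(mats) == 0L) stop("no usable windows", call. = FALSE)
    chars <- do.call(rbind, mats)
    t(apply(chars, 2, function(col) {
      vapply(c("A", "C", "G", "T"), function(b) mean(col == b), numeric(1))
    }))
  }
  site_f <- freq_matrix(sites)

  covered <- logical(g$length)
  for (i in seq_len(nrow(genes))) covered[genes$start[i]:genes$end[i]] <- TRUE
  pool <- which(!covered)
  margin <- max(abs(offsets))
  pool <- pool[pool > margin & pool <= g$length - margin]
  if (length(pool) == 0L) stop("no intergenic background available",
                               call. = FALSE)
  set.seed(seed)
  bg <- data.frame(
    pos = sample(pool, n_background, replace = TRUE),
    strand = sample(STRANDS, n_background, replace = TRUE)
  )
  bg_f <- freq_matrix(bg)
  rn <- sprintf("%+d", offsets[1]:offsets[2])
  rownames(site_f) <- rownames(bg_f) <- rn
  list(frequency = site_f, background = bg_f,
       enrichment = site_f / bg_f)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (gene_length/1000) / (total_mapped/1e6)`; vectorised over
#' genes.
#'
#' @param count mapped reads per gene.
#' @param gene_length gene length (nt).
#' @param total_mapped total mapped reads of the library.
#' @return numeric RPKM values.
#' @export
rpkm <- function(count, gene_length, total_mapped) {
  stopifnot(all(gene_length > 0), total_mapped > 0)
  count / (gene_length / 1000) / (total_mapped / 1e6)
}

#' Translation efficiency
#'
#' The ratio of a gene's Ribo-Seq RPKM to its RNA-Seq RPKM. Undefined
#' (returned as `NA`) when the RNA-Seq RPKM is zero.
#'
#' @param rpkm_ribo,rpkm_rna RPKM vectors.
#' @return numeric TE values with `NA` where `rpkm_rna == 0`.
#' @export
translation_efficiency <- function(rpkm_ribo, rpkm_rna) {
  ifelse(rpkm_rna > 0, rpkm_ribo / rpkm_rna, NA_real_)
}

#' Approximate per-gene read counts from a coverage profile
#'
#' Inputs here are per-position coverage depths, not read lists, so the
#' read count over a CDS is estimated as the summed depth divided by the
#' read length.
#'
#' @param coverage list with `plus`/`minus` coverage [end_profile()]s.
#' @param genes gene table.
#' @param read_length library read length (default 50 nt).
#' @return numeric vector of estimated counts, one per gene row.
#' @export
coverage_read_count <- function(coverage, genes, read_length = 50) {
  genes <- validate_genes(genes)
  vapply(seq_len(nrow(genes)), function(i) {
    prof <- coverage[[if (genes$strand[i] == "+") "plus" else "minus"]]
    sum(prof$counts[genes$start[i]:genes$end[i]]) / read_length
  }, numeric(1))
}

#' Per-gene expression table: RPKM and translation efficiency
#'
#' Estimates per-gene read counts from RNA-Seq and Ribo-Seq coverage,
#' converts to RPKM and derives TE. Library totals default to the summed
#' per-gene counts of each library; pass explicit totals to normalise
#' against full library sizes instead.
#'
#' @param genes gene table.
#' @param rnaseq,riboseq `plus`/`minus` coverage profile pairs.
#' @param read_length read length for depth-to-count conversion (default 50).
#' @param total_rna,total_ribo optional explicit library totals (reads).
#' @return data.frame `gene_id`, `count_rna`, `count_ribo`, `rpkm_rna`,
#'   `rpkm_ribo`, `te`. Note the sorted gene order of [validate_genes()].
#' @export
expression_table <- function(genes, rnaseq, riboseq, read_length = 50,
                             total_rna = NULL, total_ribo = NULL) {
  genes <- validate_genes(genes)
  cnt_rna <- coverage_read_count(rnaseq, genes, read_length)
  cnt_ribo <- coverage_read_count(riboseq, genes, read_length)
  total_rna <- total_rna %||% sum(cnt_rna)
  total_ribo <- total_ribo %||% sum(cnt_ribo)
  len <- genes$end - genes$start + 1L
  r_rna <- rpkm(cnt_rna, len, total_rna)
  r_ribo <- rpkm(cnt_ribo, len, total_ribo)
  data.frame(gene_id = genes$gene_id, count_rna = cnt_rna,
             count_ribo = cnt_ribo, rpkm_rna = r_rna, rpkm_ribo = r_ribo,
             te = translation_efficiency(r_ribo, r_rna),
             stringsAsFactors = FALSE)
}
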