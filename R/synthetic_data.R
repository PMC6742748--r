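## synthetic_data: ground-truth TU architectures and the six profile types.
##
## The generator plants "operon blocks": runs of same-strand genes whose
## internal intergenic gaps are <= 500 nt (candidate poly-cistronic TUs),
## separated by gaps > 500 nt. Each block is one TU with one TSS (at the
## start codon for leaderless TUs, otherwise 10-300 nt upstream) and one TEP
## 20-200 nt past the last stop codon. Profiles then emulate what the
## callers exploit: TAP(+) peaks at TSSs with only thinned TAP(-) signal,
## full-strength TAP(-) peaks at processed 5' ends, independent replicate
## Term-Seq peaks at TEPs, plateau RNA-Seq coverage over TU spans, and
## Ribo-Seq densities scaled by a per-gene translation-efficiency factor.

#' Simulation configuration
#'
#' Defaults describe a high-GC actinobacterial regime: GC 0.72, ~20%
#' leaderless TUs, 5'-UTRs of 10-300 nt, TEPs 20-200 nt past the stop codon,
#' peak means of 10 reads, 1-nt peak jitter and a background of 0.01 reads
#' per nt.
#'
#' @param seed integer RNG seed; the full dataset is a deterministic function
#'   of (seed, config).
#' @param n_genes number of genes to plant.
#' @param genome_length replicon length in nt, or `NULL` to size the replicon
#'   to fit the planted genes plus margins.
#' @param gc_fraction genomic GC content in `[0,1]`.
#' @param gene_length_range min/max gene length (nt).
#' @param short_gap_range intergenic gap range (nt) inside an operon block;
#'   must stay <= 500 so block members remain one TU.
#' @param long_gap_range gap range (nt) between blocks; must exceed 500.
#' @param block_size_probs named numeric vector of block-size probabilities
#'   (names "1","2",...); controls the mono/poly-cistronic mixture.
#' @param leaderless_fraction fraction of TUs whose TSS sits exactly on the
#'   start codon (5'-UTR length 0).
#' @param utr_range 5'-UTR length range (nt) for leadered TUs.
#' @param tep_offset_range distance range (nt) from last stop codon to TEP.
#' @param tss_peak_count_mean,tep_peak_count_mean mean reads per planted
#'   TSS / TEP peak (per library or replicate).
#' @param peak_jitter_sd SD (nt) of the integer Gaussian jitter applied to
#'   each dRNA-Seq 5'-end peak read (TSSs and processed sites); Term-Seq
#'   3'-end peaks are exact ligation points and are never jittered.
#' @param background_rate expected background reads per nt per library.
#' @param tap_minus_processed_site_rate processed 5'-end sites per kb per
#'   strand; these peak with equal mean in both TAP libraries.
#' @param tap_minus_thinning probability that a TAP(+) read at a true TSS
#'   also appears in the TAP(-) library (binomial thinning).
#' @param rnaseq_mean_depth mean RNA-Seq plateau depth over a TU.
#' @param te_log_sd SD of per-gene log-normal translation-efficiency factors
#'   (`0` plants TE exactly 1 for every gene).
#' @param count_noise if `FALSE`, peak read counts, processed-site counts and
#'   coverage depths are deterministic (their means, rounded) instead of
#'   Poisson draws: the zero-noise study condition.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 60L,
                       genome_length = NULL,
                       gc_fraction = 0.72,
                       gene_length_range = c(300L, 1500L),
                       short_gap_range = c(50L, 450L),
                       long_gap_range = c(600L, 1500L),
                       block_size_probs = c("1" = 0.75, "2" = 0.15,
                                            "3" = 0.07, "4" = 0.03),
                       leaderless_fraction = 0.20,
                       utr_range = c(10L, 300L),
                       tep_offset_range = c(20L, 200L),
                       tss_peak_count_mean = 10,
                       tep_peak_count_mean = 10,
                       peak_jitter_sd = 1,
                       background_rate = 0.01,
                       tap_minus_processed_site_rate = 0.02,
                       tap_minus_thinning = 0.2,
                       rnaseq_mean_depth = 50,
                       te_log_sd = 0.3,
                       count_noise = TRUE) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    genome_length = if (!is.null(genome_length)) as.integer(genome_length),
    gc_fraction = gc_fraction,
    gene_length_range = as.integer(gene_length_range),
    short_gap_range = as.integer(short_gap_range),
    long_gap_range = as.integer(long_gap_range),
    block_size_probs = block_size_probs / sum(block_size_probs),
    leaderless_fraction = leaderless_fraction,
    utr_range = as.integer(utr_range),
    tep_offset_range = as.integer(tep_offset_range),
    tss_peak_count_mean = tss_peak_count_mean,
    tep_peak_count_mean = tep_peak_count_mean,
    peak_jitter_sd = peak_jitter_sd,
    background_rate = background_rate,
    tap_minus_processed_site_rate = tap_minus_processed_site_rate,
    tap_minus_thinning = tap_minus_thinning,
    rnaseq_mean_depth = rnaseq_mean_depth,
    te_log_sd = te_log_sd,
    count_noise = isTRUE(count_noise)
  )
  stopifnot(
    cfg$n_genes >= 1,
    cfg$gc_fraction >= 0, cfg$gc_fraction <= 1,
    cfg$leaderless_fraction >= 0, cfg$leaderless_fraction <= 1,
    cfg$short_gap_range[2] <= 500,
    cfg$long_gap_range[1] > 500,
    cfg$utr_range[1] >= 10,
    cfg$tep_offset_range[1] >= 1,
    cfg$tss_peak_count_mean >= 0, cfg$tep_peak_count_mean >= 0,
    cfg$peak_jitter_sd >= 0, cfg$background_rate >= 0,
    cfg$tap_minus_processed_site_rate >= 0,
    cfg$tap_minus_thinning >= 0, cfg$tap_minus_thinning <= 1,
    cfg$te_log_sd >= 0
  )
  ## TSS (<=300 nt upstream) and TEP (<=200 nt downstream) excursions of
  ## adjacent blocks must not collide inside a between-block gap.
  if (cfg$long_gap_range[1] <= cfg$utr_range[2] + cfg$tep_offset_range[2]) {
    stop("long_gap_range[1] must exceed utr_range[2] + tep_offset_range[2]",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

rand_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

## Peak read count: Poisson draw, or its rounded mean in the zero-noise
## condition.
peak_count <- function(n, mean, noise) {
  if (noise) rpois(n, mean) else rep(round(mean), n)
}

#' Simulate a genome and ground-truth TU architecture
#'
#' Plants non-overlapping genes grouped into same-strand operon blocks, one
#' TU per block, and draws the genome sequence at the configured GC content.
#' Fully deterministic under `(config$seed, config)`.
#'
#' @param config [sim_config()].
#' @return list of class `tu_truth` with elements `genome` ([genome()]),
#'   `genes` (gene table with `tu_id` and `te_factor`), `tss` / `tep`
#'   (planted site tables), `tus` (planted TU table with list-column
#'   `genes`), and `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  ## Block sizes until n_genes genes are allocated.
  sizes <- integer(0)
  while (sum(sizes) < config$n_genes) {
    sizes <- c(sizes, sample(as.integer(names(config$block_size_probs)), 1L,
                             prob = config$block_size_probs))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] -
    (sum(sizes) - config$n_genes)
  sizes <- sizes[sizes > 0L]
  n_blocks <- length(sizes)
  strands <- sample(STRANDS, n_blocks, replace = TRUE)
  leaderless <- runif(n_blocks) < config$leaderless_fraction

  margin <- config$utr_range[2] + config$tep_offset_range[2]
  cursor <- margin + 1L
  genes <- list(); tus <- list(); gid <- 0L
  for (b in seq_len(n_blocks)) {
    k <- sizes[b]
    lens <- rand_int(k, config$gene_length_range)
    gaps <- if (k > 1L) rand_int(k - 1L, config$short_gap_range) else integer(0)
    starts <- ends <- integer(k)
    p <- cursor
    for (j in seq_len(k)) {
      starts[j] <- p
      ends[j] <- p + lens[j] - 1L
      p <- ends[j] + (if (j < k) gaps[j] else 0L) + 1L
    }
    ids <- sprintf("SLG_%04d", gid + seq_len(k))
    gid <- gid + k
    block_first <- starts[1]; block_last <- ends[k]
    utr <- if (leaderless[b]) 0L else rand_int(1L, config$utr_range)
    off <- rand_int(1L, config$tep_offset_range)
    if (strands[b] == "+") {
      tss_pos <- block_first - utr
      tep_pos <- block_last + off
      gene_order <- ids
    } else {
      ## transcription runs right to left: 5'-most gene is the rightmost
      tss_pos <- block_last + utr
      tep_pos <- block_first - off
      gene_order <- rev(ids)
    }
    genes[[b]] <- data.frame(
      gene_id = ids, start = starts, end = ends, strand = strands[b],
      tu_id = sprintf("TU_%04d", b), stringsAsFactors = FALSE
    )
    tus[[b]] <- data.frame(
      tu_id = sprintf("TU_%04d", b), strand = strands[b],
      tss_pos = tss_pos, tep_pos = tep_pos, leaderless = leaderless[b],
      stringsAsFactors = FALSE
    )
    tus[[b]]$genes <- list(gene_order)
    cursor <- block_last + rand_int(1L, config$long_gap_range) + 1L
  }
  genes <- do.call(rbind, genes)
  tus <- do.call(rbind, tus)

  needed <- max(genes$end) + margin
  if (is.null(config$genome_length)) {
    L <- needed
  } else {
    L <- config$genome_length
    if (needed > L) {
      stop("planted genes do not fit: need ", needed, " nt, genome_length is ",
           L, call. = FALSE)
    }
  }

  gc <- config$gc_fraction
  seq_chars <- sample(c("G", "C", "A", "T"), L, replace = TRUE,
                      prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
  ## Deterministic start codons so codon tallies have known truth.
  g5 <- gene_5p(genes)
  for (i in seq_len(nrow(genes))) {
    codon <- c("A", "T", "G")
    if (genes$strand[i] == "+") {
      seq_chars[g5[i]:(g5[i] + 2L)] <- codon
    } else {
      seq_chars[(g5[i] - 2L):g5[i]] <- rev(c("T", "A", "C"))  # revcomp ATG
    }
  }
  g <- genome(paste(seq_chars, collapse = ""))

  genes$te_factor <- rlnorm(nrow(genes), meanlog = 0, sdlog = config$te_log_sd)

  first_gene <- vapply(tus$genes, function(x) x[1], character(1))
  tss <- data.frame(
    pos = tus$tss_pos, strand = tus$strand, gene_id = first_gene,
    tu_id = tus$tu_id, leaderless = tus$leaderless, stringsAsFactors = FALSE
  )
  tep <- data.frame(
    pos = tus$tep_pos, strand = tus$strand, tu_id = tus$tu_id,
    stringsAsFactors = FALSE
  )
  structure(
    list(genome = g, genes = genes, tss = tss, tep = tep, tus = tus,
         config = config),
    class = "tu_truth"
  )
}

#' @export
print.tu_truth <- function(x, ...) {
  cat(sprintf("<tu_truth> %d genes in %d TUs over %d nt (%d leaderless TUs)\n",
              nrow(x$genes), nrow(x$tus), x$genome$length,
              sum(x$tus$leaderless)))
  invisible(x)
}

## Scatter n peak reads around pos with integer Gaussian jitter, clamped to
## the replicon. Returns integer positions (one per read).
jitter_reads <- function(pos, n, sd, L) {
  if (n == 0L) return(integer(0))
  p <- pos + as.integer(round(rnorm(n, 0, sd)))
  pmin(pmax(p, 1L), L)
}

add_reads <- function(counts, positions) {
  if (length(positions)) {
    t <- tabulate(positions, nbins = length(counts))
    counts + t
  } else counts
}

background_reads <- function(rate, L, noise) {
  n <- if (noise) rpois(1L, rate * L) else round(rate * L)
  if (n == 0L) integer(0) else sample.int(L, n, replace = TRUE)
}

#' Simulate dRNA-Seq and Term-Seq end profiles
#'
#' At each planted TSS the TAP(+) library receives a Poisson peak with
#' integer Gaussian jitter and the TAP(-) library a binomial thinning
#' (probability `tap_minus_thinning`) of those same reads, so TAP(-) never
#' exceeds TAP(+) at a primary 5' end. Processed 5'-end sites (rate per kb)
#' receive independent equal-mean peaks in both TAP libraries. The two
#' Term-Seq replicates receive independent Poisson peaks at each planted
#' TEP. All libraries get independent uniform background.
#'
#' @param truth [simulate_truth()] output.
#' @param config the same [sim_config()].
#' @return list with elements `tap_plus`, `tap_minus`, `term_r1`, `term_r2`,
#'   each a list of `plus` / `minus` [end_profile()]s, plus
#'   `processed_sites` (data.frame of planted processed 5' ends).
#' @export
simulate_end_profiles <- function(truth, config) {
  stopifnot(inherits(truth, "tu_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  L <- truth$genome$length
  noise <- config$count_noise
  prof <- list()
  for (s in STRANDS) {
    key <- if (s == "+") "plus" else "minus"
    tssp <- truth$tss$pos[truth$tss$strand == s]
    tepp <- truth$tep$pos[truth$tep$strand == s]

    reads_p <- list(); reads_m <- list()
    for (p in tssp) {
      n <- peak_count(1L, config$tss_peak_count_mean, noise)
      reads <- jitter_reads(p, n, config$peak_jitter_sd, L)
      reads_p[[length(reads_p) + 1L]] <- reads
      k <- if (noise) rbinom(1L, n, config$tap_minus_thinning)
           else round(config$tap_minus_thinning * n)
      reads_m[[length(reads_m) + 1L]] <- reads[seq_len(k)]
    }
    ## processed monophosphate 5' ends: equal mean in both libraries
    n_sites <- if (noise) {
      rpois(1L, config$tap_minus_processed_site_rate * L / 1000)
    } else round(config$tap_minus_processed_site_rate * L / 1000)
    proc_pos <- integer(0)
    if (n_sites > 0L) {
      ## keep processed sites clear of true TSSs so planted peaks stay clean
      cand <- setdiff(sample.int(L, n_sites * 10L, replace = TRUE),
                      unlist(lapply(tssp, function(p) (p - 200L):(p + 200L))))
      proc_pos <- head(cand, n_sites)
      for (p in proc_pos) {
        reads_p[[length(reads_p) + 1L]] <- jitter_reads(
          p, peak_count(1L, config$tss_peak_count_mean, noise),
          config$peak_jitter_sd, L)
        reads_m[[length(reads_m) + 1L]] <- jitter_reads(
          p, peak_count(1L, config$tss_peak_count_mean, noise),
          config$peak_jitter_sd, L)
      }
    }
    reads_p[[length(reads_p) + 1L]] <-
      background_reads(config$background_rate, L, noise)
    reads_m[[length(reads_m) + 1L]] <-
      background_reads(config$background_rate, L, noise)
    tap_p <- tabulate(unlist(reads_p), nbins = L)
    tap_m <- tabulate(unlist(reads_m), nbins = L)

    ## Term-Seq 3' ends are adaptor-ligation points: the peak sits exactly
    ## on the planted TEP (no positional jitter), unlike dRNA-Seq 5' ends.
    t1 <- tabulate(c(rep(tepp, peak_count(length(tepp),
                                          config$tep_peak_count_mean, noise)),
                     background_reads(config$background_rate, L, noise)),
                   nbins = L)
    t2 <- tabulate(c(rep(tepp, peak_count(length(tepp),
                                          config$tep_peak_count_mean, noise)),
                     background_reads(config$background_rate, L, noise)),
                   nbins = L)

    mk <- function(x, label) {
      structure(list(seqname = truth$genome$seqname, strand = s,
                     label = label, genome_length = L, counts = as.numeric(x)),
                class = "end_profile")
    }
    prof$tap_plus[[key]] <- mk(tap_p, "TAP_PLUS")
    prof$tap_minus[[key]] <- mk(tap_m, "TAP_MINUS")
    prof$term_r1[[key]] <- mk(t1, "TERMSEQ_R1")
    prof$term_r2[[key]] <- mk(t2, "TERMSEQ_R2")
    prof$processed_sites <- rbind(
      prof$processed_sites,
      if (length(proc_pos)) data.frame(pos = proc_pos, strand = s,
                                       stringsAsFactors = FALSE)
    )
  }
  prof
}

#' Simulate RNA-Seq and Ribo-Seq coverage
#'
#' RNA-Seq coverage is a per-TU plateau: every position between TSS and TEP
#' draws Poisson noise around a per-TU level (log-normal around
#' `rnaseq_mean_depth`), with only background outside TU spans. Ribo-Seq
#' coverage over each CDS is the TU level times the gene's planted
#' translation-efficiency factor, with the same noise model.
#'
#' @param truth [simulate_truth()] output.
#' @param config the same [sim_config()].
#' @return list with `rnaseq` and `riboseq`, each `plus`/`minus`
#'   [end_profile()]s, plus `tu_level` (the per-TU plateau depths).
#' @export
simulate_coverage <- function(truth, config) {
  stopifnot(inherits(truth, "tu_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  L <- truth$genome$length
  noise <- config$count_noise
  lev <- if (noise) {
    rlnorm(nrow(truth$tus), log(config$rnaseq_mean_depth), 0.5)
  } else rep(config$rnaseq_mean_depth, nrow(truth$tus))
  names(lev) <- truth$tus$tu_id

  depth_draw <- function(n, level) {
    if (noise) rpois(n, level) else rep(round(level), n)
  }
  out <- list(tu_level = lev)
  for (s in STRANDS) {
    key <- if (s == "+") "plus" else "minus"
    rna <- numeric(L); ribo <- numeric(L)
    sel <- which(truth$tus$strand == s)
    for (i in sel) {
      span <- sort(c(truth$tus$tss_pos[i], truth$tus$tep_pos[i]))
      idx <- span[1]:span[2]
      rna[idx] <- rna[idx] + depth_draw(length(idx), lev[i])
    }
    gsel <- which(truth$genes$strand == s)
    for (i in gsel) {
      idx <- truth$genes$start[i]:truth$genes$end[i]
      level <- lev[truth$genes$tu_id[i]] * truth$genes$te_factor[i]
      ribo[idx] <- ribo[idx] + depth_draw(length(idx), level)
    }
    rna <- add_reads(rna, background_reads(config$background_rate, L, noise))
    ribo <- add_reads(ribo, background_reads(config$background_rate, L, noise))
    mk <- function(x, label) {
      structure(list(seqname = truth$genome$seqname, strand = s,
                     label = label, genome_length = L, counts = x),
                class = "end_profile")
    }
    out$rnaseq[[key]] <- mk(rna, "RNASEQ")
    out$riboseq[[key]] <- mk(ribo, "RIBOSEQ")
  }
  out
}

#' Simulate a complete benchmark dataset
#'
#' Convenience wrapper: [simulate_truth()] + [simulate_end_profiles()] +
#' [simulate_coverage()].
#'
#' @param config [sim_config()].
#' @return list with `truth` and `profiles` (named: `tap_plus`, `tap_minus`,
#'   `term_r1`, `term_r2`, `rnaseq`, `riboseq`, each `plus`/`minus`), plus
#'   `processed_sites` and `tu_level`.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_truth(config)
  ends <- simulate_end_profiles(truth, config)
  cov <- simulate_coverage(truth, config)
  list(
    truth = truth,
    profiles = list(
      tap_plus = ends$tap_plus, tap_minus = ends$tap_minus,
      term_r1 = ends$term_r1, term_r2 = ends$term_r2,
      rnaseq = cov$rnaseq, riboseq = cov$riboseq
    ),
    processed_sites = ends$processed_sites,
    tu_level = cov$tu_level
  )
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `genes.gff3`, twelve bedGraphs
#' (`<library>.plus|minus.bedgraph`) and `ground_truth.tsv` (planted TSS,
#' TEP and TU table flattened).
#'
#' @param dataset [simulate_dataset()] output.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- dataset$truth
  write_genome_fasta(truth$genome, file.path(dir, "genome.fa"))
  write_annotation(truth$genes[, c("gene_id", "start", "end", "strand")],
                   file.path(dir, "genes.gff3"),
                   seqname = truth$genome$seqname)
  for (lib in names(dataset$profiles)) {
    for (key in c("plus", "minus")) {
      write_end_profile(dataset$profiles[[lib]][[key]],
                        file.path(dir, sprintf("%s.%s.bedgraph", lib, key)))
    }
  }
  gt <- truth$tus
  gt$genes <- vapply(gt$genes, paste, character(1), collapse = ",")
  write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
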