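## tu_builder: pair classified TSSs and TEPs into transcription units,
## categorize them, score them against RNA-Seq coverage, and build TU
## clusters over shared genes.
##
## Assembly walks downstream from each TSS gene-by-gene on its strand; the
## walk stops at the first intergenic gap above 500 nt. Every TEP inside the
## reachable extent closes one TU, so nested and overlapping TU variants are
## enumerated rather than collapsed. Antisense/intergenic TSSs instead scan
## 1 kbp downstream for the first TEP or gene start codon. All of this runs
## in a 5'-to-3' oriented frame: minus-strand inputs are mirrored, assembled
## with the plus-strand algorithm, and mirrored back, which guarantees
## strand symmetry.

flip_pos <- function(pos, L) L + 1L - pos

flip_genes <- function(genes, L) {
  data.frame(gene_id = genes$gene_id,
             start = flip_pos(genes$end, L),
             end = flip_pos(genes$start, L),
             strand = "+",
             stringsAsFactors = FALSE)
}

#' Assemble transcription units from classified TSSs and TEPs
#'
#' For each primary/secondary/internal TSS the caller walks downstream on
#' the TSS strand: consecutive same-strand genes chain while the intergenic
#' gap stays at or below `max_gap`; the first larger gap bounds the
#' reachable extent (just before the chain-breaking gene). Every TEP within
#' the extent yields one TU. Cis-regulatory TEPs pair only with TSSs
#' assigned to the same gene. Antisense/intergenic TSSs scan `scan` nt
#' downstream: a TEP before any gene start codon closes a single TU; a gene
#' start codon first switches to the walking rules (with `scan_all = TRUE`
#' every TEP in the scan window closes a TU instead of only the first).
#'
#' @param tss classified TSS table ([classify_tss()]).
#' @param tep classified TEP table ([classify_tep()]).
#' @param genes gene table.
#' @param genome_length replicon length (nt).
#' @param max_gap maximum intergenic distance within a TU (default 500 nt).
#' @param scan downstream scan distance for A/N TSSs (default 1000 nt).
#' @param scan_all take every TEP in the A/N scan window, not just the first.
#' @return data.frame with `tu_id`, `strand`, `tss_pos`, `tep_pos`,
#'   `start`/`end` (genomic span), `tss_category`, `tss_gene`.
#' @export
assemble_tus <- function(tss, tep, genes, genome_length, max_gap = 500,
                         scan = 1000, scan_all = FALSE) {
  genes <- validate_genes(genes)
  if (any(is.na(tss$category)) || any(is.na(tep$category))) {
    stop("classify TSSs and TEPs before assembly", call. = FALSE)
  }
  rows <- list()
  for (strand in STRANDS) {
    ts <- tss[tss$strand == strand, , drop = FALSE]
    te <- tep[tep$strand == strand, , drop = FALSE]
    gs <- genes[genes$strand == strand, , drop = FALSE]
    if (nrow(ts) == 0L || nrow(te) == 0L) next
    if (strand == "-") {
      ts$pos <- flip_pos(ts$pos, genome_length)
      te$pos <- flip_pos(te$pos, genome_length)
      gs <- flip_genes(gs, genome_length)
      gs <- gs[order(gs$start), , drop = FALSE]
    }
    got <- assemble_oriented(ts, te, gs, genome_length, max_gap, scan,
                             scan_all)
    if (nrow(got) == 0L) next
    if (strand == "-") {
      got$tss_pos <- flip_pos(got$tss_pos, genome_length)
      got$tep_pos <- flip_pos(got$tep_pos, genome_length)
    }
    got$strand <- strand
    rows[[strand]] <- got
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tss_pos = integer(0), tep_pos = integer(0),
                      tss_category = character(0), tss_gene = character(0),
                      strand = character(0))
  }
  out$start <- pmin(out$tss_pos, out$tep_pos)
  out$end <- pmax(out$tss_pos, out$tep_pos)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) out$tu_id <- sprintf("TU_%04d", seq_len(nrow(out)))
  else out$tu_id <- character(0)
  out[, c("tu_id", "strand", "tss_pos", "tep_pos", "start", "end",
          "tss_category", "tss_gene")]
}

## Everything here is 5'->3' on a virtual plus strand.
assemble_oriented <- function(ts, te, gs, L, max_gap, scan, scan_all) {
  rows <- list()
  emit <- function(tss_row, tep_pos) {
    data.frame(tss_pos = tss_row$pos, tep_pos = tep_pos,
               tss_category = tss_row$category,
               tss_gene = tss_row$gene_id %||% NA_character_,
               stringsAsFactors = FALSE)
  }
  walk_extent <- function(p) {
    ## returns the last reachable position downstream of p
    host <- which(gs$start <= p & gs$end >= p)
    prev_end <- if (length(host)) max(gs$end[host]) else NA_integer_
    limit <- L
    for (k in which(gs$start > p)) {
      if (!is.na(prev_end)) {
        gap <- gs$start[k] - prev_end - 1L
        if (gap > max_gap) {
          limit <- gs$start[k] - 1L
          break
        }
      }
      prev_end <- max(prev_end, gs$end[k], na.rm = TRUE)
    }
    limit
  }
  eligible_teps <- function(tss_row, from, to) {
    ok <- te$pos > from & te$pos <= to
    ## cis-regulatory TEPs only with TSSs assigned to the same gene
    cis <- te$category == "C"
    same_gene <- !is.na(te$gene_id) & !is.na(tss_row$gene_id) &
      te$gene_id == tss_row$gene_id
    te$pos[ok & (!cis | same_gene)]
  }

  for (i in seq_len(nrow(ts))) {
    row <- ts[i, ]
    p <- row$pos
    if (row$category %in% c("P", "S", "I")) {
      limit <- walk_extent(p)
      for (tp in eligible_teps(row, p, limit)) {
        rows[[length(rows) + 1L]] <- emit(row, tp)
      }
    } else {  # antisense / intergenic: 1-kbp scan
      win_hi <- min(p + scan, L)
      tp_all <- sort(eligible_teps(row, p, win_hi))
      g1 <- gs$start[gs$start > p & gs$start <= win_hi]
      first_gene <- if (length(g1)) min(g1) else Inf
      tp_before <- tp_all[tp_all < first_gene]
      if (length(tp_before)) {
        take <- if (scan_all) tp_before else tp_before[1]
        for (tp in take) rows[[length(rows) + 1L]] <- emit(row, tp)
      } else if (is.finite(first_gene)) {
        limit <- walk_extent(p)
        for (tp in eligible_teps(row, p, limit)) {
          rows[[length(rows) + 1L]] <- emit(row, tp)
        }
      }
      ## neither TEP nor start codon in the window: no TU from this TSS
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(tss_pos = integer(0), tep_pos = integer(0),
                      tss_category = character(0), tss_gene = character(0)))
  }
  do.call(rbind, rows)
}

#' Categorize transcription units
#'
#' Associated genes are the same-strand genes fully contained in the TU
#' span, minus the host gene of an internal TSS. One associated gene makes
#' a mono-cistronic TU, two or more a poly-cistronic TU. A TU without
#' associated genes is cis-regulatory when the distance from its TSS to the
#' next same-strand downstream gene start is below `srna_cutoff`, otherwise
#' an sRNA TU.
#'
#' @param tus TU table from [assemble_tus()].
#' @param genes gene table.
#' @param srna_cutoff distance cutoff (default 500 nt).
#' @return `tus` with list-column `genes` (associated gene ids 5' to 3'),
#'   `n_genes` and `category`.
#' @export
categorize_tus <- function(tus, genes, srna_cutoff = 500) {
  genes <- validate_genes(genes)
  g5 <- gene_5p(genes)
  tus$genes <- vector("list", nrow(tus))
  tus$n_genes <- integer(nrow(tus))
  tus$category <- character(nrow(tus))
  for (i in seq_len(nrow(tus))) {
    strand <- tus$strand[i]
    contained <- genes$strand == strand &
      genes$start >= tus$start[i] & genes$end <= tus$end[i]
    if (tus$tss_category[i] == "I") {
      host <- genes$strand == strand & genes$start <= tus$tss_pos[i] &
        genes$end >= tus$tss_pos[i]
      contained <- contained & !host
    }
    ids <- genes$gene_id[contained]
    ord <- order(if (strand == "+") genes$start[contained]
                 else -genes$end[contained])
    ids <- ids[ord]
    tus$genes[[i]] <- ids
    tus$n_genes[i] <- length(ids)
    if (length(ids) >= 2L) {
      tus$category[i] <- "polycistronic"
    } else if (length(ids) == 1L) {
      tus$category[i] <- "monocistronic"
    } else {
      p <- tus$tss_pos[i]
      d <- if (strand == "+") g5[genes$strand == strand] - p
           else p - g5[genes$strand == strand]
      d <- d[d > 0]
      tus$category[i] <- if (length(d) && min(d) < srna_cutoff) {
        "cis_regulatory"
      } else "sRNA"
    }
  }
  tus
}

#' Score TUs against RNA-Seq coverage
#'
#' An automated stand-in for visual inspection of TU calls against the
#' transcriptome: the score is the fraction of TU span positions with
#' RNA-Seq depth of at least `min_depth`; a TU passes at
#' `score >= min_frac`. Failing TUs are flagged, and removed only when
#' `drop_failing = TRUE`.
#'
#' @param tus TU table.
#' @param rnaseq list with `plus`/`minus` RNA-Seq coverage [end_profile()]s.
#' @param min_frac passing score (default 0.9).
#' @param min_depth depth threshold (default 1 read).
#' @param drop_failing remove failing TUs (default FALSE).
#' @return `tus` with `coverage_score` and `coverage_pass` columns.
#' @export
coverage_consistency <- function(tus, rnaseq, min_frac = 0.9, min_depth = 1,
                                 drop_failing = FALSE) {
  tus$coverage_score <- NA_real_
  for (i in seq_len(nrow(tus))) {
    prof <- rnaseq[[if (tus$strand[i] == "+") "plus" else "minus"]]
    idx <- tus$start[i]:tus$end[i]
    tus$coverage_score[i] <- mean(prof$counts[idx] >= min_depth)
  }
  tus$coverage_pass <- tus$coverage_score >= min_frac
  if (drop_failing) tus <- tus[tus$coverage_pass, , drop = FALSE]
  tus
}

#' Cluster TUs over shared genes
#'
#' TUs sharing at least one associated gene, directly or through a chain of
#' other TUs, form one TU cluster (connected components of the TU-gene
#' bipartite graph). Gene-less TUs are singleton clusters.
#'
#' @param tus categorized TU table ([categorize_tus()]).
#' @return list with `membership` (data.frame `tu_id`, `cluster_id`) and
#'   `clusters` (data.frame `cluster_id`, `n_tus`, `n_genes`).
#' @export
cluster_tus <- function(tus) {
  n <- nrow(tus)
  if (n == 0L) {
    return(list(
      membership = data.frame(tu_id = character(0), cluster_id = integer(0)),
      clusters = data.frame(cluster_id = integer(0), n_tus = integer(0),
                            n_genes = integer(0))
    ))
  }
  gene_nodes <- unique(unlist(tus$genes))
  edges <- character(0)
  for (i in seq_len(n)) {
    for (g in tus$genes[[i]]) edges <- c(edges, tus$tu_id[i], paste0("g:", g))
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(tus$tu_id, paste0("g:", gene_nodes)))
  if (length(edges)) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)$membership
  member <- comp[tus$tu_id]
  cluster_id <- as.integer(factor(member, levels = unique(member)))
  membership <- data.frame(tu_id = tus$tu_id, cluster_id = cluster_id,
                           stringsAsFactors = FALSE)
  clusters <- do.call(rbind, lapply(unique(cluster_id), function(cid) {
    idx <- which(cluster_id == cid)
    data.frame(cluster_id = cid, n_tus = length(idx),
               n_genes = length(unique(unlist(tus$genes[idx]))))
  }))
  list(membership = membership, clusters = clusters)
}
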