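## feature_classifier: five-way categories for TSSs and TEPs relative to a
## gene annotation.
##
## TSS categories: primary (P) / secondary (S) for sites assigned to a gene
## (within 500 nt upstream to 100 nt downstream of its start codon, ranked
## by TAP(+) count), internal (I) inside a same-strand gene body, antisense
## (A) inside an opposite-strand gene body, intergenic (N) otherwise.
##
## TEP categories: cis-regulatory (C) between a gene's primary TSS and its
## start codon (>= 60 nt from the TSS), primary (P) / secondary (S) for
## sites < 500 nt past a same-strand upstream gene (ranked by combined
## replicate count), antisense (A) inside an opposite-strand gene body,
## intergenic (N) otherwise. Precedence is strict: C, then P/S, then A,
## then N.

#' Classification parameters
#'
#' @param tss_upstream_window nt upstream of a start codon within which a
#'   TSS can be assigned to the gene (default 500).
#' @param tss_downstream_window nt downstream likewise (default 100).
#' @param tep_gene_distance maximum distance (nt) from a gene 3' end for a
#'   primary/secondary TEP (default 500).
#' @param cis_min_tss_distance minimum distance (nt) between a primary TSS
#'   and a cis-regulatory TEP (default 60).
#' @return list of class `class_params`.
#' @export
class_params <- function(tss_upstream_window = 500,
                         tss_downstream_window = 100,
                         tep_gene_distance = 500,
                         cis_min_tss_distance = 60) {
  p <- list(tss_upstream_window = tss_upstream_window,
            tss_downstream_window = tss_downstream_window,
            tep_gene_distance = tep_gene_distance,
            cis_min_tss_distance = cis_min_tss_distance)
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "class_params")
}

## Is position pos inside any gene body of the given strand subset?
inside_gene_body <- function(pos, genes) {
  any(genes$start <= pos & genes$end >= pos)
}

#' Classify TSSs against a gene annotation
#'
#' Assignment first: a TSS lying within `tss_upstream_window` nt upstream to
#' `tss_downstream_window` nt downstream of a same-strand gene's start codon
#' is assigned to that gene (the nearest qualifying start when several do;
#' distance ties break by gene id). Per gene, the assigned TSS with the
#' highest TAP(+) count is primary (P), the rest secondary (S). Unassigned
#' TSSs are internal (I) inside a same-strand gene body, antisense (A)
#' inside an opposite-strand gene body, else intergenic (N).
#'
#' @param tss TSS table from [find_tss()].
#' @param genes gene table.
#' @param params [class_params()].
#' @return `tss` with `category` and `gene_id` filled.
#' @export
classify_tss <- function(tss, genes, params = class_params()) {
  genes <- validate_genes(genes)
  if (nrow(tss) == 0L) return(tss)
  g5 <- gene_5p(genes)
  up <- params$tss_upstream_window
  down <- params$tss_downstream_window
  tss$category <- NA_character_
  tss$gene_id <- NA_character_

  for (i in seq_len(nrow(tss))) {
    p <- tss$pos[i]
    same <- genes$strand == tss$strand[i]
    in_win <- if (tss$strand[i] == "+") {
      same & p >= g5 - up & p <= g5 + down
    } else {
      same & p <= g5 + up & p >= g5 - down
    }
    if (any(in_win)) {
      idx <- which(in_win)
      d <- abs(p - g5[idx])
      idx <- idx[order(d, genes$gene_id[idx])]
      tss$gene_id[i] <- genes$gene_id[idx[1]]
    }
  }
  ## P/S per gene by TAP(+) count; count ties break toward the 5'-most site.
  assigned <- which(!is.na(tss$gene_id))
  for (g in unique(tss$gene_id[assigned])) {
    idx <- which(tss$gene_id == g)
    strand <- tss$strand[idx[1]]
    best <- idx[tss$tap_plus[idx] == max(tss$tap_plus[idx])]
    if (length(best) > 1L) {
      best <- best[tss$pos[best] == five_prime_most(tss$pos[best], strand)]
    }
    tss$category[idx] <- "S"
    tss$category[best[1]] <- "P"
  }
  ## remaining: internal / antisense / intergenic
  for (i in which(is.na(tss$category))) {
    p <- tss$pos[i]
    same <- genes[genes$strand == tss$strand[i], , drop = FALSE]
    opp <- genes[genes$strand != tss$strand[i], , drop = FALSE]
    tss$category[i] <- if (inside_gene_body(p, same)) "I"
    else if (inside_gene_body(p, opp)) "A"
    else "N"
  }
  tss
}

#' Classify TEPs against a gene annotation and primary TSS map
#'
#' Rules in strict order: (1) cis-regulatory (C) when the TEP lies strictly
#' between a gene's primary TSS and that gene's start codon on the same
#' strand, at least `cis_min_tss_distance` nt from the TSS; (2) assigned to
#' the nearest same-strand upstream gene whose 3' end is less than
#' `tep_gene_distance` nt away, ranked per gene into primary (P, highest
#' combined replicate count) and secondary (S); (3) antisense (A) inside an
#' opposite-strand gene body; (4) intergenic (N).
#'
#' @param tep TEP table from [find_tep()].
#' @param genes gene table.
#' @param primary_tss data.frame with `gene_id`, `pos`, `strand` of primary
#'   TSSs (e.g. the P rows of [classify_tss()] output), or `NULL` to skip
#'   the cis-regulatory rule (with a warning).
#' @param params [class_params()].
#' @return `tep` with `category` and `gene_id` filled.
#' @export
classify_tep <- function(tep, genes, primary_tss, params = class_params()) {
  genes <- validate_genes(genes)
  if (nrow(tep) == 0L) return(tep)
  if (is.null(primary_tss) || nrow(primary_tss) == 0L) {
    warning("no primary TSS map: cis-regulatory rule skipped")
    primary_tss <- data.frame(gene_id = character(0), pos = integer(0),
                              strand = character(0))
  }
  g5 <- gene_5p(genes)
  g3 <- gene_3p(genes)
  tep$category <- NA_character_
  tep$gene_id <- NA_character_

  pt <- primary_tss[match(genes$gene_id, primary_tss$gene_id), "pos"]

  for (i in seq_len(nrow(tep))) {
    p <- tep$pos[i]
    strand <- tep$strand[i]
    same <- genes$strand == strand

    ## (1) cis-regulatory: strictly between primary TSS and start codon,
    ##     >= 60 nt from the TSS.
    cis <- if (strand == "+") {
      same & !is.na(pt) & pt < p & p < g5 & (p - pt) >= params$cis_min_tss_distance
    } else {
      same & !is.na(pt) & pt > p & p > g5 & (pt - p) >= params$cis_min_tss_distance
    }
    if (any(cis)) {
      idx <- which(cis)
      d <- abs(p - g5[idx])
      idx <- idx[order(d, genes$gene_id[idx])]
      tep$category[i] <- "C"
      tep$gene_id[i] <- genes$gene_id[idx[1]]
      next
    }

    ## (2) nearest same-strand upstream gene < tep_gene_distance away
    updist <- if (strand == "+") p - g3 else g3 - p
    ok <- same & updist >= 0 & updist < params$tep_gene_distance
    if (any(ok)) {
      idx <- which(ok)
      idx <- idx[order(updist[idx], genes$gene_id[idx])]
      tep$gene_id[i] <- genes$gene_id[idx[1]]
      next  # P/S ranked after the loop
    }

    ## (3)/(4)
    opp <- genes[genes$strand != strand, , drop = FALSE]
    tep$category[i] <- if (inside_gene_body(p, opp)) "A" else "N"
  }

  assigned <- which(is.na(tep$category) & !is.na(tep$gene_id))
  combined <- tep$count_r1 + tep$count_r2
  for (g in unique(tep$gene_id[assigned])) {
    idx <- assigned[tep$gene_id[assigned] == g]
    strand <- tep$strand[idx[1]]
    best <- idx[combined[idx] == max(combined[idx])]
    if (length(best) > 1L) {
      best <- best[tep$pos[best] == five_prime_most(tep$pos[best], strand)]
    }
    tep$category[idx] <- "S"
    tep$category[best[1]] <- "P"
  }
  tep
}

#' Category count summary
#'
#' Per-category site counts with percentage shares, in the style of a
#' results breakdown table.
#'
#' @param records classified TSS or TEP table.
#' @param levels category order (defaults to the categories present).
#' @return data.frame `category`, `n`, `total`, `percent`, `label`.
#' @export
category_summary <- function(records, levels = NULL) {
  stopifnot("category" %in% names(records))
  if (is.null(levels)) levels <- sort(unique(records$category))
  n <- vapply(levels, function(l) sum(records$category == l), numeric(1))
  cbind(category = levels,
        fraction_summary(as.integer(n), max(nrow(records), 1L)))
}
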