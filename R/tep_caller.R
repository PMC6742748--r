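## tep_caller: transcript 3'-end positions from replicated Term-Seq
## profiles.
##
## Candidate 3' ends are restricted to intergenic space (plus a short tail
## allowance just downstream of a stop codon), chained into clusters
## (< 10 bp apart), scored with a leave-one-out modified z-score against the
## other positions of their cluster, thresholded (count >= 3, z >= 3), and
## reconciled between two biological replicates: within the intersection of
## overlapping replicate cluster spans, the surviving position with the
## highest combined count becomes the TEP.

#' Collect TEP candidates from a Term-Seq profile
#'
#' A position with at least one 3'-end read qualifies iff it lies outside
#' every same-strand gene body, or within `tail_allow` nt downstream of some
#' same-strand gene's 3' end (even when that tail overlaps another
#' annotation). Opposite-strand genes never mask a candidate.
#'
#' @param termseq Term-Seq [end_profile()] for one strand.
#' @param genes gene table.
#' @param tail_allow allowance downstream of a gene 3' end (default 10 nt).
#' @return data.frame `pos`, `count`, ascending.
#' @export
collect_tep_candidates <- function(termseq, genes, tail_allow = 10) {
  stopifnot(inherits(termseq, "end_profile"))
  genes <- validate_genes(genes)
  cand <- profile_nonzero(termseq)
  if (nrow(cand) == 0L) return(cand)
  strand <- termseq$strand
  L <- termseq$genome_length
  same <- genes[genes$strand == strand, , drop = FALSE]
  in_body <- logical(L)
  in_tail <- logical(L)
  for (i in seq_len(nrow(same))) {
    in_body[same$start[i]:same$end[i]] <- TRUE
    if (tail_allow > 0) {
      if (strand == "+") {
        tail_idx <- (same$end[i] + 1L):min(same$end[i] + tail_allow, L)
      } else {
        tail_idx <- max(same$start[i] - tail_allow, 1L):(same$start[i] - 1L)
      }
      in_tail[tail_idx] <- TRUE
    }
  }
  ok <- !in_body[cand$pos] | in_tail[cand$pos]
  cand[ok, , drop = FALSE]
}

#' Cluster TEP candidates by proximity
#'
#' Read-bearing positions less than `max_gap` bp apart chain into one
#' cluster. A cluster's span runs from its first to its last read-bearing
#' position; span positions without reads belong to the cluster with count
#' zero, so the cluster length `N` is the span length.
#'
#' @param candidates data.frame `pos`, `count` (sorted ascending).
#' @param strand "+" or "-".
#' @param max_gap chaining distance (default 10 nt).
#' @return list of `tep_cluster` objects: `strand`, `first`, `last`, `n`,
#'   `pos` (all span positions) and `r` (read counts, zero-filled).
#' @export
cluster_teps <- function(candidates, strand, max_gap = 10) {
  assert_strand(strand)
  if (nrow(candidates) == 0L) return(list())
  ids <- chain_clusters(candidates$pos, max_gap)
  lapply(unname(split(candidates, ids)), function(df) {
    first <- min(df$pos); last <- max(df$pos)
    pos <- first:last
    r <- numeric(length(pos))
    r[df$pos - first + 1L] <- df$count
    structure(list(strand = strand, first = first, last = last,
                   n = length(pos), pos = pos, r = r),
              class = "tep_cluster")
  })
}

#' Leave-one-out modified z-score of a cluster position
#'
#' For position `x` of a cluster with positions `C` and counts `r`, the
#' score compares `r(x)` with the mean and SD of the counts of the *other*
#' positions of the cluster:
#' \deqn{\mu = \frac{1}{N-1}\Big(-r(x) + \sum_{y \in C} r(y)\Big), \qquad
#'       \sigma = \sqrt{\mu(r^2) - \mu^2}, \qquad
#'       Z(x) = \frac{r(x) - \mu}{\sigma}}
#' with `N` the cluster (span) length and \eqn{\mu(r^2)} the leave-one-out
#' mean of the squared counts. Conventions where the formula is undefined:
#' a singleton cluster (`N = 1`) scores `+Inf`; when `sigma = 0`, the score
#' is `+Inf` if `r(x) > mu` and `0` otherwise.
#'
#' @param cluster `tep_cluster` from [cluster_teps()].
#' @param x genomic position, must lie within the cluster span.
#' @return numeric score (possibly `Inf`).
#' @export
modified_zscore <- function(cluster, x) {
  stopifnot(inherits(cluster, "tep_cluster"))
  if (x < cluster$first || x > cluster$last) {
    stop("position ", x, " outside cluster span [", cluster$first, ",",
         cluster$last, "]", call. = FALSE)
  }
  cluster_zscores(cluster)[x - cluster$first + 1L]
}

## Vectorised scores for every position of a cluster.
cluster_zscores <- function(cluster) {
  r <- cluster$r
  n <- cluster$n
  if (n == 1L) return(Inf)
  s1 <- sum(r)
  s2 <- sum(r^2)
  mu <- (s1 - r) / (n - 1)
  mu2 <- (s2 - r^2) / (n - 1)
  v <- pmax(mu2 - mu^2, 0)
  sigma <- sqrt(v)
  z <- ifelse(sigma > 0, (r - mu) / sigma, ifelse(r > mu, Inf, 0))
  z
}

#' Threshold cluster positions on count and z-score
#'
#' Positions with a read count below `min_reads` or a modified z-score below
#' `min_z` are discarded (both thresholds are inclusive: exactly 3 survives
#' at the defaults).
#'
#' @param clusters list of `tep_cluster`s.
#' @param min_reads minimum read count (default 3).
#' @param min_z minimum modified z-score (default 3).
#' @return data.frame `pos`, `count`, `zscore`, `cluster` (index into
#'   `clusters`) of surviving positions.
#' @export
filter_teps <- function(clusters, min_reads = 3, min_z = 3) {
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    z <- cluster_zscores(cl)
    keep <- cl$r >= min_reads & z >= min_z
    if (!any(keep)) return(NULL)
    data.frame(pos = cl$pos[keep], count = cl$r[keep], zscore = z[keep],
               cluster = i)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pos = integer(0), count = numeric(0),
                      zscore = numeric(0), cluster = integer(0))
  }
  out
}

#' Replicate-intersection selection window
#'
#' Given the spans of one cluster per biological replicate, the TEP is
#' searched within the intersection of the two spans. Returns `NULL` when
#' the spans do not overlap.
#'
#' @param span1,span2 length-2 vectors `c(first, last)`.
#' @return `c(first, last)` of the selection window, or `NULL`.
#' @export
#' @examples
#' reconcile_window(c(3, 25), c(13, 42))  # 13 25
reconcile_window <- function(span1, span2) {
  lo <- max(span1[1], span2[1])
  hi <- min(span1[2], span2[2])
  if (lo > hi) NULL else c(lo, hi)
}

#' Reconcile filtered TEP clusters between two replicates
#'
#' For every same-strand pair of clusters with overlapping spans, the
#' selection window is the span intersection; among positions that pass the
#' count/z filter in *both* replicates and lie in the window, the one with
#' the highest combined count is emitted (ties toward the 5'-most position).
#' A cluster overlapping several clusters of the other replicate is
#' evaluated against each independently; duplicate positions are
#' de-duplicated.
#'
#' @param clusters_r1,clusters_r2 `tep_cluster` lists for the two
#'   replicates (same strand).
#' @param min_reads,min_z thresholds passed to [filter_teps()].
#' @param rank how the "highest read count" ranks candidates: combined sum
#'   (default), the maximum of the two replicates, or replicate 1 alone.
#' @return data.frame `pos`, `strand`, `count_r1`, `count_r2`, `zscore_r1`,
#'   `zscore_r2`.
#' @export
reconcile_replicates <- function(clusters_r1, clusters_r2,
                                 min_reads = 3, min_z = 3,
                                 rank = c("sum", "max", "r1")) {
  rank <- match.arg(rank)
  if (length(clusters_r1) == 0L || length(clusters_r2) == 0L) {
    return(empty_tep_records())
  }
  strand <- clusters_r1[[1]]$strand
  surv1 <- filter_teps(clusters_r1, min_reads, min_z)
  surv2 <- filter_teps(clusters_r2, min_reads, min_z)
  if (nrow(surv1) == 0L || nrow(surv2) == 0L) return(empty_tep_records())

  ## overlap query on cluster spans instead of an all-pairs scan
  spans1 <- IRanges::IRanges(
    start = vapply(clusters_r1, `[[`, integer(1), "first"),
    end = vapply(clusters_r1, `[[`, integer(1), "last"))
  spans2 <- IRanges::IRanges(
    start = vapply(clusters_r2, `[[`, integer(1), "first"),
    end = vapply(clusters_r2, `[[`, integer(1), "last"))
  hits <- IRanges::findOverlaps(spans1, spans2)

  rows <- list()
  for (h in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[h]
    j <- S4Vectors::subjectHits(hits)[h]
    {
      c1 <- clusters_r1[[i]]
      c2 <- clusters_r2[[j]]
      win <- reconcile_window(c(c1$first, c1$last), c(c2$first, c2$last))
      if (is.null(win)) next
      p1 <- surv1[surv1$cluster == i & surv1$pos >= win[1] &
                    surv1$pos <= win[2], ]
      p2 <- surv2[surv2$cluster == j & surv2$pos >= win[1] &
                    surv2$pos <= win[2], ]
      common <- intersect(p1$pos, p2$pos)
      if (length(common) == 0L) next
      r1 <- p1$count[match(common, p1$pos)]
      r2 <- p2$count[match(common, p2$pos)]
      score <- switch(rank,
                      sum = r1 + r2,
                      max = pmax(r1, r2),
                      r1 = r1)
      best <- common[score == max(score)]
      sel <- five_prime_most(best, strand)
      k <- match(sel, common)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = sel, strand = strand, count_r1 = r1[k], count_r2 = r2[k],
        zscore_r1 = p1$zscore[match(sel, p1$pos)],
        zscore_r2 = p2$zscore[match(sel, p2$pos)],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_tep_records())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$pos), , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_tep_records <- function() {
  data.frame(pos = integer(0), strand = character(0),
             count_r1 = numeric(0), count_r2 = numeric(0),
             zscore_r1 = numeric(0), zscore_r2 = numeric(0),
             stringsAsFactors = FALSE)
}

#' Call TEPs from two replicate Term-Seq profile pairs
#'
#' Full caller over both strands: intergenic candidate collection, <10-bp
#' chaining, modified z-scoring, count/z thresholding per replicate, and
#' replicate reconciliation.
#'
#' @param term_r1,term_r2 lists with `plus`/`minus` [end_profile()]s for the
#'   two Term-Seq replicates.
#' @param genes gene table.
#' @param tail_allow candidate allowance downstream of gene 3' ends
#'   (default 10 nt).
#' @param max_gap cluster chaining distance (default 10 nt).
#' @param min_reads,min_z survival thresholds (default 3 and 3).
#' @param rank replicate ranking rule, see [reconcile_replicates()].
#' @return data.frame of TEP records with `category` and `gene_id`
#'   initialised to `NA` for [classify_tep()].
#' @export
find_tep <- function(term_r1, term_r2, genes, tail_allow = 10, max_gap = 10,
                     min_reads = 3, min_z = 3,
                     rank = c("sum", "max", "r1")) {
  rank <- match.arg(rank)
  genes <- validate_genes(genes)
  out <- list()
  for (key in c("plus", "minus")) {
    strand <- if (key == "plus") "+" else "-"
    c1 <- cluster_teps(
      collect_tep_candidates(term_r1[[key]], genes, tail_allow),
      strand, max_gap)
    c2 <- cluster_teps(
      collect_tep_candidates(term_r2[[key]], genes, tail_allow),
      strand, max_gap)
    out[[key]] <- reconcile_replicates(c1, c2, min_reads, min_z, rank)
  }
  res <- rbind(out$plus, out$minus)
  res <- res[order(res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res$category <- rep(NA_character_, nrow(res))
  res$gene_id <- rep(NA_character_, nrow(res))
  res
}
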