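## tss_caller: TSS identification from TAP(+)/TAP(-) dRNA-Seq 5'-end
## profiles.
##
## Candidate 5' ends from the TAP(+) library are chained into clusters
## (positions < 100 bp apart), greedily sub-clustered so each sub-cluster's
## positional SD stays < 10, count-filtered (total > 3 reads), reduced to
## the max-count member, and finally screened against the TAP(-) library:
## a position with strictly more TAP(-) than TAP(+) reads is a processed
## 5' end, not a TSS.

#' Collect TSS candidates from a TAP(+) profile
#'
#' Every position with at least one 5'-end read is a potential TSS.
#'
#' @param tap_plus TAP(+) [end_profile()] for one strand.
#' @return data.frame `pos`, `count`, ascending positions.
#' @export
collect_candidates <- function(tap_plus) {
  stopifnot(inherits(tap_plus, "end_profile"))
  profile_nonzero(tap_plus)
}

#' Cluster TSS candidates by proximity
#'
#' Candidates less than `max_gap` bp apart (gap of `max_gap - 1` or less)
#' chain into one cluster.
#'
#' @param candidates data.frame `pos`, `count` (sorted ascending).
#' @param max_gap clustering distance (default 100 nt).
#' @return list of data.frames, one per cluster.
#' @export
cluster_candidates <- function(candidates, max_gap = 100) {
  if (nrow(candidates) == 0L) return(list())
  ids <- chain_clusters(candidates$pos, max_gap)
  unname(split(candidates, ids))
}

#' Sub-cluster a TSS cluster by positional standard deviation
#'
#' Greedy left-to-right accumulation: the next position extends the current
#' sub-cluster iff the population SD of the extended position set stays
#' below `sd_limit`; otherwise it opens a new sub-cluster. Deterministic for
#' sorted input.
#'
#' @param cluster data.frame `pos`, `count` (one cluster, sorted).
#' @param sd_limit positional SD bound (default 10 nt).
#' @return list of data.frames, one per sub-cluster.
#' @export
subcluster_candidates <- function(cluster, sd_limit = 10) {
  n <- nrow(cluster)
  if (n == 0L) return(list())
  ids <- integer(n)
  cur <- 1L
  ## running first/second moments of the current sub-cluster's positions
  s1 <- 0; s2 <- 0; k <- 0L
  for (i in seq_len(n)) {
    ## offset by the cluster origin: SD is translation-invariant and the
    ## small magnitudes keep the moment difference numerically exact
    p <- as.numeric(cluster$pos[i] - cluster$pos[1])
    if (k == 0L || (s2 + p^2) / (k + 1) - ((s1 + p) / (k + 1))^2 <
          sd_limit^2) {
      s1 <- s1 + p; s2 <- s2 + p^2; k <- k + 1L
    } else {
      cur <- cur + 1L
      s1 <- p; s2 <- p^2; k <- 1L
    }
    ids[i] <- cur
  }
  unname(split(cluster, ids))
}

#' Select one TSS per qualifying sub-cluster
#'
#' Sub-clusters with a total TAP(+) count above `min_total_reads - 1` (the
#' "more than three read counts" filter at the default) emit the member
#' position with the maximum read count; ties break toward the 5'-most
#' member (smallest coordinate on "+", largest on "-").
#'
#' @param subclusters list of data.frames `pos`, `count`.
#' @param strand "+" or "-".
#' @param min_total_reads minimum sub-cluster total (default 4, i.e. > 3).
#' @return data.frame `pos`, `strand`, `tap_plus`.
#' @export
select_tss <- function(subclusters, strand, min_total_reads = 4) {
  assert_strand(strand)
  keep <- Filter(function(sc) sum(sc$count) >= min_total_reads, subclusters)
  if (length(keep) == 0L) {
    return(data.frame(pos = integer(0), strand = character(0),
                      tap_plus = numeric(0)))
  }
  rows <- lapply(keep, function(sc) {
    best <- sc$pos[sc$count == max(sc$count)]
    p <- five_prime_most(best, strand)
    data.frame(pos = p, strand = strand,
               tap_plus = sc$count[sc$pos == p],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$pos), , drop = FALSE]
}

#' Filter selected TSSs against the TAP(-) library
#'
#' A selected position with strictly more reads in the TAP(-) library than
#' in TAP(+) is discarded as a processed 5' end; ties are retained (only
#' "more" counts discard).
#'
#' @param tss data.frame from [select_tss()].
#' @param tap_minus TAP(-) [end_profile()] for the same strand.
#' @return `tss` with a `tap_minus` column, discarded rows removed.
#' @export
tap_filter <- function(tss, tap_minus) {
  stopifnot(inherits(tap_minus, "end_profile"))
  if (nrow(tss) == 0L) {
    tss$tap_minus <- numeric(0)
    return(tss)
  }
  tss$tap_minus <- tap_minus$counts[tss$pos]
  tss[tss$tap_minus <= tss$tap_plus, , drop = FALSE]
}

#' Call TSSs from TAP(+)/TAP(-) profile pairs
#'
#' Full caller over both strands: candidate collection, <`max_gap` chaining,
#' SD-bounded sub-clustering, the total-count filter, per-sub-cluster
#' max-count selection, and the TAP(-) screen.
#'
#' The count filter is applied at the sub-cluster level by default; set
#' `count_filter_level = "cluster"` to require the total over the whole
#' 100-bp cluster instead.
#'
#' @param tap_plus,tap_minus lists with `plus` and `minus` [end_profile()]s
#'   for the TAP(+) and TAP(-) libraries.
#' @param max_gap cluster chaining distance (default 100 nt).
#' @param sd_limit sub-cluster positional SD bound (default 10 nt).
#' @param min_total_reads minimum total read count (default 4).
#' @param count_filter_level `"subcluster"` (default) or `"cluster"`.
#' @return data.frame `pos`, `strand`, `tap_plus`, `tap_minus`, with
#'   `category` and `gene_id` columns initialised to `NA` for
#'   [classify_tss()].
#' @export
find_tss <- function(tap_plus, tap_minus, max_gap = 100, sd_limit = 10,
                     min_total_reads = 4,
                     count_filter_level = c("subcluster", "cluster")) {
  count_filter_level <- match.arg(count_filter_level)
  out <- list()
  for (key in c("plus", "minus")) {
    strand <- if (key == "plus") "+" else "-"
    cands <- collect_candidates(tap_plus[[key]])
    clusters <- cluster_candidates(cands, max_gap)
    if (count_filter_level == "cluster") {
      clusters <- Filter(function(cl) sum(cl$count) >= min_total_reads,
                         clusters)
    }
    subs <- unlist(lapply(clusters, subcluster_candidates,
                          sd_limit = sd_limit), recursive = FALSE)
    sel <- select_tss(
      subs, strand,
      min_total_reads = if (count_filter_level == "cluster") 1 else
        min_total_reads
    )
    out[[key]] <- tap_filter(sel, tap_minus[[key]])
  }
  res <- rbind(out$plus, out$minus)
  res <- res[order(res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res$category <- rep(NA_character_, nrow(res))
  res$gene_id <- rep(NA_character_, nrow(res))
  res
}
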