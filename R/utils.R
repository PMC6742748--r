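STRANDS <- c("+", "-")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_strand <- function(strand) {
  if (!(length(strand) == 1L && strand %in% STRANDS)) {
    stop("strand must be \"+\" or \"-\"", call. = FALSE)
  }
  strand
}

## Population standard deviation (divisor n, not n-1): the sub-clustering
## criterion bounds the dispersion of the positions themselves.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Chain positions into clusters by gap distance
#'
#' Single-linkage chaining of sorted genomic positions: a position joins the
#' current cluster when its distance to the previous position is strictly less
#' than `max_gap`, otherwise a new cluster starts. This is the shared
#' primitive behind TSS clustering (`max_gap = 100`) and TEP clustering
#' (`max_gap = 10`).
#'
#' @param pos sorted integer vector of genomic positions (1-based).
#' @param max_gap positions closer than this (gap `<= max_gap - 1`) chain.
#' @return integer vector of cluster ids (1, 2, ...), same length as `pos`.
#' @export
#' @examples
#' chain_clusters(c(100, 150, 260), max_gap = 100)  # 1 1 2
chain_clusters <- function(pos, max_gap) {
  if (is.unsorted(pos, strictly = FALSE)) {
    stop("positions must be sorted ascending", call. = FALSE)
  }
  if (length(pos) == 0L) return(integer(0))
  cumsum(c(1L, as.integer(diff(pos) >= max_gap)))
}

## 5'-most of a set of positions on a strand: smallest coordinate on "+",
## largest on "-".
five_prime_most <- function(pos, strand) {
  if (strand == "+") min(pos) else max(pos)
}

#' Summarise a count as a fraction of a total
#'
#' Small reporting utility used for category breakdown tables: formats
#' `n / total` as a percentage rounded to `digits` decimals, the way results
#' tables quote shares such as "683/1,282 (53.28%)".
#'
#' @param n numerator count(s).
#' @param total denominator count.
#' @param digits decimal places for the percentage (default 2).
#' @return data.frame with columns `n`, `total`, `percent` and a formatted
#'   `label` column.
#' @export
#' @examples
#' fraction_summary(683, 1282)$percent  # 53.28
fraction_summary <- function(n, total, digits = 2) {
  stopifnot(total > 0, all(n >= 0))
  pct <- round(100 * n / total, digits)
  data.frame(
    n = n, total = total, percent = pct,
    label = sprintf("%s/%s (%.*f%%)",
                    format(n, big.mark = ","), format(total, big.mark = ","),
                    digits, pct),
    stringsAsFactors = FALSE
  )
}

## 5'-most coding position of each gene (start codon side): start on "+",
## end on "-".
gene_5p <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)

## 3'-most coding position of each gene (stop codon side).
gene_3p <- function(genes) ifelse(genes$strand == "+", genes$end, genes$start)

validate_genes <- function(genes) {
  need <- c("gene_id", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop("gene table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(genes$start > genes$end)) stop("gene start > end", call. = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation", call. = FALSE)
  }
  if (!all(genes$strand %in% STRANDS)) {
    stop("gene strand must be \"+\" or \"-\"", call. = FALSE)
  }
  genes[order(genes$start, genes$gene_id), , drop = FALSE]
}
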