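#' Run the full TU architecture pipeline
#'
#' Convenience wrapper chaining the callers, classifiers, TU assembly,
#' coverage scoring and TU clustering on an in-memory profile set (e.g.
#' from [simulate_dataset()] or assembled from [read_end_profile()] calls).
#'
#' @param profiles named list with `tap_plus`, `tap_minus`, `term_r1`,
#'   `term_r2` and optionally `rnaseq` profile pairs (`plus`/`minus`).
#' @param genes gene table.
#' @param genome_length replicon length (nt).
#' @param params [class_params()].
#' @param tss_args,tep_args,tu_args named lists of extra arguments for
#'   [find_tss()], [find_tep()] and [assemble_tus()].
#' @return list with `tss`, `primary_tss`, `tep`, `tus` (categorized, with
#'   coverage scores when RNA-Seq is present) and `clusters`
#'   ([cluster_tus()] output).
#' @export
run_tu_pipeline <- function(profiles, genes, genome_length,
                            params = class_params(),
                            tss_args = list(), tep_args = list(),
                            tu_args = list()) {
  genes <- validate_genes(genes)
  tss <- do.call(find_tss, c(list(profiles$tap_plus, profiles$tap_minus),
                             tss_args))
  tss <- classify_tss(tss, genes, params)
  primary <- tss[tss$category == "P", c("gene_id", "pos", "strand")]
  tep <- do.call(find_tep, c(list(profiles$term_r1, profiles$term_r2, genes),
                             tep_args))
  tep <- classify_tep(tep, genes, primary, params)
  tus <- do.call(assemble_tus,
                 c(list(tss, tep, genes, genome_length), tu_args))
  tus <- categorize_tus(tus, genes)
  if (!is.null(profiles$rnaseq)) {
    tus <- coverage_consistency(tus, profiles$rnaseq)
  }
  list(tss = tss, primary_tss = primary, tep = tep, tus = tus,
       clusters = cluster_tus(tus))
}

#' Compare called sites against planted ground truth
#'
#' Matches each planted site to the nearest called site on the same strand
#' and reports recovery (planted sites with a call within `tol` nt) and
#' spurious-call (calls with no planted site within `tol` nt) rates.
#'
#' @param called data.frame with `pos`, `strand` (called sites).
#' @param planted data.frame with `pos`, `strand` (ground truth).
#' @param tol matching tolerance in nt (default 2).
#' @return list with `recovered`, `n_planted`, `recovery`, `spurious`,
#'   `n_called`, `spurious_rate`.
#' @export
site_recovery <- function(called, planted, tol = 2) {
  hit <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      same <- b$strand == a$strand[i]
      any(abs(b$pos[same] - a$pos[i]) <= tol)
    }, logical(1))
  }
  rec <- if (nrow(planted)) hit(planted, called) else logical(0)
  spu <- if (nrow(called)) !hit(called, planted) else logical(0)
  list(recovered = sum(rec), n_planted = nrow(planted),
       recovery = if (nrow(planted)) mean(rec) else NA_real_,
       spurious = sum(spu), n_called = nrow(called),
       spurious_rate = if (nrow(called)) mean(spu) else NA_real_)
}
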