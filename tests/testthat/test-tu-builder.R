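cls_tss <- function(pos, strand, category, gene_id = NA_character_,
                    tap_plus = 10) {
  data.frame(pos = as.integer(pos), strand = strand, tap_plus = tap_plus,
             tap_minus = 0, category = category, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

cls_tep <- function(pos, strand, category, gene_id = NA_character_) {
  data.frame(pos = as.integer(pos), strand = strand, count_r1 = 5,
             count_r2 = 5, zscore_r1 = Inf, zscore_r2 = Inf,
             category = category, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

test_that("the downstream walk respects the 500-nt intergenic rule", {
  L <- 5000L
  genes <- make_genes(list("G1", 100, 400, "+"), list("G2", 600, 900, "+"))
  tss <- cls_tss(50, "+", "P", "G1")
  tep <- cls_tep(950, "+", "P", "G2")
  tus <- assemble_tus(tss, tep, genes, L)
  expect_equal(nrow(tus), 1L)
  tus <- categorize_tus(tus, genes)
  expect_equal(tus$genes[[1]], c("G1", "G2"))
  expect_equal(tus$category, "polycistronic")

  # gap of 600 nt stops the walk before G2: the TEP is unreachable
  genes2 <- make_genes(list("G1", 100, 400, "+"), list("G2", 1001, 1300, "+"))
  tus2 <- assemble_tus(tss, cls_tep(1350, "+", "P", "G2"), genes2, L)
  expect_equal(nrow(tus2), 0L)
})

test_that("every TEP in the reachable extent yields one TU variant", {
  L <- 5000L
  genes <- make_genes(list("G1", 100, 400, "+"), list("G2", 600, 900, "+"))
  tss <- cls_tss(50, "+", "P", "G1")
  teps <- rbind(cls_tep(500, "+", "P", "G1"), cls_tep(950, "+", "P", "G2"))
  tus <- categorize_tus(assemble_tus(tss, teps, genes, L), genes)
  expect_equal(nrow(tus), 2L)
  expect_equal(sort(tus$tep_pos), c(500L, 950L))
  expect_equal(tus$category[tus$tep_pos == 500], "monocistronic")
  expect_equal(tus$category[tus$tep_pos == 950], "polycistronic")
})

test_that("antisense/intergenic TSSs scan 1 kbp for a TEP or start codon", {
  L <- 10000L
  genes <- make_genes(list("G1", 100, 400, "+"))
  # nearest same-strand TEP within 1 kbp closes a gene-less TU
  tus <- assemble_tus(cls_tss(5000, "+", "N"), cls_tep(5200, "+", "N"),
                      genes, L)
  expect_equal(nrow(tus), 1L)
  expect_equal(tus$tep_pos, 5200L)
  tus <- categorize_tus(tus, genes)
  expect_equal(tus$category, "sRNA")  # no downstream gene near the TSS

  # a TEP beyond 1 kbp is out of reach
  none <- assemble_tus(cls_tss(5000, "+", "N"), cls_tep(6200, "+", "N"),
                       genes, L)
  expect_equal(nrow(none), 0L)

  # a start codon first: the walking rules take over
  genes3 <- make_genes(list("G1", 5300, 5600, "+"))
  tus3 <- assemble_tus(cls_tss(5000, "+", "N"), cls_tep(5700, "+", "P", "G1"),
                       genes3, L)
  expect_equal(nrow(tus3), 1L)
  expect_equal(categorize_tus(tus3, genes3)$category, "monocistronic")
})

test_that("internal TSSs exclude their host gene from association", {
  L <- 5000L
  genes <- make_genes(list("G1", 100, 1000, "+"), list("G2", 1200, 1800, "+"))
  tss <- cls_tss(500, "+", "I")       # inside G1
  tep <- cls_tep(1900, "+", "P", "G2")
  tus <- categorize_tus(assemble_tus(tss, tep, genes, L), genes)
  expect_equal(tus$genes[[1]], "G2")  # host G1 not associated
  expect_equal(tus$category, "monocistronic")
})

test_that("cis-regulatory TEPs pair only with TSSs of the same gene", {
  L <- 5000L
  genes <- make_genes(list("G1", 1000, 1600, "+"), list("G2", 2000, 2600, "+"))
  tss <- rbind(cls_tss(900, "+", "P", "G1"), cls_tss(1950, "+", "P", "G2"))
  tep <- cls_tep(980, "+", "C", "G1")  # in G1's 5'-UTR
  tus <- assemble_tus(tss, tep, genes, L)
  expect_equal(nrow(tus), 1L)
  expect_equal(tus$tss_pos, 900L)
  tus <- categorize_tus(tus, genes)
  expect_equal(tus$category, "cis_regulatory")  # gene-less, start < 500 nt
})

test_that("gene-less TUs split into cis-regulatory and sRNA by distance", {
  L <- 10000L
  genes <- make_genes(list("G1", 5400, 5800, "+"))
  near <- categorize_tus(
    assemble_tus(cls_tss(5000, "+", "N"), cls_tep(5200, "+", "N"), genes, L),
    genes)
  expect_equal(near$category, "cis_regulatory")  # next start 400 nt away
  genes2 <- make_genes(list("G1", 5700, 6100, "+"))
  far <- categorize_tus(
    assemble_tus(cls_tss(5000, "+", "N"), cls_tep(5200, "+", "N"), genes2, L),
    genes2)
  expect_equal(far$category, "sRNA")             # next start 700 nt away
})

test_that("assembly is strand-symmetric", {
  L <- 5000L
  genes <- make_genes(list("G1", 100, 400, "+"), list("G2", 600, 900, "+"))
  tss <- cls_tss(50, "+", "P", "G1")
  tep <- cls_tep(950, "+", "P", "G2")
  fwd <- categorize_tus(assemble_tus(tss, tep, genes, L), genes)

  flip <- function(p) L + 1L - p
  genes_m <- make_genes(list("G1", flip(400), flip(100), "-"),
                        list("G2", flip(900), flip(600), "-"))
  tss_m <- cls_tss(flip(50), "-", "P", "G1")
  tep_m <- cls_tep(flip(950), "-", "P", "G2")
  rev <- categorize_tus(assemble_tus(tss_m, tep_m, genes_m, L), genes_m)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$tss_pos, flip(fwd$tss_pos))
  expect_equal(rev$tep_pos, flip(fwd$tep_pos))
  expect_equal(rev$genes[[1]], fwd$genes[[1]])
  expect_equal(rev$category, fwd$category)
})

test_that("coverage consistency scores the covered fraction of the span", {
  L <- 1000L
  tus <- data.frame(tu_id = "TU_1", strand = "+", tss_pos = 101L,
                    tep_pos = 600L, start = 101L, end = 600L,
                    tss_category = "P", tss_gene = "G1",
                    stringsAsFactors = FALSE)
  full <- list(plus = make_profile(101:600, rep(50, 500), "+", L, "RNASEQ"),
               minus = zero_profile("-", L, "RNASEQ"))
  got <- coverage_consistency(tus, full)
  expect_equal(got$coverage_score, 1)
  expect_true(got$coverage_pass)

  none <- list(plus = zero_profile("+", L, "RNASEQ"),
               minus = zero_profile("-", L, "RNASEQ"))
  got <- coverage_consistency(tus, none)
  expect_equal(got$coverage_score, 0)
  expect_false(got$coverage_pass)

  part <- list(plus = make_profile(101:550, rep(2, 450), "+", L, "RNASEQ"),
               minus = zero_profile("-", L, "RNASEQ"))
  got <- coverage_consistency(tus, part)
  expect_equal(got$coverage_score, 0.9)
  expect_true(got$coverage_pass)
  # flagged, not deleted, unless asked
  expect_equal(nrow(coverage_consistency(tus, none, drop_failing = TRUE)), 0L)
})

test_that("TU clusters are connected components over shared genes", {
  tus <- data.frame(tu_id = c("t1", "t2", "t3"), stringsAsFactors = FALSE)
  tus$genes <- list(c("G1", "G2"), c("G2", "G3"), "G5")
  cl <- cluster_tus(tus)
  expect_equal(nrow(cl$clusters), 2L)
  m <- cl$membership
  expect_equal(m$cluster_id[m$tu_id == "t1"], m$cluster_id[m$tu_id == "t2"])
  expect_false(m$cluster_id[m$tu_id == "t3"] == m$cluster_id[m$tu_id == "t1"])
  expect_equal(sum(cl$clusters$n_tus), 3L)

  # chained sharing joins transitively
  tus4 <- data.frame(tu_id = paste0("t", 1:4), stringsAsFactors = FALSE)
  tus4$genes <- list(c("G1", "G2"), c("G2", "G3"), c("G3", "G4"), "G9")
  cl4 <- cluster_tus(tus4)
  expect_equal(max(cl4$clusters$n_tus), 3L)

  # all gene-disjoint: one cluster per TU (gene-less TUs are singletons)
  tusd <- data.frame(tu_id = paste0("t", 1:3), stringsAsFactors = FALSE)
  tusd$genes <- list("G1", "G7", character(0))
  expect_equal(nrow(cluster_tus(tusd)$clusters), 3L)
})

test_that("TU count grows with genes per cluster on overlapping loci", {
  # loci with k = 1..4 genes, each with nested TU variants (one per TEP):
  # cluster with more genes carries more TUs, a positive rank association
  L <- 60000L
  genes <- list(); tss <- list(); tep <- list()
  base <- 1000L
  for (k in 1:4) {
    ids <- sprintf("L%d_g%d", k, 1:k)
    starts <- base + (0:(k - 1)) * 700L
    genes[[k]] <- do.call(make_genes, lapply(seq_len(k), function(j) {
      list(ids[j], starts[j], starts[j] + 400L, "+")
    }))
    tss[[k]] <- cls_tss(base - 100L, "+", "P", ids[1])
    tep[[k]] <- do.call(rbind, lapply(seq_len(k), function(j) {
      cls_tep(starts[j] + 450L, "+", if (j == k) "P" else "S", ids[j])
    }))
    base <- base + k * 700L + 2000L
  }
  genes <- do.call(rbind, genes)
  tus <- categorize_tus(
    assemble_tus(do.call(rbind, tss), do.call(rbind, tep), genes, L), genes)
  cl <- cluster_tus(tus)
  big <- cl$clusters[cl$clusters$n_genes >= 2, ]
  expect_gt(nrow(big), 1L)
  rho <- suppressWarnings(
    cor(big$n_tus, big$n_genes, method = "spearman"))
  expect_gt(rho, 0)
})

test_that("assembled TU invariants hold on simulated data", {
  ds <- simulate_dataset(sim_config(seed = 23, n_genes = 40))
  res <- run_tu_pipeline(ds$profiles, ds$truth$genes, ds$truth$genome$length)
  tus <- res$tus
  genes <- ds$truth$genes
  for (i in seq_len(nrow(tus))) {
    ids <- tus$genes[[i]]
    if (length(ids) == 0) next
    gs <- genes[match(ids, genes$gene_id), ]
    # associated genes fully inside the span
    expect_true(all(gs$start >= tus$start[i] & gs$end <= tus$end[i]))
    gs <- gs[order(gs$start), ]
    if (nrow(gs) > 1) {
      gaps <- gs$start[-1] - gs$end[-nrow(gs)] - 1L
      expect_true(all(gaps <= 500))
    }
  }
  cl <- res$clusters
  expect_gte(nrow(tus), nrow(cl$clusters))
  expect_equal(sum(cl$clusters$n_tus), nrow(tus))
})
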