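test_that("5'-UTR lengths and leaderless flags follow the strand", {
  genes <- make_genes(list("gA", 1000, 2000, "+"), list("gB", 3000, 4000, "-"))
  ptss <- data.frame(gene_id = c("gA", "gA", "gA", "gB"),
                     pos = c(900L, 1000L, 995L, 4100L),
                     strand = c("+", "+", "+", "-"))
  got <- utr_lengths(ptss, genes)
  expect_equal(got$utr_length, c(100L, 0L, 5L, 100L))
  expect_equal(got$leaderless, c(FALSE, TRUE, TRUE, FALSE))
  # mirrored fixtures agree across strands
  expect_equal(got$utr_length[1], got$utr_length[4])

  # TSS downstream of the start codon: length 0, flagged
  int <- utr_lengths(data.frame(gene_id = "gA", pos = 1050L, strand = "+"),
                     genes)
  expect_equal(int$utr_length, 0L)
  expect_true(int$tss_internal)
  expect_true(int$leaderless)
})

test_that("start codons are read off the genome strand-correctly", {
  # plus gene starting ATG at 11; minus gene whose revcomp start codon is GTG
  seq <- paste(rep("A", 40), collapse = "")
  substr(seq, 11, 13) <- "ATG"
  substr(seq, 28, 30) <- "CAC"  # revcomp(CAC) = GTG read 5'->3' on minus
  g <- genome(seq)
  genes <- make_genes(list("gP", 11, 22, "+"), list("gM", 19, 30, "-"))
  ptss <- data.frame(gene_id = c("gP", "gM"), pos = c(11L, 30L),
                     strand = c("+", "-"))
  got <- utr_lengths(ptss, genes, g)
  expect_equal(got$start_codon[got$gene_id == "gP"], "ATG")
  expect_equal(got$start_codon[got$gene_id == "gM"], "GTG")

  tal <- start_codon_tally(got)
  expect_equal(tal$leaderless[tal$codon == "ATG"], 1)
  expect_equal(tal$leaderless[tal$codon == "GTG"], 1)
  expect_equal(tal$all[tal$codon == "ATG"], 1)
  expect_equal(sum(tal$all), 2)
})

test_that("simulated leaderless fraction matches the planted architecture", {
  ds <- simulate_dataset(sim_config(seed = 20, n_genes = 20,
                                    leaderless_fraction = 0.2))
  truth <- ds$truth
  first_gene <- vapply(truth$tus$genes, `[`, character(1), 1)
  ptss <- data.frame(gene_id = first_gene, pos = truth$tss$pos,
                     strand = truth$tss$strand)
  got <- utr_lengths(ptss, truth$genes, truth$genome)
  expect_equal(mean(got$leaderless), mean(truth$tus$leaderless))
  expect_true(all(got$start_codon == "ATG"))  # generator plants ATG starts
})

test_that("promoter and terminator windows use the documented spans", {
  set.seed(40)
  g <- genome(paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                    collapse = ""))
  tss <- data.frame(pos = 1000L, strand = "+")
  w10 <- extract_windows(tss, g, "minus10")
  expect_equal(unname(nchar(as.character(w10))), 22L)
  expect_equal(as.character(w10)[[1]], substr(g$sequence, 980, 1001))
  w35 <- extract_windows(tss, g, "minus35")
  expect_equal(as.character(w35)[[1]], substr(g$sequence, 960, 975))

  # minus strand mirrors and reverse-complements
  tssm <- data.frame(pos = 1000L, strand = "-")
  w35m <- extract_windows(tssm, g, "minus35")
  expect_equal(as.character(w35m)[[1]],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(g$sequence, 1025, 1040)))))

  tep <- data.frame(pos = 1000L, strand = "+")
  expect_equal(unname(nchar(as.character(
    extract_windows(tep, g, "tep_context")))), 62L)
  expect_equal(as.character(extract_windows(tep, g, "tep_upstream"))[[1]],
               substr(g$sequence, 959, 999))

  # windows truncated at the replicon edge are dropped with a warning
  expect_warning(
    short <- extract_windows(data.frame(pos = c(5L, 1000L), strand = "+"),
                             g, "minus10"),
    "truncated")
  expect_length(short, 1L)
})

test_that("RBS windows require a 5'-UTR longer than 10 nt", {
  set.seed(41)
  g <- genome(paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                    collapse = ""))
  genes <- make_genes(list("g1", 500, 700, "+"), list("g2", 900, 1100, "+"),
                      list("g3", 1500, 1700, "-"))
  utr <- data.frame(gene_id = c("g1", "g2", "g3"),
                    utr_length = c(8L, 20L, 40L),
                    leaderless = c(TRUE, FALSE, FALSE),
                    tss_internal = FALSE, start_codon = "ATG")
  got <- rbs_windows(utr, genes, g)
  expect_equal(names(got), c("g2", "g3"))       # utr 8 excluded
  expect_equal(unname(nchar(as.character(got))), c(20L, 25L))  # capped at 25
  expect_equal(as.character(got)[["g2"]], substr(g$sequence, 880, 899))
})

test_that("spacer length counts nucleotides strictly between the elements", {
  # TSS-relative -35 at [-34,-31] and -10 at [-12,-7] around TSS 1000
  expect_equal(spacer_length(c(966, 969), c(988, 993), "+"), 18L)
  # mirrored on the minus strand (TSS 1000, same relative layout)
  expect_equal(spacer_length(c(1031, 1034), c(1007, 1012), "-"), 18L)
  # abutting elements: zero
  expect_equal(spacer_length(c(960, 969), c(970, 975), "+"), 0L)
  # overlapping elements: zero with a warning
  expect_warning(sp <- spacer_length(c(960, 972), c(970, 975), "+"),
                 "overlap")
  expect_equal(sp, 0L)
})

test_that("nucleotide frequencies sum to one and detect planted bases", {
  set.seed(50)
  g <- genome(paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                    collapse = ""))
  genes <- make_genes(list("g1", 18000, 19000, "+"))
  # plant sites whose +2 offset is always T on the plus strand
  pool <- 100:15000
  has_t <- pool[substring(g$sequence, pool + 2, pool + 2) == "T"]
  sites <- data.frame(pos = sample(has_t, 200), strand = "+")
  st <- nucleotide_stats(sites, g, genes, offsets = c(-3L, 3L),
                         n_background = 2000, seed = 4)
  expect_equal(unname(rowSums(st$frequency)), rep(1, 7))
  expect_equal(unname(st$frequency["+2", "T"]), 1)
  # T enriched ~4x over the uniform background at +2, ~1x elsewhere
  expect_gt(st$enrichment["+2", "T"], 3)
  expect_lt(abs(st$enrichment["-3", "T"] - 1), 0.35)
})

test_that("rpkm follows its unit definition and scaling laws", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(50, 500, 2e6), 50)
  # linear in count, inverse in length and library size
  expect_equal(rpkm(20, 1000, 1e6), 2 * rpkm(10, 1000, 1e6))
  expect_equal(rpkm(10, 2000, 1e6), rpkm(10, 1000, 1e6) / 2)
  expect_equal(rpkm(10, 1000, 2e6), rpkm(10, 1000, 1e6) / 2)
})

test_that("translation efficiency is the RPKM ratio with NA at zero RNA", {
  expect_equal(translation_efficiency(30, 10), 3)
  expect_equal(translation_efficiency(0, 10), 0)
  expect_true(is.na(translation_efficiency(5, 0)))
})

test_that("zero-noise simulations recover planted TE factors", {
  cfg <- sim_config(seed = 14, n_genes = 10, background_rate = 0,
                    peak_jitter_sd = 0, tap_minus_processed_site_rate = 0,
                    te_log_sd = 0, count_noise = FALSE)
  truth <- simulate_truth(cfg)
  cov <- simulate_coverage(truth, cfg)
  et <- expression_table(truth$genes, cov$rnaseq, cov$riboseq)
  # all genes planted at TE factor exactly 1
  expect_equal(et$te, rep(1, nrow(et)))

  # planted factors 1 vs 3 give an exact TE ratio of 3
  cfg2 <- sim_config(seed = 15, n_genes = 2, background_rate = 0,
                     peak_jitter_sd = 0, tap_minus_processed_site_rate = 0,
                     te_log_sd = 0, count_noise = FALSE)
  truth2 <- simulate_truth(cfg2)
  truth2$genes$te_factor <- c(1, 3)
  cov2 <- simulate_coverage(truth2, cfg2)
  et2 <- expression_table(truth2$genes, cov2$rnaseq, cov2$riboseq)
  expect_equal(et2$te[2] / et2$te[1], 3, tolerance = 1e-12)
})

test_that("fraction summaries format shares the way results tables do", {
  fs <- fraction_summary(683, 1282)
  expect_equal(fs$percent, 53.28)
  expect_match(fs$label, "53.28%")
  expect_equal(fraction_summary(867, 1282)$percent, 67.63)
})
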