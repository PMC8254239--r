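test_that("ORF length converts to encoded protein length", {
  expect_equal(orf_protein_length(690), 229)
  expect_equal(orf_protein_length(6), 1)
  expect_error(orf_protein_length(689), "multiple of 3")
  expect_error(orf_protein_length(3), "multiple of 3")
})

test_that("candidate-region span is the Mb boundary difference", {
  reg <- candidate_region("D10", 3.08e6, 3.42e6)
  expect_equal(region_span_mb(reg), 0.34)
  expect_error(candidate_region("D10", 10, 10), "start")
})

test_that("gene-region overlap requires at least one shared base", {
  reg <- candidate_region("c1", 100, 200)
  genes <- data.frame(gene_id = c("in", "out"), chrom = "c1",
                      start = c(150, 201), end = c(300, 300))
  hits <- genes_in_regions(reg, genes)
  expect_equal(hits$genes$gene_id, "in")
  expect_equal(hits$summary$n_genes, 1L)

  tiling <- data.frame(gene_id = paste0("g", 1:5), chrom = "c1",
                       start = seq(1, 401, by = 100),
                       end = seq(100, 500, by = 100))
  hits <- genes_in_regions(candidate_region("c1", 150, 350), tiling)
  expect_equal(sort(hits$genes$gene_id), c("g2", "g3", "g4"))

  off <- data.frame(gene_id = "far", chrom = "c9", start = 1, end = 10)
  expect_message(res <- genes_in_regions(reg, off), "skipped")
  expect_equal(nrow(res$genes), 0)
})

test_that("gene-region overlap agrees with brute-force enumeration", {
  set.seed(13)
  for (rep in 1:20) {
    nr <- sample(1:4, 1); ng <- sample(1:12, 1)
    rs <- sample(1:500, nr)
    regions <- data.frame(chrom = sample(c("c1", "c2"), nr, replace = TRUE),
                          start = rs, end = rs + sample(10:200, nr))
    gs <- sample(1:600, ng)
    genes <- data.frame(gene_id = paste0("g", seq_len(ng)),
                        chrom = sample(c("c1", "c2"), ng, replace = TRUE),
                        start = gs, end = gs + sample(5:150, ng))
    got <- suppressMessages(genes_in_regions(regions, genes))$genes
    want <- brute_genes_in_regions(regions, genes)
    got <- got[order(got$region_id, got$gene_id), ]
    want <- want[order(want$region_id, want$gene_id), ]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("start-codon offsets are strand-aware and anchored at the A of ATG", {
  expect_equal(offset_from_start_codon(3330215, 3330532, "+"), -317)
  expect_equal(offset_from_start_codon(100, 100, "+"), 0)
  expect_equal(offset_from_start_codon(110, 100, "-"), -10)
  expect_equal(offset_from_start_codon(90, 100, "-"), 10)
  expect_error(offset_from_start_codon(1, 1, "x"), "strand")
})

test_that("SNP locations classify against gene models", {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "c1", strand = c("+", "-"),
    start = c(1000, 100), end = c(3000, 450),
    start_codon = c(1500, 400))
  exons <- data.frame(gene_id = c("gA", "gA"),
                      start = c(1000, 2200), end = c(1800, 3000))

  utr <- classify_snp("c1", 1200, genes, exons)
  expect_equal(utr$location_class, "five_prime_utr")
  expect_equal(utr$offset_from_start_codon, -300)

  expect_equal(classify_snp("c1", 1600, genes, exons)$location_class, "exonic")
  expect_equal(classify_snp("c1", 2000, genes, exons)$location_class, "intronic")
  # without exon structures the downstream gene body counts as exonic
  expect_equal(classify_snp("c1", 2000, genes)$location_class, "exonic")

  # 5' of gA (+, window upstream of start 1000) and of gB (-, window after 450)
  up <- classify_snp("c1", 500, genes, exons, upstream_window = 1000)
  expect_equal(up$location_class, "upstream")
  expect_setequal(strsplit(up$upstream_of, ",")[[1]], c("gA", "gB"))

  far <- classify_snp("c1", 900000, genes, exons)
  expect_equal(far$location_class, "intergenic")
  expect_equal(far$upstream_of, "")
})

test_that("zygosity calls use the alt-fraction rule at sufficient depth", {
  expect_equal(call_zygosity(9, 1), "hom")
  expect_equal(call_zygosity(1, 9), "hom")
  expect_equal(call_zygosity(8, 2), "het")
  expect_equal(call_zygosity(5, 5), "het")
  expect_true(is.na(call_zygosity(4, 4)))
  expect_equal(call_zygosity(c(9, 8), c(1, 2)), c("hom", "het"))
})

test_that("the nine-SNP recessive-model screen retains exactly the 5'-UTR SNP", {
  snps <- triage_fixture()
  res <- triage_snps(snps, triage_directions)
  expect_equal(sum(res$retained), 1L)
  expect_equal(res$snp_id[res$retained], "A3330215T")
  expect_equal(sum(res$excluded_r1), 2L)
  expect_equal(sum(res$excluded_r2), 6L)
  expect_equal(sort(res$reasons[!res$retained]),
               sort(c(rep("R1", 2), rep("R2", 6))))
  expect_true(all(nzchar(res$reasons[!res$retained])))
})

test_that("triage is order-independent", {
  snps <- triage_fixture()
  res <- triage_snps(snps, triage_directions)
  perm <- sample(nrow(snps))
  res_perm <- triage_snps(snps[perm, ], triage_directions)
  expect_equal(res_perm$retained, res$retained[perm])
  expect_equal(res_perm$reasons, res$reasons[perm])
})

test_that("concordant shared-upstream genes do not trigger exclusion", {
  snps <- data.frame(snp_id = "s1", zygosity_y = "hom",
                     upstream_of = "gX,gY")
  expect_true(triage_snps(snps, c(gX = "down", gY = "down"))$retained)
  expect_true(triage_snps(snps, c(gX = "down", gY = "ns"))$retained)
  expect_false(triage_snps(snps, c(gX = "down", gY = "up"))$retained)
  single <- data.frame(snp_id = "s2", zygosity_y = "hom", upstream_of = "gX")
  expect_true(triage_snps(single, c(gX = "up"))$retained)
})

test_that("a shared-upstream gene without an expression direction is an error", {
  snps <- data.frame(snp_id = "s1", zygosity_y = "hom",
                     upstream_of = "gX,gZ")
  expect_error(triage_snps(snps, c(gX = "down")), "gZ")
  expect_error(triage_snps(snps, c(gX = "down", gZ = "higher")), "up/down/ns")
})
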