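test_that("sequence identity is exact for equal lengths and global otherwise", {
  set.seed(30)
  s <- random_seq(900)
  expect_equal(seq_identity(s, s), 100)
  s2 <- mutate_seq(s, 9L)
  expect_equal(seq_identity(s, s2), 100 * 891 / 900)
  # unequal lengths: end-to-end alignment, identity over the mean length
  expect_equal(seq_identity(s, substr(s, 1, 600)), 100 * 600 / 750,
               tolerance = 0.01)
})

test_that("reciprocal best hits build OGs with paralog flags and cut-offs", {
  set.seed(31)
  x <- random_seq(600)
  y <- random_seq(600)
  z <- random_seq(600)
  genes <- data.frame(
    genome_id = c("A", "A", "B", "B", "C", "C"),
    gene_id = c("A|x", "A|y", "B|x", "B|y", "C|x", "C|y"),
    seq = c(x, y,
            mutate_seq(x, 30L), mutate_seq(y, 18L),   # 95%, 97%
            mutate_seq(x, 24L), mutate_seq(y, 30L)),  # 96%, 95%
    stringsAsFactors = FALSE)
  ogs <- build_ogs(genes)
  expect_equal(ogs$n_genomes, 3L)
  asn <- stats::setNames(ogs$assignment$og_id, ogs$assignment$gene_id)
  expect_equal(length(unique(asn[c("A|x", "B|x", "C|x")])), 1L)
  expect_equal(length(unique(asn[c("A|y", "B|y", "C|y")])), 1L)
  expect_false(asn[["A|x"]] == asn[["A|y"]])
  expect_setequal(core_single_copy_ogs(ogs), unique(unname(asn)))

  # a planted ortholog at 85% identity stays below the 90% cut-off
  genes2 <- data.frame(
    genome_id = c("A", "B"), gene_id = c("A|w", "B|w"),
    seq = c(x, mutate_seq(x, 90L)), stringsAsFactors = FALSE)
  ogs2 <- build_ogs(genes2)
  expect_equal(nrow(ogs2$ogs), 2L)  # two singleton OGs, no RBH edge
  expect_length(core_single_copy_ogs(ogs2), 0L)

  # a within-genome duplicate makes the OG non-single-copy
  genes3 <- rbind(genes, data.frame(
    genome_id = "A", gene_id = "A|x2", seq = mutate_seq(x, 6L),
    stringsAsFactors = FALSE))
  ogs3 <- build_ogs(genes3)
  asn3 <- ogs3$assignment
  og_x <- asn3$og_id[asn3$gene_id == "A|x"]
  expect_false(og_x %in% core_single_copy_ogs(ogs3))
})

test_that("core OGs on synthetic genes match the planted inventory", {
  pop <- small_pop()
  genes <- population_genes(pop)
  ogs <- build_ogs(genes)
  # planted core = conserved + core families + accessory carried by all
  carry <- truth_manifest(pop)$accessory_carriage
  n_universal_acc <- sum(colSums(carry) == nrow(carry))
  expected <- pop$spec$n_core_genes + pop$spec$n_conserved_genes +
    n_universal_acc
  expect_length(core_single_copy_ogs(ogs), expected)

  # gene share from OGs equals the planted inventory arithmetic
  gsm <- gene_share_matrix(ogs)
  tgs <- truth_gene_share(pop)
  expect_equal(gsm[rownames(tgs), colnames(tgs)], tgs)
})

test_that("shared gene fraction closed forms", {
  set.seed(32)
  seqs <- vapply(1:100, function(i) random_seq(300), "")
  a <- data.frame(genome_id = "a", gene_id = paste0("a|", 1:100),
                  seq = seqs, stringsAsFactors = FALSE)
  b <- data.frame(genome_id = "b", gene_id = paste0("b|", 1:95),
                  seq = seqs[1:95], stringsAsFactors = FALSE)
  ogs <- build_ogs(rbind(a, b))
  # b = a minus 5 of 100 genes: 100 * 95 / 97.5
  expect_equal(shared_gene_fraction("a", "b", ogs), 100 * 95 / 97.5)
  expect_equal(shared_gene_fraction("a", "a", ogs), 100)
})

test_that("greedy allele dereplication matches planted truth and examples", {
  set.seed(33)
  s <- random_seq(900)
  # 3 identical sequences: one allele
  d <- dereplicate_alleles(c(g1 = s, g2 = s, g3 = s))
  expect_equal(max(d$allele_id), 1L)
  # one mismatch in 900 = 99.89% >= 99.8: same allele
  d2 <- dereplicate_alleles(c(g1 = s, g2 = mutate_seq(s, 1L)))
  expect_equal(max(d2$allele_id), 1L)
  # 99.0% to the founder: distinct allele
  d3 <- dereplicate_alleles(c(g1 = s, g2 = mutate_seq(s, 9L)))
  expect_equal(max(d3$allele_id), 2L)

  # synthetic population: counts equal the generator's mutation classes
  pop <- small_pop()
  genes <- population_genes(pop)
  ogs <- build_ogs(genes)
  cat_al <- allele_catalog(genes, ogs)
  # map catalog OGs back to planted families via their member gene ids
  fam_of <- vapply(split(sub("^.*\\|", "", ogs$assignment$gene_id),
                         ogs$assignment$og_id),
                   function(x) unique(x)[1], "")
  truth <- truth_allele_counts(pop)
  obs <- stats::setNames(cat_al$n_alleles, fam_of[names(cat_al$n_alleles)])
  core_fams <- names(obs)[grepl("^core", names(obs))]
  expect_equal(unname(obs[core_fams]), unname(truth[core_fams]))
  # every core-OG gene belongs to exactly one cluster covering all genomes
  per_og <- table(cat_al$alleles$og_id)
  expect_true(all(per_og == nrow(pop$genomes)))
})

test_that("allele sharing is 100% within genomovars and low between", {
  pop <- small_pop()
  genes <- population_genes(pop)
  ogs <- build_ogs(genes)
  cat_al <- allele_catalog(genes, ogs)
  units <- assign_genomovars(truth_ani_table(pop))
  sh <- allele_sharing(cat_al, units)
  expect_true(all(diag(sh) == 100))
  # between genomovars only the fully conserved (rRNA-like) OGs are shared
  n_core_ogs <- length(cat_al$core_ogs)
  expected_between <- 100 * pop$spec$n_conserved_genes / n_core_ogs
  expect_true(all(abs(sh[upper.tri(sh)] - expected_between) < 1e-9))
})

test_that("percent_in_range summary arithmetic", {
  expect_equal(percent_in_range(c(10, 25, 30, 111), 22, 37), 50)
  x <- c(rep(25, 523), rep(111, 270))
  expect_equal(round(percent_in_range(x, 22, 37)), 66)
})
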