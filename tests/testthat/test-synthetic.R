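test_that("population spec validates its stated world", {
  expect_error(population_spec(between_divergence = c(0.001, 0.03)),
               "planted ANI gap")
  expect_error(population_spec(strain_divergence = 0.01), "below")
  expect_error(population_spec(genome_length = 10000L, n_core_genes = 40L),
               "gene span exceeds genome")
  sp <- population_spec()
  expect_equal(sp$forbidden_band, c(99.2, 99.8))
})

test_that("generation is reproducible and honours the forbidden band", {
  spec <- population_spec(n_genomovars = 4L, strains_per_genomovar = 2L,
                          genome_length = 20000L, n_core_genes = 10L,
                          rng_seed = 71L)
  p1 <- generate_population(spec)
  p2 <- generate_population(spec)
  g1 <- as_genome_set(p1); g2 <- as_genome_set(p2)
  expect_identical(lapply(g1, as.character), lapply(g2, as.character))

  # byte-identical FASTA output from the same seed
  d <- withr::local_tempdir()
  f1 <- write_genomes(g1, file.path(d, "a"))
  f2 <- write_genomes(g2, file.path(d, "b"))
  expect_identical(readLines(f1[1]), readLines(f2[1]))

  # no realised pair inside the planted forbidden band (also asserted
  # internally at generation time)
  tab <- truth_ani_table(p1)
  band <- p1$spec$forbidden_band
  expect_false(any(tab$ani > band[1] + 1e-9 & tab$ani < band[2] - 1e-9))
})

test_that("planted divergence bands land where the population spec puts them", {
  pop <- default_pop()
  tab <- truth_ani_table(pop)
  gv <- truth_gv(pop)
  same_gv <- gv[tab$query_id] == gv[tab$subject_id]
  strain <- stats::setNames(pop$genomes$strain_id, pop$genomes$genome_id)
  same_st <- strain[tab$query_id] == strain[tab$subject_id]
  # between-genomovar ANI within the documented envelope
  expect_true(all(tab$ani[!same_gv] >= 96.8 & tab$ani[!same_gv] <= 99.25))
  # within-genomovar (between-strain) pairs sit above the gap
  expect_true(all(tab$ani[same_gv & !same_st] >= 99.78))
  expect_true(all(tab$ani[same_gv & !same_st] < 99.99))
  # multi-isolate strains exceed the strain threshold
  spec2 <- population_spec(n_genomovars = 3L, strains_per_genomovar = 2L,
                           isolates_per_strain = 2L, genome_length = 20000L,
                           n_core_genes = 10L, rng_seed = 72L)
  pop2 <- generate_population(spec2)
  tab2 <- truth_ani_table(pop2)
  st2 <- stats::setNames(pop2$genomes$strain_id, pop2$genomes$genome_id)
  within_strain <- st2[tab2$query_id] == st2[tab2$subject_id]
  expect_true(all(tab2$ani[within_strain] > 99.99))

  # zero strain divergence means identical isolates (ANI exactly 100)
  spec3 <- population_spec(n_genomovars = 2L, strains_per_genomovar = 2L,
                           isolates_per_strain = 2L, strain_divergence = 0,
                           genome_length = 20000L, n_core_genes = 10L,
                           rng_seed = 73L)
  pop3 <- generate_population(spec3)
  tab3 <- truth_ani_table(pop3)
  st3 <- stats::setNames(pop3$genomes$strain_id, pop3$genomes$genome_id)
  ws3 <- st3[tab3$query_id] == st3[tab3$subject_id]
  expect_true(all(tab3$ani[ws3] == 100))
})

test_that("manifest bookkeeping is complete and consistent", {
  pop <- small_pop()
  man <- truth_manifest(pop)
  expect_equal(sum(man$abundances$abundance), 1)
  expect_setequal(man$genomes$genome_id, pop$genomes$genome_id)
  # every genome's inventory contains all universal families
  univ <- pop$families$family_id[pop$families$class != "accessory"]
  inv <- split(man$gene_inventory$family_id, man$gene_inventory$genome_id)
  expect_true(all(vapply(inv, function(f) all(univ %in% f), logical(1))))
  # genome lengths = universal + carried accessory
  lens <- genome_lengths(as_genome_set(pop))
  fam_len <- stats::setNames(pop$families$length, pop$families$family_id)
  expected <- vapply(names(lens), function(g)
    sum(fam_len[inv[[g]]]), numeric(1))
  expect_equal(as.numeric(lens), unname(expected))
})

test_that("every read's source exists and lies inside its segment", {
  pop <- small_pop()
  sim <- simulate_reads(pop, n_reads = 500L, seed = 81L)
  tr <- sim$truth
  expect_true(all(tr$genome_id %in% pop$genomes$genome_id))
  fam_len <- stats::setNames(pop$families$length, pop$families$family_id)
  expect_true(all(tr$offset >= 1L))
  expect_true(all(tr$offset + pop$spec$read_length - 1L <=
                    fam_len[tr$family_id]))
  # emitted read sequences equal the source segment plus planted errors
  ok <- vapply(seq_len(50), function(i) {
    cp <- pop$copies[[tr$genome_id[i]]][[tr$family_id[i]]]
    win <- tr$offset[i]:(tr$offset[i] + pop$spec$read_length - 1L)
    mism <- sum(charToRaw(as.character(sim$reads[[i]])) != cp[win])
    mism == tr$n_errors[i]
  }, logical(1))
  expect_true(all(ok))
})
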