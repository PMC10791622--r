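# Memoised fixtures shared across test files; everything is generated in code
# from fixed seeds.
.fx <- new.env(parent = emptyenv())

# default-scale world: 10 genomovars x 3 strains, 50 kb universal genome
default_pop <- function() {
  if (is.null(.fx$default_pop))
    .fx$default_pop <- generate_population(population_spec(rng_seed = 101L))
  .fx$default_pop
}

# small world for cheap unit tests: 5 genomovars x 2 strains, 20 kb
small_pop <- function() {
  if (is.null(.fx$small_pop))
    .fx$small_pop <- generate_population(population_spec(
      n_genomovars = 5L, strains_per_genomovar = 2L, genome_length = 20000L,
      n_core_genes = 12L, n_accessory_genes = 8L, rng_seed = 103L))
  .fx$small_pop
}

truth_gv <- function(pop) {
  stats::setNames(pop$genomes$genomovar_id, pop$genomes$genome_id)
}

# two named membership vectors describe the same partition of the same set
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant exactly n substitutions into a sequence
mutate_seq <- function(s, n) {
  r <- charToRaw(s)
  bases <- charToRaw("ACGT")
  pos <- sample.int(length(r), n)
  r[pos] <- bases[(match(r[pos], bases) %% 4L) + 1L]
  rawToChar(r)
}
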