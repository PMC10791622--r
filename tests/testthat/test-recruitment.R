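mk_hits <- function(df) {
  base <- data.frame(mismatches = 0L, gap_opens = 0L, qstart = 1L,
                     qend = 150L, sstart = 1L, send = 150L, evalue = 1e-70)
  hit_table(cbind(df, base[rep(1, nrow(df)), ]))
}

test_that("best hit by bit score with tie flagging", {
  h <- mk_hits(data.frame(
    read_id = c("r1", "r1", "r2", "r2", "r3"),
    genome_id = c("gA", "gB", "gA", "gB", "gA"),
    identity = c(99, 97, 98, 98, 96),
    alignment_length = 150L,
    bitscore = c(280, 250, 270, 270, 260)))
  b <- best_hits(h)
  b <- b[order(b$read_id), ]
  expect_equal(b$genome_id[b$read_id == "r1"], "gA")  # 280 beats 250
  expect_false(b$is_tie[b$read_id == "r1"])
  expect_true(b$is_tie[b$read_id == "r2"])   # equal scores, different genomes
  expect_false(b$is_tie[b$read_id == "r3"])  # single hit
})

test_that("species filter applies both identity and coverage rules", {
  h <- mk_hits(data.frame(
    read_id = c("r1", "r2", "r3"), genome_id = "gA",
    identity = c(96.0, 94.9, 99.0),
    alignment_length = c(120L, 150L, 100L),
    bitscore = c(200, 250, 150)))
  sp <- species_filter(best_hits(h))
  expect_equal(sp$read_id, "r1")  # 96% & 80% pass; 94.9% fails; 66.7% fails
})

test_that("genomovar assignment is exclusive at the 99.3 rule", {
  reps <- c(gvA = "gA", gvB = "gB")
  h <- mk_hits(data.frame(
    read_id = c("r1", "r2", "r2", "r3", "r3"),
    genome_id = c("gA", "gA", "gB", "gA", "gB"),
    identity = c(99.333, 99.5, 99.4, 99.2, 99.2),
    alignment_length = 150L,
    bitscore = c(290, 292, 291, 288, 288)))
  a <- genomovar_assign(h, reps)
  a <- stats::setNames(a$status, a$read_id)
  expect_equal(a[["r1"]], "assigned")      # one mismatch in 150 = 99.33
  expect_equal(a[["r2"]], "ambiguous")     # >= 99.3 to both representatives
  expect_equal(a[["r3"]], "sub_threshold") # 99.2 everywhere
  expect_error(genomovar_assign(h, character(0)), "empty")
})

test_that("abundance profile normalises by genome length and total reads", {
  reps <- c(gvA = "gA", gvB = "gB")
  n <- c(gA = 300L, gB = 100L)
  rows <- do.call(rbind, lapply(names(n), function(g)
    data.frame(read_id = sprintf("%s_%04d", g, seq_len(n[[g]])),
               genome_id = g, identity = 100, alignment_length = 150L,
               bitscore = 300)))
  h <- mk_hits(rows)
  # equal lengths: fractions proportional to read counts
  p1 <- recruit_profile(h, reps, genome_lengths = c(gA = 1e6, gB = 1e6),
                        total_reads = 4000L)
  expect_equal(p1$genomovars$population_fraction, c(0.75, 0.25))
  expect_equal(p1$species_fraction, 400 / 4000)
  # equal reads, lengths 4 Mb vs 2 Mb: fractions 1/3 vs 2/3
  rows2 <- rows
  rows2$genome_id <- rep(c("gA", "gB"), each = 200)
  p2 <- recruit_profile(mk_hits(rows2), reps,
                        genome_lengths = c(gA = 4e6, gB = 2e6),
                        total_reads = 4000L)
  expect_equal(p2$genomovars$population_fraction, c(1 / 3, 2 / 3))
  # density includes the total-read normalisation
  expect_equal(p2$genomovars$density, c(200 / (4e6 * 4000), 200 / (2e6 * 4000)))
})

test_that("read accounting partitions the species read set on simulated data", {
  pop <- small_pop()
  tab <- truth_ani_table(pop)
  asn <- assign_genomovars(tab)
  reps <- pick_representatives(asn, tab)
  sim <- simulate_reads(pop, n_reads = 5000L, targets = unname(reps),
                        emit_reads = FALSE, seed = 41L)
  lens <- genome_lengths(as_genome_set(pop, unname(reps)))
  prof <- recruit_profile(sim$hits, reps, lens, total_reads = 10000L)
  expect_equal(unname(prof$counts["species"]),
               unname(sum(prof$counts[c("counted", "tie_discarded",
                                        "sub_threshold", "ambiguous")])))
  expect_true(all(prof$genomovars$population_fraction >= 0))
  expect_equal(sum(prof$genomovars$population_fraction), 1)

  # species_fraction is invariant to the choice of representative genome
  reps2 <- vapply(split(pop$genomes$genome_id, pop$genomes$genomovar_id),
                  function(g) g[length(g)], "")
  sim2 <- simulate_reads(pop, n_reads = 5000L, targets = unname(reps2),
                         emit_reads = FALSE, seed = 41L)
  prof2 <- recruit_profile(sim2$hits, reps2,
                           genome_lengths(as_genome_set(pop, unname(reps2))),
                           total_reads = 10000L)
  expect_equal(prof2$species_fraction, prof$species_fraction,
               tolerance = 0.02)
})

test_that("simulated reads hit their source at the exact planted identity", {
  pop <- small_pop()
  # error rate 0: every read matches its source genome at 100%
  sim0 <- simulate_reads(pop, n_reads = 300L, per_base_error = 0,
                         emit_reads = FALSE, seed = 42L)
  self <- merge(sim0$hits, sim0$truth, by = c("read_id", "genome_id"))
  expect_equal(nrow(self), 300L)
  expect_true(all(self$identity == 100))

  # exactly one error per 150 bp read: identity 99.33 to the source
  sim1 <- simulate_reads(pop, n_reads = 300L, errors_per_read = 1L,
                         emit_reads = FALSE, seed = 43L)
  self1 <- merge(sim1$hits, sim1$truth, by = c("read_id", "genome_id"))
  expect_true(all(round(self1$identity, 2) == 99.33))

  # planted abundances are respected within binomial bounds
  ab <- c(gv01 = 0.75, gv02 = 0.25)
  ab_full <- stats::setNames(numeric(length(pop$gv_ids)), pop$gv_ids)
  ab_full[names(ab)] <- ab
  sim2 <- simulate_reads(pop, n_reads = 20000L, abundances = ab_full,
                         emit_reads = FALSE, track_uniqueness = FALSE,
                         seed = 44L)
  n1 <- sum(sim2$truth$genomovar_id == "gv01")
  expect_lt(abs(n1 - 15000), 3 * sqrt(20000 * 0.75 * 0.25))
})
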