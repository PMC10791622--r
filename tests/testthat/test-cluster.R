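mk_tab <- function(...) {
  # build an ani_table from triples: list(a, b, ani)
  rows <- list(...)
  ani_table(data.frame(
    query_id = vapply(rows, `[[`, "", 1),
    subject_id = vapply(rows, `[[`, "", 2),
    ani = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
    stringsAsFactors = FALSE))
}

test_that("genomovar clustering recovers planted gap-separated groups", {
  # two planted groups: within > 99.8, between < 99.2; with a gap spanning
  # the threshold every linkage gives the same partition (oracle: brute force
  # over partitions collapses to the connected components)
  tab <- mk_tab(list("a", "b", 99.9), list("a", "c", 99.85),
                list("b", "c", 99.95), list("d", "e", 99.88),
                list("d", "f", 99.91), list("e", "f", 99.84),
                list("a", "d", 99.0), list("a", "e", 98.9),
                list("a", "f", 99.1), list("b", "d", 98.8),
                list("b", "e", 99.05), list("b", "f", 98.95),
                list("c", "d", 99.15), list("c", "e", 98.85),
                list("c", "f", 99.12))
  asn <- assign_genomovars(tab)
  expect_false(attr(asn, "linkage_sensitive"))
  part <- split(asn$genome_id, asn$genomovar_id)
  expect_setequal(lapply(part, sort), list(c("a", "b", "c"), c("d", "e", "f")))
  # deterministic ids from the lexicographically smallest member
  expect_setequal(names(part), c("gv_a", "gv_d"))

  # all pairs identical: one genomovar
  tab1 <- mk_tab(list("x", "y", 100), list("x", "z", 100), list("y", "z", 100))
  expect_equal(length(unique(assign_genomovars(tab1)$genomovar_id)), 1L)

  # missing pair is an error naming the pair
  expect_error(assign_genomovars(mk_tab(list("a", "b", 99.9),
                                        list("a", "c", 99.2))),
               "missing ANI for pair")
})

test_that("chain across the threshold is linkage-sensitive and straddlers are reported", {
  tab <- mk_tab(list("a", "b", 99.6), list("b", "c", 99.6),
                list("a", "c", 99.4))
  asn <- assign_genomovars(tab)
  # single linkage chains a-b-c together; complete linkage must split
  expect_equal(length(unique(asn$genomovar_id)), 1L)
  expect_true(attr(asn, "linkage_sensitive"))
  cl <- attr(asn, "complete_linkage")
  expect_gt(length(unique(cl)), 1L)
  strad <- attr(asn, "straddling_pairs")
  expect_setequal(paste(strad$genome_a, strad$genome_b),
                  c("a b", "b c", "a c"))
})

test_that("threshold monotonicity: raising the threshold only refines", {
  pop <- small_pop()
  tab <- truth_ani_table(pop)
  thresholds <- c(99.0, 99.5, 99.95)
  parts <- lapply(thresholds, function(th) {
    a <- assign_genomovars(tab, th)
    stats::setNames(a$genomovar_id, a$genome_id)
  })
  for (k in 1:2) {
    coarse <- parts[[k]]; fine <- parts[[k + 1]]
    # every fine cluster sits inside one coarse cluster
    expect_true(all(vapply(split(names(fine), fine), function(g)
      length(unique(coarse[g])) == 1L, logical(1))))
  }
})

test_that("strain rule needs BOTH high ANI and high gene share, nested in genomovars", {
  tab <- mk_tab(list("a", "b", 99.995), list("a", "c", 99.98),
                list("b", "c", 99.98))
  share <- matrix(100, 3, 3, dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c")))
  share["a", "b"] <- share["b", "a"] <- 99.4
  share["a", "c"] <- share["c", "a"] <- 99.5
  share["b", "c"] <- share["c", "b"] <- 99.5
  st <- assign_strains(tab, gene_share = share)
  s <- stats::setNames(st$strain_id, st$genome_id)
  expect_equal(s[["a"]], s[["b"]])   # ani 99.995 > 99.99 and share 99.4 > 99
  expect_false(s[["a"]] == s[["c"]]) # ani 99.98 fails despite share 99.5

  share["a", "b"] <- share["b", "a"] <- 95
  st2 <- assign_strains(tab, gene_share = share)
  s2 <- stats::setNames(st2$strain_id, st2$genome_id)
  expect_false(s2[["a"]] == s2[["b"]])  # share 95 fails despite ANI

  # strains nest inside genomovars by construction
  pop <- small_pop()
  ttab <- truth_ani_table(pop)
  st3 <- assign_strains(ttab, gene_share = truth_gene_share(pop))
  nest <- table(st3$strain_id, st3$genomovar_id)
  expect_true(all(rowSums(nest > 0) == 1L))
})

test_that("representatives are ANI medoids with lexicographic ties", {
  # c is closest to both others
  tab <- mk_tab(list("a", "b", 99.6), list("a", "c", 99.9),
                list("b", "c", 99.9))
  asn <- assign_genomovars(tab, threshold = 99.5)
  reps <- pick_representatives(asn, tab)
  expect_equal(unname(reps), "c")

  # singleton represents itself; exact tie broken lexicographically
  tab2 <- mk_tab(list("a", "b", 99.9), list("x", "y", 98.0),
                 list("a", "x", 98.0), list("a", "y", 98.0),
                 list("b", "x", 98.0), list("b", "y", 98.0))
  asn2 <- assign_genomovars(tab2)
  reps2 <- pick_representatives(asn2, tab2)
  expect_equal(unname(reps2[["gv_a"]]), "a")  # a/b tie at equal summed ANI
  expect_equal(unname(reps2[["gv_x"]]), "x")
  expect_equal(unname(reps2[["gv_y"]]), "y")
})
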