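test_that("collapse_haplotypes merges identical sequences and labels canonically", {
  a <- toy_alignment(c(x = "AAT", y = "AAT", z = "ACT"))
  ht <- collapse_haplotypes(a)
  expect_equal(ht$haplotypes$count, c(2L, 1L))
  expect_equal(ht$haplotypes$label, c("H01", "H02"))
  expect_setequal(ht$members$H01, c("x", "y"))

  same <- toy_alignment(stats::setNames(rep("ACGT", 5), paste0("s", 1:5)))
  expect_equal(nrow(collapse_haplotypes(same)$haplotypes), 1L)
  expect_equal(collapse_haplotypes(same)$haplotypes$count, 5L)
})

test_that("complete deletion removes gap/N columns before comparison", {
  a <- toy_alignment(c(x = "A-GT", y = "ACGT", z = "ACGA"))
  ht <- collapse_haplotypes(a, "complete_deletion")
  # column 2 dropped; x and y identical on the rest? x=AGT vs y=AGT vs z=AGA
  expect_equal(ht$columns, c(1L, 3L, 4L))
  expect_equal(sort(ht$haplotypes$count), c(1L, 2L))
  all_missing <- toy_alignment(c(x = "-N", y = "A-"))
  expect_error(collapse_haplotypes(all_missing), "no informative sites")
})

test_that("haplotype partition is invariant under sample order", {
  set.seed(11)
  seqs <- stats::setNames(sample(random_haplotypes(4, 8), 20, replace = TRUE),
                          paste0("s", 1:20))
  ht1 <- collapse_haplotypes(toy_alignment(seqs))
  perm <- sample(20)
  ht2 <- collapse_haplotypes(toy_alignment(seqs[perm]))
  expect_identical(ht1$haplotypes, ht2$haplotypes)
  expect_identical(lapply(ht1$members, sort), lapply(ht2$members, sort))
  expect_equal(sum(ht1$haplotypes$count), 20L)
})

test_that("most_common_haplotype breaks ties by lexicographic sequence", {
  ht <- make_hap_table(c("TTT", "AAA"), counts = c(2, 2))
  win <- most_common_haplotype(ht)
  expect_equal(ht$haplotypes$sequence[ht$haplotypes$label == win], "AAA")
  single <- make_hap_table("ACG", counts = 3)
  expect_equal(most_common_haplotype(single), "H01")
})

test_that("assign_groups partitions haplotypes by ancient/modern occurrence", {
  ht <- make_hap_table(c("AAA", "AAC", "AAG", "AAT"),
                       counts = c(5, 3, 2, 1))
  # members: H01 mixed, H02 modern only, H03 ancient+modern, H04 ancient only
  ht$members <- list(H01 = c("a1", "m1", "m2", "m3", "m4"),
                     H02 = c("m5", "m6", "m7"),
                     H03 = c("a2", "m8"),
                     H04 = c("a3"))
  anc <- c("a1", "a2", "a3"); mod <- paste0("m", 1:8)
  g <- assign_groups(ht, anc, mod)
  expect_equal(g$group, c("common", "not_found_in_ancient",
                          "ancient_shared", "unique_ancient"))
  expect_error(assign_groups(ht, c(anc, "m1"), mod), "overlap")
  expect_error(assign_groups(ht, anc[-1], mod), "not covered")
})

test_that("grouping recovers the generator's plan on a synthetic panel", {
  # ancient carry H-A and H-B; modern carry H-A (common) and H-C
  seqs <- c(rep("AAAA", 30), rep("CCCC", 5), rep("GGGG", 10))
  ids <- c(paste0("m", 1:25), paste0("a", 1:5),   # AAAA: 25 modern, 5 ancient
           paste0("a", 6:10),                      # CCCC: ancient only
           paste0("m", 26:35))                     # GGGG: modern only
  aln <- toy_alignment(stats::setNames(seqs, ids))
  ht <- collapse_haplotypes(aln)
  g <- assign_groups(ht, grep("^a", ids, value = TRUE),
                     grep("^m", ids, value = TRUE))
  truth <- c(AAAA = "common", CCCC = "unique_ancient",
             GGGG = "not_found_in_ancient")
  got <- stats::setNames(g$group, ht$haplotypes$sequence[match(g$label, ht$haplotypes$label)])
  expect_identical(got[names(truth)], truth)
})

test_that("assign_period bins by half-open period edges and range midpoints", {
  expect_equal(assign_period(make_metadata(1, date_early = 1300, date_late = 1300)),
               "Medieval")
  expect_equal(assign_period(make_metadata(1, date_early = 1550, date_late = 1550)),
               "Post-Medieval")
  expect_equal(assign_period(make_metadata(1, date_early = 1200, date_late = 1200)),
               "Medieval")
  expect_equal(assign_period(make_metadata(1, date_early = 1500, date_late = 1600)),
               "Post-Medieval")  # midpoint 1550
  expect_equal(assign_period(make_metadata(1, date_early = -700, date_late = -700)),
               "Prehistoric")
  expect_equal(assign_period(make_metadata(1, date_early = 1900, date_late = 1900)),
               "Modern")
  expect_error(assign_period(make_metadata(1, date_early = -800, date_late = -800)),
               "out of covered range")
})

test_that("build_counts cross-tabulates and conserves totals", {
  md <- rbind(make_metadata(5, period = "Prehistoric"),
              make_metadata(14, period = "Medieval"))
  md$id <- paste0("u", seq_len(nrow(md)))
  md$grp <- rep(c("x", "y"), length.out = 19)
  tab <- build_counts(md, "period", "grp")
  expect_equal(sum(tab), 19L)
  expect_equal(unname(rowSums(tab)[c("Prehistoric", "Medieval")]), c(5L, 14L))
  one <- md[1, ]
  t1 <- build_counts(one, "period", "grp")
  expect_equal(sum(t1), 1L)
  expect_error(build_counts(md[0, ], "period", "grp"), "empty")
})

test_that("per-sample reconstruction of the modern-panel table reproduces margins", {
  m <- modern_region_counts()
  samples <- do.call(rbind, lapply(rownames(m), function(g)
    do.call(rbind, lapply(colnames(m), function(r) {
      k <- m[g, r]
      if (k == 0) return(NULL)
      data.frame(id = paste0(g, r, seq_len(k)), group = g, region = r)
    }))))
  tab <- build_counts(samples, "group", "region")
  expect_equal(unname(colSums(tab)[paste0("r", 1:10)]),
               c(49L, 81L, 244L, 1537L, 50L, 26L, 26L, 25L, 32L, 24L))
  expect_equal(sum(tab), 2094L)
})
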