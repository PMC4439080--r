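rules <- load_ruleset()

# a sequence covering the diagnostic sites, all-reference (T3) profile,
# assembled from the rule set itself so tests stay in sync with the config
ref_profile <- function() {
  pos <- sort(as.integer(unique(unlist(lapply(rules$sites, names)))))
  base <- stats::setNames(rep("A", length(pos)), pos)
  base["15953"] <- "G"                       # T macro-group reference allele
  for (lab in c("P", "R", "T1", "T1f", "T2", "T3b", "T4", "T5")) {
    s <- rules$own_sites[[lab]]
    for (p in names(s)) base[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  }
  base
}

test_that("shipped default rule set loads and encodes the 15953 T/Q split", {
  expect_s3_class(rules, "haplogroup_rules")
  expect_true("Q" %in% rules$rules)
  expect_equal(unname(rules$sites$Q["15953"]), "A")
  expect_true("15953" %in% names(rules$sites$T))
  # children inherit parent sites
  expect_true(all(names(rules$sites$T3b) %in%
                    c(names(rules$sites$T3), names(rules$own_sites$T3b))))
})

test_that("rule config validation rejects empty and contradictory configs", {
  f <- tempfile(fileext = ".tsv")
  writeLines("label\tparent\tsites", f)
  expect_error(load_ruleset(f), "empty")
  writeLines(c("label\tparent\tsites",
               "A\t.\t100=G",
               "B\tA\t100=T"), f)
  expect_error(load_ruleset(f), "contradicts parent")
  writeLines(c("label\tparent\tsites",
               "A\tB\t100=G",
               "B\tA\t200=T"), f)
  expect_error(load_ruleset(f), "cycle")
  writeLines(c("label\tparent\tsites",
               "A\t.\t99999=G"), f)
  expect_error(load_ruleset(f), "outside reference")
})

test_that("classifier returns the deepest matched rule", {
  prof <- ref_profile()
  cols <- as.integer(names(prof))
  expect_equal(classify_mt(prof, cols, rules), "T3")

  q <- prof; q["15953"] <- "A"
  expect_equal(classify_mt(q, cols, rules), "Q")

  t3b <- prof; t3b[names(rules$own_sites$T3b)] <- rules$own_sites$T3b
  expect_equal(classify_mt(t3b, cols, rules), "T3b")

  t1f <- prof
  t1f[names(rules$own_sites$T1)] <- rules$own_sites$T1
  t1f[names(rules$own_sites$T1f)] <- rules$own_sites$T1f
  expect_equal(classify_mt(t1f, cols, rules), "T1f")

  allN <- stats::setNames(rep("N", length(prof)), names(prof))
  expect_equal(classify_mt(allN, cols, rules), "unassigned")
})

test_that("ambiguity at a diagnostic site blocks depth without contradiction", {
  prof <- ref_profile()
  cols <- as.integer(names(prof))
  t3b <- prof; t3b[names(rules$own_sites$T3b)] <- rules$own_sites$T3b
  # replace the T3b allele (G) by an ambiguity including it: stays T3
  amb <- t3b; amb[names(rules$own_sites$T3b)] <- "R"  # A/G
  expect_equal(classify_mt(amb, cols, rules), "T3")
})

test_that("classification depends only on diagnostic positions", {
  prof <- ref_profile()
  diag_cols <- as.integer(names(prof))
  extra_cols <- setdiff(seq(16031, 16130), diag_cols)
  set.seed(3)
  for (i in 1:10) {
    noise <- sample(c("A", "C", "G", "T"), length(extra_cols), replace = TRUE)
    seq_full <- c(prof, stats::setNames(noise, extra_cols))
    cols <- as.integer(names(seq_full))
    expect_equal(classify_mt(seq_full, cols, rules), "T3")
  }
})

test_that("a child label always satisfies its parent's requirements", {
  prof <- ref_profile()
  cols <- as.integer(names(prof))
  set.seed(5)
  for (i in 1:30) {
    s <- prof
    flip <- sample(length(s), sample(3, 1))
    s[flip] <- sample(c("A", "C", "G", "T"), length(flip), replace = TRUE)
    lab <- classify_mt(s, cols, rules)
    if (lab %in% rules$rules && !is.na(rules$parent[lab])) {
      par_req <- rules$sites[[rules$parent[lab]]]
      expect_true(all(s[names(par_req)] == par_req),
                  label = paste("parent consistency for", lab))
    }
  }
})

test_that("Y haplotype calls follow the configured allele mapping", {
  frag <- strrep("C", 155)
  g <- paste0(substr(frag, 1, 77), "G", substr(frag, 79, 155))
  t <- paste0(substr(frag, 1, 77), "T", substr(frag, 79, 155))
  n <- paste0(substr(frag, 1, 77), "N", substr(frag, 79, 155))
  expect_equal(classify_y(g, 78)$label, "Y2")
  expect_equal(classify_y(t, 78)$label, "Y1")
  expect_equal(classify_y(n, 78)$label, "no_amplification")
  expect_equal(classify_y(g, 78, mapping = c(G = "Y1", T = "Y2"))$label, "Y1")
  expect_error(classify_y("ACGT", 78), "does not cover")
})

test_that("batch classification recovers planted panel labels exactly", {
  plan <- list(cohort_sizes = c(Prehistoric = 5, Medieval = 14,
                                "Post-Medieval" = 26),
               haplogroup_freqs = c(T3 = 0.45, T3b = 0.25, T2 = 0.1,
                                    T1f = 0.1, Q = 0.1),
               private_rate = 2,
               y1_freq = list(Prehistoric = 0.1, Medieval = 0.1,
                              "Post-Medieval" = 0.5))
  p <- simulate_panel(plan, rules, seed = 21)
  cls <- batch_classify(p$aln, rules)
  expect_identical(cls$label, p$truth$haplogroup)
  # private mutations present yet labels exact (monotone under private mutation)
  expect_gt(segregating_sites(p$aln), 0)
  # y calls recover truth for males
  ycall <- vapply(names(p$y$fragments), function(id)
    classify_y(p$y$fragments[[id]], p$y$offset, p$y$mapping)$label, "")
  truth_y <- p$truth$y_label[match(names(ycall), p$truth$id)]
  expect_identical(unname(ycall), truth_y)

  empty <- batch_classify(
    structure(list(ids = character(0), columns = p$aln$columns,
                   matrix = p$aln$matrix[0, , drop = FALSE]),
              class = "aligned_seqs"), rules)
  expect_equal(nrow(empty), 0L)
})
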