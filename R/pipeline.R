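#' Replication consensus QC for amplicon records
#'
#' Ancient-DNA authenticity filter: a (sample, fragment) pair passes when
#' at least `min_amplifications` amplicons agree on an identical sequence,
#' and the agreeing amplicons span at least `min_extractions` independent
#' extractions and `min_labs` laboratories.  Failures are outputs, not
#' errors, each annotated with a reason.
#'
#' @param records A data.frame with columns `sample_id`, `fragment`,
#'   `extraction_id`, `lab_id`, `amplification_id`, `sequence`.
#' @param min_amplifications,min_extractions,min_labs Replication
#'   thresholds (defaults 3, 2, 2).
#' @return A data.frame with one row per (sample, fragment): `status`
#'   (`"pass"`/`"fail"`), `reason`, `consensus` (the agreed sequence, NA on
#'   failure).
#' @export
replication_consensus <- function(records, min_amplifications = 3,
                                  min_extractions = 2, min_labs = 2) {
  req <- c("sample_id", "fragment", "extraction_id", "lab_id",
           "amplification_id", "sequence")
  stopifnot(all(req %in% names(records)))
  key <- interaction(records$sample_id, records$fragment, drop = TRUE)
  out <- lapply(split(records, key), function(g) {
    res <- data.frame(sample_id = g$sample_id[1], fragment = g$fragment[1],
                      status = "fail", reason = NA_character_,
                      consensus = NA_character_, stringsAsFactors = FALSE)
    if (nrow(g) < min_amplifications) {
      res$reason <- "insufficient replicates"
      return(res)
    }
    tab <- sort(table(g$sequence), decreasing = TRUE)
    if (tab[1] < min_amplifications) {
      res$reason <- "discordant"
      return(res)
    }
    agree <- g[g$sequence == names(tab)[1], ]
    if (length(unique(agree$extraction_id)) < min_extractions) {
      res$reason <- "insufficient extractions"
      return(res)
    }
    if (length(unique(agree$lab_id)) < min_labs) {
      res$reason <- "insufficient laboratories"
      return(res)
    }
    res$status <- "pass"; res$reason <- "replicated"
    res$consensus <- names(tab)[1]
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Concordance of osteological sex with Y-chromosomal amplification
#'
#' Cross-tabulates osteological sex against Y amplification status; under
#' correct sexing and clean data no female sample should amplify with
#' Y-chromosomal primers.
#'
#' @param samples Metadata data.frame with `id` and `sex`.
#' @param ycalls A data.frame with `id` and `label` (`"Y1"`, `"Y2"`, or
#'   `"no_amplification"`); samples absent from `ycalls` count as
#'   `no_amplification`.
#' @return A `contingency_table` of sex by amplification status.
#' @export
sex_concordance <- function(samples, ycalls) {
  status <- rep("no_amplification", nrow(samples))
  if (!is.null(ycalls) && nrow(ycalls)) {
    i <- match(samples$id, ycalls$id)
    hit <- !is.na(i) & ycalls$label[i] %in% c("Y1", "Y2")
    status[hit] <- "amplified"
  }
  tab <- table(samples$sex, status)
  contingency_table(matrix(as.integer(tab), nrow(tab), ncol(tab),
                           dimnames = dimnames(tab)))
}

#' Run the full haplotype analysis pipeline
#'
#' Orchestrates QC (optional) -> haplotype collapsing -> haplogroup
#' classification -> per-cohort diversity -> median-joining network ->
#' cohort counts and frequency tests, writing a report directory of TSV /
#' GraphML / JSON outputs plus a structured log with the seed and the
#' sample counts surviving every stage.
#'
#' @param cfg A list with elements:
#'   \describe{
#'     \item{alignment}{an `aligned_seqs`, or a list of
#'       `list(fasta =, start =, end =)` fragment specs concatenated in
#'       order.}
#'     \item{metadata}{a metadata data.frame or TSV path
#'       ([read_metadata()] columns).}
#'     \item{amplicons}{optional amplicon data.frame for
#'       [replication_consensus()]; samples failing QC are dropped.}
#'     \item{ruleset}{a `haplogroup_rules` or config path (shipped default
#'       if omitted).}
#'     \item{heterochrony}{list(rate_pct_per_myr, generation_length).}
#'     \item{epsilon}{median-joining relaxation (default 0).}
#'     \item{y_calls}{optional data.frame(id, label) of Y haplotype calls.}
#'     \item{y_tables}{optional named list of 2x2 count matrices to test.}
#'     \item{seed}{integer seed (mandatory).}
#'     \item{outdir}{output directory.}
#'   }
#' @return Invisibly, a list of the computed objects (haplotypes,
#'   classification, diversity table, network, tests, paths).
#' @export
run_pipeline <- function(cfg) {
  if (is.null(cfg$seed)) stop("cfg$seed is mandatory")
  if (is.null(cfg$outdir)) stop("cfg$outdir is required")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message("[pipeline] ", msg)
  }
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)
  note("seed = ", cfg$seed)

  ## inputs
  aln <- tryCatch({
    if (inherits(cfg$alignment, "aligned_seqs")) cfg$alignment
    else concat_regions(lapply(cfg$alignment, function(f)
      read_alignment(f$fasta, region_spec(f$start, f$end))))
  }, error = function(e) fail("read_alignment", e))
  samples <- tryCatch({
    if (is.character(cfg$metadata)) read_metadata(cfg$metadata)
    else cfg$metadata
  }, error = function(e) fail("read_metadata", e))
  note("input: ", length(aln$ids), " sequences, ", nrow(samples),
       " metadata records")

  ## QC
  if (!is.null(cfg$amplicons)) {
    qc <- tryCatch(replication_consensus(cfg$amplicons),
                   error = function(e) fail("replication_consensus", e))
    utils::write.table(qc, file.path(cfg$outdir, "qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    failed <- unique(qc$sample_id[qc$status == "fail"])
    keep <- !(aln$ids %in% failed)
    note("QC: ", sum(!keep), " sample(s) failed replication; ",
         sum(keep), " retained")
    aln <- new_aligned_seqs(aln$ids[keep], aln$columns,
                            aln$matrix[keep, , drop = FALSE])
  }

  ## haplotypes
  ht <- tryCatch(collapse_haplotypes(aln),
                 error = function(e) fail("collapse_haplotypes", e))
  note("haplotypes: ", nrow(ht$haplotypes), " among ", sum(ht$haplotypes$count),
       " samples")
  write_haplotype_table(ht, file.path(cfg$outdir, "haplotypes.tsv"))

  ## classification
  rules <- tryCatch({
    if (inherits(cfg$ruleset, "haplogroup_rules")) cfg$ruleset
    else if (is.character(cfg$ruleset)) load_ruleset(cfg$ruleset)
    else load_ruleset()
  }, error = function(e) fail("load_ruleset", e))
  cls <- tryCatch(batch_classify(aln, rules),
                  error = function(e) fail("batch_classify", e))
  note("haplogroups: ",
       paste(names(attr(cls, "counts")), attr(cls, "counts"),
             sep = "=", collapse = ", "))
  utils::write.table(cls, file.path(cfg$outdir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## per-cohort diversity
  het <- cfg$heterochrony
  if (is.null(het)) het <- list(rate_pct_per_myr = 43, generation_length = 7)
  sm <- samples[match(aln$ids, samples$id), ]
  period <- vapply(seq_len(nrow(sm)), function(i) assign_period(sm[i, ]), "")
  ages <- vapply(seq_len(nrow(sm)), function(i)
    sample_age(sm[i, ], seed = cfg$seed + i), 0)
  div <- tryCatch({
    rows <- lapply(c(split(seq_along(aln$ids), period),
                     list(Total = seq_along(aln$ids))), function(idx) {
      if (length(idx) < 2) return(NULL)
      sub <- new_aligned_seqs(aln$ids[idx], aln$columns,
                              aln$matrix[idx, , drop = FALSE])
      diversity_estimates(sub, ages = ages[idx],
                          rate_pct_per_myr = het$rate_pct_per_myr,
                          generation_length = het$generation_length)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    cbind(cohort = names(rows), do.call(rbind, lapply(rows, as.data.frame)))
  }, error = function(e) fail("diversity", e))
  write_diversity_table(div, file.path(cfg$outdir, "diversity.tsv"))
  note("diversity: ", nrow(div), " cohort row(s)")

  ## network
  eps <- if (is.null(cfg$epsilon)) 0L else cfg$epsilon
  net <- tryCatch(
    annotate_nodes(build_mjn(ht, epsilon = eps),
                   data.frame(id = aln$ids, period = period)),
    error = function(e) fail("build_mjn", e))
  export_network(net, file.path(cfg$outdir, "network.graphml"))
  note("network: ", nrow(net$nodes), " nodes (",
       sum(net$nodes$type == "median"), " median), ", nrow(net$edges),
       " edges")

  ## cohort counts and tests
  hap_of <- stats::setNames(rep(names(ht$members), lengths(ht$members)),
                            unlist(ht$members))
  tab_samples <- data.frame(id = aln$ids, period = period,
                            haplogroup = cls$label[match(aln$ids, cls$id)],
                            stringsAsFactors = FALSE)
  tests <- list()
  if (length(unique(tab_samples$period)) >= 2 &&
      length(unique(tab_samples$haplogroup)) >= 2) {
    counts <- build_counts(tab_samples, "period", "haplogroup")
    utils::write.table(unclass(counts), file.path(cfg$outdir, "counts.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    tests$period_by_haplogroup <- select_test(counts)
  }
  if (!is.null(cfg$y_tables)) {
    # temporal Y-haplotype comparisons are 2x2 with small haplotype counts;
    # the exact test is reported for all of them, larger tables fall back
    # to the selection rule
    for (nm in names(cfg$y_tables)) {
      m <- contingency_table(cfg$y_tables[[nm]])
      tests[[nm]] <- if (nrow(m) == 2 && ncol(m) == 2) fisher_exact_2x2(m)
                     else select_test(m)
    }
  }
  if (length(tests)) {
    td <- do.call(rbind, lapply(names(tests), function(nm)
      data.frame(table = nm, method = tests[[nm]]$method,
                 statistic = tests[[nm]]$statistic, df = tests[[nm]]$df,
                 p_value = tests[[nm]]$p_value,
                 selection_reason = tests[[nm]]$selection_reason)))
    utils::write.table(td, file.path(cfg$outdir, "tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (nm in names(tests))
      note("test ", nm, ": ", tests[[nm]]$method, " p = ",
           signif(tests[[nm]]$p_value, 3))
  }

  ## sex concordance
  if (!is.null(cfg$y_calls)) {
    sc <- sex_concordance(sm, cfg$y_calls)
    utils::write.table(unclass(sc), file.path(cfg$outdir, "sex_concordance.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }

  writeLines(log_lines, file.path(cfg$outdir, "log.txt"))
  jsonlite::write_json(
    list(seed = cfg$seed, n_sequences = length(aln$ids),
         n_haplotypes = nrow(ht$haplotypes),
         package_version = as.character(utils::packageVersion("archaeopop"))),
    file.path(cfg$outdir, "run.json"), auto_unbox = TRUE)
  invisible(list(haplotypes = ht, classification = cls, diversity = div,
                 network = net, tests = tests, outdir = cfg$outdir))
}
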