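#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences over the analysis region merge into one haplotype.
#' Under `complete_deletion` (the default, matching the usual treatment of
#' missing data in haplotype software) every column carrying a gap (`-`) or
#' `N` in any sample is removed before comparison; under `pairwise` no
#' columns are removed here and downstream statistics handle missing cells
#' pair by pair.
#'
#' Labels `H01`, `H02`, ... are assigned canonically: by descending count,
#' ties broken by lexicographically smaller sequence.  This makes the
#' labelling invariant under permutation of the input samples.
#'
#' @param aln An `aligned_seqs` object.
#' @param missing_policy `"complete_deletion"` or `"pairwise"`.
#' @return An object of class `haplotype_table`: a list with `haplotypes`
#'   (data.frame of `label`, `sequence`, `count`), `members` (list of sample
#'   id vectors per haplotype), `columns` (retained reference positions).
#' @export
collapse_haplotypes <- function(aln,
                                missing_policy = c("complete_deletion", "pairwise")) {
  stopifnot(inherits(aln, "aligned_seqs"))
  missing_policy <- match.arg(missing_policy)
  if (length(aln$ids) == 0L) stop("empty alignment")
  m <- aln$matrix
  keep <- rep(TRUE, ncol(m))
  if (missing_policy == "complete_deletion")
    keep <- !apply(m == "-" | m == "N", 2, any)
  if (!any(keep)) stop("no informative sites: all columns removed by missing-data policy")
  m <- m[, keep, drop = FALSE]
  seqs <- apply(m, 1, paste0, collapse = "")
  groups <- split(aln$ids, seqs)
  ord <- order(-lengths(groups), names(groups))
  groups <- groups[ord]
  labels <- sprintf("H%02d", seq_along(groups))
  structure(list(
    haplotypes = data.frame(label = labels, sequence = names(groups),
                            count = unname(lengths(groups)),
                            stringsAsFactors = FALSE),
    members = stats::setNames(unname(groups), labels),
    columns = aln$columns[keep]
  ), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Haplotype table: %d haplotypes, %d samples, %d sites\n",
              nrow(x$haplotypes), sum(x$haplotypes$count), length(x$columns)))
  d <- utils::head(x$haplotypes, 10)
  long <- nchar(d$sequence) > 24
  d$sequence[long] <- paste0(substr(d$sequence[long], 1, 21), "...")
  print(d)
  if (nrow(x$haplotypes) > 10) cat("...\n")
  invisible(x)
}

#' Write a haplotype table to TSV
#' @param table A `haplotype_table`.
#' @param path Output path.
#' @export
write_haplotype_table <- function(table, path) {
  d <- table$haplotypes
  d$members <- vapply(table$members[d$label], paste, "", collapse = ",")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Most frequent haplotype
#'
#' Ties are broken by lexicographically smallest sequence so the result is
#' deterministic.
#'
#' @param table A `haplotype_table`.
#' @return The label of the most frequent haplotype.
#' @export
most_common_haplotype <- function(table) {
  h <- table$haplotypes
  if (nrow(h) == 0L) stop("empty haplotype table")
  h <- h[order(-h$count, h$sequence), ]
  h$label[1]
}

GROUP_LEVELS <- c("common", "ancient_shared", "unique_ancient",
                  "not_found_in_ancient")

#' Group haplotypes by occurrence in ancient versus modern samples
#'
#' Implements the grouping used for temporal/geographic frequency analysis:
#' the single most frequent haplotype in the combined panel is `common`; the
#' remainder are `ancient_shared` (carried by at least one ancient and one
#' modern sample), `unique_ancient` (ancient only) or `not_found_in_ancient`
#' (modern only).
#'
#' @param table A `haplotype_table` over the combined ancient + modern panel.
#' @param ancient_ids,modern_ids Disjoint character vectors covering all
#'   member ids of `table`.
#' @return A data.frame with `label` and `group`.
#' @export
assign_groups <- function(table, ancient_ids, modern_ids) {
  if (length(intersect(ancient_ids, modern_ids)))
    stop("ancient and modern id sets overlap")
  all_ids <- unlist(table$members)
  uncovered <- setdiff(all_ids, c(ancient_ids, modern_ids))
  if (length(uncovered))
    stop("samples not covered by either id set: ",
         paste(utils::head(uncovered, 5), collapse = ", "))
  common <- most_common_haplotype(table)
  grp <- vapply(table$haplotypes$label, function(lab) {
    if (lab == common) return("common")
    mem <- table$members[[lab]]
    has_a <- any(mem %in% ancient_ids); has_m <- any(mem %in% modern_ids)
    if (has_a && has_m) "ancient_shared"
    else if (has_a) "unique_ancient"
    else "not_found_in_ancient"
  }, "")
  data.frame(label = table$haplotypes$label, group = unname(grp),
             stringsAsFactors = FALSE)
}

#' Assign a temporal cohort from a calendar date
#'
#' Bins by half-open intervals: Prehistoric [700 BC, 1200), Medieval
#' [1200, 1550), Post-Medieval [1550, 1800), Modern [1800, Inf).  A date
#' range is binned by its midpoint — the simplest deterministic rule given
#' that only the period edges are defined.
#'
#' @param record A single-row metadata data.frame (or list) with
#'   `date_early`/`date_late` calendar years (negative = BC).
#' @return One of `"Prehistoric"`, `"Medieval"`, `"Post-Medieval"`,
#'   `"Modern"`.
#' @export
assign_period <- function(record) {
  e <- record$date_early[1]; l <- record$date_late[1]
  if (is.na(e) && is.na(l)) stop("no date information for sample ", record$id[1])
  year <- if (is.na(l)) e else if (is.na(e)) l else (e + l) / 2
  if (year < -700) stop("date ", year, " out of covered range (before 700 BC)")
  if (year < 1200) "Prehistoric"
  else if (year < 1550) "Medieval"
  else if (year < 1800) "Post-Medieval"
  else "Modern"
}

#' Cross-tabulate samples into a cohort contingency table
#'
#' @param samples A metadata data.frame; one row per sample.
#' @param row_by,col_by Column names of `samples` to tabulate.
#' @return An object of class `contingency_table`: an integer matrix with
#'   dimnames, plus `total` attribute.
#' @export
build_counts <- function(samples, row_by, col_by) {
  if (nrow(samples) == 0L) stop("empty sample set")
  for (f in c(row_by, col_by))
    if (!f %in% names(samples) || anyNA(samples[[f]]))
      stop("field '", f, "' missing or incomplete")
  tab <- table(samples[[row_by]], samples[[col_by]])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  contingency_table(m)
}

#' Construct a contingency table from a count matrix
#' @param counts A non-negative integer matrix with dimnames.
#' @return The matrix with class `contingency_table`.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  structure(counts, class = c("contingency_table", "matrix"))
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- unclass(x)
  print(stats::addmargins(as.table(m)))
  invisible(x)
}
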