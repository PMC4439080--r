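#' Circular reference frame
#'
#' Defines a circular reference (e.g. the bovine mitochondrial genome,
#' GenBank V00654, 16338 sites) against which alignment columns are
#' addressed.  All positions are 1-based inclusive and wrap at `length`.
#'
#' @param name Reference identifier, e.g. `"V00654"`.
#' @param length Positive integer, number of sites on the circle.
#' @return An object of class `circular_reference`.
#' @export
#' @examples
#' bov_mt_reference()
circular_reference <- function(name, length) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("reference length must be a positive integer")
  structure(list(name = as.character(name), length = length),
            class = "circular_reference")
}

#' @rdname circular_reference
#' @export
bov_mt_reference <- function() circular_reference("V00654", 16338L)

#' @export
print.circular_reference <- function(x, ...) {
  cat("Circular reference", x$name, "-", x$length, "sites\n")
  invisible(x)
}

#' Region on a circular reference
#'
#' A contiguous run of positions from `start` to `end` inclusive, walking
#' forward on the circle; `start` may exceed `end`, in which case the region
#' wraps once through the origin (as for the bovine D-loop, 16031--178).
#'
#' @param start,end 1-based positions on the reference.
#' @param reference A [circular_reference()].
#' @return An object of class `region_spec`.
#' @export
#' @examples
#' region_spec(16031, 178, bov_mt_reference())
region_spec <- function(start, end, reference = bov_mt_reference()) {
  stopifnot(inherits(reference, "circular_reference"))
  start <- as.integer(start); end <- as.integer(end)
  L <- reference$length
  if (is.na(start) || is.na(end) || start < 1L || end < 1L || start > L || end > L)
    stop("region positions must lie in [1, ", L, "]")
  structure(list(start = start, end = end, reference = reference),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("Region %d-%d on %s (%d bp)\n", x$start, x$end,
              x$reference$name, region_length(x)))
  invisible(x)
}

#' Length of a circular region
#'
#' Counts positions walking the circle from `start` to `end` inclusive.
#' The D-loop region 16031--178 on the 16338-site bovine reference spans
#' 486 bp; the ND5 region 12911--13091 spans 181 bp.
#'
#' @param region A [region_spec()].
#' @return Integer number of positions.
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "region_spec"))
  L <- region$reference$length
  if (region$start <= region$end) region$end - region$start + 1L
  else L - region$start + 1L + region$end
}

#' @rdname region_length
#' @return `region_positions` returns the ordered integer vector of
#'   reference positions covered by the region.
#' @export
region_positions <- function(region) {
  stopifnot(inherits(region, "region_spec"))
  L <- region$reference$length
  if (region$start <= region$end) seq.int(region$start, region$end)
  else c(seq.int(region$start, L), seq.int(1L, region$end))
}

VALID_SYMBOLS <- c("A", "C", "G", "T", "-", "N",
                   "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

## IUPAC ambiguity expansion used by the haplogroup classifier
IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

new_aligned_seqs <- function(ids, columns, matrix) {
  stopifnot(!anyDuplicated(ids), ncol(matrix) == length(columns),
            nrow(matrix) == length(ids))
  rownames(matrix) <- ids
  structure(list(ids = ids, columns = as.integer(columns), matrix = matrix),
            class = "aligned_seqs")
}

#' Construct an aligned sequence set from character data
#'
#' @param seqs Named character vector of equal-length sequences, or a
#'   character matrix (rows = samples, one symbol per cell).
#' @param columns Integer vector of reference positions, one per alignment
#'   column; defaults to `1:L`.
#' @return An object of class `aligned_seqs` with fields `ids`, `columns`
#'   and `matrix`.
#' @export
aligned_seqs <- function(seqs, columns = NULL) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
    ids <- rownames(seqs)
    if (is.null(ids)) ids <- paste0("s", seq_len(nrow(seqs)))
  } else {
    if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
    if (length(unique(nchar(seqs))) > 1L)
      stop("sequences differ in length")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    ids <- names(seqs)
  }
  bad <- !(m %in% VALID_SYMBOLS)
  if (any(bad)) {
    warning(sum(bad), " unknown symbol(s) mapped to N")
    m[bad] <- "N"
  }
  if (is.null(columns)) columns <- seq_len(ncol(m))
  if (length(columns) != ncol(m))
    stop("columns length (", length(columns), ") does not match alignment width (",
         ncol(m), ")")
  new_aligned_seqs(ids, columns, m)
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat(sprintf("Aligned sequence set: %d sequences x %d columns (positions %d..%d)\n",
              length(x$ids), length(x$columns),
              x$columns[1], x$columns[length(x$columns)]))
  invisible(x)
}

#' Sequences of an alignment as strings
#' @param aln An `aligned_seqs` object.
#' @return Named character vector.
#' @export
alignment_strings <- function(aln) {
  stopifnot(inherits(aln, "aligned_seqs"))
  stats::setNames(apply(aln$matrix, 1, paste0, collapse = ""), aln$ids)
}

#' Read a pre-aligned FASTA file against a circular region
#'
#' Records must all have the same length, equal to the region length.
#' Symbols are upper-cased; anything outside the nucleotide/IUPAC/gap
#' alphabet is mapped to `N` with a warning.
#'
#' @param path Path to a FASTA file (single-line or wrapped).
#' @param region A [region_spec()] giving the reference coordinates of the
#'   alignment columns.
#' @return An `aligned_seqs` object whose `columns` are the region positions.
#' @export
read_alignment <- function(path, region) {
  stopifnot(inherits(region, "region_spec"))
  d <- tryCatch(
    suppressWarnings(ape::read.dna(path, format = "fasta",
                                   as.character = TRUE, as.matrix = TRUE)),
    error = function(e) NULL)
  if (is.null(d) || nrow(d) == 0L) stop("empty or unreadable FASTA file: ", path)
  L <- region_length(region)
  if (ncol(d) != L)
    stop(sprintf("record '%s' has length %d, expected region length %d",
                 rownames(d)[1], ncol(d), L))
  aligned_seqs(toupper(d), columns = region_positions(region))
}

#' Write an aligned sequence set to FASTA
#' @param aln An `aligned_seqs` object.
#' @param path Output file path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aligned_seqs"))
  lines <- as.vector(rbind(paste0(">", aln$ids), unname(alignment_strings(aln))))
  writeLines(lines, path)
  invisible(path)
}

#' Concatenate alignments over disjoint regions
#'
#' Used to join the 486 bp D-loop and 181 bp ND5 fragments into the 667 bp
#' haplotype region.  All sets must carry identical sample ids in the same
#' order and cover disjoint column sets.
#'
#' @param sets A list of `aligned_seqs` objects.
#' @return A single `aligned_seqs` with columns concatenated in the given
#'   order.
#' @export
concat_regions <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  ids <- sets[[1]]$ids
  for (s in sets[-1]) {
    if (!identical(s$ids, ids)) {
      d <- union(setdiff(s$ids, ids), setdiff(ids, s$ids))
      stop("sample id mismatch between sets: ",
           paste(utils::head(d, 10), collapse = ", "))
    }
  }
  cols <- unlist(lapply(sets, `[[`, "columns"))
  if (anyDuplicated(cols)) stop("regions overlap in reference positions")
  new_aligned_seqs(ids, cols, do.call(cbind, lapply(sets, `[[`, "matrix")))
}

PERIOD_LEVELS <- c("Prehistoric", "Medieval", "Post-Medieval", "Modern")

#' Read per-sample metadata
#'
#' Expects a UTF-8 TSV with header columns `id`, `site`, `region`, `period`,
#' `date_early`, `date_late`, `age_bp`, `sex`.  Dates are calendar years
#' (negative = BC).  Missing optional fields become `NA` (`sex` becomes
#' `"unknown"`).
#'
#' @param path Path to the TSV file.
#' @return A data.frame of validated sample records.
#' @export
read_metadata <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("id", "site", "region", "period", "date_early", "date_late",
                "age_bp", "sex")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("metadata missing required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(d$id))
    stop("duplicate sample id at row ", which(duplicated(d$id))[1])
  for (col in c("date_early", "date_late", "age_bp")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.na(d[[col]]) & is.na(v))
    if (length(bad))
      stop("unparseable value in column '", col, "' at row ", bad[1])
    d[[col]] <- v
  }
  swap <- which(!is.na(d$date_early) & !is.na(d$date_late) &
                  d$date_early > d$date_late)
  if (length(swap))
    stop("date_early > date_late at row ", swap[1])
  d$sex[is.na(d$sex)] <- "unknown"
  bad_sex <- !(d$sex %in% c("male", "female", "indeterminate", "unknown"))
  if (any(bad_sex))
    stop("invalid sex value at row ", which(bad_sex)[1])
  d
}

#' Write sample metadata to TSV
#' @param records A metadata data.frame as returned by [read_metadata()].
#' @param path Output path.
#' @export
write_metadata <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Age of a sample in years BP
#'
#' Returns the point radiocarbon age when present.  Samples dated only by
#' archaeological context carry a calendar date range; for those a uniform
#' draw within the range is taken (the range states only bounds, so the
#' uniform is the minimal assumption), converted to years BP with present =
#' 1950 and reproducible under `seed`.
#'
#' @param record A single-row metadata data.frame (or list) with fields
#'   `age_bp`, `date_early`, `date_late`.
#' @param seed Integer seed controlling the draw; mandatory so repeated runs
#'   of a heterochrony analysis are reproducible.
#' @param present Calendar year taken as "present" for BP conversion.
#' @return Age in years BP.
#' @export
sample_age <- function(record, seed, present = 1950) {
  if (!is.na(record$age_bp[1])) return(as.numeric(record$age_bp[1]))
  e <- record$date_early[1]; l <- record$date_late[1]
  if (is.na(e) || is.na(l)) stop("no age information for sample ", record$id[1])
  if (e == l) return(present - e)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  year <- stats::runif(1, min = e, max = l)
  present - year
}

## save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
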