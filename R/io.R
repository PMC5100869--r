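#' Read a Bismark-dialect coverage file
#'
#' Parses the six-column, headerless, tab-separated per-cytosine format
#' (chrom, start, end, percent methylation, methylated count, unmethylated
#' count; 1-based closed coordinates). Counts are the raw observable: when
#' the percentage column disagrees with `100 * meth / (meth + unmeth)` by
#' more than 0.1 a warning is raised and the counts are trusted.
#' Structurally malformed lines (wrong column count, non-integer counts)
#' raise an error naming the line number.
#'
#' @param path File path.
#'
#' @return A data.frame with columns `chrom`, `pos`, `meth`, `total`.
#' @export
readBismarkCoverage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), total = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1L]
    stop("malformed coverage line ", bad, " in ", path,
         ": expected 6 tab-separated fields, found ", nf[bad])
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  meth <- suppressWarnings(as.integer(m[, 5L]))
  unmeth <- suppressWarnings(as.integer(m[, 6L]))
  badnum <- which(is.na(pos) | is.na(meth) | is.na(unmeth))
  if (length(badnum)) {
    stop("malformed coverage line ", badnum[1L], " in ", path,
         ": non-integer position or counts")
  }
  if (any(meth < 0) || any(unmeth < 0)) {
    stop("negative counts in ", path)
  }
  total <- meth + unmeth
  pct <- suppressWarnings(as.numeric(m[, 4L]))
  chk <- total > 0 & !is.na(pct)
  off <- which(chk & abs(pct - 100 * meth / total) > 0.1 + 1e-9)
  if (length(off)) {
    warning(length(off), " line(s) in ", path,
            " have a percentage column inconsistent with the counts ",
            "(first at line ", off[1L], "); counts are used.")
  }
  data.frame(chrom = m[, 1L], pos = pos, meth = meth, total = total,
             stringsAsFactors = FALSE)
}

#' Read a BED interval track
#'
#' BED uses 0-based half-open coordinates; the returned
#' [GenomicRanges::GRanges] is 1-based closed, so BED `chr1 0 100` covers
#' plus-strand positions 1..100. A sixth column, when present, supplies the
#' strand. Intervals are returned sorted by (chrom, start); `start >= end`
#' raises an error naming the line.
#'
#' @param path File path.
#' @param track_name Optional track label stored in `metadata()`.
#'
#' @return A sorted [GenomicRanges::GRanges].
#' @export
readBedTrack <- function(path, track_name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$name <- track_name
    return(gr)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop("malformed BED line ", bad, " in ", path, ": fewer than 3 fields")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0)) {
    bad <- which(is.na(start0) | is.na(end0))[1L]
    stop("malformed BED line ", bad, " in ", path, ": non-integer coordinates")
  }
  badint <- which(start0 >= end0)
  if (length(badint)) {
    stop("invalid BED interval at line ", badint[1L], " in ", path,
         ": start >= end")
  }
  strand <- rep("*", length(lines))
  has6 <- nf >= 6L
  if (any(has6)) {
    s6 <- vapply(parts[has6], `[[`, "", 6L)
    s6[!s6 %in% c("+", "-")] <- "*"
    strand[has6] <- s6
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1L, end0),
                               strand = strand)
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$name <- track_name
  gr
}

#' Assemble a MethylationExperiment from per-sample records
#'
#' The site universe is the union of sites across samples, ordered by
#' (chrom, pos); a (site, sample) pair absent from a sample's records is
#' recorded with zero total and masked. Sites with zero coverage in every
#' sample are dropped with a message. Duplicate (chrom, pos) within one
#' sample is an error.
#'
#' @param records Named list of data.frames as returned by
#'   [readBismarkCoverage()]; names must match `samples$sample_id`.
#' @param samples Sample sheet data.frame with at least `sample_id` and
#'   `age_group`.
#' @param context Site context label (`"CpG"` or `"CpH"`).
#'
#' @return A [MethylationExperiment-class].
#' @export
buildMethylationExperiment <- function(records, samples, context = "CpG") {
  samples <- as.data.frame(samples)
  if (nrow(samples) == 0L) stop("sample sheet is empty")
  if (is.null(names(records)) ||
      !setequal(names(records), samples$sample_id)) {
    stop("names(records) must match samples$sample_id")
  }
  records <- records[samples$sample_id]
  for (id in names(records)) {
    r <- records[[id]]
    if (nrow(r) && anyDuplicated(siteId(r$chrom, r$pos))) {
      stop("duplicate (chrom, pos) records in sample ", id)
    }
  }
  all_sites <- unique(do.call(rbind, lapply(records, function(r) {
    r[, c("chrom", "pos"), drop = FALSE]
  })))
  if (is.null(all_sites) || nrow(all_sites) == 0L) {
    stop("no sites present in any sample")
  }
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  ids <- siteId(all_sites$chrom, all_sites$pos)
  n <- nrow(all_sites)
  p <- nrow(samples)
  meth <- matrix(0L, n, p)
  total <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    r <- records[[j]]
    if (nrow(r) == 0L) next
    idx <- match(siteId(r$chrom, r$pos), ids)
    meth[idx, j] <- as.integer(r$meth)
    total[idx, j] <- as.integer(r$total)
  }
  never_covered <- rowSums(total) == 0L
  if (any(never_covered)) {
    message("dropping ", sum(never_covered),
            " site(s) with zero coverage in every sample")
    meth <- meth[!never_covered, , drop = FALSE]
    total <- total[!never_covered, , drop = FALSE]
    all_sites <- all_sites[!never_covered, , drop = FALSE]
  }
  sites <- GenomicRanges::GRanges(all_sites$chrom,
                                  IRanges::IRanges(all_sites$pos, width = 1L))
  S4Vectors::mcols(sites)$context <- rep(context, length(sites))
  MethylationExperiment(meth, total, sites, samples)
}

#' Write and read tabular results
#'
#' Plain TSV with header, `NA` encoded literally; lossless for the result
#' tables produced by this package (differential calls, pattern calls,
#' enrichment tables, QC logs).
#'
#' @param x A data.frame.
#' @param path Output path.
#'
#' @return `writeMethTable()` returns `path` invisibly; `readMethTable()`
#'   the data.frame.
#' @export
writeMethTable <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname writeMethTable
#' @export
readMethTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
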