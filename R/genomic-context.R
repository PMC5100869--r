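#' Local CpG density and GC content
#'
#' For each site, counts the CpG dinucleotides whose plus-strand C lies in
#' the window `[pos - flank, pos + flank]` (401 bp at the default flank,
#' focal CpG included) and computes the window's GC fraction. Windows are
#' clipped at contig ends.
#'
#' @param sites A [GenomicRanges::GRanges] of width-1 sites on the genome's
#'   contig.
#' @param genome A [SyntheticGenome-class].
#' @param flank Window half-width in bp.
#'
#' @return A data.frame with `site`, `cpg_density`, `gc_content`.
#' @export
windowStats <- function(sites, genome, flank = 200) {
  stopifnot(is(sites, "GRanges"), is(genome, "SyntheticGenome"), flank >= 0)
  L <- length(genome)
  pos <- GenomicRanges::start(sites)
  if (any(pos < 1L | pos > L)) stop("site position outside the contig")
  lo <- pmax(1L, pos - as.integer(flank))
  hi <- pmin(L, pos + as.integer(flank))
  cg <- cpgPositions(genome)
  density <- findInterval(hi, cg) - findInterval(lo - 1L, cg)
  v <- Biostrings::Views(genomeSequence(genome), start = lo, end = hi)
  gc <- rowSums(Biostrings::letterFrequency(v, c("C", "G"))) / (hi - lo + 1L)
  data.frame(site = siteId(as.character(GenomeInfoDb::seqnames(sites)), pos),
             cpg_density = density, gc_content = unname(gc),
             stringsAsFactors = FALSE)
}

#' Strand-aware promoter construction
#'
#' Promoters are the `upstream` bp immediately 5' of each gene's
#' transcription start site: `[start - upstream, start)` for plus-strand
#' genes and `(end, end + upstream]` for minus-strand genes (1-based closed
#' output), clipped at contig bounds when sequence lengths are known.
#'
#' @param genes A stranded [GenomicRanges::GRanges] of gene bodies.
#' @param upstream Promoter length in bp.
#'
#' @return A [GenomicRanges::GRanges] of promoters (one per gene, zero-width
#'   promoters at a contig edge dropped).
#' @export
promotersFromGenes <- function(genes, upstream = 1000) {
  stopifnot(is(genes, "GRanges"), upstream >= 1)
  str <- as.character(BiocGenerics::strand(genes))
  if (any(str == "*")) stop("gene records must be stranded (+ or -)")
  s <- GenomicRanges::start(genes)
  e <- GenomicRanges::end(genes)
  plus <- str == "+"
  p_start <- ifelse(plus, s - upstream, e + 1L)
  p_end <- ifelse(plus, s - 1L, e + upstream)
  p_start <- pmax(p_start, 1L)
  sl <- GenomeInfoDb::seqlengths(genes)
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  if (!all(is.na(sl))) {
    lim <- sl[chrom]
    p_end <- ifelse(is.na(lim), p_end, pmin(p_end, lim))
  }
  keep <- p_end >= p_start
  GenomicRanges::GRanges(chrom[keep],
                         IRanges::IRanges(p_start[keep], p_end[keep]),
                         strand = str[keep])
}

#' Make genic tracks mutually exclusive
#'
#' Applies the two-step subtraction hierarchy: exons minus promoters, then
#' introns minus the remaining exons. Promoters are returned unchanged.
#' Residual intron/promoter overlap is possible under this literal two-step
#' rule and is reported via the `residual_intron_promoter_overlap`
#' attribute.
#'
#' @param promoters,exons,introns [GenomicRanges::GRanges] tracks (strand
#'   ignored; overlapping intervals are merged).
#'
#' @return A list of three disjoint-by-construction tracks: `promoters`,
#'   `exons`, `introns`.
#' @export
makeExclusiveGenic <- function(promoters, exons, introns) {
  red <- function(gr) {
    GenomicRanges::reduce(GenomicRanges::granges(gr), ignore.strand = TRUE)
  }
  prom <- red(promoters)
  ex <- GenomicRanges::setdiff(red(exons), prom, ignore.strand = TRUE)
  intr <- GenomicRanges::setdiff(red(introns), ex, ignore.strand = TRUE)
  residual <- sum(IRanges::width(GenomicRanges::intersect(
    intr, prom, ignore.strand = TRUE)))
  out <- list(promoters = prom, exons = ex, introns = intr)
  attr(out, "residual_intron_promoter_overlap") <- residual
  out
}

#' Annotate sites with feature overlap, distance and window statistics
#'
#' For each track, whether the site's C position falls inside an interval
#' and the distance in bp to the nearest interval on the same chromosome
#' (0 when overlapping, `NA` when the chromosome carries no interval).
#' When a genome is supplied, local CpG density and GC content are appended.
#'
#' @param sites A [GenomicRanges::GRanges] of width-1 sites.
#' @param tracks Named list of [GenomicRanges::GRanges] tracks (merged and
#'   strand-stripped internally).
#' @param genome Optional [SyntheticGenome-class] for [windowStats()].
#' @param flank Window half-width for the window statistics.
#'
#' @return A data.frame with `site`, then `<track>_overlap` (logical) and
#'   `<track>_distance` (bp) per track, plus `cpg_density` and `gc_content`
#'   when a genome is given.
#' @export
annotateSites <- function(sites, tracks, genome = NULL, flank = 200) {
  stopifnot(is(sites, "GRanges"))
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop("'tracks' must be a named list")
  }
  out <- data.frame(
    site = siteId(as.character(GenomeInfoDb::seqnames(sites)),
                  GenomicRanges::start(sites)),
    stringsAsFactors = FALSE)
  for (nm in names(tracks)) {
    tr <- GenomicRanges::reduce(GenomicRanges::granges(tracks[[nm]]),
                                ignore.strand = TRUE)
    ov <- GenomicRanges::countOverlaps(sites, tr, ignore.strand = TRUE) > 0
    dist <- rep(NA_real_, length(sites))
    if (length(tr)) {
      hits <- GenomicRanges::distanceToNearest(sites, tr,
                                               ignore.strand = TRUE)
      dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    }
    out[[paste0(nm, "_overlap")]] <- ov
    out[[paste0(nm, "_distance")]] <- dist
  }
  if (!is.null(genome)) {
    ws <- windowStats(sites, genome, flank)
    out$cpg_density <- ws$cpg_density
    out$gc_content <- ws$gc_content
  }
  out
}

#' Naive fold enrichment or depletion of two proportions
#'
#' The unadjusted ratio of the focal proportion to the universe proportion,
#' always reported as a fold of at least 1 together with its direction:
#' e.g. 5.3% of promoter CpGs changing versus 8.5% of all CpGs is a
#' 1.60-fold depletion.
#'
#' @param prop_focal,prop_universe Strictly positive proportions or
#'   percentages (same units).
#'
#' @return A list with `fold` (>= 1) and `direction` (`"enrichment"`,
#'   `"depletion"` or `"none"`).
#' @export
#' @examples
#' naiveFold(5.3, 8.5)
naiveFold <- function(prop_focal, prop_universe) {
  stopifnot(length(prop_focal) == 1L, length(prop_universe) == 1L)
  if (prop_focal <= 0 || prop_universe <= 0) {
    stop("proportions must be strictly positive")
  }
  fold <- max(prop_focal / prop_universe, prop_universe / prop_focal)
  direction <- if (prop_focal < prop_universe) {
    "depletion"
  } else if (prop_focal > prop_universe) {
    "enrichment"
  } else "none"
  list(fold = fold, direction = direction)
}

#' CpG-density-matched resampling enrichment
#'
#' Tests whether a focal set of CpGs overlaps each feature track more (or
#' less) often than expected given its local CpG density. Each of
#' `n_resamples` draws picks, for every focal site, a universe site with
#' exactly the same local CpG density (integer equality, no binning),
#' without replacement within one resample; the focal sites themselves stay
#' eligible unless `exclude_focal`. Per track, the observed overlap count is
#' compared to the resampled distribution: `fold = observed / mean(resample
#' counts)`, `p_enrich` is the fraction of resamples with a count at least
#' the observed one and `p_deplete` the fraction at most the observed one
#' (ties count in both, so the two p-values sum to at least 1).
#'
#' @param annotation Universe annotation from [annotateSites()] (must carry
#'   `cpg_density` and at least one `*_overlap` column).
#' @param focal Character vector of focal site ids (must all be in the
#'   universe).
#' @param n_resamples Number of resampling draws.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param exclude_focal Exclude the focal sites from the resampling pool.
#' @param plus_one Use the zero-avoiding estimator `(1 + #extreme) /
#'   (1 + n)` for both tails.
#'
#' @return A data.frame with one row per track: `track`, `observed`,
#'   `resample_mean`, `fold`, `p_enrich`, `p_deplete`, `n_resamples`.
#' @export
densityMatchedEnrichment <- function(annotation, focal, n_resamples = 1000,
                                     seed = NULL, exclude_focal = FALSE,
                                     plus_one = FALSE) {
  stopifnot(is.data.frame(annotation), "cpg_density" %in% colnames(annotation),
            n_resamples >= 1)
  ov_cols <- grep("_overlap$", colnames(annotation), value = TRUE)
  if (length(ov_cols) == 0L) stop("annotation carries no *_overlap column")
  if (anyDuplicated(annotation$site)) stop("duplicate sites in the universe")
  focal_idx <- match(focal, annotation$site)
  if (anyNA(focal_idx)) {
    stop("focal site(s) absent from the universe: ",
         paste(utils::head(focal[is.na(focal_idx)], 5L), collapse = ", "))
  }
  ov <- as.matrix(annotation[, ov_cols, drop = FALSE])
  storage.mode(ov) <- "integer"
  density <- annotation$cpg_density
  pool <- seq_len(nrow(annotation))
  if (exclude_focal) pool <- setdiff(pool, focal_idx)
  buckets <- split(pool, density[pool])
  need <- table(density[focal_idx])
  have <- vapply(names(need), function(d) {
    b <- buckets[[d]]
    if (is.null(b)) 0L else length(b)
  }, integer(1))
  short <- names(need)[have < as.integer(need)]
  if (length(short)) {
    stop("density value(s) without enough matched universe sites: ",
         paste(short, collapse = ", "))
  }
  need_n <- as.integer(need)
  need_buckets <- buckets[names(need)]
  observed <- colSums(ov[focal_idx, , drop = FALSE])
  withSeed(seed, {
    counts <- matrix(0L, n_resamples, length(ov_cols))
    for (r in seq_len(n_resamples)) {
      idx <- unlist(lapply(seq_along(need_n), function(i) {
        sampleExactly(need_buckets[[i]], need_n[i])
      }), use.names = FALSE)
      counts[r, ] <- colSums(ov[idx, , drop = FALSE])
    }
    mu <- colMeans(counts)
    p_enr <- p_dep <- numeric(length(ov_cols))
    for (j in seq_along(ov_cols)) {
      ge <- sum(counts[, j] >= observed[j])
      le <- sum(counts[, j] <= observed[j])
      if (plus_one) {
        p_enr[j] <- (1 + ge) / (1 + n_resamples)
        p_dep[j] <- (1 + le) / (1 + n_resamples)
      } else {
        p_enr[j] <- ge / n_resamples
        p_dep[j] <- le / n_resamples
      }
    }
    data.frame(track = sub("_overlap$", "", ov_cols),
               observed = unname(observed), resample_mean = mu,
               fold = ifelse(mu > 0, observed / mu, NA_real_),
               p_enrich = p_enr, p_deplete = p_dep,
               n_resamples = n_resamples,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}
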