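# Where do QTLs of each regulatory pattern fall? Chromatin-state relative
# ratios and genomic-location hypergeometric enrichment.

#' Validate a chromatin-state segmentation
#'
#' Segmentation intervals use the BED convention: 0-based, half-open
#' `[start, end)`. Intervals must be well-formed and non-overlapping within
#' each chromosome.
#'
#' @param segmentation Data frame with `chrom`, `start`, `end`, `state`.
#' @return The segmentation, invisibly, sorted by chrom then start.
#' @export
validate_segmentation <- function(segmentation) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(segmentation)))
  if (any(segmentation$start >= segmentation$end))
    stop("malformed interval: start must be < end (0-based half-open)")
  seg <- segmentation[order(segmentation$chrom, segmentation$start), , drop = FALSE]
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segmentation intervals on ", ch)
  }
  invisible(seg)
}

# positions are 1-based variant coordinates; BED intervals half-open 0-based,
# so position p lies in [start, end) iff start + 1 <= p <= end on 1-based scale
.interval_hits <- function(chrom, pos, intervals) {
  lvls <- union(unique(chrom), unique(intervals$chrom))
  q <- GenomicRanges::GRanges(factor(chrom, lvls),
                              IRanges::IRanges(pos, width = 1L))
  subj <- GenomicRanges::GRanges(factor(intervals$chrom, lvls),
                                 IRanges::IRanges(intervals$start + 1L,
                                                  intervals$end))
  GenomicRanges::findOverlaps(q, subj)
}

#' Assign chromatin states to variant positions
#'
#' Each 1-based variant position is assigned the label of the unique
#' segmentation interval containing it under the half-open BED convention
#' (a position at an interval's `start` belongs to it; at its `end` it does
#' not). Positions in annotation gaps get `NA`.
#'
#' @param chrom,pos Variant chromosomes and 1-based positions.
#' @param segmentation Data frame as in [validate_segmentation()].
#' @return Character vector of state labels (`NA` = unassigned).
#' @export
assign_state <- function(chrom, pos, segmentation) {
  seg <- validate_segmentation(segmentation)
  hits <- .interval_hits(chrom, pos, seg)
  out <- rep(NA_character_, length(pos))
  out[S4Vectors::queryHits(hits)] <- seg$state[S4Vectors::subjectHits(hits)]
  out
}

#' Assign genomic region classes with precedence
#'
#' Region annotations may overlap (a variant can be both exonic and
#' promoter-proximal); each variant receives the covering class of highest
#' precedence. Classes absent from `precedence` rank after all listed ones,
#' in their order of appearance.
#'
#' @param chrom,pos Variant chromosomes and 1-based positions.
#' @param regions Data frame `chrom`, `start`, `end` (BED 0-based half-open),
#'   `region` (class label).
#' @param precedence Character vector, highest priority first.
#' @return Character vector of region classes (`NA` = uncovered).
#' @export
assign_region <- function(chrom, pos, regions,
                          precedence = c("promoter", "exon", "intron",
                                         "upstream", "downstream")) {
  stopifnot(all(c("chrom", "start", "end", "region") %in% names(regions)))
  if (any(regions$start >= regions$end))
    stop("malformed interval: start must be < end (0-based half-open)")
  lvl <- c(precedence, setdiff(unique(regions$region), precedence))
  hits <- .interval_hits(chrom, pos, regions)
  out <- rep(NA_character_, length(pos))
  if (length(hits)) {
    df <- data.frame(q = S4Vectors::queryHits(hits),
                     pri = match(regions$region[S4Vectors::subjectHits(hits)], lvl),
                     lab = regions$region[S4Vectors::subjectHits(hits)])
    df <- df[order(df$q, df$pri), ]
    df <- df[!duplicated(df$q), ]
    out[df$q] <- df$lab
  }
  out
}

#' Chromatin-state relative-ratio matrix
#'
#' For state i and pattern j with counts `n_ij` (QTLs of pattern j in state
#' i), `n_i`, `n_j` and total `n`, the relative ratio is
#' \deqn{ratio_{ij} = \frac{n_{ij} / n_j}{n_i / n}.}
#' Values above 1 mean state i is overrepresented among pattern-j QTLs.
#' QTLs with an `NA` state (annotation gaps) are excluded from `n` and
#' reported separately. The identity
#' \eqn{\sum_j (n_j/n)\, ratio_{ij} = 1} holds for every state with
#' `n_i > 0`.
#'
#' @param states Character vector of state labels per QTL (`NA` allowed).
#' @param patterns Integer vector (1-6) of pattern assignments per QTL.
#' @param state_levels Optional fixed state ordering for the matrix rows.
#' @return List: `ratio` (state x pattern matrix; `NA` where `n_i` or `n_j`
#'   is 0), `counts` (`n_ij` matrix), `n_state`, `n_pattern`, `n`,
#'   `n_unassigned`.
#' @export
chromatin_ratio_matrix <- function(states, patterns, state_levels = NULL) {
  stopifnot(length(states) == length(patterns))
  if (!all(patterns %in% 1:6)) stop("patterns must be integers 1..6")
  keep <- !is.na(states)
  n_unassigned <- sum(!keep)
  states <- states[keep]; patterns <- patterns[keep]
  n <- length(states)
  if (n == 0L) stop("no QTLs with an assigned state")
  if (is.null(state_levels)) state_levels <- sort(unique(states))
  counts <- table(factor(states, levels = state_levels),
                  factor(patterns, levels = 1:6))
  counts <- unclass(counts)
  n_i <- rowSums(counts); n_j <- colSums(counts)
  ratio <- sweep(sweep(counts, 2, n_j, "/"), 1, n_i / n, "/")
  ratio[, n_j == 0] <- NA_real_
  ratio[n_i == 0, ] <- NA_real_
  list(ratio = ratio, counts = counts, n_state = n_i, n_pattern = n_j,
       n = n, n_unassigned = n_unassigned)
}

#' Genomic-location enrichment by hypergeometric test
#'
#' For each (region class r, pattern j) cell, tests overrepresentation of
#' region r among the pattern-j QTLs with the upper-tail hypergeometric
#' probability of drawing at least the observed overlap when `n_j` QTLs are
#' sampled from `n` of which `n_r` lie in region r. P-values are
#' Benjamini-Hochberg adjusted across all cells.
#'
#' @param regions Character vector of region classes per QTL (`NA` excluded).
#' @param patterns Integer vector (1-6) of pattern assignments per QTL.
#' @return Data frame: `region`, `pattern`, `overlap`, `n_region`,
#'   `n_pattern`, `n`, `p_value`, `p_adj`.
#' @export
location_hypergeom <- function(regions, patterns) {
  stopifnot(length(regions) == length(patterns))
  keep <- !is.na(regions)
  regions <- regions[keep]; patterns <- patterns[keep]
  n <- length(regions)
  if (n == 0L) stop("no QTLs with an assigned region class")
  rl <- sort(unique(regions))
  pl <- sort(unique(patterns))
  grid <- expand.grid(region = rl, pattern = pl, stringsAsFactors = FALSE)
  grid$overlap <- mapply(function(r, j) sum(regions == r & patterns == j),
                         grid$region, grid$pattern)
  grid$n_region <- as.integer(table(factor(regions, levels = rl))[grid$region])
  grid$n_pattern <- as.integer(table(factor(patterns, levels = pl))[
    as.character(grid$pattern)])
  grid$n <- n
  grid$p_value <- stats::phyper(grid$overlap - 1L, grid$n_region,
                                n - grid$n_region, grid$n_pattern,
                                lower.tail = FALSE)
  grid$p_adj <- stats::p.adjust(grid$p_value, method = "BH")
  grid
}
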