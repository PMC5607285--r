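#' Consensus peak set
#'
#' A data frame of genomic intervals (chrom, start, end, peak_id) in 0-based
#' half-open coordinates, sorted by (chrom, start), with unique ids.
#'
#' @param peaks data frame with columns chrom, start, end and optionally
#'   peak_id (ids `peak_000001`... are generated when absent).
#' @return the validated, sorted data frame with class `peak_set`.
#' @export
peak_set <- function(peaks) {
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(peaks))) {
    stop("peak set needs columns chrom, start, end", call. = FALSE)
  }
  if (is.null(peaks$peak_id)) {
    peaks$peak_id <- sprintf("peak_%06d", seq_len(nrow(peaks)))
  }
  peaks <- peaks[, c("chrom", "start", "end", "peak_id")]
  peaks$chrom <- as.character(peaks$chrom)
  peaks$peak_id <- as.character(peaks$peak_id)
  if (!is.numeric(peaks$start) || !is.numeric(peaks$end)) {
    stop("start and end must be numeric", call. = FALSE)
  }
  peaks$start <- as.numeric(peaks$start)
  peaks$end <- as.numeric(peaks$end)
  bad <- which(peaks$start < 0 | peaks$start >= peaks$end)
  if (length(bad)) {
    stop("invalid interval(s) (need 0 <= start < end) at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(peaks$peak_id)) {
    stop("duplicate peak ids", call. = FALSE)
  }
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  if (!identical(ord, seq_len(nrow(peaks)))) {
    message("peak set re-sorted by (chrom, start)")
    peaks <- peaks[ord, ]
  }
  rownames(peaks) <- NULL
  class(peaks) <- c("peak_set", "data.frame")
  peaks
}

#' Read a BED3+ peak file
#'
#' Accepts BED with at least chrom/start/end and an optional name column;
#' extra columns are ignored. Intervals are validated per line and sorted.
#'
#' @param path BED file path (0-based half-open, tab-separated).
#' @return a [peak_set()] data frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty BED file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], " in ", path,
         ": fewer than 3 fields", call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], " in ", path,
         ": non-numeric coordinates", call. = FALSE)
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], " in ", path,
         ": need 0 <= start < end", call. = FALSE)
  }
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = start, end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4L)) df$peak_id <- vapply(fields, `[`, "", 4L)
  peak_set(df)
}

#' Write a peak set as BED4
#'
#' @param peaks a [peak_set()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  out <- data.frame(peaks$chrom,
                    formatC(peaks$start, format = "d"),
                    formatC(peaks$end, format = "d"),
                    peaks$peak_id)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1L,
                                          end = peaks$end),
                         peak_id = peaks$peak_id)
}

#' Annotate peaks by distance to the nearest gene TSS
#'
#' Distance is measured from the TSS to the nearest peak edge (0 when the
#' TSS falls inside the peak). Peaks within 2 kb of a TSS are classed
#' `promoter`, farther peaks `distal`; peaks on chromosomes carrying no TSS
#' get distance `Inf` and class `distal` with a warning.
#'
#' @param peaks a [peak_set()] data frame.
#' @param tss data frame with columns gene_id, chrom, pos (0-based TSS
#'   position) and optionally strand.
#' @param promoter_distance class boundary in bp (default 2000).
#' @return data frame: peak_id, gene_id (nearest), distance (bp), class.
#' @export
annotate_tss_distance <- function(peaks, tss, promoter_distance = 2000) {
  stopifnot(inherits(peaks, "peak_set"))
  tss <- as.data.frame(tss, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "chrom", "pos") %in% names(tss))) {
    stop("TSS table needs columns gene_id, chrom, pos", call. = FALSE)
  }
  if (anyDuplicated(tss$gene_id)) stop("duplicate gene ids", call. = FALSE)
  if (any(tss$pos < 0)) stop("TSS positions must be >= 0", call. = FALSE)

  pk <- peaks_to_granges(peaks)
  ts <- GenomicRanges::GRanges(tss$chrom,
                               IRanges::IRanges(start = tss$pos + 1L, width = 1L))
  hit <- GenomicRanges::nearest(pk, ts, select = "arbitrary")

  gene <- rep(NA_character_, length(pk))
  dist <- rep(Inf, length(pk))
  ok <- !is.na(hit)
  if (any(!ok)) {
    warning(sum(!ok), " peak(s) on chromosome(s) without any TSS; distance Inf")
  }
  if (any(ok)) {
    gene[ok] <- tss$gene_id[hit[ok]]
    t1 <- tss$pos[hit[ok]] + 1L                 # 1-based TSS position
    s1 <- peaks$start[ok] + 1L
    e1 <- peaks$end[ok]
    dist[ok] <- ifelse(t1 < s1, s1 - t1, ifelse(t1 > e1, t1 - e1, 0))
  }
  data.frame(peak_id = peaks$peak_id, gene_id = gene, distance = dist,
             class = ifelse(dist <= promoter_distance, "promoter", "distal"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign each gene its most discriminative linked peak
#'
#' Among the peaks linked to a gene (typically nearest-TSS links from
#' [annotate_tss_distance()]), keeps the one with the largest absolute log2
#' fold change; ties are broken by larger mean accessibility, then by
#' lexicographic peak id. Genes without a linked peak are omitted.
#'
#' @param links data frame with columns peak_id, gene_id, log2fc, and
#'   optionally mean_accessibility.
#' @return data frame gene_id, peak_id, log2fc, one row per gene.
#' @export
assign_peak_to_gene <- function(links) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (!all(c("peak_id", "gene_id", "log2fc") %in% names(links))) {
    stop("links need columns peak_id, gene_id, log2fc", call. = FALSE)
  }
  links <- links[!is.na(links$gene_id), , drop = FALSE]
  if (is.null(links$mean_accessibility)) links$mean_accessibility <- 0
  ord <- order(links$gene_id, -abs(links$log2fc), -links$mean_accessibility,
               links$peak_id)
  links <- links[ord, ]
  best <- links[!duplicated(links$gene_id),
                c("gene_id", "peak_id", "log2fc")]
  rownames(best) <- NULL
  best
}

#' Correlate chromatin accessibility and expression fold changes per gene
#'
#' Pearson correlation between per-gene peak accessibility fold changes and
#' gene expression fold changes, optionally restricted to a cell-specific
#' subset of genes.
#'
#' @param peak_fc named numeric vector (gene -> peak log2 fold change).
#' @param expression_fc named numeric vector (gene -> expression log2 fold
#'   change).
#' @param subset optional gene ids to restrict to (e.g. genes whose peak and
#'   transcript are both cell-specific).
#' @return list with `r`, `p`, `n`.
#' @export
fold_change_concordance <- function(peak_fc, expression_fc, subset = NULL) {
  genes <- intersect(names(peak_fc), names(expression_fc))
  if (!is.null(subset)) genes <- intersect(genes, subset)
  if (length(genes) < 3L) {
    stop("need at least 3 paired genes (have ", length(genes), ")",
         call. = FALSE)
  }
  ct <- cor.test(peak_fc[genes], expression_fc[genes], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(genes))
}
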