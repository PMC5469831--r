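#' @importFrom rtracklayer import export
#' @importFrom utils read.delim write.table
NULL

# Required metadata contract for the gene container used throughout:
# a GRanges with a unique, non-NA `gene_id` column and '+'/'-' strands.
.checkGenes <- function(genes) {
  if (!is(genes, "GRanges")) stop("genes must be a GRanges")
  if (is.null(genes$gene_id)) stop("genes need a 'gene_id' metadata column")
  if (anyNA(genes$gene_id) || anyDuplicated(genes$gene_id))
    stop("gene_id values must be unique and non-NA")
  if (any(!as.character(strand(genes)) %in% c("+", "-")))
    stop("every gene needs an explicit '+' or '-' strand")
  invisible(genes)
}

#' Construct a gene annotation
#'
#' Builds the validated `GRanges` gene container used by the whole pipeline.
#' Each gene is a single transcribed region (isoforms are assumed collapsed
#' upstream, e.g. to the longest transcript). The TSS is the 5' end:
#' `start` on '+', `end` on '-'.
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome names.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"` per gene.
#' @return `GRanges` with a `gene_id` column.
#' @examples
#' g <- geneModel("g1", "chr1", 1001, 2000, "+")
#' geneTSS(g)  # 1001
#' @export
geneModel <- function(gene_id, chrom, start, end, strand) {
  if (any(end < start)) stop("gene end < start")
  g <- GRanges(chrom, IRanges(start, end), strand = strand,
               gene_id = as.character(gene_id))
  .checkGenes(g)
}

#' Transcription start sites
#'
#' @param genes Gene `GRanges` (see [geneModel()]).
#' @return Integer vector of 1-based TSS positions, named by `gene_id`.
#' @export
geneTSS <- function(genes) {
  .checkGenes(genes)
  tss <- ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
  names(tss) <- genes$gene_id
  as.integer(tss)
}

#' Read a gene annotation from GFF3 or BED12
#'
#' GFF3 records of type `gene` (or all records when no `gene` rows exist)
#' are used; the identifier is taken from `ID` (falling back to `Name`).
#' BED12 uses the `name` column. Coordinates are converted by rtracklayer to
#' the 1-based inclusive convention used internally.
#'
#' @param path File path.
#' @param format `"gff3"` or `"bed12"`.
#' @return Gene `GRanges`; empty (with a warning) for an empty file.
#' @export
readAnnotation <- function(path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  gr <- tryCatch(
    if (format == "gff3") import(path, format = "gff3")
    else import(path, format = "bed"),
    error = function(e) stop("malformed annotation '", path, "': ",
                             conditionMessage(e)))
  if (length(gr) == 0L) {
    warning("annotation '", path, "' contains no records")
    return(GRanges(gene_id = character()))
  }
  if (format == "gff3") {
    if (!is.null(gr$type) && any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
  } else {
    ids <- gr$name
  }
  if (is.null(ids) || anyNA(ids))
    stop("annotation records lack identifiers (GFF3 ID / BED name)")
  if (anyDuplicated(ids))
    stop("duplicate gene_id in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  geneModel(ids, as.character(seqnames(gr)), start(gr), end(gr),
            as.character(strand(gr)))
}

#' Write a gene annotation as GFF3
#'
#' @param genes Gene `GRanges`.
#' @param path Output path.
#' @export
writeAnnotation <- function(genes, path) {
  .checkGenes(genes)
  g <- granges(genes)
  mcols(g)$type <- "gene"
  mcols(g)$ID <- genes$gene_id
  export(g, path, format = "gff3")
  invisible(path)
}

#' Read a 4-column bedGraph coverage file
#'
#' Intervals within the file must not overlap and values must be
#' non-negative; uncovered bases get coverage 0.
#'
#' @param path bedGraph path.
#' @param label Library label for the resulting track.
#' @param seqlengths Optional named chromosome lengths.
#' @return A [CoverageTrack-class].
#' @export
readBedGraph <- function(path, label = basename(path), seqlengths = NULL) {
  gr <- tryCatch(import(path, format = "bedGraph"),
    error = function(e) stop("malformed bedGraph '", path, "': ",
                             conditionMessage(e)))
  coverageTrack(gr, label = label, seqlengths = seqlengths)
}

#' Write a CoverageTrack as bedGraph
#'
#' Zero-coverage runs are omitted (bedGraph implicit-zero semantics).
#'
#' @param track A [CoverageTrack-class].
#' @param path Output path.
#' @export
writeBedGraph <- function(track, path) {
  grl <- lapply(chromNames(track), function(ch) {
    r <- track@cov[[ch]]
    ir <- IRanges::IRanges(start = cumsum(c(1L, S4Vectors::runLength(r)))[
            seq_along(S4Vectors::runLength(r))],
          width = S4Vectors::runLength(r))
    keep <- runValue(r) != 0
    GRanges(ch, ir[keep], score = runValue(r)[keep])
  })
  gr <- suppressWarnings(do.call(c, grl))  # seqlevel union across chroms
  export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read ChIP-seq peaks (narrowPeak or BED)
#'
#' narrowPeak carries a summit offset in column 10 (-1 meaning absent); for
#' plain BED, or for -1 offsets, the summit defaults to the interval
#' midpoint (reported via a message). Summits are stored as absolute
#' 1-based positions in a `summit` column.
#'
#' @param path File path.
#' @param format `"narrowPeak"` or `"bed"`.
#' @param markLabel Stored in the `mark` column of the result.
#' @return `GRanges` with `summit`, `score` and `mark` columns.
#' @export
readPeaks <- function(path, format = c("narrowPeak", "bed"),
                      markLabel = "mark") {
  format <- match.arg(format)
  gr <- tryCatch(
    if (format == "narrowPeak")
      import(path, format = "BED",
             extraCols = c(signalValue = "numeric", pValue = "numeric",
                           qValue = "numeric", peak = "integer"))
    else import(path, format = "BED"),
    error = function(e) stop("malformed peak file '", path, "': ",
                             conditionMessage(e)))
  if (format == "narrowPeak" && !is.null(gr$peak) && all(gr$peak >= 0)) {
    # offset is relative to the 0-based start; start(gr) is already 1-based
    summit <- start(gr) + gr$peak
  } else {
    message("no summit column; defaulting summits to interval midpoints")
    summit <- as.integer(floor((start(gr) + end(gr)) / 2))
  }
  sc <- gr$score
  if (is.null(sc)) sc <- rep(0, length(gr))
  out <- granges(gr)
  strand(out) <- "*"
  mcols(out) <- S4Vectors::DataFrame(summit = as.integer(summit),
                                     score = as.numeric(sc),
                                     mark = markLabel)
  bad <- summit < start(out) | summit > end(out)
  if (any(bad)) stop(sum(bad), " summit(s) fall outside their peak")
  out
}

#' Write peaks as narrowPeak
#'
#' @param peaks Peak `GRanges` as from [readPeaks()].
#' @param path Output path.
#' @export
writePeaks <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = if (!is.null(peaks$name)) peaks$name
           else sprintf("peak_%d", seq_along(peaks)),
    score = if (!is.null(peaks$score)) peaks$score else 0,
    strand = ".",
    signalValue = if (!is.null(peaks$score)) peaks$score else 0,
    pValue = -1, qValue = -1,
    peak = if (!is.null(peaks$summit)) peaks$summit - start(peaks)
           else as.integer(floor((end(peaks) - start(peaks)) / 2)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-by-tissue FPKM table
#'
#' TSV with a header; first column gene ids, remaining columns one tissue
#' each. `.` denotes missing and becomes `NA`.
#'
#' @param path TSV path.
#' @return Numeric matrix, rows = genes, columns = tissues.
#' @export
readExpression <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("NA", "."))
  if (ncol(df) < 2L) stop("expression table needs >= 2 columns")
  if (anyDuplicated(df[[1L]])) stop("duplicate gene_id in expression table")
  if (anyDuplicated(colnames(df)[-1L])) stop("duplicate tissue labels")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric FPKM values")
  if (any(m < 0, na.rm = TRUE)) stop("negative FPKM values")
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a gene-by-tissue FPKM table
#' @param fpkm Matrix as returned by [readExpression()].
#' @param path Output path.
#' @export
writeExpression <- function(fpkm, path) {
  df <- data.frame(gene_id = rownames(fpkm), fpkm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat gene-to-term annotation map
#'
#' Two-column TSV (`gene_id`, `term_id`), one pair per line, no hierarchy.
#'
#' @param path TSV path.
#' @return `data.frame` with character columns `gene_id`, `term_id`,
#'   duplicates removed.
#' @export
readTermMap <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (!all(c("gene_id", "term_id") %in% colnames(df)))
    stop("term map needs 'gene_id' and 'term_id' columns")
  unique(df[, c("gene_id", "term_id")])
}

#' Write a flat term map
#' @param termMap `data.frame` with `gene_id`, `term_id`.
#' @param path Output path.
#' @export
writeTermMap <- function(termMap, path) {
  write.table(termMap[, c("gene_id", "term_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a per-gene feature table
#'
#' TSV round trip for the per-gene feature table produced by
#' [quantifyGenes()]; every feature column is named in the header and
#' missing values are written as `.`.
#'
#' @param table `data.frame` with a `gene_id` column.
#' @param path TSV path.
#' @return `writeFeatureTable` returns `path` invisibly; `readFeatureTable`
#'   the `data.frame`.
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(is.data.frame(table), "gene_id" %in% colnames(table))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  read.delim(path, check.names = FALSE, na.strings = ".")
}

# Exact-name chromosome compatibility check between an annotation and a
# track; disjoint name sets are an input error, not a silent zero.
.checkChromCompat <- function(genes, track) {
  gch <- unique(as.character(seqnames(genes)))
  tch <- chromNames(track)
  if (!length(intersect(gch, tch)))
    stop("annotation and coverage track share no chromosome names; ",
         "annotation: ", paste(gch, collapse = ","),
         " / track: ", paste(tch, collapse = ","))
  invisible(TRUE)
}
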