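#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp. Order is
#' preserved; duplicate names or non-positive lengths are format errors that
#' name the offending line.
#'
#' @param path file path
#' @return named integer vector of chromosome lengths, in file order
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop_fmt("chrom.sizes file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(setNames(integer(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- setNames(integer(length(lines)), character(length(lines)))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L)
      stop_fmt("chrom.sizes line %d: expected 'name<TAB>length'", i)
    len <- suppressWarnings(as.numeric(p[2]))
    if (is.na(len) || len != as.integer(len) || len < 1)
      stop_fmt("chrom.sizes line %d: length must be a positive integer, got '%s'", i, p[2])
    names(out)[i] <- p[1]
    out[i] <- as.integer(len)
  }
  if (anyDuplicated(names(out)))
    stop_fmt("chrom.sizes: duplicate chromosome name '%s'",
             names(out)[duplicated(names(out))][1])
  out
}

#' Write a chrom.sizes file
#' @param sizes named integer vector
#' @param path output path
#' @return invisibly, `path`
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), as.integer(sizes), sep = "\t"), path)
  invisible(path)
}

# Attach seqlengths and (optionally) drop contigs absent from `sizes`,
# with a logged warning -- unplaced/alt contigs are tolerated but not used.
apply_chrom_sizes <- function(gr, sizes, what = "intervals") {
  if (is.null(sizes)) return(gr)
  absent <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(sizes))
  if (any(absent)) {
    msg_log("dropping %d %s on contigs absent from chrom sizes", sum(absent), what)
    gr <- gr[!absent]
  }
  GenomeInfoDb_safe_seqlevels(gr, sizes)
}

# Set seqlevels/seqlengths without importing GenomeInfoDb explicitly
# (it is a dependency of GenomicRanges and always available).
GenomeInfoDb_safe_seqlevels <- function(gr, sizes) {
  # bounds are checked explicitly below; silence the constructor's own note
  gr <- suppressWarnings(GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    mcols(gr),
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = names(sizes),
                                    seqlengths = as.integer(sizes))
  ))
  bad <- GenomicRanges::end(gr) > GenomeInfoDb::seqlengths(gr)[
    as.character(GenomicRanges::seqnames(gr))]
  if (any(bad))
    stop_fmt("%d interval(s) extend beyond their chromosome length", sum(bad))
  gr
}

#' Construct a peak set
#'
#' Peaks are held as a `GRanges` with metadata columns `name`, `score` and
#' `qvalue` (linear-scale FDR-corrected significance, `NA` when absent) and
#' the factor/timepoint labels stored in `metadata()`.
#'
#' @param chrom,start0,end character / integer vectors; `start0` is 0-based
#'   (BED convention), `end` exclusive
#' @param name,score,qvalue optional per-peak annotations
#' @param factor,timepoint labels for the whole set
#' @param sizes optional named chromosome lengths for bounds validation
#' @return `GRanges`
#' @export
peak_set <- function(chrom, start0, end, name = NA_character_,
                     score = NA_real_, qvalue = NA_real_,
                     factor = NA_character_, timepoint = NA_character_,
                     sizes = NULL) {
  if (any(start0 < 0)) stop_fmt("peak start < 0")
  if (any(start0 >= end)) stop_fmt("peak with start >= end (empty interval)")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end))
  mcols(gr)$name <- rep_len(as.character(name), length(gr))
  mcols(gr)$score <- rep_len(as.numeric(score), length(gr))
  mcols(gr)$qvalue <- rep_len(as.numeric(qvalue), length(gr))
  metadata(gr)$factor <- factor
  metadata(gr)$timepoint <- timepoint
  if (!is.null(sizes)) gr <- apply_chrom_sizes(gr, sizes, "peaks")
  gr
}

#' Read peaks from BED6 or ENCODE narrowPeak
#'
#' narrowPeak column 9 is a -log10 q-value per the ENCODE convention; it is
#' converted to the linear scale (`10^-x`) on read so that "sorted by
#' FDR-corrected q-value" means ascending linear q. File order is preserved.
#'
#' @param path file path
#' @param format `"bed6"` or `"narrowPeak"`
#' @param factor,timepoint labels attached to the returned set
#' @param sizes optional chromosome lengths; peaks on contigs absent from it
#'   are dropped with a logged warning
#' @return `GRanges` peak set (see [peak_set()])
#' @export
read_peaks <- function(path, format = c("bed6", "narrowPeak"),
                       factor = NA_character_, timepoint = NA_character_,
                       sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("peak file not found: %s", path)
  need <- if (format == "bed6") 6L else 10L
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               colClasses = "character", quote = ""),
    error = function(e) stop_fmt("cannot parse %s: %s", path, conditionMessage(e)))
  if (ncol(df) < need)
    stop_fmt("%s: %s requires %d columns, found %d", path, format, need, ncol(df))
  start0 <- as.numeric(df[[2]]); end <- as.numeric(df[[3]])
  bad <- which(is.na(start0) | is.na(end) | start0 >= end | start0 < 0)
  if (length(bad))
    stop_fmt("%s line %d: invalid interval [%s, %s)", path, bad[1],
             df[[2]][bad[1]], df[[3]][bad[1]])
  q <- if (format == "narrowPeak") 10^(-as.numeric(df[[9]])) else NA_real_
  peak_set(df[[1]], start0, end,
           name = df[[4]], score = as.numeric(df[[5]]), qvalue = q,
           factor = factor, timepoint = timepoint, sizes = sizes)
}

#' Write peaks as BED6 or narrowPeak
#' @param peaks `GRanges` peak set
#' @param path output path
#' @param format `"bed6"` or `"narrowPeak"`
#' @return invisibly, `path`
#' @export
write_peaks <- function(peaks, path, format = c("bed6", "narrowPeak")) {
  format <- match.arg(format)
  nm <- mcols(peaks)$name %||% rep(".", length(peaks))
  nm[is.na(nm)] <- "."
  sc <- mcols(peaks)$score %||% rep(0, length(peaks))
  sc[is.na(sc)] <- 0
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks),
                   name = nm, score = sc,
                   strand = ".", stringsAsFactors = FALSE)
  if (format == "narrowPeak") {
    q <- mcols(peaks)$qvalue
    if (is.null(q) || anyNA(q)) stop_fmt("narrowPeak output requires q-values")
    df$signalValue <- sc
    df$pValue <- -1
    df$qValue <- -log10(q)
    df$peak <- -1
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED12 or a minimal GTF
#'
#' BED12 coordinates are used as-is (0-based half-open, converted to the
#' internal 1-based `GRanges` representation); GTF `gene` features are
#' converted from 1-based inclusive. The TSS is the 5' end of the span on
#' the annotated strand.
#'
#' @param path file path
#' @param format `"bed12"` or `"gtf"`
#' @param sizes optional chromosome lengths
#' @return `GRanges` with `gene_id` and `biotype` metadata columns
#' @export
read_gene_models <- function(path, format = c("bed12", "gtf"), sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("gene model file not found: %s", path)
  if (format == "bed12") {
    df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                     colClasses = "character", quote = "")
    if (ncol(df) < 12L) stop_fmt("%s: BED12 requires 12 columns", path)
    strand <- df[[6]]
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad)) stop_fmt("%s line %d: unknown strand '%s'", path, bad[1], strand[bad[1]])
    start0 <- as.numeric(df[[2]]); end <- as.numeric(df[[3]])
    if (any(start0 >= end)) stop_fmt("%s: gene with start >= end", path)
    gr <- GenomicRanges::GRanges(df[[1]], IRanges::IRanges(start0 + 1L, end),
                                 strand = strand)
    mcols(gr)$gene_id <- df[[4]]
    mcols(gr)$biotype <- if (ncol(df) >= 13L) df[[13]] else "coding"
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(f, function(p) length(p) >= 9L && p[3] == "gene", logical(1))
    f <- f[keep]
    if (length(f) == 0L) stop_fmt("%s: no gene features found", path)
    ids <- vapply(f, function(p) {
      m <- regmatches(p[9], regexec('gene_id[ =]+"?([^";]+)"?', p[9]))[[1]]
      if (length(m) < 2L) stop_fmt("GTF record without gene_id attribute")
      m[2]
    }, character(1))
    strand <- vapply(f, `[`, character(1), 7)
    if (any(!strand %in% c("+", "-"))) stop_fmt("%s: unknown strand in GTF", path)
    start1 <- as.numeric(vapply(f, `[`, character(1), 4))
    end <- as.numeric(vapply(f, `[`, character(1), 5))
    gr <- GenomicRanges::GRanges(vapply(f, `[`, character(1), 1),
                                 IRanges::IRanges(start1, end), strand = strand)
    mcols(gr)$gene_id <- ids
    mcols(gr)$biotype <- "coding"
  }
  if (anyDuplicated(mcols(gr)$gene_id))
    stop_fmt("%s: duplicate gene_id '%s'", path,
             mcols(gr)$gene_id[duplicated(mcols(gr)$gene_id)][1])
  if (!is.null(sizes)) gr <- apply_chrom_sizes(gr, sizes, "genes")
  gr
}

#' Write gene models as BED12
#' @param genes `GRanges` with `gene_id` (and optionally `biotype`)
#' @param path output path
#' @return invisibly, `path`
#' @export
write_gene_models <- function(genes, path) {
  s0 <- GenomicRanges::start(genes) - 1L
  e <- GenomicRanges::end(genes)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                   start = s0, end = e, name = mcols(genes)$gene_id,
                   score = 0L, strand = as.character(GenomicRanges::strand(genes)),
                   thickStart = s0, thickEnd = e, rgb = "0",
                   blockCount = 1L, blockSizes = paste0(e - s0, ","),
                   blockStarts = "0,",
                   biotype = mcols(genes)$biotype %||% "coding",
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Steps are sorted on read; overlapping input steps are an error (no silent
#' averaging). Positions not covered by any step have implicit value 0.
#'
#' @param path file path
#' @param sizes optional chromosome lengths
#' @return `GRanges` with a `score` column, sorted and non-overlapping
#' @export
read_bedgraph <- function(path, sizes = NULL) {
  if (!file.exists(path)) stop_fmt("bedGraph file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   colClasses = c("character", "numeric", "numeric", "numeric"),
                   quote = "")
  if (ncol(df) < 4L) stop_fmt("%s: bedGraph requires 4 columns", path)
  if (any(df[[2]] >= df[[3]])) stop_fmt("%s: step with non-positive span", path)
  if (any(df[[2]] < 0)) stop_fmt("%s: negative coordinate", path)
  gr <- GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  mcols(gr)$score <- df[[4]]
  gr <- GenomicRanges::sort(gr)
  hit <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(hit) > 0L) stop_fmt("%s: overlapping bedGraph steps", path)
  if (!is.null(sizes)) gr <- apply_chrom_sizes(gr, sizes, "steps")
  gr
}

#' Write a bedGraph signal track
#' @param track `GRanges` with `score`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(track)),
                   GenomicRanges::start(track) - 1L,
                   GenomicRanges::end(track),
                   mcols(track)$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct an FPKM expression table
#'
#' @param values non-negative numeric matrix, genes x samples, with gene ids
#'   as rownames
#' @param samples data.frame with columns `label`, `timepoint`, `replicate`
#'   matching the matrix columns in order
#' @return object of class `fpkm_table`
#' @export
fpkm_table <- function(values, samples) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values))) stop_fmt("FPKM matrix needs gene ids as rownames")
  if (ncol(values) != nrow(samples))
    stop_fmt("FPKM matrix has %d columns but %d sample records",
             ncol(values), nrow(samples))
  if (!all(c("label", "timepoint", "replicate") %in% names(samples)))
    stop_fmt("sample metadata needs label, timepoint, replicate columns")
  if (any(values < 0)) stop_fmt("negative FPKM value")
  if (any(table(samples$timepoint) < 1L)) stop_fmt("timepoint without replicates")
  colnames(values) <- samples$label
  structure(list(values = values, samples = samples), class = "fpkm_table")
}

#' @export
print.fpkm_table <- function(x, ...) {
  cat(sprintf("FPKM table: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$timepoint), collapse = ", ")))
  invisible(x)
}

#' Read a gene x sample FPKM matrix from TSV
#'
#' @param path TSV with a header line; first column `gene_id`, remaining
#'   columns FPKM per sample in the order of `sample_meta`
#' @param sample_meta data.frame with `label`, `timepoint`, `replicate`
#' @return `fpkm_table`
#' @export
read_fpkm_table <- function(path, sample_meta) {
  if (!file.exists(path)) stop_fmt("FPKM file not found: %s", path)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "",
                   check.names = FALSE, quote = "")
  if (ncol(df) - 1L != nrow(sample_meta))
    stop_fmt("%s: %d sample columns but %d metadata records",
             path, ncol(df) - 1L, nrow(sample_meta))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_fmt("%s: non-numeric FPKM values", path)
  if (any(m < 0)) stop_fmt("%s: negative FPKM value", path)
  rownames(m) <- as.character(df[[1]])
  fpkm_table(m, sample_meta)
}

#' Write an FPKM table as TSV
#' @param table `fpkm_table`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_fpkm_table <- function(table, path) {
  df <- data.frame(gene_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
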