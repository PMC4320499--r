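#' Read a gene annotation table
#'
#' Two formats are supported. \code{format = "bed"}: headerless 4-column BED
#' (\code{chrom}, \code{start}, \code{end}, \code{name}) with 0-based
#' half-open coordinates, read as-is. \code{format = "tsv"}: header columns
#' \code{gene}, \code{chrom}, \code{start}, \code{end}, \code{cytoband},
#' assumed 1-based inclusive and converted. Both are returned as a
#' [GenomicRanges::GRanges] (1-based closed, the Bioconductor convention)
#' named by gene symbol, with metadata columns \code{gene} and
#' \code{cytoband}. Chromosome labels are normalized by stripping any
#' \code{"chr"} prefix.
#'
#' @param path file path.
#' @param format \code{"bed"} or \code{"tsv"}.
#' @return a \code{GRanges}; gene symbols are unique or an error is raised.
#' @export
readGeneAnnotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "bed") {
    if (!length(lines))
      return(emptyAnnotation())
    parts <- strsplit(lines, "[ \t]+")
    bad <- which(vapply(parts, length, 0L) < 4)
    if (length(bad))
      stopf("malformed BED row at line %d of %s", bad[1], path)
    df <- data.frame(gene = vapply(parts, `[`, "", 4),
                     chrom = stripChr(vapply(parts, `[`, "", 1)),
                     start = as.numeric(vapply(parts, `[`, "", 2)) + 1,
                     end = as.numeric(vapply(parts, `[`, "", 3)),
                     cytoband = NA_character_, stringsAsFactors = FALSE)
  } else {
    if (length(lines) <= 1) return(emptyAnnotation())
    df <- readTsv(path)
    need <- c("gene", "chrom", "start", "end", "cytoband")
    if (!all(need %in% names(df)))
      stopf("TSV annotation needs header columns %s", paste(need, collapse = "/"))
    df$start <- suppressWarnings(as.numeric(df$start))
    df$end <- suppressWarnings(as.numeric(df$end))
    bad <- which(is.na(df$start) | is.na(df$end) | !nzchar(df$gene))
    if (length(bad))
      stopf("malformed annotation row at line %d of %s", bad[1] + 1L, path)
    df$chrom <- stripChr(df$chrom)
  }
  if (any(df$start > df$end))
    stopf("annotation interval with start > end for gene %s",
          df$gene[df$start > df$end][1])
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup))
    stopf("duplicated gene symbol(s) in annotation: %s",
          paste(dup, collapse = ", "))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    gene = df$gene, cytoband = df$cytoband)
  names(gr) <- df$gene
  gr
}

emptyAnnotation <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene = character(),
                                               cytoband = character())
  gr
}

#' Parse a karyotype-style cytoband scope
#'
#' Turns notation such as \code{"del(7)(q22q36)"} or \code{"del(17)(p13.1)"}
#' into its chromosome and band range; a single band yields a degenerate
#' range.
#'
#' @param scope karyotype string.
#' @return list with \code{chrom}, \code{band_from}, \code{band_to}.
#' @export
parseCytobandScope <- function(scope) {
  m <- regmatches(scope,
       regexec("^[a-z]+\\(([0-9XY]+)\\)\\(([pq][0-9.]+)([pq][0-9.]+)?\\)$",
               scope))[[1]]
  if (length(m) == 0)
    stopf("cannot parse cytoband scope '%s'", scope)
  list(chrom = m[2], band_from = m[3],
       band_to = if (nzchar(m[4])) m[4] else m[3])
}

#' Read a patient aberration table
#'
#' Tab-separated with header columns \code{kind}, \code{scope_type},
#' \code{chrom}, \code{start}, \code{end}, \code{band_from}, \code{band_to},
#' \code{gene}, \code{zygosity}; unused scope fields are left empty.
#' \code{scope_type = "karyotype"} accepts notation like
#' \code{del(7)(q22q36)} in the \code{chrom} column and expands it to a
#' cytoband range. Interval coordinates are 1-based inclusive. Band
#' existence is checked at resolve time, not here.
#'
#' @param path file path.
#' @return data.frame of aberrations (one per row), class
#'   \code{AberrationSet}.
#' @export
readAberrations <- function(path) {
  if (!file.exists(path)) stopf("aberration file not found: %s", path)
  df <- readTsv(path)
  need <- c("kind", "scope_type", "chrom", "start", "end", "band_from",
            "band_to", "gene", "zygosity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("aberration table lacks column(s): %s", paste(missing, collapse = ", "))
  df$zygosity[!nzchar(df$zygosity)] <- "unspecified"
  bad <- !df$kind %in% ABERRATION_KINDS
  if (any(bad))
    stopf("unrecognized aberration kind '%s' at line %d", df$kind[bad][1],
          which(bad)[1] + 1L)
  kar <- df$scope_type == "karyotype"
  if (any(kar)) {
    parsed <- lapply(df$chrom[kar], parseCytobandScope)
    df$scope_type[kar] <- "cytoband_range"
    df$chrom[kar] <- vapply(parsed, `[[`, "", "chrom")
    df$band_from[kar] <- vapply(parsed, `[[`, "", "band_from")
    df$band_to[kar] <- vapply(parsed, `[[`, "", "band_to")
  }
  bad <- !df$scope_type %in% SCOPE_TYPES
  if (any(bad))
    stopf("unrecognized scope_type '%s' at line %d", df$scope_type[bad][1],
          which(bad)[1] + 1L)
  bad <- !df$zygosity %in% ZYGOSITIES
  if (any(bad))
    stopf("unrecognized zygosity '%s' at line %d", df$zygosity[bad][1],
          which(bad)[1] + 1L)
  bad <- df$kind %in% c("monosomy", "trisomy") &
    df$scope_type != "whole_chromosome"
  if (any(bad))
    stopf("monosomy/trisomy require whole_chromosome scope (line %d)",
          which(bad)[1] + 1L)
  bad <- df$kind %in% c("mutation_gof", "mutation_lof") &
    df$scope_type != "gene"
  if (any(bad))
    stopf("mutations require gene scope (line %d)", which(bad)[1] + 1L)
  df$chrom <- stripChr(df$chrom)
  df$start <- suppressWarnings(as.numeric(df$start))
  df$end <- suppressWarnings(as.numeric(df$end))
  class(df) <- c("AberrationSet", "data.frame")
  df
}

#' Direction of expression change implied by an aberration kind
#'
#' Losses and loss-of-function mutations knock genes down; gains, trisomy,
#' translocation-driven amplification and gain-of-function mutations push
#' them up.
#'
#' @param kind aberration kind.
#' @return \code{"up"} or \code{"down"}.
#' @export
aberrationDirection <- function(kind) {
  map <- c(copy_gain = "up", copy_loss = "down", monosomy = "down",
           trisomy = "up", translocation_amplification = "up",
           mutation_gof = "up", mutation_lof = "down")
  out <- unname(map[kind])
  if (anyNA(out)) stopf("unrecognized aberration kind '%s'",
                        kind[is.na(out)][1])
  out
}

#' Cytogenetic band order table
#'
#' Major-band order per chromosome used to decide whether a gene's cytoband
#' falls inside a karyotype-style band range without base coordinates. The
#' packaged table covers the chromosomes of the shipped fixtures; supply
#' your own (columns \code{chrom}, \code{band}, in chromosome order
#' pter to qter) for other genomes.
#'
#' @param path optional path to an alternative table.
#' @return data.frame with columns \code{chrom}, \code{band}, \code{ord}.
#' @export
cytobandOrder <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cytoband_order.tsv",
                        package = "AvatarScreen", mustWork = TRUE)
  df <- readTsv(path)
  df$ord <- stats::ave(seq_len(nrow(df)), df$chrom, FUN = seq_along)
  df
}

# key for a band within chrom: c(major order, minor or NA)
bandKey <- function(chrom, band, bandTable) {
  major <- sub("^([pq][0-9]+).*$", "\\1", band)
  minorStr <- sub("^[pq][0-9]+\\.?", "", band)
  # sub-bands order like decimal digits: q36.12 lies between q36.1 and q36.2
  minor <- if (nzchar(minorStr)) as.numeric(paste0("0.", minorStr)) else NA_real_
  hit <- bandTable$ord[bandTable$chrom == chrom & bandTable$band == major]
  if (!length(hit))
    stopf("cytoband %s%s absent from the band-order table", chrom, band)
  c(hit[1], minor)
}

bandWithin <- function(key, from, to) {
  geq <- key[1] > from[1] ||
    (key[1] == from[1] && (is.na(from[2]) || (!is.na(key[2]) && key[2] >= from[2]) ||
                             (is.na(key[2]) && is.na(from[2]))))
  leq <- key[1] < to[1] ||
    (key[1] == to[1] && (is.na(to[2]) || (!is.na(key[2]) && key[2] <= to[2]) ||
                           (is.na(key[2]) && is.na(to[2]))))
  # a bare major band (no minor) matches endpoints given at major resolution
  if (key[1] == from[1] && is.na(key[2]) && !is.na(from[2])) geq <- FALSE
  if (key[1] == to[1] && is.na(key[2]) && !is.na(to[2])) leq <- FALSE
  geq && leq
}

#' Resolve aberrations to affected genes
#'
#' Maps each aberration's genomic scope onto the annotation:
#' whole-chromosome events take every annotated gene on the chromosome;
#' intervals take genes with any overlap (>= 1 bp); cytoband ranges take
#' genes whose cytoband sorts within the range (inclusive) per the
#' band-order table; gene scopes take the named gene. Direction of change
#' follows [aberrationDirection()].
#'
#' @param aberrations an \code{AberrationSet} (or compatible data.frame) as
#'   returned by [readAberrations()]; a single row works too.
#' @param annotation \code{GRanges} from [readGeneAnnotation()].
#' @param bandTable band-order table from [cytobandOrder()].
#' @return data.frame with columns \code{gene}, \code{change}
#'   (\code{up}/\code{down}), \code{kind}, \code{zygosity}; one row per
#'   (aberration, gene) hit, genes sorted within each aberration.
#' @export
resolveGenes <- function(aberrations, annotation,
                         bandTable = cytobandOrder()) {
  ann <- data.frame(gene = annotation$gene,
                    chrom = as.character(GenomicRanges::seqnames(annotation)),
                    cytoband = annotation$cytoband,
                    stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(aberrations)), function(i) {
    ab <- aberrations[i, ]
    genes <- switch(ab$scope_type,
      whole_chromosome = sort(ann$gene[ann$chrom == ab$chrom]),
      interval = {
        if (is.na(ab$start) || is.na(ab$end) || ab$start > ab$end)
          stopf("unresolvable interval scope: %s:%s-%s", ab$chrom, ab$start,
                ab$end)
        q <- GenomicRanges::GRanges(ab$chrom,
               IRanges::IRanges(ab$start, ab$end))
        hits <- GenomicRanges::findOverlaps(q, annotation,
                                            minoverlap = 1L)
        sort(annotation$gene[S4Vectors::subjectHits(hits)])
      },
      cytoband_range = {
        from <- bandKey(ab$chrom, ab$band_from, bandTable)
        to <- bandKey(ab$chrom, ab$band_to, bandTable)
        if (from[1] > to[1]) { tmp <- from; from <- to; to <- tmp }
        onChrom <- ann[ann$chrom == ab$chrom & !is.na(ann$cytoband) &
                         nzchar(ann$cytoband), , drop = FALSE]
        inBand <- vapply(onChrom$cytoband, function(b) {
          band <- sub(sprintf("^%s", ab$chrom), "", b)
          bandWithin(bandKey(ab$chrom, band, bandTable), from, to)
        }, TRUE)
        sort(onChrom$gene[inBand])
      },
      gene = {
        if (!ab$gene %in% ann$gene)
          stopf("unresolvable gene scope: %s not in annotation", ab$gene)
        ab$gene
      },
      stopf("unresolvable scope type '%s'", ab$scope_type))
    if (!length(genes)) return(NULL)
    data.frame(gene = genes, change = aberrationDirection(ab$kind),
               kind = ab$kind, zygosity = ab$zygosity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene = character(), change = character(),
                      kind = character(), zygosity = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
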