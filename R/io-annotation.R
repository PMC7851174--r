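#' Construct a transcript exon structure
#'
#' @param transcript_id Transcript identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of genomic exon intervals,
#'   0-based half-open; sorted and non-overlapping after validation.
#' @return An object of class `"transcript_structure"`.
#' @export
transcript_structure <- function(transcript_id, strand, exons) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1) stop_format("transcript needs >= 1 exon")
  if (!strand %in% c("+", "-")) stop_format("strand must be '+' or '-'")
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop_format("exon end must exceed start")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop_format("overlapping exons in %s", transcript_id)
  }
  structure(list(transcript_id = transcript_id, strand = strand,
                 exons = exons),
            class = "transcript_structure")
}

#' Read gene annotation from GTF or BED
#'
#' GTF input (via rtracklayer) yields gene bodies and per-gene transcript
#' exon structures; BED input yields gene bodies only (name column as gene
#' id). Coordinates are converted to the internal 0-based half-open
#' convention.
#'
#' @param path Path to a `.gtf`/`.gff` or `.bed` file.
#' @return An object of class `"gene_annotation"`: `genes` (data frame with
#'   `gene_id`, `chrom`, `start`, `end`, `strand`) and `transcripts` (named
#'   list of lists of [transcript_structure()], empty for BED input).
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path)) {
    gr <- rtracklayer::import(path, format = "BED")
    genes <- data.frame(gene_id = gr$name,
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
    return(structure(list(genes = genes, transcripts = list()),
                     class = "gene_annotation"))
  }
  gr <- rtracklayer::import(path, format = "GTF")
  ex <- gr[gr$type == "exon"]
  df <- data.frame(gene_id = ex$gene_id,
                   transcript_id = ex$transcript_id,
                   chrom = as.character(GenomicRanges::seqnames(ex)),
                   start = GenomicRanges::start(ex) - 1L,
                   end = GenomicRanges::end(ex),
                   strand = as.character(GenomicRanges::strand(ex)),
                   stringsAsFactors = FALSE)
  tx_by_gene <- split(df, df$gene_id)
  transcripts <- lapply(tx_by_gene, function(d) {
    lapply(split(d, d$transcript_id), function(t) {
      transcript_structure(t$transcript_id[1], t$strand[1],
                           cbind(t$start, t$end))
    })
  })
  genes <- do.call(rbind, lapply(tx_by_gene, function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               strand = d$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(genes = genes, transcripts = transcripts),
            class = "gene_annotation")
}

#' Read a BED annotation track
#'
#' @param path Path to a BED file.
#' @param name Track name (defaults to the file basename).
#' @return An object of class `"annotation_track"`: `name` and `intervals`
#'   (data frame `chrom`, `start`, `end`, 0-based half-open).
#' @export
read_annotation_track <- function(path, name = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  annotation_track(name %||% sub("\\.bed(\\.gz)?$", "", basename(path)),
                   data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                              start = GenomicRanges::start(gr) - 1L,
                              end = GenomicRanges::end(gr),
                              stringsAsFactors = FALSE))
}

#' Construct an annotation track from intervals
#'
#' @param name Track name.
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return An object of class `"annotation_track"`.
#' @export
annotation_track <- function(name, intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end <= intervals$start)) stop_format("empty interval in track %s", name)
  structure(list(name = name, intervals = as.data.frame(intervals)),
            class = "annotation_track")
}

#' Test which positions fall in a track
#'
#' @param track An [annotation_track()].
#' @param chrom,pos Vectors of chromosome and 0-based position.
#' @return Logical vector.
#' @export
in_track <- function(track, chrom, pos) {
  vapply(seq_along(pos), function(i) {
    any(track$intervals$chrom == chrom[i] &
          track$intervals$start <= pos[i] &
          track$intervals$end > pos[i])
  }, logical(1))
}
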