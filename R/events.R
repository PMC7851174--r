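## Alternative-splicing / alternative-termini event classification between
## two transcript isoforms of the same gene. The two exon structures are
## compared through their chains of exon boundaries; boundaries present in
## both isoforms (same position, same side) delimit the variable regions,
## and the pattern of isoform-specific boundaries inside each region is
## matched against the canonical event grammar. Coordinates are compared
## exactly. A pair of isoforms may yield several events.

## exon boundary sites of a transcript: data frame (pos, side) with side
## "s" (exon start) or "e" (exon end), genomic order
.tx_sites <- function(tx) {
  ex <- tx$exons
  data.frame(pos = as.vector(t(ex)),
             side = rep(c("s", "e"), nrow(ex)),
             stringsAsFactors = FALSE)
}

.site_key <- function(s) paste(s$pos, s$side)

## strand-aware label mapping (internal labels are computed on the genomic
## strand-plus orientation, then flipped)
.map_label <- function(label, strand) {
  if (strand == "+") return(label)
  flip <- c(alt_5ss = "alt_3ss", alt_3ss = "alt_5ss",
            alt_first_exon = "alt_last_exon", alt_last_exon = "alt_first_exon",
            alt_5utr = "alt_3utr", alt_3utr = "alt_5utr",
            tandem_5utr = "tandem_3utr", tandem_3utr = "tandem_5utr",
            complex_5p = "complex_3p", complex_3p = "complex_5p")
  out <- flip[label]
  out[is.na(out)] <- label[is.na(out)]
  unname(out)
}

.pattern <- function(sub) paste(ifelse(sub$side == "s", "a", "d"), collapse = "")

## classify one internal variable region from the two isoform-specific
## boundary subchains
.classify_internal <- function(subA, subB, strand) {
  pA <- .pattern(subA); pB <- .pattern(subB)
  if (pA == "" && pB == "") return(character(0))
  one_empty <- function(p, q) (pA == p && pB == q) || (pA == q && pB == p)
  if (one_empty("ad", "")) return("exon_skipping")
  if (one_empty("da", "")) return("intron_retention")
  if (pA == "d" && pB == "d") return(.map_label("alt_5ss", strand))
  if (pA == "a" && pB == "a") return(.map_label("alt_3ss", strand))
  if (pA == "ad" && pB == "ad") {
    ## two internal exons, one per isoform: mutually exclusive if disjoint
    if (subA$pos[2] <= subB$pos[1] || subB$pos[2] <= subA$pos[1]) {
      return("mutually_exclusive_exons")
    }
  }
  "complex_internal"
}

## classify a terminal variable region; `left` refers to the genomic left
.classify_terminal <- function(subA, subB, anchor_side, txA, txB, left, strand) {
  pA <- .pattern(subA); pB <- .pattern(subB)
  if (pA == "" && pB == "") return(character(0))
  term5 <- if (left) "5" else "3"
  complex_lab <- .map_label(paste0("complex_", term5, "p"), strand)
  tandem_lab <- .map_label(paste0("tandem_", term5, "utr"), strand)
  alt_exon_lab <- .map_label(if (left) "alt_first_exon" else "alt_last_exon", strand)
  alt_utr_lab <- .map_label(paste0("alt_", term5, "utr"), strand)
  if (left) {
    ## only the two transcription start coordinates differ, terminal exon
    ## body shared up to a common exon end: tandem UTR
    if (pA == "a" && pB == "a" && identical(anchor_side, "e") &&
        anchor_after_first_exon(txA, txB)) {
      return(tandem_lab)
    }
    if (pA == "ad" && pB == "ad") return(c(alt_exon_lab, alt_utr_lab))
  } else {
    if (pA == "d" && pB == "d" && identical(anchor_side, "s") &&
        anchor_before_last_exon(txA, txB)) {
      return(tandem_lab)
    }
    if (pA == "ad" && pB == "ad") return(c(alt_exon_lab, alt_utr_lab))
  }
  complex_lab
}

## the first anchor is the shared end of both first exons
anchor_after_first_exon <- function(txA, txB) {
  txA$exons[1, 2] == txB$exons[1, 2]
}

## the last anchor is the shared start of both last exons
anchor_before_last_exon <- function(txA, txB) {
  txA$exons[nrow(txA$exons), 1] == txB$exons[nrow(txB$exons), 1]
}

#' Classify the events distinguishing two transcript isoforms
#'
#' Compares the exon structures of two isoforms of the same gene and emits
#' the alternative-splicing / alternative-termini events that distinguish
#' them: exon skipping, alternative 5'/3' splice sites (strand-aware),
#' intron retention, mutually exclusive exons, alternative first/last exons
#' (with the matching alternative 5'/3' UTR label), tandem 5'/3' UTRs
#' (same terminal exon body, different start/end coordinate), and complex
#' categories for variable regions that fit no simple pattern
#' (`complex_internal`, `complex_5p`, `complex_3p`). Identical structures
#' return an empty set; any difference yields at least one label, and a
#' pair may yield several.
#'
#' @param a,b [transcript_structure()] objects on the same strand.
#' @return Character vector of event labels (possibly with repeats).
#' @examples
#' a <- transcript_structure("t1", "+", rbind(c(0, 100), c(200, 300), c(400, 500)))
#' b <- transcript_structure("t2", "+", rbind(c(0, 100), c(400, 500)))
#' classify_events(a, b)
#' @export
classify_events <- function(a, b) {
  stopifnot(inherits(a, "transcript_structure"),
            inherits(b, "transcript_structure"))
  if (a$strand != b$strand) stop_format("strand mismatch")
  strand <- a$strand
  if (nrow(a$exons) == nrow(b$exons) && all(a$exons == b$exons)) {
    return(character(0))
  }
  sA <- .tx_sites(a); sB <- .tx_sites(b)
  kA <- .site_key(sA); kB <- .site_key(sB)
  anchors <- sA[kA %in% kB, , drop = FALSE]
  ownA <- sA[!kA %in% kB, , drop = FALSE]
  ownB <- sB[!kB %in% kA, , drop = FALSE]
  if (nrow(anchors) == 0) {
    ## nothing shared: a single unresolvable difference spanning both termini
    return("complex_internal")
  }
  events <- character(0)
  bounds <- c(-Inf, anchors$pos, Inf)
  for (r in seq_len(length(bounds) - 1L)) {
    lo <- bounds[r]; hi <- bounds[r + 1L]
    subA <- ownA[ownA$pos > lo & ownA$pos < hi, , drop = FALSE]
    subB <- ownB[ownB$pos > lo & ownB$pos < hi, , drop = FALSE]
    if (nrow(subA) == 0 && nrow(subB) == 0) next
    lab <- if (r == 1L) {
      .classify_terminal(subA, subB, anchors$side[1], a, b,
                         left = TRUE, strand = strand)
    } else if (r == length(bounds) - 1L) {
      .classify_terminal(subA, subB, anchors$side[nrow(anchors)], a, b,
                         left = FALSE, strand = strand)
    } else {
      .classify_internal(subA, subB, strand)
    }
    events <- c(events, lab)
  }
  events
}

#' Select the isoform pair an sQTL acts on
#'
#' Over the genotype-group pair achieving the gene's MD, returns the
#' transcript with the largest positive change in mean adjusted relative
#' expression and the transcript with the largest negative change — the two
#' isoforms that changed the most in opposite directions.
#'
#' @param group_means Groups-by-transcripts matrix of mean adjusted relative
#'   expression (named columns).
#' @return Character vector `c(up, down)` of the two transcript ids.
#' @export
select_isoform_pair <- function(group_means) {
  m <- as.matrix(group_means)
  if (nrow(m) < 2 || ncol(m) < 2) stop_format("need >= 2 groups and >= 2 transcripts")
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  combos <- combn(nrow(m), 2)
  best <- which.max(apply(combos, 2L, function(ij) {
    max(abs(m[ij[2], ] - m[ij[1], ]))
  }))
  ij <- combos[, best]
  delta <- m[ij[2], ] - m[ij[1], ]
  if (min(delta) >= 0 || max(delta) <= 0) {
    stop_format("no opposite-direction change between groups %d and %d",
                ij[1], ij[2])
  }
  c(colnames(m)[which.max(delta)], colnames(m)[which.min(delta)])
}
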