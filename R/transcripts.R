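# Representative coding-sequence selection from transcript sets: ORF
# finding with minimum-length thresholds, longest-transcript and
# longest-ORF rules, and translation.

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds Nucleotide string, length a multiple of 3.
#' @param n_tolerant If \code{TRUE}, codons containing characters other
#'   than ACGT translate to \code{"X"} instead of raising an error.
#' @return Amino-acid string; a terminal stop codon is dropped.  An
#'   internal stop codon is an error.
#' @examples
#' translate_cds("ATGGGTTAA")  # "MG"
#' @export
translate_cds <- function(cds, n_tolerant = FALSE) {
  cds <- toupper(cds)
  codons <- split_codons(cds)
  gc <- genetic_code()
  aas <- unname(gc[codons])
  if (anyNA(aas)) {
    if (!n_tolerant) {
      stop("ambiguous codon at position ", which(is.na(aas))[1], call. = FALSE)
    }
    aas[is.na(aas)] <- "X"
  }
  stops <- which(aas == "*")
  if (length(stops) > 0) {
    if (any(stops < length(aas))) {
      stop("internal stop codon at codon ", stops[1], call. = FALSE)
    }
    aas <- aas[-length(aas)]
  }
  paste(aas, collapse = "")
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Find open reading frames in a transcript
#'
#' Scans the three forward frames (and optionally the three reverse-strand
#' frames) for ATG-to-stop spans.  Spans that reach the end of the sequence
#' without a stop codon are reported as partial.  Only ORFs meeting both
#' the nucleotide and amino-acid thresholds are returned, sorted by length
#' descending (ties: smaller start, then + strand).
#'
#' @param sequence Transcript nucleotide string.
#' @param min_nt Minimum ORF length in nucleotides including the stop
#'   (default 300).
#' @param min_aa Minimum protein length (default 50).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open on the reported strand), \code{strand}, \code{length},
#'   \code{partial}, \code{cds}, \code{protein}.
#' @export
find_orfs <- function(sequence, min_nt = 300, min_aa = 50,
                      both_strands = TRUE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty sequence", call. = FALSE)
  if (min_nt < 3 || min_aa < 1) {
    stop("min_nt must be >= 3 and min_aa >= 1", call. = FALSE)
  }
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (strand in strands) {
    seq <- if (strand == "+") sequence else .revcomp(sequence)
    out[[strand]] <- .scan_orfs(seq, strand)
  }
  orfs <- do.call(rbind, unname(out))
  if (is.null(orfs) || nrow(orfs) == 0) return(.empty_orfs())
  keep <- orfs$length >= min_nt & nchar(orfs$protein) >= min_aa
  orfs <- orfs[keep, , drop = FALSE]
  ord <- order(-orfs$length, orfs$start, orfs$strand)
  orfs <- orfs[ord, , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

.empty_orfs <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             length = integer(0), partial = logical(0), cds = character(0),
             protein = character(0), stringsAsFactors = FALSE)
}

.scan_orfs <- function(seq, strand) {
  gc <- genetic_code()
  n <- nchar(seq)
  rows <- list()
  for (frame in 0:2) {
    starts <- seq.int(1 + frame, n - 2, by = 3)
    if (length(starts) == 0) next
    codons <- substring(seq, starts, starts + 2)
    aas <- unname(gc[codons])
    aas[is.na(aas)] <- "X"
    open_at <- NA_integer_  # codon index where the current ORF opened
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- i
      if (!is.na(open_at) && aas[i] == "*") {
        rows[[length(rows) + 1L]] <- .orf_row(seq, starts, open_at, i,
                                              strand, partial = FALSE)
        open_at <- NA_integer_
      }
    }
    if (!is.na(open_at)) {
      rows[[length(rows) + 1L]] <- .orf_row(seq, starts, open_at,
                                            length(codons), strand,
                                            partial = TRUE)
    }
  }
  do.call(rbind, rows)
}

.orf_row <- function(seq, starts, from, to, strand, partial) {
  start0 <- starts[from] - 1L
  end0 <- starts[to] + 2L
  cds <- substr(seq, start0 + 1L, end0)
  data.frame(start = start0, end = end0, strand = strand,
             length = end0 - start0, partial = partial, cds = cds,
             protein = translate_cds(cds, n_tolerant = TRUE),
             stringsAsFactors = FALSE)
}

#' Select one representative coding sequence per gene
#'
#' Applies the longest-transcript-per-gene rule, then the longest-ORF rule
#' within that transcript.  Ties on transcript length go to the
#' lexicographically smallest transcript id; ties on ORF length go to the
#' smallest start, then the + strand.
#'
#' @param gene_id Gene identifier shared by all transcripts.
#' @param transcripts data.frame with columns \code{id}, \code{gene_id},
#'   \code{sequence}.
#' @param min_nt,min_aa ORF thresholds passed to \code{\link{find_orfs}}.
#' @param both_strands Passed to \code{\link{find_orfs}}.
#' @return A one-row data.frame (class \code{"coding_gene"} row) with
#'   columns \code{gene_id}, \code{transcript_id}, \code{orf_start},
#'   \code{orf_end}, \code{strand}, \code{cds}, \code{protein}, or
#'   \code{NULL} when no ORF passes the thresholds.
#' @export
select_representative <- function(gene_id, transcripts, min_nt = 300,
                                  min_aa = 50, both_strands = TRUE) {
  if (!all(transcripts$gene_id == gene_id)) {
    stop("transcripts with mixed gene_ids passed for gene ", gene_id,
         call. = FALSE)
  }
  lens <- nchar(transcripts$sequence)
  ord <- order(-lens, transcripts$id)
  tx <- transcripts[ord[1], ]
  orfs <- find_orfs(tx$sequence, min_nt = min_nt, min_aa = min_aa,
                    both_strands = both_strands)
  orfs <- orfs[!orfs$partial, , drop = FALSE]
  if (nrow(orfs) == 0) return(NULL)
  best <- orfs[1, ]
  cds <- best$cds
  # drop the terminal stop from the reported protein; keep it in the CDS
  data.frame(gene_id = gene_id, transcript_id = tx$id,
             orf_start = best$start, orf_end = best$end,
             strand = best$strand, cds = cds, protein = best$protein,
             stringsAsFactors = FALSE)
}

#' Select representatives for a whole transcript set
#'
#' @param transcripts data.frame with columns \code{id}, \code{gene_id},
#'   \code{sequence}.
#' @param ... Passed to \code{\link{select_representative}}.
#' @return data.frame of representatives, one row per gene with a passing
#'   ORF, sorted by \code{gene_id}.
#' @export
select_representatives <- function(transcripts, ...) {
  genes <- sort(unique(transcripts$gene_id))
  rows <- lapply(genes, function(g) {
    select_representative(g, transcripts[transcripts$gene_id == g, ,
                                         drop = FALSE], ...)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  out
}
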