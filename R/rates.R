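# Nei-Gojobori Ka/Ks estimation on protein-guided codon alignments.

#' Jukes-Cantor correction for multiple hits
#'
#' @param p Observed proportion of differing sites, \code{0 <= p}.
#' @return Corrected distance \code{-(3/4) * log(1 - (4/3) p)}; \code{NA}
#'   when \code{p >= 3/4} (outside the model's domain).
#' @examples
#' jukes_cantor(0.1)  # 0.10733
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) stop("jukes_cantor: p must be non-negative", call. = FALSE)
  ifelse(p < 0.75, -0.75 * log(1 - (4 / 3) * p), NA_real_) + 0
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each aligned protein residue back to its source codon, and each
#' protein gap to a whole-codon gap \code{"---"}.  The ungapped proteins
#' must equal the translations of the supplied coding sequences (terminal
#' stop codons on the CDS are ignored).
#'
#' @param aln_a,aln_b Aligned protein strings of equal length (gaps
#'   \code{"-"}).
#' @param cds_a,cds_b Coding sequences the proteins were translated from.
#' @return Object of class \code{"codon_alignment"}: list with equal-length
#'   character vectors \code{codons_a}, \code{codons_b}.
#' @export
backtranslate_alignment <- function(aln_a, aln_b, cds_a, cds_b) {
  if (nchar(aln_a) != nchar(aln_b)) {
    stop("aligned proteins differ in length", call. = FALSE)
  }
  col_a <- .map_codons(aln_a, cds_a, "a")
  col_b <- .map_codons(aln_b, cds_b, "b")
  structure(list(codons_a = col_a, codons_b = col_b),
            class = "codon_alignment")
}

.map_codons <- function(aln, cds, which) {
  codons <- split_codons(cds)
  gc <- genetic_code()
  if (length(codons) > 0 && gc[codons[length(codons)]] %in% "*") {
    codons <- codons[-length(codons)]
  }
  res <- character(nchar(aln))
  chars <- strsplit(aln, "")[[1]]
  i <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "-") {
      res[k] <- "---"
      next
    }
    i <- i + 1L
    if (i > length(codons)) {
      stop("protein ", which, " is longer than its CDS allows", call. = FALSE)
    }
    aa <- translate_cds(codons[i], n_tolerant = TRUE)
    if (aa != chars[k]) {
      stop("protein/CDS mismatch for sequence ", which, " at residue ", i,
           ": codon ", codons[i], " translates to ", aa, ", protein has ",
           chars[k], call. = FALSE)
    }
    res[k] <- codons[i]
  }
  if (i < length(codons)) {
    stop("CDS ", which, " has ", length(codons) - i,
         " unaligned trailing codons", call. = FALSE)
  }
  res
}

#' Nei-Gojobori rate estimates for a codon alignment
#'
#' Computes fractional synonymous (S) and nonsynonymous (N) site counts
#' averaged over the two sequences, pathway-averaged synonymous (Sd) and
#' nonsynonymous (Nd) difference counts summed over columns, the observed
#' proportions pS and pN, Jukes-Cantor-corrected Ks and Ka, their ratio,
#' and a two-sided Fisher's exact p-value.  Columns containing a gap, an
#' ambiguous base, or a stop codon are skipped.
#'
#' @param alignment A \code{codon_alignment} (or a list with
#'   \code{codons_a}/\code{codons_b}), or a character vector interpreted as
#'   \code{codons_a} with \code{codons_b} supplied as the second argument.
#' @param codons_b Optional second codon vector when \code{alignment} is a
#'   plain vector.
#' @return Object of class \code{"rate_estimate"}: list with fields
#'   \code{n_codons}, \code{S}, \code{N}, \code{Sd}, \code{Nd}, \code{pS},
#'   \code{pN}, \code{Ks}, \code{Ka}, \code{omega}, \code{p_value} and
#'   \code{flag} (one of \code{"ok"}, \code{"identical"},
#'   \code{"ks_undefined"}, \code{"only_syn"}, \code{"only_nonsyn"}).
#' @export
ng_rates <- function(alignment, codons_b = NULL) {
  if (is.character(alignment)) {
    alignment <- list(codons_a = alignment, codons_b = codons_b)
  }
  ca <- toupper(alignment$codons_a)
  cb <- toupper(alignment$codons_b)
  if (length(ca) != length(cb)) {
    stop("codon vectors differ in length", call. = FALSE)
  }
  codons <- sense_codons()
  ok <- ca %in% codons & cb %in% codons
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0L) {
    stop("no comparable (ungapped, unambiguous) codon columns", call. = FALSE)
  }
  sites <- ng_site_table()
  diffs <- ng_diff_tables()
  S <- (sum(sites[ca, "s"]) + sum(sites[cb, "s"])) / 2
  N <- (sum(sites[ca, "n"]) + sum(sites[cb, "n"])) / 2
  idx <- cbind(match(ca, rownames(diffs$sd)), match(cb, colnames(diffs$sd)))
  Sd <- sum(diffs$sd[idx])
  Nd <- sum(diffs$nd[idx])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  flag <- if (Sd == 0 && Nd == 0) "identical"
          else if (is.na(Ks) || is.na(Ka)) "ks_undefined"
          else if (Nd == 0) "only_syn"
          else if (Sd == 0) "only_nonsyn"
          else "ok"
  omega <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(
    n_codons = length(ca), S = S, N = N, Sd = Sd, Nd = Nd,
    pS = pS, pN = pN, Ks = Ks, Ka = Ka, omega = omega,
    p_value = fisher_significance(S, N, Sd, Nd), flag = flag
  ), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "Nei-Gojobori estimate over %d codons\n  S = %.2f  N = %.2f  Sd = %.3f  Nd = %.3f\n  Ks = %s  Ka = %s  Ka/Ks = %s  p = %.4g  [%s]\n",
    x$n_codons, x$S, x$N, x$Sd, x$Nd,
    .fmt5(x$Ks), .fmt5(x$Ka), .fmt5(x$omega), x$p_value, x$flag))
  invisible(x)
}

.fmt5 <- function(x) if (is.na(x)) "NA" else sprintf("%.5f", x)

#' Fisher's exact test on substitution counts
#'
#' Two-sided Fisher's exact test on the 2x2 table of (rounded) synonymous
#' and nonsynonymous differences against remaining sites, the small-sample
#' significance test conventionally paired with counting-method Ka/Ks.
#'
#' @param S,N Synonymous/nonsynonymous site counts (positive).
#' @param Sd,Nd Difference counts, \code{0 <= Sd <= S}, \code{0 <= Nd <= N}.
#' @return Two-sided p-value.
#' @export
fisher_significance <- function(S, N, Sd, Nd) {
  if (any(c(S, N) <= 0)) stop("S and N must be positive", call. = FALSE)
  if (any(c(Sd, Nd) < 0)) stop("negative difference counts", call. = FALSE)
  tab <- matrix(c(round(Sd), round(S - Sd), round(Nd), round(N - Nd)),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) tab[tab < 0] <- 0
  stats::fisher.test(tab)$p.value
}
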