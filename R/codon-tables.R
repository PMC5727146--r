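# Codon-level machinery shared by the simulator and the Nei-Gojobori
# estimator: the standard genetic code, per-codon synonymous/nonsynonymous
# site fractions, and pathway-averaged difference counts for codon pairs.

.ksage <- new.env(parent = emptyenv())

#' Standard genetic code as a named vector
#'
#' Codon -> one-letter amino acid, stop codons as \code{"*"}. Taken from
#' \code{Biostrings::GENETIC_CODE}.
#' @return Named character vector of length 64.
#' @keywords internal
genetic_code <- function() {
  if (is.null(.ksage$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .ksage$gc <- stats::setNames(as.character(gc), names(gc))
  }
  .ksage$gc
}

#' The 61 sense codons
#' @return Character vector of sense codons in alphabetical order.
#' @keywords internal
sense_codons <- function() {
  gc <- genetic_code()
  sort(names(gc)[gc != "*"])
}

.bases <- c("A", "C", "G", "T")

# All 9 single-base neighbours of a codon.
codon_neighbours <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(.bases, nts[pos])) {
      mut <- nts
      mut[pos] <- b
      out <- c(out, paste(mut, collapse = ""))
    }
  }
  out
}

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' Counting-method site fractions: at each codon position the three possible
#' single-base changes are classified as synonymous or nonsynonymous;
#' changes creating a stop codon are excluded from both the numerator and
#' the denominator, so each position contributes exactly one site split
#' between the two classes and \code{s + n == 3} for every sense codon.
#'
#' @param codon A single sense codon (3-letter uppercase string).
#' @return Named numeric vector \code{c(s = ..., n = ...)}.
#' @examples
#' count_sites("GGT")  # all third-position changes synonymous: s = 1
#' count_sites("TTT")  # s = 1/3
#' @export
count_sites <- function(codon) {
  tab <- ng_site_table()
  if (!codon %in% rownames(tab)) {
    stop("count_sites: '", codon, "' is not a sense codon", call. = FALSE)
  }
  c(s = tab[codon, "s"], n = tab[codon, "n"])
}

# Precomputed site fractions for all 61 sense codons.
ng_site_table <- function() {
  if (!is.null(.ksage$sites)) return(.ksage$sites)
  gc <- genetic_code()
  codons <- sense_codons()
  tab <- matrix(0, nrow = length(codons), ncol = 2,
                dimnames = list(codons, c("s", "n")))
  for (codon in codons) {
    aa <- gc[[codon]]
    nts <- strsplit(codon, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      syn <- 0L
      viable <- 0L
      for (b in setdiff(.bases, nts[pos])) {
        mut <- nts
        mut[pos] <- b
        maa <- gc[[paste(mut, collapse = "")]]
        if (maa == "*") next
        viable <- viable + 1L
        if (maa == aa) syn <- syn + 1L
      }
      if (viable > 0L) s <- s + syn / viable
    }
    tab[codon, "s"] <- s
    tab[codon, "n"] <- 3 - s
  }
  .ksage$sites <- tab
  tab
}

#' Pathway-averaged substitution counts between two codons
#'
#' For codons differing at k positions, all k! orderings of the single-base
#' steps are enumerated; each step is synonymous if it preserves the amino
#' acid. Pathways passing through a stop codon are excluded; if every
#' pathway does, all are kept (the classical fallback). The per-pathway
#' (synonymous, nonsynonymous) tallies are averaged.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector \code{c(sd = ..., nd = ...)}; \code{sd + nd}
#'   equals the number of differing positions.
#' @examples
#' count_differences("GGT", "GGC")  # c(sd = 1, nd = 0)
#' count_differences("TTT", "GTA")  # c(sd = 0.5, nd = 1.5)
#' @export
count_differences <- function(codon_a, codon_b) {
  gc <- genetic_code()
  for (codon in c(codon_a, codon_b)) {
    if (is.na(gc[codon]) || gc[[codon]] == "*") {
      stop("count_differences: '", codon, "' is not a sense codon",
           call. = FALSE)
    }
  }
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  nts_a <- strsplit(codon_a, "")[[1]]
  nts_b <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(nts_a != nts_b)
  perms <- .permutations(diff_pos)
  tally <- function(order, allow_stop) {
    cur <- nts_a
    sd <- 0L; nd <- 0L
    for (pos in order) {
      prev_aa <- gc[[paste(cur, collapse = "")]]
      cur[pos] <- nts_b[pos]
      new_aa <- gc[[paste(cur, collapse = "")]]
      if (new_aa == "*" && !allow_stop) return(NULL)
      if (new_aa == prev_aa) sd <- sd + 1L else nd <- nd + 1L
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, tally, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(perms, tally, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# All permutations of a small vector (k <= 3 here).
.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# 61 x 61 lookup matrices of pathway-averaged sd/nd, built lazily.
ng_diff_tables <- function() {
  if (!is.null(.ksage$diffs)) return(.ksage$diffs)
  codons <- sense_codons()
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- sd
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- count_differences(codons[i], codons[j])
      sd[i, j] <- sd[j, i] <- d[["sd"]]
      nd[i, j] <- nd[j, i] <- d[["nd"]]
    }
  }
  .ksage$diffs <- list(sd = sd, nd = nd)
  .ksage$diffs
}

#' Split a coding sequence into codons
#'
#' @param cds Nucleotide string; length must be a multiple of 3.
#' @return Character vector of 3-letter codons.
#' @export
split_codons <- function(cds) {
  if (nchar(cds) %% 3 != 0) {
    stop("sequence length ", nchar(cds), " is not a multiple of 3",
         call. = FALSE)
  }
  substring(cds, seq(1, nchar(cds), by = 3), seq(3, nchar(cds), by = 3))
}
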