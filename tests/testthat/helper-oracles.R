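# Independent oracles used to check the package implementations on small
# instances: a plain Gotoh dynamic-programming aligner, a hypergeometric
# enumeration of Fisher's two-sided p, and brute-force codon-site /
# substitution-pathway enumerators written directly against the genetic
# code table.

STD_CODE <- as.character(Biostrings::GENETIC_CODE)
names(STD_CODE) <- names(Biostrings::GENETIC_CODE)

# Global affine-gap alignment score by explicit three-matrix DP
# (no traceback; scores only).
oracle_gotoh_score <- function(a, b, mat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  # M: end in match/mismatch; X: gap in b (consume a); Y: gap in a
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- -gap_open - gap_extend * (i - 1)
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- -gap_open - gap_extend * (j - 1)
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[ca[i - 1], cb[j - 1]]
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend,
                     Y[i - 1, j] - gap_open - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend,
                     X[i, j - 1] - gap_open - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Two-sided Fisher p for a 2x2 table by summing hypergeometric
# probabilities no larger than the observed one.
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Site fractions by direct neighbour enumeration: at each position the
# synonymous fraction among the non-stop single-base changes.
oracle_sites <- function(codon) {
  aa <- STD_CODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    cod <- strsplit(codon, "")[[1]]
    syn <- 0; viable <- 0
    for (base in c("A", "C", "G", "T")) {
      if (base == cod[pos]) next
      mut <- cod; mut[pos] <- base
      mut_aa <- STD_CODE[[paste(mut, collapse = "")]]
      if (mut_aa == "*") next
      viable <- viable + 1
      if (mut_aa == aa) syn <- syn + 1
    }
    if (viable > 0) s <- s + syn / viable
  }
  c(s = s, n = 3 - s)
}

# Pathway-averaged difference counts by enumerating every ordering of the
# differing positions, dropping orderings that pass through a stop codon
# (keeping all if none survives).
oracle_diffs <- function(ca, cb) {
  va <- strsplit(ca, "")[[1]]
  vb <- strsplit(cb, "")[[1]]
  pos <- which(va != vb)
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  orders <- if (k == 1) list(pos) else {
    perms <- list()
    idx <- seq_len(k)
    rec <- function(prefix, left) {
      if (length(left) == 0) {
        perms[[length(perms) + 1]] <<- prefix
      } else {
        for (x in left) rec(c(prefix, x), setdiff(left, x))
      }
    }
    rec(integer(0), pos)
    perms
  }
  walk <- function(ord, allow_stop) {
    cur <- va; sd <- 0; nd <- 0
    for (p in ord) {
      aa0 <- STD_CODE[[paste(cur, collapse = "")]]
      cur[p] <- vb[p]
      aa1 <- STD_CODE[[paste(cur, collapse = "")]]
      if (aa1 == "*" && !allow_stop) return(NULL)
      if (aa1 == aa0) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(orders, walk, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(orders, walk, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# Tiny convenience: a one-speciation, two-species scenario.
two_species_scenario <- function(ks = 0.05, n_families = 20,
                                 codon_length = 100, omega = 0.3,
                                 seed = 1L, wgd_ks = NULL,
                                 retention_prob = 1) {
  events <- list()
  if (!is.null(wgd_ks)) {
    events[[1]] <- list(kind = "wgd", lineage = "root", ks = wgd_ks)
  }
  events[[length(events) + 1]] <-
    list(kind = "speciation", lineage = "root", into = c("s1", "s2"),
         ks = ks)
  evol_scenario(species = c("s1", "s2"), events = events,
                n_families = n_families, codon_length = codon_length,
                omega = omega, retention_prob = retention_prob,
                seed = seed)
}
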