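# Ks-sample modelling: the ordered exclusion ledger, log-Gaussian mixture
# fitting with BIC model choice, peak extraction, molecular-clock dating,
# and the Ka/Ks selection screen.

#' Build an exclusion ledger from category counts
#'
#' Bookkeeping helper: given the number of input pairs and the counts
#' removed per category, the number retained follows from the partition
#' invariant.
#'
#' @param n_input Total pairs entering the screen.
#' @param n_identical Pairs with no substitutions at all.
#' @param n_ks_undefined Pairs whose corrected rates are undefined
#'   (saturation).
#' @param n_only_nonsyn,n_only_syn Pairs with only one substitution type.
#' @param n_ks_above_cutoff Pairs with Ks above the paralog-suspicion
#'   cutoff.
#' @param cutoff The Ks cutoff used (default 0.1).
#' @return Object of class \code{"exclusion_ledger"} with the six counts
#'   plus \code{n_retained}.
#' @export
exclusion_ledger <- function(n_input, n_identical = 0, n_ks_undefined = 0,
                             n_only_nonsyn = 0, n_only_syn = 0,
                             n_ks_above_cutoff = 0, cutoff = 0.1) {
  counts <- c(n_identical, n_ks_undefined, n_only_nonsyn, n_only_syn,
              n_ks_above_cutoff)
  if (any(c(n_input, counts) < 0)) stop("negative counts", call. = FALSE)
  n_retained <- n_input - sum(counts)
  if (n_retained < 0) stop("categories exceed input", call. = FALSE)
  structure(list(n_input = n_input, n_identical = n_identical,
                 n_ks_undefined = n_ks_undefined,
                 n_only_nonsyn = n_only_nonsyn, n_only_syn = n_only_syn,
                 n_ks_above_cutoff = n_ks_above_cutoff,
                 n_retained = n_retained, cutoff = cutoff),
            class = "exclusion_ledger")
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf(
    paste0("Exclusion ledger (Ks cutoff %g)\n  input: %d\n",
           "  identical: %d\n  Ks undefined: %d\n  only nonsynonymous: %d\n",
           "  only synonymous: %d\n  Ks > cutoff: %d\n  retained: %d\n"),
    x$cutoff, x$n_input, x$n_identical, x$n_ks_undefined, x$n_only_nonsyn,
    x$n_only_syn, x$n_ks_above_cutoff, x$n_retained))
  invisible(x)
}

#' Apply the ordered exclusion ledger to rate estimates
#'
#' Pairs are assigned to exactly one category in the fixed order:
#' identical, Ks-undefined, only-nonsynonymous, only-synonymous,
#' Ks above cutoff, retained.  Retained pairs have both substitution
#' types and a defined Ks at or below the cutoff.
#'
#' @param rates data.frame of batch rate estimates (needs columns
#'   \code{Sd}, \code{Nd}, \code{Ks}, \code{flag}).
#' @param ks_cutoff Ks threshold above which pairs are suspected hidden
#'   paralogs (default 0.1); use \code{Inf} to disable.
#' @return List with \code{retained} (the surviving rows, with a
#'   \code{category} column on the full input copy in \code{assigned}) and
#'   \code{ledger} (an \code{\link{exclusion_ledger}}).
#' @export
apply_exclusion_ledger <- function(rates, ks_cutoff = 0.1) {
  cat_of <- function(flag, ks) {
    if (flag == "identical") "identical"
    else if (flag == "ks_undefined") "ks_undefined"
    else if (flag == "only_nonsyn") "only_nonsyn"
    else if (flag == "only_syn") "only_syn"
    else if (!is.na(ks) && ks > ks_cutoff) "ks_above_cutoff"
    else "retained"
  }
  category <- mapply(cat_of, rates$flag, rates$Ks)
  rates$category <- unname(category)
  tab <- function(k) sum(category == k)
  ledger <- exclusion_ledger(
    n_input = nrow(rates), n_identical = tab("identical"),
    n_ks_undefined = tab("ks_undefined"),
    n_only_nonsyn = tab("only_nonsyn"), n_only_syn = tab("only_syn"),
    n_ks_above_cutoff = tab("ks_above_cutoff"), cutoff = ks_cutoff)
  list(retained = rates[category == "retained", , drop = FALSE],
       assigned = rates, ledger = ledger)
}

#' Fit log-Gaussian mixture models to a Ks sample
#'
#' EM on ln(Ks) for each candidate component count, each started from
#' several quantile-spread initialisations; the model with the lowest BIC
#' (a Bayes-factor surrogate) is selected.  The procedure is fully
#' deterministic: initialisations are quantile-based, not random.
#'
#' @param ks Numeric vector of Ks values (> 0).
#' @param k_candidates Component counts to try (default 1:4).
#' @param fit_range Two-element range; values outside are dropped before
#'   fitting (default \code{c(0.005, 2)}, avoiding the zero-inflation
#'   spike and the saturation tail).
#' @param min_points Minimum retained values (default 20).
#' @param n_init Initialisations per k (default 3).
#' @param max_iter,tol EM stopping rule (default 500 iterations or
#'   log-likelihood improvement below 1e-8).
#' @param seed Accepted for interface stability; the fit is deterministic.
#' @return Object of class \code{"ks_mixture_fit"}: list with
#'   \code{components} (data.frame weight, mu, sigma, ks_peak), \code{k},
#'   \code{loglik}, \code{bic}, \code{fit_range}, \code{n_points}, and
#'   \code{candidates} (per-k loglik/bic table).
#' @export
fit_log_gaussian_mixture <- function(ks, k_candidates = 1:4,
                                     fit_range = c(0.005, 2),
                                     min_points = 20, n_init = 3,
                                     max_iter = 500, tol = 1e-8,
                                     seed = NULL) {
  if (any(ks <= 0, na.rm = TRUE)) {
    ks <- ks[!is.na(ks) & ks > 0]
  } else {
    ks <- ks[!is.na(ks)]
  }
  x <- log(ks[ks >= fit_range[1] & ks <= fit_range[2]])
  if (length(x) < min_points) {
    stop("only ", length(x), " Ks values inside the fit range; need >= ",
         min_points, call. = FALSE)
  }
  fits <- list()
  for (k in k_candidates) {
    best <- NULL
    for (init in seq_len(n_init)) {
      f <- .em_gaussian(x, k, init, n_init, max_iter, tol)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    best$bic <- -2 * best$loglik + (3 * k - 1) * log(length(x))
    fits[[as.character(k)]] <- best
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  chosen <- fits[[which.min(bics)]]
  comp <- data.frame(weight = chosen$weight, mu = chosen$mu,
                     sigma = chosen$sigma,
                     ks_peak = exp(chosen$mu))
  comp <- comp[order(comp$mu), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(
    components = comp, k = nrow(comp), loglik = chosen$loglik,
    bic = chosen$bic, fit_range = fit_range, n_points = length(x),
    candidates = data.frame(k = as.integer(names(fits)),
                            loglik = vapply(fits, `[[`, numeric(1),
                                            "loglik"),
                            bic = unname(bics))),
    class = "ks_mixture_fit")
}

# One EM run on x for k components, initialised by spreading means over
# quantiles (shifted per initialisation index).
.em_gaussian <- function(x, k, init, n_init, max_iter, tol) {
  n <- length(x)
  if (k == 1) {
    mu <- mean(x); sigma <- max(stats::sd(x), 1e-3)
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    return(list(weight = 1, mu = mu, sigma = sigma, loglik = ll))
  }
  shift <- (init - 1) / (2 * n_init)
  probs <- (seq_len(k) - 0.5) / k + shift
  probs <- pmin(pmax(probs, 0.02), 0.98)
  mu <- as.numeric(stats::quantile(x, probs, names = FALSE))
  sigma <- rep(max(stats::sd(x) / k, 1e-3), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    resp <- dens / rs
    nk <- colSums(resp)
    nk[nk < 1e-8] <- 1e-8
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- vapply(seq_len(k), function(j) {
      sqrt(sum(resp[, j] * (x - mu[j])^2) / nk[j])
    }, numeric(1))
    sigma <- pmax(sigma, 1e-3)
    if (is.finite(ll_old) && ll - ll_old < tol) { ll_old <- ll; break }
    ll_old <- ll
  }
  list(weight = w, mu = mu, sigma = sigma, loglik = ll_old)
}

#' @export
print.ks_mixture_fit <- function(x, ...) {
  cat(sprintf("Log-Gaussian mixture: k = %d, n = %d, BIC = %.2f\n",
              x$k, x$n_points, x$bic))
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  component %d: weight %.3f, Ks peak %.4f (sigma_ln %.3f)\n",
                i, comp$weight[i], comp$ks_peak[i], comp$sigma[i]))
  }
  invisible(x)
}

#' Extract Ks peaks from a mixture fit
#'
#' One peak per component whose weight meets the threshold, located at
#' \code{exp(mu)}; sorted ascending.  The maximum-weight component among
#' those reported is flagged dominant.
#'
#' @param fit A \code{\link{fit_log_gaussian_mixture}} result.
#' @param min_weight Minimum component weight (default 0.10).
#' @return data.frame (ks_peak, weight, dominant) sorted by ks_peak.
#' @export
find_peaks <- function(fit, min_weight = 0.10) {
  comp <- fit$components[fit$components$weight >= min_weight, ,
                         drop = FALSE]
  comp <- comp[order(comp$ks_peak), , drop = FALSE]
  out <- data.frame(ks_peak = comp$ks_peak, weight = comp$weight,
                    dominant = FALSE)
  if (nrow(out) > 0) out$dominant[which.max(out$weight)] <- TRUE
  rownames(out) <- NULL
  out
}

#' Date a Ks peak with a strict molecular clock
#'
#' T = Ks / (2 r), with r the per-year synonymous substitution rate; the
#' factor 2 accounts for the two diverging branches.  The dicot rate
#' 1.5e-8 substitutions per synonymous site per year is the default.
#'
#' @param ks_peak Ks value at the peak (>= 0).
#' @param rate Substitution rate per synonymous site per year (> 0).
#' @param label Optional event label.
#' @return Object of class \code{"dated_event"}: list with
#'   \code{ks_peak}, \code{rate}, \code{T_my} (age in million years) and
#'   \code{label}.
#' @examples
#' date_event(0.5)$T_my   # 16.7 (rounded to 1 decimal)
#' @export
date_event <- function(ks_peak, rate = 1.5e-8, label = NA_character_) {
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (ks_peak < 0) stop("ks_peak must be >= 0", call. = FALSE)
  structure(list(ks_peak = ks_peak, rate = rate,
                 T_my = ks_peak / (2 * rate) / 1e6, label = label),
            class = "dated_event")
}

#' @export
print.dated_event <- function(x, ...) {
  cat(sprintf("%s: Ks peak %.4g -> %.1f MY (rate %.3g /site/year)\n",
              if (is.na(x$label)) "event" else x$label, x$ks_peak, x$T_my,
              x$rate))
  invisible(x)
}

#' Classify retained pairs by selection regime
#'
#' Pairs with Ka/Ks below one are called purifying, above one positive;
#' a ratio of exactly one is binned as purifying.  Optionally the positive
#' class can additionally require Fisher significance.
#'
#' @param retained data.frame of retained rate estimates (columns
#'   \code{omega}, \code{p_value}; pair id columns carried through).
#' @param require_significance If \code{TRUE}, positive calls also need
#'   \code{p_value <= alpha} (default FALSE: the ratio alone decides).
#' @param alpha Significance level when gating (default 0.05).
#' @return List with \code{calls} (input plus a \code{class} column) and
#'   \code{summary}: class counts, percentages (2 decimals), and mean Ka,
#'   Ks, Ka/Ks.
#' @export
classify_selection <- function(retained, require_significance = FALSE,
                               alpha = 0.05) {
  if (nrow(retained) > 0 && anyNA(retained$omega)) {
    stop("pair without defined Ka/Ks reached the selection screen",
         call. = FALSE)
  }
  class <- ifelse(retained$omega > 1, "positive", "purifying")
  if (require_significance) {
    class[class == "positive" & retained$p_value > alpha] <- "purifying"
  }
  retained$class <- class
  n_pos <- sum(class == "positive")
  n_pur <- sum(class == "purifying")
  list(calls = retained,
       summary = c(list(n_retained = nrow(retained), n_purifying = n_pur,
                        n_positive = n_pos),
                   selection_percentages(n_pur, n_pos),
                   list(mean_ka = mean(retained$Ka),
                        mean_ks = mean(retained$Ks),
                        mean_omega = mean(retained$omega))))
}

#' Class percentages from purifying/positive counts
#'
#' @param n_purifying,n_positive Non-negative counts.
#' @return List \code{pct_purifying}, \code{pct_positive}, each rounded to
#'   2 decimals.
#' @export
selection_percentages <- function(n_purifying, n_positive) {
  total <- n_purifying + n_positive
  if (total == 0) return(list(pct_purifying = NA_real_,
                              pct_positive = NA_real_))
  list(pct_purifying = round(100 * n_purifying / total, 2),
       pct_positive = round(100 * n_positive / total, 2))
}
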