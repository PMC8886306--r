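#' Kendall tau-b rank correlation with exact permutation p-value
#'
#' Tau-b applies the average-rank tie correction:
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)}}
#' where C and D are the concordant and discordant pair counts, n0 =
#' n(n-1)/2 and n1, n2 are the tied-pair counts of the two vectors.
#' For n <= `exact_max_n` the two-sided p-value is exact, by full
#' enumeration of all n! orderings (720 permutations at the n = 6 of a
#' six-pattern severity ranking, where the normal approximation is
#' unreliable); for larger n the tie-corrected normal approximation of
#' [stats::cor.test()] is used.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @param exact_max_n Largest n for which the permutation p is
#'   enumerated exactly.
#' @return List with elements `tau`, `p` and `n`.
#' @examples
#' kendall_tau_b(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
kendall_tau_b <- function(x, y, exact_max_n = 8L) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("tau is undefined for a constant vector")
  tau <- tau_b_stat(x, y)
  if (n <= exact_max_n) {
    perms <- permutations(n)
    taus <- apply(perms, 1L, function(idx) tau_b_stat(x, y[idx]))
    p <- mean(abs(taus) >= abs(tau) - 1e-12)
  } else {
    p <- stats::cor.test(x, y, method = "kendall", exact = FALSE)$p.value
  }
  list(tau = tau, p = p, n = n)
}

# pair-counting tau-b
tau_b_stat <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, "-")[lower.tri(diag(n))])
  dy <- sign(outer(y, y, "-")[lower.tri(diag(n))])
  C <- sum(dx * dy > 0)
  D <- sum(dx * dy < 0)
  n0 <- n * (n - 1) / 2
  n1 <- sum(dx == 0)
  n2 <- sum(dy == 0)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# all permutations of 1..n as a (n!) x n matrix
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Read a severity rank table
#'
#' TSV with one row per error pattern and columns `pattern`,
#' `clinical` (mean clinician severity ranking, 1 = least to 6 = most
#' severe) and the mean effect scores `wcm`, `ipc`, `pcc`, `lvn`,
#' `pwp` (SD columns, if present, are carried along). The package
#' bundles such a table for Swedish child speech, see
#' [ref_rank_table()].
#'
#' @param path File path.
#' @return Data frame, one row per pattern.
#' @export
read_rank_table <- function(path) {
  rt <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("pattern", "clinical", "wcm", "ipc", "pcc", "lvn", "pwp")
  miss <- setdiff(need, names(rt))
  if (length(miss))
    stop("rank table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(rt$pattern)) stop("duplicate pattern rows in rank table")
  rt
}

#' Bundled severity rank table for Swedish child speech
#'
#' Mean clinician severity rankings (n = 33 practicing SLPs, scale 1-6)
#' and token-weighted mean effect scores of the five measures for the
#' six error patterns, as published for a Swedish child-speech corpus
#' simulation. Used as the reference input of the face-validity
#' rank-correlation analysis.
#'
#' @return Data frame as [read_rank_table()].
#' @export
ref_rank_table <- function() {
  read_rank_table(phonsim_file("ranktables", "swe_child_speech.tsv"))
}

#' Severity correlation matrix across measures
#'
#' Pairwise Kendall tau-b (with exact permutation p-values) over the
#' clinician rankings and the five measure columns of a rank table.
#' The structural measures enter as absolute values --- a complexity
#' *change* of either sign is an effect --- while PCC, LVN and PWP
#' enter raw.
#'
#' @param rt Rank table (see [read_rank_table()]).
#' @return List of two matrices, `tau` and `p`, with unit diagonal and
#'   dimnames `clinical`, `wcm`, `ipc`, `pcc`, `lvn`, `pwp`.
#' @examples
#' m <- severity_correlation_matrix(ref_rank_table())
#' round(m$tau["clinical", ], 2)
#' @export
severity_correlation_matrix <- function(rt) {
  cols <- c("clinical", "wcm", "ipc", "pcc", "lvn", "pwp")
  miss <- setdiff(cols, names(rt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  vals <- rt[, cols]
  vals$wcm <- abs(vals$wcm)
  vals$ipc <- abs(vals$ipc)
  k <- length(cols)
  tau <- diag(k); p <- matrix(NA_real_, k, k)
  dimnames(tau) <- dimnames(p) <- list(cols, cols)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    kt <- kendall_tau_b(vals[[i]], vals[[j]])
    tau[i, j] <- tau[j, i] <- kt$tau
    p[i, j] <- p[j, i] <- kt$p
  }
  list(tau = tau, p = p)
}

#' Summarise per-respondent clinician rankings
#'
#' Takes a table of individual severity rankings (one row per
#' respondent, one column per error pattern, values 1 = least severe
#' to 6 = most severe) and returns per-pattern means and SDs, the
#' `clinical` column of a rank table. Respondent exclusion (e.g. by
#' years of experience) is the caller's responsibility.
#'
#' @param rankings Data frame or matrix of rankings, columns named by
#'   pattern.
#' @return Data frame with columns `pattern`, `clinical`,
#'   `clinical_sd`, `n_respondents`.
#' @export
summarize_rankings <- function(rankings) {
  m <- as.matrix(rankings)
  if (is.null(colnames(m))) stop("ranking columns must be named by pattern")
  data.frame(
    pattern = colnames(m),
    clinical = colMeans(m),
    clinical_sd = apply(m, 2, stats::sd),
    n_respondents = nrow(m),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
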