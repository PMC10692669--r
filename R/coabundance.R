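#' Rank protein complexes by subunit co-abundance
#'
#' For every complex with at least \code{min_members} measured members, the
#' co-abundance score is the mean Pearson correlation over all member pairs,
#' computed across samples on pairwise-complete observations. Complexes are
#' ranked by score and partitioned into quartile classes: the
#' ceiling(N/4) highest-correlation complexes are \code{stable}, the
#' ceiling(N/4) lowest are \code{variable}, the rest \code{intermediate}
#' (ties broken by complex id). Member pairs sharing fewer than 3 samples are
#' skipped; complexes left without a valid pair are excluded.
#'
#' @param m Numeric matrix of log2 abundances, features x samples (missing
#'   values allowed).
#' @param cat A complex catalog: data.frame with columns \code{complex_id},
#'   \code{member}.
#' @param min_members Minimum measured members per complex (default 5).
#' @return A \code{complex_stability} data.frame: \code{complex_id},
#'   \code{mean_correlation}, \code{n_members}, \code{n_pairs}, \code{rank}
#'   (1 = highest correlation), \code{class}.
#' @export
complex_coabundance <- function(m, cat, min_members = 5) {
  stopifnot(min_members >= 2)
  rows <- lapply(unique(cat$complex_id), function(cx) {
    members <- unique(cat$member[cat$complex_id == cx])
    members <- members[members %in% rownames(m)]
    if (length(members) < min_members) return(NULL)
    sub <- m[members, , drop = FALSE]
    cors <- numeric(); skipped <- 0L
    for (i in seq_len(length(members) - 1)) {
      for (j in (i + 1):length(members)) {
        shared <- !is.na(sub[i, ]) & !is.na(sub[j, ])
        if (sum(shared) < 3) { skipped <- skipped + 1L; next }
        cors <- c(cors, cor(sub[i, shared], sub[j, shared]))
      }
    }
    if (skipped > 0) {
      message(sprintf("complex %s: skipped %d pair(s) with < 3 shared samples",
                      cx, skipped))
    }
    if (!length(cors)) return(NULL)
    data.frame(complex_id = cx, mean_correlation = mean(cors),
               n_members = length(members), n_pairs = length(cors),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(complex_id = character(), mean_correlation = numeric(),
                      n_members = integer(), n_pairs = integer(),
                      rank = integer(), class = character())
    class(out) <- c("complex_stability", "data.frame")
    return(out)
  }
  ord <- order(-out$mean_correlation, out$complex_id)
  out <- out[ord, , drop = FALSE]
  n <- nrow(out)
  out$rank <- seq_len(n)
  q <- ceiling(n / 4)
  cls <- rep("intermediate", n)
  cls[seq_len(min(q, n))] <- "stable"
  nv <- min(q, n - q)
  if (nv > 0) cls[seq(n - nv + 1, n)] <- "variable"
  out$class <- cls
  rownames(out) <- NULL
  class(out) <- c("complex_stability", "data.frame")
  out
}

#' Per-subunit abundance variance
#'
#' Sample variance (n-1 denominator) of each listed member over its observed
#' values, ignoring missing entries. Members with fewer than 2 observations
#' get NA (reported).
#'
#' @param m Numeric matrix of log2 abundances, features x samples.
#' @param members Character vector of member features (must be rows of
#'   \code{m}).
#' @return Named numeric vector of variances.
#' @export
subunit_variance <- function(m, members) {
  miss <- setdiff(members, rownames(m))
  if (length(miss)) stopf("member(s) absent from the matrix: %s",
                          paste(miss, collapse = ", "))
  v <- vapply(members, function(mm) {
    obs <- m[mm, ][!is.na(m[mm, ])]
    if (length(obs) < 2) NA_real_ else var(obs)
  }, numeric(1))
  if (anyNA(v)) {
    message(sprintf("%d member(s) with < 2 observations: variance NA", sum(is.na(v))))
  }
  v
}

#' Gene-wise mRNA-protein correlation
#'
#' Pearson correlation per shared gene between log2 mRNA and log2 protein
#' abundances over samples matched by name; genes with fewer than
#' \code{min_samples} paired observations are excluded with a reason.
#'
#' @param rna,prot Numeric matrices (genes x samples, log2 scale); samples are
#'   matched by column name, genes by row name.
#' @param min_samples Minimum paired observations per gene (default 4).
#' @return data.frame: \code{gene}, \code{correlation}, \code{n_paired};
#'   excluded genes with reasons in attribute \code{"excluded"}.
#' @export
gene_wise_correlation <- function(rna, prot, min_samples = 4) {
  shared_s <- intersect(colnames(rna), colnames(prot))
  if (!length(shared_s)) stopf("no shared samples between the matrices")
  shared_g <- intersect(rownames(rna), rownames(prot))
  res <- list(); excl <- list()
  for (g in shared_g) {
    x <- rna[g, shared_s]; y <- prot[g, shared_s]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_samples) {
      excl[[g]] <- sprintf("only %d paired observations (< %d)", sum(ok), min_samples)
      next
    }
    res[[g]] <- data.frame(gene = g, correlation = cor(x[ok], y[ok]),
                           n_paired = sum(ok), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(gene = character(), correlation = numeric(),
                                      n_paired = integer())
  rownames(out) <- NULL
  attr(out, "excluded") <- unlist(excl)
  out
}

#' Read a complex catalog from a two-column TSV
#'
#' @param path TSV with columns \code{complex_id}, \code{member}.
#' @return data.frame catalog.
#' @export
read_complex_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("complex_id", "member"), names(df))
  if (length(miss)) stopf("complex catalog lacks column(s): %s",
                          paste(miss, collapse = ", "))
  df
}
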