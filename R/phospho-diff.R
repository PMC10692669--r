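#' Construct a fragment-level intensity table
#'
#' The long-format container for DIA fragment quantities: one row per fragment
#' per sample, with condition/replicate annotations, plus a peptide metadata
#' table (protein accession, peptide sequence, 1-based phospho offsets within
#' the peptide). Exactly one condition must be designated the control.
#'
#' @param data data.frame with columns \code{peptide_id}, \code{fragment_id},
#'   \code{sample}, \code{condition}, \code{replicate}, \code{intensity}
#'   (non-negative or NA for missing).
#' @param peptides data.frame with columns \code{peptide_id}, \code{protein},
#'   \code{sequence}, \code{offsets} (comma-separated 1-based offsets of the
#'   phospho-residues within the peptide).
#' @param control The control condition label; must occur in
#'   \code{data$condition}.
#' @return An object of class \code{fragment_table}.
#' @export
fragment_table <- function(data, peptides, control = "CTRL") {
  need <- c("peptide_id", "fragment_id", "sample", "condition", "replicate", "intensity")
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("fragment data lacks column(s): %s", paste(miss, collapse = ", "))
  need_p <- c("peptide_id", "protein", "sequence", "offsets")
  miss <- setdiff(need_p, names(peptides))
  if (length(miss)) stopf("peptide metadata lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(data$intensity < 0, na.rm = TRUE)) stopf("negative intensities are not allowed")
  if (nrow(data) > 0 && !(control %in% data$condition)) {
    stopf("control condition '%s' absent from the data", control)
  }
  structure(list(data = data, peptides = peptides, control = control),
            class = "fragment_table")
}

#' @export
print.fragment_table <- function(x, ...) {
  cat(sprintf("<fragment_table> %d measurements, %d fragments, %d peptides\n",
              nrow(x$data), length(unique(x$data$fragment_id)),
              length(unique(x$data$peptide_id))))
  cat(sprintf("  conditions: %s (control: %s)\n",
              paste(unique(x$data$condition), collapse = ", "), x$control))
  invisible(x)
}

#' Filter fragment-level intensities
#'
#' Applies the reliability filters used for DIA phosphoproteomic fragment data,
#' in this fixed order:
#' \enumerate{
#'   \item intensity filter: values not strictly above \code{min_intensity}
#'     (default 2000) are set missing;
#'   \item detection filter: a fragment detected fewer than
#'     \code{min_detected_per_condition} times in every condition is dropped;
#'   \item coherence filter, iterated to a fixed point: within each peptide, a
#'     fragment is dropped if the Pearson correlation of its log2 profile with
#'     the per-sample median profile of the peptide is below \code{min_corr},
#'     or if its mean log2 intensity deviates from the peptide consensus
#'     (mean of fragment means) by more than \code{sd_factor} standard
#'     deviations of the fragment means;
#'   \item fragment-count filter: peptides with fewer than
#'     \code{min_fragments} surviving fragments are dropped entirely.
#' }
#' Iterating step 3 to a fixed point makes the whole filter idempotent:
#' applying it twice gives exactly the result of applying it once. The
#' intensity boundary is strict (exactly \code{min_intensity} is removed).
#' The coherence-filter internals of the upstream tool this emulates are not
#' published; the correlation/SD definitions here are this package's
#' documented interpretation.
#'
#' @param t A \code{fragment_table}.
#' @param min_intensity Absolute intensity threshold; values \code{<=} it
#'   become missing.
#' @param min_fragments Minimum surviving fragments per peptide.
#' @param min_detected_per_condition Minimum detections in at least one
#'   condition.
#' @param sd_factor Allowed deviation of a fragment's mean log2 intensity from
#'   the peptide consensus, in standard deviations.
#' @param min_corr Minimum correlation with the peptide median profile;
#'   fragments with fewer than 3 shared samples with the median profile are
#'   kept (too little data to judge).
#' @return A filtered \code{fragment_table}; empty input gives an empty table,
#'   and a filter that removes everything warns.
#' @export
filter_fragments <- function(t, min_intensity = 2000, min_fragments = 5,
                             min_detected_per_condition = 2, sd_factor = 2,
                             min_corr = 0.25) {
  stopifnot(inherits(t, "fragment_table"),
            min_intensity >= 0, min_fragments >= 0,
            min_detected_per_condition >= 0, sd_factor >= 0)
  d <- t$data
  if (nrow(d) == 0) return(t)
  had_rows <- TRUE
  # 1. absolute intensity: strictly above the threshold is kept
  d$intensity[!is.na(d$intensity) & d$intensity <= min_intensity] <- NA_real_

  # 2. detection count: keep fragments detected enough times in >= 1 condition
  det <- stats::aggregate(!is.na(d$intensity),
                          by = list(fragment_id = d$fragment_id, condition = d$condition),
                          FUN = sum)
  best <- tapply(det$x, det$fragment_id, max)
  keep_frag <- names(best)[best >= min_detected_per_condition]
  d <- d[d$fragment_id %in% keep_frag, , drop = FALSE]

  # 3. coherence (correlation / SD) filter, iterated to a fixed point
  repeat {
    drop <- character()
    for (pep in unique(d$peptide_id)) {
      dp <- d[d$peptide_id == pep, , drop = FALSE]
      frs <- unique(dp$fragment_id)
      if (length(frs) < 2) next
      m <- tapply(log2(dp$intensity), list(dp$fragment_id, dp$sample),
                  function(v) v[1])
      med <- apply(m, 2, median, na.rm = TRUE)
      fmean <- rowMeans(m, na.rm = TRUE)
      mu <- mean(fmean); s <- sd(fmean)
      for (fr in rownames(m)) {
        prof <- m[fr, ]
        shared <- !is.na(prof) & !is.na(med)
        if (sum(shared) >= 3 && sd(prof[shared]) > 0 && sd(med[shared]) > 0) {
          if (cor(prof[shared], med[shared]) < min_corr) {
            drop <- c(drop, fr)
            next
          }
        }
        if (!is.na(s) && s > 0 && abs(fmean[fr] - mu) > sd_factor * s) {
          drop <- c(drop, fr)
        }
      }
    }
    if (!length(drop)) break
    d <- d[!(d$fragment_id %in% drop), , drop = FALSE]
  }

  # 4. minimum fragments per peptide
  nf <- tapply(d$fragment_id, d$peptide_id, function(f) length(unique(f)))
  keep_pep <- names(nf)[nf >= min_fragments]
  d <- d[d$peptide_id %in% keep_pep, , drop = FALSE]

  if (had_rows && nrow(d) == 0) {
    warnf("all fragments of all peptides were removed by filtering")
    return(structure(list(data = d,
                          peptides = t$peptides[0, , drop = FALSE],
                          control = t$control), class = "fragment_table"))
  }
  structure(list(data = d,
                 peptides = t$peptides[t$peptides$peptide_id %in% d$peptide_id, , drop = FALSE],
                 control = t$control),
            class = "fragment_table")
}

#' Impute missing fragment replicate values
#'
#' Missing values of a fragment are replaced by 20\% of the minimum observed
#' intensity of that fragment; observed values are never changed. Fragments
#' with no observed value at all cannot be imputed and are dropped with a
#' warning.
#'
#' @param t A \code{fragment_table}.
#' @return A \code{fragment_table} without missing values.
#' @export
impute_missing <- function(t) {
  stopifnot(inherits(t, "fragment_table"))
  d <- t$data
  if (nrow(d) == 0) return(t)
  mins <- tapply(d$intensity, d$fragment_id, function(v) {
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  })
  dead <- names(mins)[is.na(mins)]
  if (length(dead)) {
    warnf("%d fragment(s) entirely missing were dropped (cannot impute)", length(dead))
    d <- d[!(d$fragment_id %in% dead), , drop = FALSE]
  }
  na <- is.na(d$intensity)
  d$intensity[na] <- 0.2 * as.numeric(mins[d$fragment_id[na]])
  structure(list(data = d, peptides = t$peptides, control = t$control),
            class = "fragment_table")
}

#' Map phosphopeptides to protein phosphosite positions
#'
#' Locates each peptide sequence in its stated protein and converts the
#' peptide-level phospho offsets (1-based within the peptide) into
#' protein-level site keys. The residue letter is taken from the protein
#' sequence, which is authoritative; positions are 1-based. Peptides absent
#' from their protein are excluded and reported; if a peptide occurs more than
#' once in the protein, the first occurrence is used and the peptide flagged.
#'
#' @param t A \code{fragment_table} (only the peptide metadata is used).
#' @param proteome Named character vector: accession -> protein sequence.
#' @return data.frame with one row per (peptide, site): \code{peptide_id},
#'   \code{protein}, \code{residue}, \code{position}, \code{multiplicity}
#'   (number of phospho-residues on the peptide), \code{ambiguous} (TRUE when
#'   the peptide matched more than once). Excluded peptides are listed in
#'   attribute \code{"excluded"}.
#' @export
map_sites <- function(t, proteome) {
  peps <- if (inherits(t, "fragment_table")) t$peptides else t
  out <- vector("list", nrow(peps))
  excluded <- character()
  for (i in seq_len(nrow(peps))) {
    acc <- peps$protein[i]
    seqp <- proteome[[acc]]
    if (is.null(seqp) || is.na(seqp)) {
      excluded <- c(excluded, peps$peptide_id[i]); next
    }
    hits <- gregexpr(peps$sequence[i], seqp, fixed = TRUE)[[1]]
    if (hits[1] == -1) {
      excluded <- c(excluded, peps$peptide_id[i]); next
    }
    start <- hits[1]
    offs <- as.integer(strsplit(as.character(peps$offsets[i]), ",", fixed = TRUE)[[1]])
    pos <- start + offs - 1L
    out[[i]] <- data.frame(
      peptide_id = peps$peptide_id[i], protein = acc,
      residue = vapply(pos, function(p) substr(seqp, p, p), character(1)),
      position = pos, multiplicity = length(offs),
      ambiguous = length(hits) > 1,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(peptide_id = character(), protein = character(),
                      residue = character(), position = integer(),
                      multiplicity = integer(), ambiguous = logical())
  }
  if (length(excluded)) {
    warnf("%d peptide(s) not found in their stated protein were excluded: %s",
          length(excluded), paste(head(excluded, 5), collapse = ", "))
  }
  attr(res, "excluded") <- excluded
  res
}

#' Per-treatment phosphosite differential abundance
#'
#' Rolls fragments up to peptides (summed fragment intensity per sample), maps
#' peptides to phosphosites, and computes per site: log2 fold change (mean
#' log2 summed signal, treatment minus control), a raw p value from a
#' two-sample Welch t-test on the log2 replicate values, and
#' Benjamini-Hochberg adjusted FDR across the sites of the treatment. When
#' both groups have zero variance the t-test degenerates: p is 1 for equal
#' means and 0 otherwise (documented convention). Rows are per (peptide, site);
#' use \code{\link{collapse_duplicate_sites}} to enforce one row per site.
#'
#' @param t A \code{fragment_table}, typically filtered and imputed.
#' @param sites Site map from \code{\link{map_sites}}.
#' @param treatment Treatment condition label.
#' @param control Control condition label (defaults to the table's control).
#' @return A \code{diff_table} data.frame: \code{peptide_id}, \code{protein},
#'   \code{residue}, \code{position}, \code{multiplicity}, \code{treatment},
#'   \code{log2fc}, \code{p}, \code{fdr}, \code{mean_control}.
#' @export
differential <- function(t, sites, treatment, control = t$control) {
  stopifnot(inherits(t, "fragment_table"))
  d <- t$data
  for (lab in c(treatment, control)) {
    reps <- unique(d$replicate[d$condition == lab])
    if (length(reps) < 2) stopf("condition '%s' has fewer than 2 replicates", lab)
  }
  d <- d[d$condition %in% c(treatment, control), , drop = FALSE]
  # peptide-level signal: sum of fragment intensities per sample
  agg <- stats::aggregate(intensity ~ peptide_id + sample + condition,
                          data = d, FUN = sum, na.rm = TRUE, na.action = stats::na.pass)
  agg$log2s <- log2(agg$intensity)
  rows <- lapply(unique(agg$peptide_id), function(pep) {
    a <- agg[agg$peptide_id == pep, ]
    xt <- a$log2s[a$condition == treatment]
    xc <- a$log2s[a$condition == control]
    xt <- xt[is.finite(xt)]; xc <- xc[is.finite(xc)]
    if (length(xt) < 2 || length(xc) < 2) return(NULL)
    lfc <- mean(xt) - mean(xc)
    p <- welch_p(xt, xc)
    data.frame(peptide_id = pep, log2fc = lfc, p = p,
               mean_control = mean(2^xc), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(peptide_id = character(), log2fc = numeric(),
                      p = numeric(), mean_control = numeric())
  }
  out <- merge(sites[c("peptide_id", "protein", "residue", "position", "multiplicity")],
               res, by = "peptide_id")
  out$treatment <- treatment
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(out$protein, out$position, out$peptide_id),
             c("peptide_id", "protein", "residue", "position", "multiplicity",
               "treatment", "log2fc", "p", "fdr", "mean_control")]
  rownames(out) <- NULL
  class(out) <- c("diff_table", "data.frame")
  out
}

# Two-sample Welch t-test p value on log2 replicate values, with an explicit
# degenerate branch when the pooled variance is zero.
welch_p <- function(x, y) {
  vx <- var(x); vy <- var(y)
  if (vx + vy == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  se2 <- vx / length(x) + vy / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                 vy^2 / (length(y)^2 * (length(y) - 1)))
  2 * pt(-abs(tstat), df)
}

#' Collapse peptides mapping to the same phosphosite
#'
#' When several phosphopeptides map to one site, the peptide with the higher
#' mean control signal is kept; exact ties are broken by the lexicographically
#' smallest peptide id. FDR is recomputed (Benjamini-Hochberg, within
#' treatment) over the retained rows so the adjusted values always refer to
#' the reported site set.
#'
#' @param d A \code{diff_table} from \code{\link{differential}}.
#' @return A \code{diff_table} with exactly one row per site per treatment.
#' @export
collapse_duplicate_sites <- function(d) {
  stopifnot(inherits(d, "data.frame"))
  if (nrow(d) == 0) return(d)
  key <- paste(d$treatment, d$protein, d$residue, d$position, sep = "\r")
  ord <- order(key, -d$mean_control, d$peptide_id)
  d2 <- d[ord, , drop = FALSE]
  d2 <- d2[!duplicated(key[ord]), , drop = FALSE]
  for (tr in unique(d2$treatment)) {
    sel <- d2$treatment == tr
    d2$fdr[sel] <- p.adjust(d2$p[sel], method = "BH")
  }
  d2 <- d2[order(d2$protein, d2$position, d2$treatment), , drop = FALSE]
  rownames(d2) <- NULL
  class(d2) <- c("diff_table", "data.frame")
  d2
}

#' @export
print.diff_table <- function(x, ...) {
  cat(sprintf("<diff_table> %d site records, treatments: %s\n", nrow(x),
              paste(unique(x$treatment), collapse = ", ")))
  NextMethod()
}
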