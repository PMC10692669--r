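#' Signed site scores from a differential table
#'
#' Converts per-site differential statistics into the signed input scores used
#' for site-centric enrichment: \code{sign(log2FC) * -log10(max(FDR, floor))}.
#' A zero fold change gives a zero score regardless of FDR; the floor keeps
#' scores finite when FDR underflows.
#'
#' @param d A \code{diff_table} (one row per site per treatment; collapse
#'   duplicates first).
#' @param fdr_floor Positive lower bound applied to FDR before the log10.
#' @return data.frame with columns \code{site} (\code{"ACC;S473"}),
#'   \code{protein}, \code{residue}, \code{position}, \code{multiplicity},
#'   \code{treatment}, \code{score}.
#' @export
score_sites <- function(d, fdr_floor = 1e-10) {
  stopifnot(fdr_floor > 0)
  score <- sign(d$log2fc) * -log10(pmax(d$fdr, fdr_floor))
  data.frame(site = site_id(d$protein, d$residue, d$position),
             protein = d$protein, residue = d$residue, position = d$position,
             multiplicity = if ("multiplicity" %in% names(d)) d$multiplicity else 1L,
             treatment = d$treatment, score = score,
             stringsAsFactors = FALSE)
}

#' Demultiplex multiply-phosphorylated records to single sites
#'
#' Records derived from peptides carrying several phospho-residues are
#' expanded so each constituent single site carries the parent score. When an
#' expanded record collides with an existing single-site record (or another
#' expansion) on the same site, the record with the larger absolute score is
#' kept; exact ties keep the record that comes first in site order.
#'
#' @param scores Score table from \code{\link{score_sites}}.
#' @return Score table with one record per site (per treatment).
#' @export
demultiplex <- function(scores) {
  if (!"multiplicity" %in% names(scores)) scores$multiplicity <- 1L
  key <- paste(scores$treatment, scores$site, sep = "\r")
  ord <- order(key, -abs(scores$score))
  out <- scores[ord, , drop = FALSE]
  out <- out[!duplicated(key[ord]), , drop = FALSE]
  out$multiplicity <- 1L
  rownames(out) <- NULL
  out
}

# Running-sum enrichment score. Sites are ranked by descending score; member
# sites add dir * |score|^weight (normalized by the total member weight), and
# each non-member position subtracts an equal share of the signed member total
# so the running statistic ends at zero. es_type "area" returns the mean of
# the running statistic over all rank positions (signed area under the
# running enrichment score); "max" returns the classic maximum-deviation KS
# statistic.
running_es <- function(s_ranked, member_pos, dir_sign, weight = 1,
                       es_type = c("area", "max")) {
  es_type <- match.arg(es_type)
  n <- length(s_ranked)
  m <- length(member_pos)
  w <- abs(s_ranked[member_pos])^weight
  nr <- sum(w)
  contrib <- if (nr > 0) dir_sign * w / nr else rep(0, m)
  t0 <- sum(contrib)
  x <- rep(if (n > m) -t0 / (n - m) else 0, n)
  x[member_pos] <- contrib
  res <- cumsum(x)
  if (es_type == "area") mean(res) else res[which.max(abs(res))]
}

# O(m) evaluation of the area-type ES (used for permutations).
area_es_fast <- function(s_ranked, member_pos, dir_sign, weight = 1) {
  n <- length(s_ranked)
  m <- length(member_pos)
  w <- abs(s_ranked[member_pos])^weight
  nr <- sum(w)
  contrib <- if (nr > 0) dir_sign * w / nr else rep(0, m)
  t0 <- sum(contrib)
  tail_w <- n - member_pos + 1
  s_all <- n * (n + 1) / 2
  dec <- if (n > m) t0 / (n - m) else 0
  (sum(contrib * tail_w) - dec * (s_all - sum(tail_w))) / n
}

#' Site-centric signed enrichment against directional signatures
#'
#' Ranks all scored sites by descending signed score and computes, per
#' signature, a running-sum enrichment statistic in which down-direction
#' signature sites contribute with flipped sign (the global ranking is not
#' altered). The enrichment score (ES) is by default the signed area under the
#' running statistic (its mean over all rank positions); the classic
#' maximum-deviation statistic is available via \code{es_type = "max"}.
#' Significance comes from site-label permutations: the normalized enrichment
#' score (NES) divides ES by the mean |ES| of permutations with the same sign,
#' and the permutation p value is the fraction of same-sign permutations with
#' |ES| at least the observed. FDR is Benjamini-Hochberg, by default within
#' each signature category.
#'
#' @param scores Score table (columns \code{site}, \code{score}) for one
#'   treatment; see \code{\link{score_sites}} and \code{\link{demultiplex}}.
#' @param db A \code{signature_db} (columns \code{signature}, \code{category},
#'   \code{site}, \code{direction}).
#' @param n_perm Number of site-label permutations (>= 100); the reference
#'   analysis scale is 1e5, the default 1000 is desk scale and recorded in the
#'   output attributes.
#' @param weight Exponent on |score| for member increments.
#' @param min_overlap Minimum number of measured signature sites; signatures
#'   below it are absent from the output.
#' @param seed Integer seed for the permutations.
#' @param es_type \code{"area"} (default) or \code{"max"}.
#' @param fdr_by \code{"category"} (default) or \code{"global"}.
#' @return An \code{enrichment_result} data.frame: \code{signature},
#'   \code{category}, \code{es}, \code{nes}, \code{p}, \code{fdr},
#'   \code{overlap}, \code{note}. Attributes record n_perm, es_type and seed.
#' @export
enrich <- function(scores, db, n_perm = 1000, weight = 1, min_overlap = 2,
                   seed = 1, es_type = c("area", "max"),
                   fdr_by = c("category", "global")) {
  es_type <- match.arg(es_type)
  fdr_by <- match.arg(fdr_by)
  stopifnot(nrow(scores) > 0, n_perm >= 100)
  if (anyDuplicated(scores$site)) {
    stopf("duplicate sites in the score table; demultiplex/collapse first")
  }
  ord <- order(-scores$score, scores$site)
  s_ranked <- scores$score[ord]
  site_rank <- stats::setNames(seq_along(ord), scores$site[ord])
  n <- length(s_ranked)

  sigs <- split(db[c("site", "direction")], db$signature)
  cat_of <- tapply(db$category, db$signature, `[`, 1)

  rows <- with_seed(seed, {
    lapply(names(sigs), function(sg) {
      sdf <- sigs[[sg]]
      sdf <- sdf[!duplicated(sdf$site), , drop = FALSE]
      hit <- sdf$site %in% names(site_rank)
      m <- sum(hit)
      if (m < min_overlap) return(NULL)
      pos <- unname(site_rank[sdf$site[hit]])
      dirs <- ifelse(sdf$direction[hit] == "d", -1, 1)
      es <- running_es(s_ranked, pos, dirs, weight, es_type)
      perm <- numeric(n_perm)
      if (es_type == "area") {
        for (b in seq_len(n_perm)) {
          perm[b] <- area_es_fast(s_ranked, sample.int(n, m), dirs, weight)
        }
      } else {
        for (b in seq_len(n_perm)) {
          perm[b] <- running_es(s_ranked, sort(sample.int(n, m)), dirs, weight, es_type)
        }
      }
      note <- ""
      if (es == 0) {
        nes <- 0; p <- 1
      } else {
        same <- perm[sign(perm) == sign(es)]
        if (!length(same)) {
          nes <- NA_real_; p <- NA_real_
          note <- "no same-sign permutations; NES undefined"
        } else {
          nes <- es / mean(abs(same))
          p <- sum(abs(same) >= abs(es)) / length(same)
          p <- max(p, 1 / length(same))
        }
      }
      data.frame(signature = sg, category = unname(cat_of[sg]), es = es,
                 nes = nes, p = p, overlap = m, note = note,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(signature = character(), category = character(),
                      es = numeric(), nes = numeric(), p = numeric(),
                      overlap = integer(), note = character())
  }
  out$fdr <- NA_real_
  if (nrow(out)) {
    if (fdr_by == "category") {
      for (cc in unique(out$category)) {
        sel <- out$category == cc
        out$fdr[sel] <- p.adjust(out$p[sel], method = "BH")
      }
    } else {
      out$fdr <- p.adjust(out$p, method = "BH")
    }
  }
  out <- out[order(out$category, out$signature),
             c("signature", "category", "es", "nes", "p", "fdr", "overlap", "note")]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            n_perm = n_perm, es_type = es_type, weight = weight, seed = seed)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d signatures (%s statistic, %d permutations)\n",
              nrow(x), attr(x, "es_type"), attr(x, "n_perm")))
  NextMethod()
}
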